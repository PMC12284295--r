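#' Detect runs of homozygosity in one sample
#'
#' Direct implementation of the stated criteria: a run is a maximal chain of
#' consecutive homozygous calls (no intervening heterozygous call) in which
#' adjacent supporting SNPs are at most `max_gap` bp apart, reported when its
#' span is at least `min_length` bp and it contains at least `min_snps`
#' supporting SNPs.  Missing genotypes neither support nor break a chain but
#' do count toward the gap between supporting SNPs.  Run coordinates span
#' the first to the last supporting SNP and are reported half-open
#' (`start` = first SNP position - 1, `end` = last SNP position).
#'
#' @param x A `variant_table`.
#' @param sample Sample id.
#' @param min_length Minimum span in bp (from first to last supporting SNP,
#'   inclusive).
#' @param min_snps Minimum number of supporting SNPs.
#' @param max_gap Maximum distance between adjacent supporting SNPs in bp.
#' @return data.frame `sample, scaffold, start, end, n_snps`.
#' @export
detect_roh <- function(x, sample, min_length = 50000, min_snps = 25,
                       max_gap = 50000) {
  stopifnot(inherits(x, "variant_table"), sample %in% sample_names(x))
  gt <- x$gt[, sample]
  out <- list()
  for (sc in unique(x$sites$scaffold)) {
    here <- x$sites$scaffold == sc
    pos <- x$sites$pos[here]
    g <- gt[here]
    ord <- order(pos)
    pos <- pos[ord]; g <- g[ord]
    chain <- numeric()
    flush <- function(chain) {
      if (length(chain) >= min_snps &&
          (chain[length(chain)] - chain[1] + 1) >= min_length)
        data.frame(sample = sample, scaffold = sc, start = chain[1] - 1,
                   end = chain[length(chain)], n_snps = length(chain),
                   stringsAsFactors = FALSE)
      else NULL
    }
    for (i in seq_along(pos)) {
      if (is.na(g[i])) next                      # missing: neutral
      if (g[i] == 1) {                           # het breaks the chain
        out[[length(out) + 1L]] <- flush(chain)
        chain <- numeric()
      } else {                                   # hom supports
        if (length(chain) && pos[i] - chain[length(chain)] > max_gap) {
          out[[length(out) + 1L]] <- flush(chain)
          chain <- numeric()
        }
        chain <- c(chain, pos[i])
      }
    }
    out[[length(out) + 1L]] <- flush(chain)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(), scaffold = character(),
                      start = numeric(), end = numeric(), n_snps = integer())
  rownames(res) <- NULL
  res
}

#' Detect runs of homozygosity for all samples
#'
#' @param x A `variant_table`.
#' @param ... Passed to [detect_roh()].
#' @return Row-bound run table across samples.
#' @export
detect_roh_all <- function(x, ...) {
  do.call(rbind, lapply(sample_names(x), function(s) detect_roh(x, s, ...)))
}

.runs_to_granges <- function(runs) {
  GenomicRanges::GRanges(runs$scaffold,
                         IRanges::IRanges(runs$start + 1L, runs$end))
}

.granges_to_df <- function(gr) {
  data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Lineage-consensus runs of homozygosity
#'
#' Merges the runs of all individuals of a lineage (overlapping or bookended
#' runs coalesce) into candidate intervals and keeps a candidate only when
#' every individual of the lineage has at least one run overlapping it.
#'
#' @param runs Run table (as from [detect_roh_all()]) with a `sample`
#'   column.
#' @param samples Sample ids constituting the lineage.
#' @return data.frame `scaffold, start, end` (0-based half-open) of
#'   consensus intervals.
#' @export
lineage_consensus <- function(runs, samples) {
  if (length(samples) == 0) stop("lineage with 0 individuals")
  runs <- runs[runs$sample %in% samples, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric()))
  all_gr <- GenomicRanges::reduce(.runs_to_granges(runs))
  keep <- rep(TRUE, length(all_gr))
  for (s in samples) {
    sgr <- .runs_to_granges(runs[runs$sample == s, , drop = FALSE])
    keep <- keep & GenomicRanges::countOverlaps(all_gr, sgr) > 0
  }
  .granges_to_df(all_gr[keep])
}

#' Substrain-specific runs of homozygosity
#'
#' Intersects the lineage-consensus intervals across every lineage of each
#' substrain, then subtracts (at bp resolution) anything overlapping a
#' consensus interval of the other substrain.
#'
#' @param consensus_by_lineage Named list of consensus tables (one per
#'   lineage, as from [lineage_consensus()]).
#' @param substrain_map Named character vector mapping lineage name to
#'   substrain.
#' @param substrains The two substrains to contrast.
#' @return Named list (one element per substrain) of specific-interval
#'   tables `scaffold, start, end`.
#' @export
substrain_specific_roh <- function(consensus_by_lineage, substrain_map,
                                   substrains = c("FS", "PH")) {
  grs <- lapply(consensus_by_lineage, function(d)
    GenomicRanges::GRanges(d$scaffold, IRanges::IRanges(d$start + 1L, d$end)))
  per_ss <- lapply(substrains, function(ss) {
    lins <- names(substrain_map)[substrain_map == ss]
    lins <- intersect(lins, names(grs))
    if (!length(lins)) return(GenomicRanges::GRanges())
    Reduce(GenomicRanges::intersect, grs[lins])
  })
  names(per_ss) <- substrains
  union_of <- function(ss) {
    lins <- names(substrain_map)[substrain_map == ss]
    lins <- intersect(lins, names(grs))
    if (!length(lins)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(grs[lins])))
  }
  out <- list()
  out[[substrains[1]]] <-
    .granges_to_df(GenomicRanges::setdiff(per_ss[[1]], union_of(substrains[2])))
  out[[substrains[2]]] <-
    .granges_to_df(GenomicRanges::setdiff(per_ss[[2]], union_of(substrains[1])))
  out
}

#' GC content inside and outside intervals
#'
#' Computes (G+C)/(A+C+G+T) over the interval bases and over their
#' complement, per scaffold and pooled; ambiguous bases are excluded from
#' the denominator.
#'
#' @param fasta Path to a FASTA file or a `DNAStringSet`.
#' @param intervals data.frame `scaffold, start, end` (0-based half-open).
#' @return data.frame `scaffold, region (inside/outside), gc, n_bases`,
#'   including pooled rows with scaffold `"all"`.
#' @export
gc_content <- function(fasta, intervals) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  count_gc <- function(dna_parts) {
    if (length(dna_parts) == 0) return(c(gc = 0, acgt = 0))
    freq <- Biostrings::letterFrequency(dna_parts, c("G", "C", "A", "T"))
    tot <- colSums(freq)
    c(gc = tot[["G"]] + tot[["C"]], acgt = sum(tot))
  }
  rows <- list()
  tot_in <- c(gc = 0, acgt = 0)
  tot_out <- c(gc = 0, acgt = 0)
  for (sc in names(seqs)) {
    len <- length(seqs[[sc]])
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(pmin(iv$start + 1, len),
                                           pmin(iv$end, len)))
    ir <- ir[IRanges::width(ir) > 0]
    comp <- IRanges::setdiff(IRanges::IRanges(1, len), ir)
    inside <- count_gc(Biostrings::DNAStringSet(seqs[[sc]],
                                                start = IRanges::start(ir),
                                                end = IRanges::end(ir)))
    outside <- count_gc(Biostrings::DNAStringSet(seqs[[sc]],
                                                 start = IRanges::start(comp),
                                                 end = IRanges::end(comp)))
    tot_in <- tot_in + inside
    tot_out <- tot_out + outside
    rows[[sc]] <- data.frame(
      scaffold = sc, region = c("inside", "outside"),
      gc = c(ifelse(inside[["acgt"]] > 0, inside[["gc"]] / inside[["acgt"]], NA),
             ifelse(outside[["acgt"]] > 0, outside[["gc"]] / outside[["acgt"]], NA)),
      n_bases = c(inside[["acgt"]], outside[["acgt"]]),
      stringsAsFactors = FALSE)
  }
  rows[["all"]] <- data.frame(
    scaffold = "all", region = c("inside", "outside"),
    gc = c(ifelse(tot_in[["acgt"]] > 0, tot_in[["gc"]] / tot_in[["acgt"]], NA),
           ifelse(tot_out[["acgt"]] > 0, tot_out[["gc"]] / tot_out[["acgt"]], NA)),
    n_bases = c(tot_in[["acgt"]], tot_out[["acgt"]]),
    stringsAsFactors = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
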