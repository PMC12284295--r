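#' Read a multi-sample VCF and its sample metadata
#'
#' Parses a VCFv4.2 file with `GT`, `AD`, `DP` and `GQ` FORMAT fields into a
#' [variant_table()] and validates the accompanying metadata table against
#' the VCF sample columns.  Multiallelic records are excluded by default
#' (the analyses are defined on biallelic allele frequencies) or split into
#' one biallelic record per alternate allele with `multiallelic = "split"`.
#' Missing FORMAT values become missing calls.
#'
#' @param vcf_path Path to a (plain-text) VCF file.
#' @param metadata_path Path to a tab-separated metadata table with header
#'   `sample_id lineage substrain generation parent offspring_type`.  Every
#'   VCF sample must appear in it.
#' @param multiallelic `"drop"` (default) or `"split"`.
#' @return A list with elements `table` (a `variant_table`) and `pedigree`
#'   (the metadata rows for the VCF samples, in VCF column order).
#' @export
read_vcf <- function(vcf_path, metadata_path, multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, "GT", convertNA = TRUE)
  ad_raw <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  samples <- colnames(gt_raw)

  meta <- read_metadata(metadata_path)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    stop("VCF sample(s) absent from metadata: ", paste(missing, collapse = ", "))
  pedigree <- meta[match(samples, meta$sample_id), , drop = FALSE]
  rownames(pedigree) <- NULL
  validate_pedigree(pedigree)

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  rows <- which(!multi)
  alt_index <- rep(1L, length(rows))
  if (multiallelic == "split" && any(multi)) {
    for (r in which(multi)) {
      alts <- strsplit(alt[r], ",", fixed = TRUE)[[1]]
      rows <- c(rows, rep(r, length(alts)))
      alt_index <- c(alt_index, seq_along(alts))
    }
    ord <- order(rows, alt_index)
    rows <- rows[ord]
    alt_index <- alt_index[ord]
  }

  ## dosage of alternate allele k, computed per unique genotype string
  gt_dosage <- function(strings, k) {
    u <- unique(strings)
    dos <- vapply(strsplit(gsub("|", "/", u, fixed = TRUE), "/", fixed = TRUE),
                  function(al) {
                    if (length(al) != 2L || any(al == ".") || any(is.na(al)))
                      return(NA_integer_)
                    sum(al == as.character(k))
                  }, integer(1))
    dos[match(strings, u)]
  }
  ad_field <- function(strings, k) {
    parts <- strsplit(strings, ",", fixed = TRUE)
    ref <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
    altd <- suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) < k + 1L) NA_character_ else p[k + 1L], character(1))))
    list(ref = ref, alt = altd)
  }

  n <- length(rows)
  gt <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
  ad_ref <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  ad_alt <- ad_ref
  for (k in unique(alt_index)) {
    sel <- alt_index == k
    rsel <- rows[sel]
    gt[sel, ] <- gt_dosage(as.vector(gt_raw[rsel, , drop = FALSE]), k)
    ad <- ad_field(as.vector(ad_raw[rsel, , drop = FALSE]), k)
    ad_ref[sel, ] <- ad$ref
    ad_alt[sel, ] <- ad$alt
  }
  alts <- vapply(seq_len(n), function(i)
    strsplit(alt[rows[i]], ",", fixed = TRUE)[[1]][alt_index[i]], character(1))
  sites <- data.frame(scaffold = fix[rows, "CHROM"],
                      pos = as.integer(fix[rows, "POS"]),
                      ref = fix[rows, "REF"], alt = alts,
                      id = ifelse(is.na(fix[rows, "ID"]) | fix[rows, "ID"] == ".",
                                  paste0(fix[rows, "CHROM"], ":", fix[rows, "POS"],
                                         "_", alts),
                                  fix[rows, "ID"]),
                      stringsAsFactors = FALSE)
  dpm <- matrix(as.numeric(dp[rows, , drop = FALSE]), n, length(samples),
                dimnames = list(NULL, samples))
  gqm <- matrix(as.numeric(gq[rows, , drop = FALSE]), n, length(samples),
                dimnames = list(NULL, samples))
  tab <- variant_table(sites, gt, ad_ref, ad_alt, dpm, gqm)
  list(table = tab, pedigree = pedigree)
}

#' Read a sample metadata / pedigree table
#'
#' @param path Tab-separated file with header
#'   `sample_id lineage substrain generation parent offspring_type`.
#' @return data.frame with those columns (`parent` is `NA` for founders).
#' @export
read_metadata <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  need <- c("sample_id", "lineage", "substrain", "generation", "parent",
            "offspring_type")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  meta
}

#' Validate pedigree structure
#'
#' Checks that parent links form a forest (no cycles, parents known) and that
#' the substrain label is consistent within each lineage.
#'
#' @param pedigree data.frame as returned by [read_metadata()].
#' @return The pedigree, invisibly; errors on violation.
#' @export
validate_pedigree <- function(pedigree) {
  known <- pedigree$parent %in% pedigree$sample_id | is.na(pedigree$parent)
  if (!all(known))
    stop("unknown parent sample(s): ",
         paste(unique(pedigree$parent[!known]), collapse = ", "))
  ## cycle check by iterated parent lookup
  parent <- setNames(pedigree$parent, pedigree$sample_id)
  for (s in pedigree$sample_id) {
    seen <- character()
    p <- s
    while (!is.na(p)) {
      if (p %in% seen) stop("pedigree contains a cycle through ", p)
      seen <- c(seen, p)
      p <- parent[[p]]
    }
  }
  by_lin <- split(pedigree$substrain, pedigree$lineage)
  bad <- names(by_lin)[vapply(by_lin, function(x) length(unique(x)) > 1, logical(1))]
  if (length(bad))
    stop("substrain not consistent within lineage(s): ", paste(bad, collapse = ", "))
  invisible(pedigree)
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open); an empty file yields an empty
#'   set of ranges.
#' @return A `GRanges` (1-based internally).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges())
  bed <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED file: ", path, " (", conditionMessage(e), ")"))
  if (ncol(bed) < 3 || !is.numeric(bed[[2]]) || !is.numeric(bed[[3]]) ||
      any(bed[[3]] < bed[[2]]))
    stop("malformed BED file: ", path)
  GenomicRanges::GRanges(bed[[1]], IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
}

#' Read a reproduction-event log
#'
#' @param path Tab-separated log with header `worm_id parent_id birth_date
#'   event_date event_type offspring_id offspring_type`.
#' @return data.frame of reproduction records.
#' @export
read_repro_log <- function(path) {
  log <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  need <- c("worm_id", "parent_id", "birth_date", "event_date", "event_type",
            "offspring_id", "offspring_type")
  if (!all(need %in% names(log)))
    stop("reproduction log must contain columns: ", paste(need, collapse = ", "))
  if (!all(log$event_type %in% c("division", "death")))
    stop("event_type must be 'division' or 'death'")
  log
}

#' Apply the downstream site filters
#'
#' Retains a site only if (i) in every sample the depth lies within
#' `depth_band` times that sample's mean depth, (ii) the pooled
#' alternate-allele frequency across called genotypes does not exceed
#' `af_max` (strict `>` removes; an all-heterozygous site at pooled frequency
#' exactly 0.5 is retained), and (iii) the site does not overlap the repeat
#' intervals.  Missing depths or sites with no called genotype fail.  The
#' depth band uses the per-sample mean stored in the table, so the filter is
#' idempotent.
#'
#' @param x A `variant_table`.
#' @param repeat_bed Optional `GRanges` (e.g. from [read_bed()]) of
#'   repetitive regions.
#' @param depth_band Length-2 multiplier band around the per-sample mean
#'   depth.
#' @param af_max Pooled alternate-allele frequency ceiling.
#' @return The filtered `variant_table` (site order preserved).
#' @export
apply_site_filters <- function(x, repeat_bed = NULL, depth_band = c(0.5, 2),
                               af_max = 0.5) {
  stopifnot(inherits(x, "variant_table"))
  if (nrow(x$sites) == 0) return(x)
  lo <- matrix(depth_band[1] * x$mean_depth, nrow(x$dp), ncol(x$dp), byrow = TRUE)
  hi <- matrix(depth_band[2] * x$mean_depth, nrow(x$dp), ncol(x$dp), byrow = TRUE)
  ok_dp <- x$dp >= lo & x$dp <= hi
  ok_dp[is.na(ok_dp)] <- FALSE
  keep <- rowSums(ok_dp) == ncol(x$dp)

  n_called <- rowSums(!is.na(x$gt))
  af <- rowSums(x$gt, na.rm = TRUE) / (2 * n_called)
  keep <- keep & n_called > 0 & af <= af_max

  if (!is.null(repeat_bed) && length(repeat_bed) > 0) {
    hits <- GenomicRanges::countOverlaps(.site_ranges(x), repeat_bed)
    keep <- keep & hits == 0
  }
  subset_sites(x, keep)
}

#' Restrict to confidently genotyped sites
#'
#' Keeps only sites genotyped with GQ strictly above `gq_min` in every
#' sample (missing GQ fails).
#'
#' @param x A `variant_table`.
#' @param gq_min Genotype-quality threshold (strict `>`).
#' @return The filtered `variant_table`.
#' @export
genotype_confident_subset <- function(x, gq_min = 20) {
  stopifnot(inherits(x, "variant_table"))
  ok <- x$gq > gq_min
  ok[is.na(ok)] <- FALSE
  subset_sites(x, rowSums(ok) == ncol(x$gq))
}
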