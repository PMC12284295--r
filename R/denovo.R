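## callable = depth within the per-sample band around the stored mean depth
.callable_matrix <- function(x, depth_band = c(0.5, 2)) {
  lo <- matrix(depth_band[1] * x$mean_depth, nrow(x$dp), ncol(x$dp), byrow = TRUE)
  hi <- matrix(depth_band[2] * x$mean_depth, nrow(x$dp), ncol(x$dp), byrow = TRUE)
  ok <- x$dp >= lo & x$dp <= hi
  ok[is.na(ok)] <- FALSE
  ok
}

#' Transitive descendants of a sample in a pedigree
#'
#' @param pedigree Sample metadata with `sample_id` and `parent`.
#' @param sample Focal sample id.
#' @return Character vector of all descendants (children, grandchildren,
#'   ...), excluding the sample itself.
#' @export
descendants <- function(pedigree, sample) {
  out <- character()
  frontier <- sample
  while (length(frontier)) {
    kids <- pedigree$sample_id[!is.na(pedigree$parent) &
                                 pedigree$parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Call newly detected mutations in a focal sample
#'
#' Pedigree-aware candidate filter: a site is a newly detected mutation of
#' the focal worm when (i) the focal carries it (non-hom-ref call), (ii) its
#' parent is called hom-ref, (iii) every other library in the table is
#' called hom-ref -- excluding the focal's descendants, transitively, since
#' a genuine new mutation may be passed on, (iv) the locus is absent from
#' all supplied external exclusion sets, (v) the site is callable (depth
#' within the per-sample band) in every library, (vi) no other surviving
#' candidate of the same focal lies within `cluster_bp` on the same scaffold
#' (both members of any such pair are removed), and (vii) the locus lies
#' within gene bodies and outside repeats when those interval sets are
#' supplied.
#'
#' @param x A `variant_table`.
#' @param pedigree Sample metadata with `sample_id`, `parent`, `generation`,
#'   `lineage`.
#' @param focal Focal sample id; its parent must be in the table.
#' @param exclusion_sets List of data.frames with `scaffold`/`pos` columns
#'   (external variant sets to exclude).
#' @param cluster_bp Minimum allowed distance between candidates.
#' @param genes_bed,repeats_bed Optional `GRanges` of gene bodies /
#'   repetitive regions.
#' @param depth_band Callable depth band as multiplier of per-sample mean.
#' @param min_support Allele-support gate for the reported AF.
#' @return data.frame `site_id, scaffold, pos, ref, alt, focal, lineage,
#'   generation, af` (one row per call).
#' @export
call_newly_detected <- function(x, pedigree, focal, exclusion_sets = list(),
                                cluster_bp = 150, genes_bed = NULL,
                                repeats_bed = NULL, depth_band = c(0.5, 2),
                                min_support = 10) {
  stopifnot(inherits(x, "variant_table"))
  row <- pedigree[pedigree$sample_id == focal, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown focal sample: ", focal)
  parent <- row$parent
  if (is.na(parent) || !parent %in% sample_names(x))
    stop("focal sample ", focal, " has no sequenced parent")

  cm <- .carrier_matrix(x, "any")
  cand <- cm[, focal] & !is.na(x$gt[, parent]) & x$gt[, parent] == 0

  exempt <- c(focal, descendants(pedigree, focal))
  others <- setdiff(sample_names(x), exempt)
  g_others <- x$gt[, others, drop = FALSE]
  cand <- cand & rowSums(g_others == 0, na.rm = TRUE) == length(others)

  for (ex in exclusion_sets) {
    key <- paste0(x$sites$scaffold, ":", x$sites$pos)
    cand <- cand & !(key %in% paste0(ex$scaffold, ":", ex$pos))
  }

  cand <- cand & rowSums(.callable_matrix(x, depth_band)) == ncol(x$gt)

  loci <- .site_ranges(x)
  if (!is.null(genes_bed))
    cand <- cand & GenomicRanges::countOverlaps(loci, genes_bed) > 0
  if (!is.null(repeats_bed) && length(repeats_bed))
    cand <- cand & GenomicRanges::countOverlaps(loci, repeats_bed) == 0

  ## symmetric cluster removal among surviving candidates
  idx <- which(cand)
  if (length(idx) > 1) {
    drop <- logical(length(idx))
    sc <- x$sites$scaffold[idx]
    ps <- x$sites$pos[idx]
    for (i in seq_along(idx)) {
      near <- sc == sc[i] & abs(ps - ps[i]) <= cluster_bp
      near[i] <- FALSE
      if (any(near)) drop[i] <- TRUE
    }
    idx <- idx[!drop]
  }

  af <- allele_frequency(x$ad_ref[idx, focal], x$ad_alt[idx, focal],
                         min_support)
  data.frame(site_id = x$sites$id[idx], scaffold = x$sites$scaffold[idx],
             pos = x$sites$pos[idx], ref = x$sites$ref[idx],
             alt = x$sites$alt[idx], focal = rep(focal, length(idx)),
             lineage = rep(row$lineage, length(idx)),
             generation = rep(row$generation, length(idx)),
             af = as.numeric(af), stringsAsFactors = FALSE)
}

#' Call newly detected mutations for every sample with a sequenced parent
#'
#' @param x A `variant_table`.
#' @param pedigree Sample metadata.
#' @param ... Passed to [call_newly_detected()].
#' @return Row-bound call table across focal samples.
#' @export
call_newly_detected_all <- function(x, pedigree, ...) {
  focals <- pedigree$sample_id[!is.na(pedigree$parent) &
                                 pedigree$parent %in% sample_names(x) &
                                 pedigree$sample_id %in% sample_names(x)]
  calls <- lapply(focals, function(f) call_newly_detected(x, pedigree, f, ...))
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(site_id = character(), scaffold = character(),
                      pos = integer(), ref = character(), alt = character(),
                      focal = character(), lineage = character(),
                      generation = integer(), af = numeric())
  out
}

#' False-negative rate of heterozygous calls between parent and offspring
#'
#' Among parent sites that are called heterozygous with allele frequency in
#' `af_band` (operationalising "heterozygous in all cells", AF about 0.5)
#' and that are callable in the offspring, the fraction not called as a
#' carrier in the offspring.
#'
#' @param x A `variant_table`.
#' @param parent,offspring Sample ids.
#' @param af_band AF window around 0.5 qualifying a parental het.
#' @param depth_band Callable depth band.
#' @param min_support Allele-support gate for the parental AF.
#' @return List with `rate`, `n_missed` and `n_sites`.
#' @export
false_negative_rate <- function(x, parent, offspring, af_band = c(0.4, 0.6),
                                depth_band = c(0.5, 2), min_support = 10) {
  stopifnot(inherits(x, "variant_table"))
  af_p <- allele_frequency(x$ad_ref[, parent], x$ad_alt[, parent], min_support)
  callable <- .callable_matrix(x, depth_band)
  qualify <- !is.na(x$gt[, parent]) & x$gt[, parent] == 1 &
    !is.na(af_p) & af_p >= af_band[1] & af_p <= af_band[2] &
    callable[, offspring]
  carrier_off <- !is.na(x$gt[, offspring]) & x$gt[, offspring] >= 1
  n <- sum(qualify)
  miss <- sum(qualify & !carrier_off)
  list(rate = if (n > 0) miss / n else NA_real_, n_missed = miss, n_sites = n)
}

#' Pooled false-negative rate over all parent-offspring pairs
#'
#' @param x A `variant_table`.
#' @param pedigree Sample metadata.
#' @param ... Passed to [false_negative_rate()].
#' @return List with pooled `rate`, `n_missed`, `n_sites` and a `per_pair`
#'   data.frame.
#' @export
false_negative_rate_all <- function(x, pedigree, ...) {
  pairs <- pedigree[!is.na(pedigree$parent) &
                      pedigree$parent %in% sample_names(x) &
                      pedigree$sample_id %in% sample_names(x), , drop = FALSE]
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    fn <- false_negative_rate(x, pairs$parent[i], pairs$sample_id[i], ...)
    data.frame(parent = pairs$parent[i], offspring = pairs$sample_id[i],
               rate = fn$rate, n_missed = fn$n_missed, n_sites = fn$n_sites,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(rate = sum(per$n_missed) / sum(per$n_sites),
       n_missed = sum(per$n_missed), n_sites = sum(per$n_sites),
       per_pair = per)
}

#' Transmission fraction of newly detected mutations
#'
#' For each focal head generation with calls, the fraction of its newly
#' detected mutations that are detected again (carrier call) in the next
#' head generation of the same lineage.  Per-lineage fractions pool the
#' generations of that lineage; the overall mean and (sample, n-1) standard
#' deviation are taken across lineages.
#'
#' @param calls Call table from [call_newly_detected_all()].
#' @param x A `variant_table`.
#' @param pedigree Sample metadata; the next head generation of a focal is
#'   the sample whose `parent` is the focal.
#' @return List with `per_generation` (one row per focal with a successor:
#'   `lineage, generation, n_calls, n_transmitted, fraction`), `per_lineage`,
#'   `mean`, `sd`, and the `calls` table with a `transmitted` column (`NA`
#'   where no successor was sequenced).
#' @export
transmission_fraction <- function(calls, x, pedigree) {
  nxt <- setNames(rep(NA_character_, nrow(pedigree)), pedigree$sample_id)
  kids <- pedigree[!is.na(pedigree$parent), , drop = FALSE]
  nxt[kids$parent] <- kids$sample_id
  cm <- .carrier_matrix(x, "any")
  site_row <- match(calls$site_id, x$sites$id)
  succ <- nxt[calls$focal]
  has_succ <- !is.na(succ) & succ %in% sample_names(x)
  transmitted <- rep(NA, nrow(calls))
  transmitted[has_succ] <- cm[cbind(site_row[has_succ],
                                    match(succ[has_succ], sample_names(x)))]
  calls$transmitted <- transmitted

  meas <- calls[has_succ, , drop = FALSE]
  per_gen <- NULL
  if (nrow(meas)) {
    per_gen <- stats::aggregate(cbind(n_transmitted = transmitted) ~
                                  lineage + generation + focal,
                                data = meas, FUN = sum)
    cnt <- stats::aggregate(cbind(n_calls = transmitted) ~
                              lineage + generation + focal,
                            data = meas, FUN = length)
    per_gen <- merge(per_gen, cnt)
    per_gen$fraction <- per_gen$n_transmitted / per_gen$n_calls
    per_gen <- per_gen[order(per_gen$lineage, per_gen$generation), ]
    rownames(per_gen) <- NULL
  }
  per_lin <- NULL
  if (nrow(meas)) {
    per_lin <- stats::aggregate(
      cbind(n_transmitted = transmitted) ~ lineage, data = meas, FUN = sum)
    cnt <- stats::aggregate(cbind(n_calls = transmitted) ~ lineage,
                            data = meas, FUN = length)
    per_lin <- merge(per_lin, cnt)
    per_lin$fraction <- per_lin$n_transmitted / per_lin$n_calls
  }
  fr <- if (is.null(per_lin)) numeric() else per_lin$fraction
  list(per_generation = per_gen, per_lineage = per_lin,
       mean = if (length(fr)) mean(fr) else NA_real_,
       sd = if (length(fr) > 1) sd(fr) else NA_real_,
       calls = calls)
}

#' Per-generation mutation rate
#'
#' Newly detected mutations divided by the number of potential detection
#' sites: the callable (non-repetitive, gene-body) loci times the ploidy
#' factor.  With the study-scale inputs (111 mutations over 148,090,923
#' diploid loci) this is ~3.75e-7 per bp per generation.
#'
#' @param n_new Count of newly detected mutations.
#' @param callable_bp Callable loci (default the study-scale 148,090,923
#'   non-repetitive gene-body bp).
#' @param ploidy_factor Ploidy multiplier (2 for diploids).
#' @return List with `rate` (per bp per generation), `potential_sites`,
#'   `n_new`, `callable_bp`.
#' @examples
#' mutation_rate(111)$rate  # ~3.75e-7
#' @export
mutation_rate <- function(n_new, callable_bp = 148090923, ploidy_factor = 2) {
  stopifnot(n_new >= 0, callable_bp > 0)
  potential <- ploidy_factor * callable_bp
  list(rate = n_new / potential, potential_sites = potential,
       n_new = n_new, callable_bp = callable_bp)
}
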