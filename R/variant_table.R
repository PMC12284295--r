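#' Construct a variant table
#'
#' The central container: biallelic sites (rows) by samples (columns) with
#' per-call genotype, allele depths, total depth and genotype quality.
#' Genotypes are coded as alternate-allele dosage: 0 (hom-ref), 1 (het),
#' 2 (hom-alt), `NA` (missing).  Sites are sorted by scaffold and position at
#' construction, and the per-sample mean depth over the full (pre-filter)
#' table is stored so that downstream depth-band filters are idempotent under
#' subsetting.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt` and optionally `id`, `is_indel`.
#' @param gt Integer matrix (sites x samples) of dosages in `{0, 1, 2, NA}`.
#' @param ad_ref,ad_alt,dp,gq Numeric matrices of the same dimension:
#'   reference / alternate allele depths, total depth, genotype quality.
#' @param mean_depth Optional per-sample mean depth; computed from `dp` when
#'   omitted.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, ad_ref, ad_alt, dp, gq,
                          mean_depth = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  n <- nrow(sites)
  for (m in list(gt, ad_ref, ad_alt, dp, gq))
    stopifnot(is.matrix(m), nrow(m) == n)
  stopifnot(!is.null(colnames(gt)))
  if (is.null(sites$id))
    sites$id <- paste0(sites$scaffold, ":", sites$pos)
  if (is.null(sites$is_indel))
    sites$is_indel <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L
  bad <- which(ad_ref + ad_alt > dp)
  if (length(bad))
    stop("ad_ref + ad_alt exceeds dp for ", length(bad), " calls")
  ord <- order(sites$scaffold, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  if (anyDuplicated(sites[, c("scaffold", "pos", "alt")]))
    stop("duplicated (scaffold, pos, alt) records")
  if (is.null(mean_depth))
    mean_depth <- colMeans(dp[ord, , drop = FALSE], na.rm = TRUE)
  dn <- list(NULL, colnames(gt))
  obj <- list(sites = sites,
              gt = gt[ord, , drop = FALSE],
              ad_ref = ad_ref[ord, , drop = FALSE],
              ad_alt = ad_alt[ord, , drop = FALSE],
              dp = dp[ord, , drop = FALSE],
              gq = gq[ord, , drop = FALSE],
              mean_depth = mean_depth)
  for (m in c("gt", "ad_ref", "ad_alt", "dp", "gq"))
    dimnames(obj[[m]]) <- dn
  if (is.null(names(obj$mean_depth)))
    names(obj$mean_depth) <- colnames(gt)
  class(obj) <- "variant_table"
  obj
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$gt)))
  cat(sprintf("  scaffolds: %s\n",
              paste(unique(x$sites$scaffold), collapse = ", ")))
  cat(sprintf("  mean depth: %.1f-%.1f; %.1f%% het calls\n",
              min(x$mean_depth), max(x$mean_depth),
              100 * mean(x$gt == 1, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), ncol(x$gt))

#' Sample names of a variant table
#' @param x A `variant_table`.
#' @return Character vector of sample ids.
#' @export
sample_names <- function(x) colnames(x$gt)

#' Subset the sites of a variant table
#'
#' Row subsetting that preserves the stored per-sample mean depth (so depth
#' filters remain idempotent) and site order.
#'
#' @param x A `variant_table`.
#' @param i Logical or integer index over sites.
#' @return A `variant_table`.
#' @export
subset_sites <- function(x, i) {
  stopifnot(inherits(x, "variant_table"))
  out <- list(sites = x$sites[i, , drop = FALSE],
              gt = x$gt[i, , drop = FALSE],
              ad_ref = x$ad_ref[i, , drop = FALSE],
              ad_alt = x$ad_alt[i, , drop = FALSE],
              dp = x$dp[i, , drop = FALSE],
              gq = x$gq[i, , drop = FALSE],
              mean_depth = x$mean_depth)
  rownames(out$sites) <- NULL
  class(out) <- "variant_table"
  out
}

## GRanges of the site loci (SNPs: 1 bp; indels: the REF span)
.site_ranges <- function(x) {
  GenomicRanges::GRanges(x$sites$scaffold,
                         IRanges::IRanges(x$sites$pos,
                                          x$sites$pos + nchar(x$sites$ref) - 1L))
}
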