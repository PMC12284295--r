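#' Genotype dosage matrix
#'
#' @param x A `variant_table`.
#' @return samples x sites matrix of alternate-allele dosages (0/1/2, `NA`
#'   missing), with site ids as column names.
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  g <- t(x$gt)
  colnames(g) <- x$sites$id
  g
}

#' Greedy sliding-window LD pruning
#'
#' Within a sliding window of `window` SNPs advanced by `step` SNPs,
#' pairwise r-squared (squared Pearson correlation of dosages, missing
#' pairs deleted) is computed among the sites still kept; whenever a pair
#' exceeds `r2_max` the later site is removed.  Removed sites stay removed
#' as the window advances.  Sites with constant dosage have undefined
#' correlation, treated as 0 (kept unless paired with a violating earlier
#' site).
#'
#' @param geno samples x sites dosage matrix (see [genotype_matrix()]);
#'   sites must be in genomic order.
#' @param window,step Window size and step in SNPs.
#' @param r2_max r-squared threshold (strict `>` removes).
#' @return Integer vector of kept site indices (also named by column when
#'   the matrix has column names).
#' @export
ld_prune <- function(geno, window = 50, step = 10, r2_max = 0.1) {
  m <- ncol(geno)
  if (m == 0) return(integer())
  if (any(colMeans(is.na(geno)) == 1))
    stop("sites with 100% missing dosage cannot be pruned")
  keep <- rep(TRUE, m)
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    act <- idx[keep[idx]]
    if (length(act) < 2) next
    r2 <- suppressWarnings(cor(geno[, act, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    for (j in seq_along(act)[-1]) {
      if (!keep[act[j]]) next
      earlier <- act[seq_len(j - 1L)]
      earlier <- earlier[keep[earlier]]
      if (length(earlier) && any(r2[match(earlier, act), j] > r2_max))
        keep[act[j]] <- FALSE
    }
    if (max(idx) == m) break
  }
  which(keep)
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are imputed to the site mean, sites are mean-centred, and
#' the eigen-decomposition of the sample covariance is obtained via singular
#' value decomposition.
#'
#' @param geno samples x sites dosage matrix.
#' @param n_comp Number of components to return (capped by the rank).
#' @return List with `scores` (samples x components), `explained`
#'   (fraction of variance per returned component) and `sdev`.
#' @export
pca_genotypes <- function(geno, n_comp = 10) {
  if (nrow(geno) < 2) stop("PCA needs at least 2 samples")
  imp <- apply(geno, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    col[is.na(col)] <- mu
    col
  })
  p <- prcomp(imp, center = TRUE, scale. = FALSE)
  k <- min(n_comp, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
       sdev = p$sdev)
}

## Weir & Cockerham (1984) two-population variance components, vectorised
## over sites.  n: individuals called, p: alt allele frequency, h: observed
## heterozygote proportion, per population.
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Per-site Weir-Cockerham FST from genotype counts
#'
#' Two-population Weir & Cockerham (1984) estimator `a / (a + b + c)` from
#' genotype counts at a biallelic site.  The estimate can be negative in
#' finite samples; it is `NA` when either population has no called genotype,
#' when both populations are single individuals, or when the denominator is
#' zero (site monomorphic overall).
#'
#' @param counts1,counts2 Length-3 vectors `c(n_hom_ref, n_het, n_hom_alt)`
#'   of genotype counts in each population.
#' @return FST estimate (possibly negative) or `NA`.
#' @examples
#' fst_site(c(0, 0, 5), c(5, 0, 0))  # reciprocally fixed: 1
#' fst_site(c(0, 5, 0), c(0, 5, 0))  # all-heterozygous in both: 0
#' @export
fst_site <- function(counts1, counts2) {
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  p1 <- (counts1[2] + 2 * counts1[3]) / (2 * n1)
  p2 <- (counts2[2] + 2 * counts2[3]) / (2 * n2)
  h1 <- counts1[2] / n1
  h2 <- counts2[2] / n2
  w <- .wc_components(n1, p1, h1, n2, p2, h2)
  den <- w$a + w$b + w$c
  if (!is.finite(den) || den == 0) return(NA_real_)
  unname(w$a / den)
}

#' Per-site FST between two sample groups of a variant table
#'
#' @param x A `variant_table`.
#' @param samples1,samples2 Sample ids of the two populations.
#' @return Numeric vector of per-site FST estimates (`NA` where undefined).
#' @export
fst_sites <- function(x, samples1, samples2) {
  stopifnot(inherits(x, "variant_table"))
  g1 <- x$gt[, samples1, drop = FALSE]
  g2 <- x$gt[, samples2, drop = FALSE]
  stat <- function(g) {
    n <- rowSums(!is.na(g))
    list(n = n,
         p = ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, rowSums(g == 1, na.rm = TRUE) / n, NA_real_))
  }
  s1 <- stat(g1); s2 <- stat(g2)
  w <- .wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  den <- w$a + w$b + w$c
  out <- ifelse(s1$n > 0 & s2$n > 0 & is.finite(den) & den != 0,
                w$a / den, NA_real_)
  as.numeric(out)
}

#' Mean of per-site statistics in non-overlapping windows
#'
#' Windows are tiled from position 0 of each scaffold, half-open
#' `[start, start + window)`; a 1-based site position `pos` falls into the
#' window containing `pos - 1`.  Windows with no defined value are omitted.
#'
#' @param scaffold,pos,values Per-site scaffold, 1-based position and value.
#' @param window Window width in bp.
#' @param stat Statistic label for the output.
#' @return data.frame `scaffold, start, end, stat, value, n_variants`.
#' @export
windowed_mean <- function(scaffold, pos, values, window = 10000,
                          stat = "stat") {
  ok <- !is.na(values)
  if (!any(ok))
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), stat = character(), value = numeric(),
                      n_variants = integer()))
  start <- floor((pos[ok] - 1) / window) * window
  key <- paste0(scaffold[ok], ":", start)
  agg <- stats::aggregate(list(value = values[ok]),
                          by = list(scaffold = scaffold[ok], start = start),
                          FUN = mean)
  cnt <- stats::aggregate(list(n_variants = values[ok]),
                          by = list(scaffold = scaffold[ok], start = start),
                          FUN = length)
  out <- merge(agg, cnt, by = c("scaffold", "start"))
  out$end <- out$start + window
  out$stat <- stat
  out <- out[order(out$scaffold, out$start),
             c("scaffold", "start", "end", "stat", "value", "n_variants")]
  rownames(out) <- NULL
  out
}

#' Per-site nucleotide diversity
#'
#' Mean number of pairwise differences at a site with `n_ref` reference and
#' `n_alt` alternate called alleles: `n_ref * n_alt / choose(n, 2)`.
#'
#' @param n_ref,n_alt Called allele counts (vectorised).
#' @return Per-site diversity; `NA` when fewer than 2 alleles are called.
#' @examples
#' pi_site(2, 2)  # 4/6
#' @export
pi_site <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  ifelse(n >= 2, n_ref * n_alt / choose(n, 2), NA_real_)
}

#' Called allele counts per site within a sample group
#'
#' @param x A `variant_table`.
#' @param samples Sample ids (defaults to all).
#' @return data.frame `n_ref, n_alt` per site.
#' @export
allele_counts <- function(x, samples = sample_names(x)) {
  g <- x$gt[, samples, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  n_alt <- rowSums(g, na.rm = TRUE)
  data.frame(n_ref = 2 * n_called - n_alt, n_alt = n_alt)
}

#' Windowed nucleotide diversity
#'
#' Sum of per-site diversity in each 10-kb (by default) window divided by
#' the window length; positions without an observed variant contribute 0,
#' so empty windows have diversity 0.  Scaffold lengths determine how many
#' windows are tiled; when omitted, tiling stops at the last variant.
#'
#' @param scaffold,pos,pi_values Per-site scaffold, 1-based position and
#'   diversity (e.g. from [pi_site()]); `NA` values are treated as 0.
#' @param window Window width in bp.
#' @param scaffold_lengths Optional named vector of scaffold lengths.
#' @return data.frame `scaffold, start, end, stat, value, n_variants` with
#'   one row per tiled window.
#' @export
windowed_pi <- function(scaffold, pos, pi_values, window = 10000,
                        scaffold_lengths = NULL) {
  pi_values[is.na(pi_values)] <- 0
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(pos, scaffold, max)
  }
  out <- lapply(names(scaffold_lengths), function(sc) {
    n_win <- max(1L, ceiling(scaffold_lengths[[sc]] / window))
    starts <- (seq_len(n_win) - 1) * window
    here <- scaffold == sc
    win <- floor((pos[here] - 1) / window) + 1L
    sums <- rep(0, n_win)
    cnts <- rep(0L, n_win)
    if (any(here)) {
      t1 <- tapply(pi_values[here], win, sum)
      t2 <- tapply(pi_values[here], win, length)
      wi <- as.integer(names(t1))
      sums[wi] <- t1
      cnts[wi] <- t2
    }
    data.frame(scaffold = sc, start = starts, end = starts + window,
               stat = "pi", value = sums / window, n_variants = cnts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windowed diversity difference between two groups
#'
#' Per aligned window, the first group's diversity minus the second's;
#' windows present in only one input contribute 0 for the missing side.
#'
#' @param windows1,windows2 Window tables from [windowed_pi()].
#' @return data.frame of `pi_diff` windows.
#' @export
pi_difference <- function(windows1, windows2) {
  key1 <- paste0(windows1$scaffold, ":", windows1$start)
  key2 <- paste0(windows2$scaffold, ":", windows2$start)
  keys <- union(key1, key2)
  v1 <- setNames(windows1$value, key1)[keys]
  v2 <- setNames(windows2$value, key2)[keys]
  v1[is.na(v1)] <- 0
  v2[is.na(v2)] <- 0
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.frame(scaffold = parts[, 1], start = as.numeric(parts[, 2]),
                    stat = "pi_diff", value = as.numeric(v1 - v2),
                    stringsAsFactors = FALSE)
  out$end <- out$start + (windows1$end - windows1$start)[1]
  out <- out[order(out$scaffold, out$start),
             c("scaffold", "start", "end", "stat", "value")]
  rownames(out) <- NULL
  out
}

#' Per-sample heterozygosity
#'
#' @param x A `variant_table`.
#' @return Named vector: heterozygous calls / called genotypes per sample.
#' @export
heterozygosity <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  colSums(x$gt == 1, na.rm = TRUE) / colSums(!is.na(x$gt))
}

#' Model table for diversity versus sequencing depth
#'
#' Builds the per-scaffold table pairing mean pairwise nucleotide diversity
#' (within each lineage's samples) with the lineage's mean sample depth and
#' a bottleneck indicator, ready for a quasibinomial GLM of
#' `pi ~ mean_depth * bottleneck`.
#'
#' @param x A `variant_table`.
#' @param pedigree Sample metadata with `lineage` and `substrain`.
#' @param bottleneck_substrain Substrain labelling bottleneck-derived
#'   lineages.
#' @param scaffold_lengths Named scaffold lengths (bp) used to express
#'   diversity per bp.
#' @return data.frame `lineage, scaffold, pi, mean_depth, bottleneck`.
#' @export
diversity_vs_depth_table <- function(x, pedigree, bottleneck_substrain = "FSB",
                                     scaffold_lengths) {
  stopifnot(inherits(x, "variant_table"))
  out <- list()
  for (ln in unique(pedigree$lineage)) {
    ss <- pedigree$sample_id[pedigree$lineage == ln]
    ss <- intersect(ss, sample_names(x))
    if (!length(ss)) next
    ac <- allele_counts(x, ss)
    pv <- pi_site(ac$n_ref, ac$n_alt)
    pv[is.na(pv)] <- 0
    tot <- tapply(pv, x$sites$scaffold, sum)
    sc <- names(scaffold_lengths)
    pi_bp <- ifelse(sc %in% names(tot), tot[sc], 0) / scaffold_lengths[sc]
    out[[ln]] <- data.frame(
      lineage = ln, scaffold = sc, pi = as.numeric(pi_bp),
      mean_depth = mean(x$mean_depth[ss]),
      bottleneck = pedigree$substrain[pedigree$lineage == ln][1] ==
        bottleneck_substrain,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quasibinomial GLM of diversity on depth and bottleneck status
#'
#' Delegates to [stats::glm()] with `pi ~ mean_depth * bottleneck` and a
#' quasibinomial family, as appropriate for a per-bp proportion response.
#'
#' @param tbl Table from [diversity_vs_depth_table()].
#' @return A fitted `glm` object.
#' @export
fit_diversity_glm <- function(tbl) {
  glm(pi ~ mean_depth * bottleneck, family = quasibinomial(), data = tbl)
}
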