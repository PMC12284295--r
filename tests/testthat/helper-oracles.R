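# Independent brute-force reference implementations used to cross-check the
# package's vectorised/streamlined algorithms on small instances.

# Weir-Cockerham two-population FST, transcribed independently from the
# variance-components definition, looping over subpopulations.
oracle_fst <- function(counts1, counts2) {
  counts <- list(counts1, counts2)
  n <- vapply(counts, sum, numeric(1))
  if (any(n == 0)) return(NA_real_)
  p <- vapply(counts, function(cc) (cc[2] + 2 * cc[3]) / (2 * sum(cc)), numeric(1))
  h <- vapply(counts, function(cc) cc[2] / sum(cc), numeric(1))
  r <- 2
  nbar <- mean(n)
  if (nbar <= 1) return(NA_real_)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Per-site diversity by enumerating all allele pairs.
oracle_pi <- function(n_ref, n_alt) {
  alleles <- c(rep(0L, n_ref), rep(1L, n_alt))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0L
  pairs <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1L
    if (alleles[i] != alleles[j]) diff <- diff + 1L
  }
  diff / pairs
}

# Greedy LD pruning re-implemented naively: r2 recomputed from scratch for
# every pair inside every window.
oracle_prune <- function(geno, window = 50, step = 10, r2_max = 0.1) {
  m <- ncol(geno)
  removed <- rep(FALSE, m)
  s <- 1L
  while (s <= max(1L, m - 1L)) {
    idx <- s:min(s + window - 1L, m)
    for (j in idx) {
      if (removed[j]) next
      for (i in idx[idx < j]) {
        if (removed[i]) next
        r <- suppressWarnings(cor(geno[, i], geno[, j],
                                  use = "pairwise.complete.obs"))
        r2 <- if (is.na(r)) 0 else r^2
        if (r2 > r2_max) {
          removed[j] <- TRUE
          break
        }
      }
    }
    if (max(idx) >= m) break
    s <- s + as.integer(step)
  }
  which(!removed)
}

# Exhaustive O(n^2) chain search for runs of homozygosity on one scaffold.
# gt: dosage vector (NA missing), pos: positions.  A valid chain is a pair of
# hom calls (i, j) such that no het lies strictly between, all adjacent hom
# supports inside are <= max_gap apart, and the chain is maximal.
oracle_roh <- function(pos, gt, min_length = 50000, min_snps = 25,
                       max_gap = 50000) {
  ord <- order(pos)
  pos <- pos[ord]; gt <- gt[ord]
  hom <- which(!is.na(gt) & gt != 1)
  het_pos <- pos[!is.na(gt) & gt == 1]
  valid <- function(i, j) {
    hp <- hom[hom >= i & hom <= j]
    if (any(het_pos > pos[i] & het_pos < pos[j])) return(FALSE)
    all(diff(pos[hp]) <= max_gap)
  }
  runs <- list()
  for (ii in seq_along(hom)) {
    for (jj in ii:length(hom)) {
      i <- hom[ii]; j <- hom[jj]
      if (!valid(i, j)) next
      # maximality: cannot extend to the previous/next hom support
      if (ii > 1 && valid(hom[ii - 1], j)) next
      if (jj < length(hom) && valid(i, hom[jj + 1])) next
      n_snps <- sum(hom >= i & hom <= j)
      if (n_snps >= min_snps && (pos[j] - pos[i] + 1) >= min_length)
        runs[[length(runs) + 1L]] <- c(start = pos[i] - 1, end = pos[j],
                                       n_snps = n_snps)
    }
  }
  if (!length(runs))
    return(data.frame(start = numeric(), end = numeric(), n_snps = numeric()))
  out <- unique(as.data.frame(do.call(rbind, runs)))
  out[order(out$start), , drop = FALSE]
}

# Brute-force per-site re-check of the newly-detected-mutation rules.
oracle_denovo <- function(x, pedigree, focal, exclusion_sets = list(),
                          cluster_bp = 150, depth_band = c(0.5, 2)) {
  parent <- pedigree$parent[pedigree$sample_id == focal]
  desc <- character()
  frontier <- focal
  repeat {
    kids <- pedigree$sample_id[!is.na(pedigree$parent) &
                                 pedigree$parent %in% frontier]
    kids <- setdiff(kids, desc)
    if (!length(kids)) break
    desc <- c(desc, kids)
    frontier <- kids
  }
  others <- setdiff(colnames(x$gt), c(focal, desc))
  excl_keys <- unlist(lapply(exclusion_sets, function(e)
    paste0(e$scaffold, ":", e$pos)))
  ok <- logical(nrow(x$sites))
  for (i in seq_len(nrow(x$sites))) {
    g <- x$gt[i, ]
    if (is.na(g[[focal]]) || g[[focal]] < 1) next
    if (is.na(g[[parent]]) || g[[parent]] != 0) next
    if (!all(!is.na(g[others]) & g[others] == 0)) next
    if (paste0(x$sites$scaffold[i], ":", x$sites$pos[i]) %in% excl_keys) next
    dp <- x$dp[i, ]
    band_ok <- !is.na(dp) & dp >= depth_band[1] * x$mean_depth &
      dp <= depth_band[2] * x$mean_depth
    if (!all(band_ok)) next
    ok[i] <- TRUE
  }
  idx <- which(ok)
  keep <- rep(TRUE, length(idx))
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a == b) next
    if (x$sites$scaffold[idx[a]] == x$sites$scaffold[idx[b]] &&
        abs(x$sites$pos[idx[a]] - x$sites$pos[idx[b]]) <= cluster_bp)
      keep[a] <- FALSE
  }
  idx[keep]
}

# Brute-force chain scan over a worm's division dates.
oracle_chains <- function(dates, threshold = 6) {
  dates <- sort(unique(dates))
  chains <- list(dates[1])
  for (d in dates[-1]) {
    last <- chains[[length(chains)]]
    if (d - last[length(last)] < threshold)
      chains[[length(chains)]] <- c(last, d)
    else
      chains[[length(chains) + 1L]] <- d
  }
  chains
}

# Dictionary bucketing for windowed means.
oracle_windowed_mean <- function(scaffold, pos, values, window = 10000) {
  buckets <- new.env(parent = emptyenv())
  for (i in seq_along(values)) {
    if (is.na(values[i])) next
    key <- paste0(scaffold[i], "|", floor((pos[i] - 1) / window) * window)
    buckets[[key]] <- c(buckets[[key]], values[i])
  }
  keys <- ls(buckets)
  out <- data.frame(
    scaffold = sub("\\|.*$", "", keys),
    start = as.numeric(sub("^.*\\|", "", keys)),
    value = vapply(keys, function(k) mean(buckets[[k]]), numeric(1)),
    n_variants = vapply(keys, function(k) length(buckets[[k]]), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bp-resolution boolean-mask oracle for substrain-specific interval algebra.
oracle_substrain_specific <- function(consensus_by_lineage, substrain_map,
                                      scaffold, len) {
  mask <- function(d) {
    m <- rep(FALSE, len)
    d <- d[d$scaffold == scaffold, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      lo <- d$start[i] + 1
      hi <- min(d$end[i], len)
      if (hi >= lo) m[lo:hi] <- TRUE
    }
    m
  }
  res <- list()
  for (ss in unique(substrain_map)) {
    lins <- names(substrain_map)[substrain_map == ss]
    inter <- Reduce(`&`, lapply(consensus_by_lineage[lins], mask))
    other <- names(substrain_map)[substrain_map != ss]
    un <- Reduce(`|`, lapply(consensus_by_lineage[other], mask))
    res[[ss]] <- inter & !un
  }
  res
}

mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values] - 1, end = ends[r$values])
}
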