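test_that("LD pruning removes the later site of duplicated pairs and keeps independent sites", {
  set.seed(31)
  base <- matrix(sample(0:2, 200 * 20, replace = TRUE), 200, 20)
  dup <- cbind(base[, 1], base)            # site 2 duplicates site 1
  kept <- ld_prune(dup, window = 10, step = 5, r2_max = 0.1)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  indep <- matrix(sample(0:2, 200 * 15, replace = TRUE), 200, 15)
  expect_equal(ld_prune(indep, window = 15, step = 5, r2_max = 0.5),
               1:15)
  expect_error(ld_prune(matrix(NA_integer_, 4, 2)), "missing")
})

test_that("greedy pruning matches the brute-force window scan", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(10:40, 1)
    m <- sample(20:70, 1)
    geno <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    # plant a correlated block
    b <- sample(m - 5, 1)
    for (k in 1:4) {
      col <- geno[, b]
      flip <- runif(n) < 0.1
      col[flip] <- sample(0:2, sum(flip), replace = TRUE)
      geno[, b + k] <- col
    }
    geno[runif(length(geno)) < 0.05] <- NA
    w <- sample(c(8, 15, 50), 1)
    st <- sample(c(3, 10), 1)
    expect_equal(ld_prune(geno, w, st, 0.1), oracle_prune(geno, w, st, 0.1))
  }
})

test_that("PCA separates planted groups and matches a direct SVD", {
  gt <- rbind(matrix(0L, 5, 100), matrix(2L, 5, 100))
  pc <- pca_genotypes(gt)
  g1 <- pc$scores[1:5, 1]
  g2 <- pc$scores[6:10, 1]
  expect_lt(max(abs(g1 - mean(g1))), 1e-8)      # zero within-group spread
  expect_lt(max(abs(g2 - mean(g2))), 1e-8)
  expect_gt(abs(mean(g1) - mean(g2)), 1)

  # identical samples land on identical coordinates
  extra <- matrix(sample(0:2, 10 * 20, replace = TRUE), 10, 20)
  dupg <- rbind(extra[1, ], extra[1, ], extra)
  pc2 <- pca_genotypes(dupg)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)

  # eigen-decomposition oracle: direct SVD of the centred matrix
  set.seed(33)
  geno <- matrix(sample(0:2, 12 * 80, replace = TRUE), 12, 80)
  pc3 <- pca_genotypes(geno, n_comp = 5)
  cen <- scale(geno, center = TRUE, scale = FALSE)
  sv <- svd(cen)
  ref <- sv$u %*% diag(sv$d)
  for (k in 1:5)
    expect_lt(min(max(abs(pc3$scores[, k] - ref[, k])),
                  max(abs(pc3$scores[, k] + ref[, k]))), 1e-8)
  expect_error(pca_genotypes(geno[1, , drop = FALSE]), "2 samples")
})

test_that("PCA coordinates are invariant (up to sign) to sample order", {
  set.seed(34)
  geno <- matrix(sample(0:2, 10 * 50, replace = TRUE), 10, 50)
  perm <- sample(10)
  pc_a <- pca_genotypes(geno, n_comp = 3)
  pc_b <- pca_genotypes(geno[perm, ], n_comp = 3)
  for (k in 1:3)
    expect_lt(min(max(abs(pc_b$scores[, k] - pc_a$scores[perm, k])),
                  max(abs(pc_b$scores[, k] + pc_a$scores[perm, k]))), 1e-8)
})

test_that("per-site FST reproduces the variance-components estimator", {
  # reciprocally fixed populations of any sizes give exactly 1
  expect_equal(fst_site(c(0, 0, 5), c(5, 0, 0)), 1)
  expect_equal(fst_site(c(0, 0, 3), c(9, 0, 0)), 1)
  # all-het in both populations gives exactly 0
  expect_equal(fst_site(c(0, 5, 0), c(0, 5, 0)), 0)
  # identical non-trivial genotype arrays: estimator is <= 0
  expect_lte(fst_site(c(2, 2, 1), c(2, 2, 1)), 0)
  # hand-derived value for {4 het, 1 hom-ref} vs {5 hom-ref}
  expect_equal(fst_site(c(1, 4, 0), c(5, 0, 0)), 0.375)
  # monomorphic overall: undefined
  expect_true(is.na(fst_site(c(5, 0, 0), c(4, 0, 0))))
  # empty population: missing
  expect_true(is.na(fst_site(c(0, 0, 0), c(2, 2, 1))))
})

test_that("vectorised FST agrees with the scalar oracle on random sites", {
  set.seed(35)
  for (rep in 1:100) {
    c1 <- c(sample(0:4, 2, replace = TRUE), sample(0:3, 1))
    c2 <- c(sample(0:4, 2, replace = TRUE), sample(0:3, 1))
    expect_equal(fst_site(c1, c2), oracle_fst(c1, c2), tolerance = 1e-12)
  }
  # matrix path equals per-site path, with missing genotypes dropped
  x <- random_table(80, 8, p_missing = 0.1, seed = 36)
  v <- fst_sites(x, paste0("s", 1:4), paste0("s", 5:8))
  for (i in seq_len(80)) {
    g1 <- x$gt[i, 1:4]; g2 <- x$gt[i, 5:8]
    cnt <- function(g) c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                         sum(g == 2, na.rm = TRUE))
    expect_equal(v[i], oracle_fst(cnt(g1), cnt(g2)), tolerance = 1e-12)
  }
})

test_that("windowed means bucket by 10-kb tiles anchored at zero", {
  w <- windowed_mean(c("sc1", "sc1"), c(1000, 9999), c(0.2, 0.4))
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 0)
  expect_equal(w$end, 10000)
  expect_equal(w$value, 0.3)
  expect_equal(w$n_variants, 2L)
  # windows without defined sites are absent
  w2 <- windowed_mean("sc1", 25000, NA_real_)
  expect_equal(nrow(w2), 0L)
  # random layout equals the dictionary-bucketing oracle
  set.seed(37)
  sc <- sample(c("a", "b"), 300, replace = TRUE)
  pos <- sample.int(1e5, 300)
  val <- ifelse(runif(300) < 0.1, NA, runif(300))
  w3 <- windowed_mean(sc, pos, val)
  o <- oracle_windowed_mean(sc, pos, val)
  expect_equal(w3$scaffold, o$scaffold)
  expect_equal(w3$start, o$start)
  expect_equal(w3$value, o$value)
  expect_equal(w3$n_variants, o$n_variants)
})

test_that("per-site diversity equals the pair-enumeration oracle", {
  expect_equal(pi_site(2, 2), 4 / 6)
  expect_equal(pi_site(3, 0), 0)
  expect_equal(pi_site(1, 1), 1)
  expect_true(is.na(pi_site(1, 0)))
  set.seed(38)
  for (rep in 1:50) {
    nr <- sample(0:10, 1); na_ <- sample(0:10, 1)
    expect_equal(pi_site(nr, na_), oracle_pi(nr, na_))
  }
})

test_that("windowed diversity is the per-window sum over the window length", {
  w <- windowed_pi("sc1", 3000, 0.5, scaffold_lengths = c(sc1 = 20000))
  expect_equal(w$value, c(0.5 / 10000, 0))
  expect_equal(w$n_variants, c(1L, 0L))
  # splitting the sites into two calls and recombining changes nothing
  set.seed(39)
  pos <- sort(sample.int(50000, 40))
  pv <- runif(40)
  all_w <- windowed_pi("sc1", pos, pv, scaffold_lengths = c(sc1 = 50000))
  half <- seq_len(20)
  w1 <- windowed_pi("sc1", pos[half], pv[half],
                    scaffold_lengths = c(sc1 = 50000))
  w2 <- windowed_pi("sc1", pos[-half], pv[-half],
                    scaffold_lengths = c(sc1 = 50000))
  expect_equal(all_w$value, w1$value + w2$value)
  # brute-force sum/length oracle
  for (i in seq_len(nrow(all_w))) {
    inw <- pos > all_w$start[i] & pos <= all_w$end[i]
    expect_equal(all_w$value[i], sum(pv[inw]) / 10000)
  }
})

test_that("diversity differences subtract aligned windows and are antisymmetric", {
  w1 <- data.frame(scaffold = "sc1", start = c(0, 10000), end = c(10000, 20000),
                   value = c(3e-4, 1e-4))
  w2 <- data.frame(scaffold = "sc1", start = 0, end = 10000, value = 1e-4)
  d <- pi_difference(w1, w2)
  expect_equal(d$value, c(2e-4, 1e-4))
  d_rev <- pi_difference(w2, w1)
  expect_equal(d_rev$value, -d$value)
  expect_equal(pi_difference(w1, w1)$value, c(0, 0))
})

test_that("heterozygosity is the het fraction of called genotypes", {
  gt <- cbind(c(rep(1L, 50), rep(0L, 50)), c(rep(0L, 99), NA))
  x <- make_table(gt)
  h <- heterozygosity(x)
  expect_equal(unname(h), c(0.5, 0))
})

test_that("bottlenecking is not flagged under the equal-diversity null", {
  # both substrains' diversities simulated from the same model; the GLM
  # should call the bottleneck term non-significant in >= 90% of replicates
  set.seed(40)
  hits <- 0L
  n_lin <- 10
  n_scaf <- 20
  for (rep in 1:100) {
    tbl <- data.frame(
      lineage = rep(paste0("L", seq_len(n_lin)), each = n_scaf),
      scaffold = rep(paste0("sc", seq_len(n_scaf)), n_lin),
      mean_depth = rep(rnorm(n_lin, 60, 5), each = n_scaf),
      bottleneck = rep(rep(c(FALSE, TRUE), each = n_lin / 2), each = n_scaf))
    tbl$pi <- rbinom(n_lin * n_scaf, 10000, 2e-3) / 10000
    fit <- fit_diversity_glm(tbl)
    p <- summary(fit)$coefficients["bottleneckTRUE", 4]
    if (p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
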