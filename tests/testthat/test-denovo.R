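test_that("newly detected mutations require focal-only carriage with full coverage", {
  gt <- rbind(c(0L, 1L, 0L, 0L, 0L),   # focal-only: called for g1
              c(0L, 1L, 0L, 1L, 0L),   # also in an unrelated library: rejected
              c(1L, 1L, 1L, 0L, 0L),   # parent carries: rejected
              c(0L, 1L, 1L, 0L, 0L),   # carried by g1 and its child g2: called
              c(0L, 0L, 1L, 0L, 0L))   # g2-only
  fx <- denovo_fixture(gt)
  calls <- call_newly_detected(fx$x, fx$ped, "g1")
  expect_equal(sort(calls$pos), fx$x$sites$pos[c(1, 4)])
  # descendant exemption is transitive: the g2 carrier does not veto g1
  expect_true(fx$x$sites$pos[4] %in% calls$pos)
  # g2's own calling sees site 4 vetoed by its parent g1 carrying it
  calls2 <- call_newly_detected(fx$x, fx$ped, "g2")
  expect_equal(calls2$pos, fx$x$sites$pos[5])
  expect_error(call_newly_detected(fx$x, fx$ped, "g0"), "no sequenced parent")
})

test_that("uncovered or excluded loci and clustered candidates are removed", {
  gt <- rbind(c(0L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L))
  pos <- c(1000L, 5000L, 5100L, 9000L, 20000L)
  fx <- denovo_fixture(gt, pos = pos)
  # sites at 5000/5100 are 100 bp apart: both removed by the cluster rule
  calls <- call_newly_detected(fx$x, fx$ped, "g1")
  expect_equal(calls$pos, c(1000L, 9000L, 20000L))
  # at exactly 150 bp both are removed; at 151 bp both are kept
  fx150 <- denovo_fixture(gt, pos = c(1000L, 5000L, 5150L, 9000L, 20000L))
  expect_equal(call_newly_detected(fx150$x, fx150$ped, "g1")$pos,
               c(1000L, 9000L, 20000L))
  fx151 <- denovo_fixture(gt, pos = c(1000L, 5000L, 5151L, 9000L, 20000L))
  expect_equal(call_newly_detected(fx151$x, fx151$ped, "g1")$pos,
               c(1000L, 5000L, 5151L, 9000L, 20000L))
  # a depth excursion in any library makes the site uncallable
  dp <- matrix(40, 5, 5)
  dp[4, 5] <- 150                         # u2's depth outside [0.5, 2] x mean
  fxd <- denovo_fixture(gt, pos = pos, dp = dp)
  expect_false(9000L %in% call_newly_detected(fxd$x, fxd$ped, "g1")$pos)
  # external exclusion sets only ever shrink the call set
  excl <- data.frame(scaffold = "sc1", pos = 1000L)
  calls_ex <- call_newly_detected(fx$x, fx$ped, "g1",
                                  exclusion_sets = list(excl))
  expect_true(all(calls_ex$pos %in% calls$pos))
  expect_false(1000L %in% calls_ex$pos)
  # gene-body restriction and repeat exclusion
  genes <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 10000))
  calls_g <- call_newly_detected(fx$x, fx$ped, "g1", genes_bed = genes)
  expect_false(20000L %in% calls_g$pos)
  reps <- GenomicRanges::GRanges("sc1", IRanges::IRanges(900, 1100))
  calls_r <- call_newly_detected(fx$x, fx$ped, "g1", repeats_bed = reps)
  expect_false(1000L %in% calls_r$pos)
})

test_that("calling matches the brute-force rule checker on random tables", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(30:80, 1)
    gt <- matrix(sample(c(0L, 0L, 0L, 0L, 1L, 2L, NA), n * 5, replace = TRUE),
                 n, 5, dimnames = list(NULL, c("g0", "g1", "g2", "u1", "u2")))
    dp <- matrix(sample(c(10, 40, 45, 100), n * 5, replace = TRUE,
                        prob = c(.05, .6, .3, .05)), n, 5)
    pos <- sort(sample.int(20000, n))
    fx <- denovo_fixture(gt, pos = pos, dp = dp)
    focal <- sample(c("g1", "g2", "u2"), 1)
    calls <- call_newly_detected(fx$x, fx$ped, focal)
    want <- oracle_denovo(fx$x, fx$ped, focal)
    expect_equal(match(calls$site_id, fx$x$sites$id), want)
  }
})

test_that("false-negative calibration counts missing parental hets", {
  # 100 qualifying parental hets, 1 missing in the offspring
  gt <- matrix(1L, 100, 2, dimnames = list(NULL, c("par", "off")))
  gt[7, 2] <- 0L
  ped <- data.frame(sample_id = c("par", "off"), lineage = "B1",
                    substrain = "FSB", generation = 0:1,
                    parent = c(NA, "par"), offspring_type = c("founder", "head"),
                    stringsAsFactors = FALSE)
  x <- make_table(gt)
  fn <- false_negative_rate(x, "par", "off")
  expect_equal(fn$rate, 0.01)
  expect_equal(fn$n_sites, 100L)
  gt[7, 2] <- 1L
  expect_equal(false_negative_rate(make_table(gt), "par", "off")$rate, 0)
  # parental hets outside the AF band around 0.5 do not qualify
  y <- make_table(gt)
  y$ad_alt[1:20, "par"] <- 8              # AF 0.2 at depth 40
  y$ad_ref[1:20, "par"] <- 32
  expect_equal(false_negative_rate(y, "par", "off")$n_sites, 80L)
})

test_that("the simulator's dropout rate is recovered within 3 SE", {
  cfg <- quick_config(seed = 72, founder_het_sites = 1500, mu = 0,
                      dropout_rate = 0.02)
  sim <- simulate_cohort(cfg)
  paths <- emit_vcf(sim, withr::local_tempdir())
  r <- read_vcf(paths$vcf, paths$metadata)
  fn <- false_negative_rate_all(r$table, r$pedigree)
  se <- sqrt(0.02 * 0.98 / fn$n_sites)
  expect_lt(abs(fn$rate - 0.02), 3 * se)
})

test_that("transmission fractions pool calls per lineage with sample SD across lineages", {
  calls <- data.frame(
    site_id = paste0("v", 1:30), scaffold = "sc1", pos = 1:30, ref = "A",
    alt = "T", focal = rep(c("g1", "u2"), each = 15),
    lineage = rep(c("B1", "B2"), each = 15),
    generation = 1L, af = 0.2, stringsAsFactors = FALSE)
  gt <- matrix(0L, 30, 5, dimnames = list(NULL, c("g0", "g1", "g2", "u1", "u2")))
  # 3/15 of B1 calls carried by the next head g2; B2 has no successor of u2
  gt[1:3, "g2"] <- 1L
  fx <- denovo_fixture(gt, pos = 1:30 * 100L)
  calls$site_id <- fx$x$sites$id[match(calls$pos * 100L, fx$x$sites$pos)]
  tf <- transmission_fraction(calls, fx$x, fx$ped)
  expect_equal(tf$per_lineage$fraction, 0.2)   # only B1 measurable
  expect_equal(tf$mean, 0.2)
  expect_true(is.na(tf$sd))                    # single lineage: no SD
  expect_equal(sum(tf$calls$transmitted, na.rm = TRUE), 3L)
  expect_true(all(is.na(tf$calls$transmitted[calls$focal == "u2"])))
})

test_that("mutation-rate arithmetic follows the diploid callable-site definition", {
  mr <- mutation_rate(111)
  expect_equal(mr$potential_sites, 296181846)
  expect_equal(mr$rate, 111 / 296181846)
  expect_equal(signif(mr$rate, 3), 3.75e-7)
  expect_equal(mutation_rate(0)$rate, 0)
  expect_equal(mutation_rate(296181846)$rate, 1)
  expect_error(mutation_rate(-1), "n_new")
})

test_that("recovered somatic mutation counts match the configured rate", {
  # sparse genome and Poisson depth so callability loss is negligible
  cfg <- quick_config(seed = 73, founder_het_sites = 300, mu = 40,
                      n_generations = 3, depth_dispersion = 0,
                      mean_depth = 60, n_scaffolds = 4,
                      scaffold_length = 5e6)
  sim <- simulate_cohort(cfg)
  paths <- emit_vcf(sim, withr::local_tempdir())
  r <- read_vcf(paths$vcf, paths$metadata)
  calls <- call_newly_detected_all(r$table, r$pedigree)
  fn <- false_negative_rate_all(r$table, r$pedigree)
  n_focal <- sum(!is.na(r$pedigree$parent))
  mean_count <- nrow(calls) / n_focal / (1 - fn$rate)
  # detection of an f0-fraction clone at 60x is itself ~93% efficient
  p_det <- 1 - pbinom(5, 60, cfg$init_cell_fraction / 2)
  se <- sqrt(cfg$mu / n_focal)
  expect_lt(abs(mean_count - cfg$mu * p_det), 3 * se)
})
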