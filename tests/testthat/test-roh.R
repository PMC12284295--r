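test_that("run detection applies the span, SNP-count and gap criteria", {
  # 30 hom SNPs spaced 2 kb: span 58 kb, one run
  x <- roh_table(seq(10000, by = 2000, length.out = 30), rep(0L, 30))
  runs <- detect_roh(x, "s1")
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 30L)
  expect_equal(runs$start, 10000 - 1)
  expect_equal(runs$end, 10000 + 29 * 2000)

  # 24 hom SNPs spanning 60 kb: below the SNP minimum
  x <- roh_table(round(seq(10000, 70000, length.out = 24)), rep(0L, 24))
  expect_equal(nrow(detect_roh(x, "s1")), 0L)

  # an internal gap > 50 kb splits the chain; each side re-qualifies alone
  pos <- c(seq(10000, by = 2000, length.out = 30),
           seq(10000 + 29 * 2000 + 60000, by = 2000, length.out = 30))
  x <- roh_table(pos, rep(0L, 60))
  runs <- detect_roh(x, "s1")
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$n_snps, c(30L, 30L))

  # a heterozygous call breaks the chain outright
  pos <- seq(10000, by = 2000, length.out = 61)
  gt <- rep(0L, 61); gt[31] <- 1L
  runs <- detect_roh(roh_table(pos, gt), "s1")
  expect_equal(nrow(runs), 2L)

  # missing genotypes neither support nor break, but count toward the gap
  gt2 <- rep(0L, 61); gt2[31] <- NA
  runs2 <- detect_roh(roh_table(pos, gt2), "s1")
  expect_equal(nrow(runs2), 1L)
  expect_equal(runs2$n_snps, 60L)
})

test_that("run detection matches the exhaustive chain-search oracle", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(30:150, 1)
    pos <- sort(sample.int(4e5, n))
    gt <- sample(c(0L, 0L, 0L, 2L, 1L, NA), n, replace = TRUE)
    x <- roh_table(pos, gt)
    got <- detect_roh(x, "s1", min_length = 3e4, min_snps = 8, max_gap = 2e4)
    want <- oracle_roh(pos, gt, min_length = 3e4, min_snps = 8, max_gap = 2e4)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, as.integer(want$n_snps))
    }
    # reported runs are pairwise non-overlapping
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= head(got$end, -1)))
  }
})

test_that("lineage consensus keeps only intervals supported by every individual", {
  runs <- data.frame(sample = c("a", "b", "c"), scaffold = "sc1",
                     start = 0, end = 100000, n_snps = 50)
  cons <- lineage_consensus(runs, c("a", "b", "c"))
  expect_equal(cons, data.frame(scaffold = "sc1", start = 0, end = 100000))

  # one individual without overlap drops the candidate
  runs2 <- runs[1:2, ]
  expect_equal(nrow(lineage_consensus(runs2, c("a", "b", "c"))), 0L)
  expect_error(lineage_consensus(runs, character()), "0 individuals")

  # staggered overlapping runs merge, then require support from everyone
  runs3 <- data.frame(sample = c("a", "b", "a", "b"), scaffold = "sc1",
                      start = c(0, 50000, 200000, 400000),
                      end = c(80000, 120000, 300000, 500000), n_snps = 30)
  cons3 <- lineage_consensus(runs3, c("a", "b"))
  expect_equal(cons3$start, 0)
  expect_equal(cons3$end, 120000)          # only the merged first block is shared
})

test_that("substrain-specific intervals match the bp-mask oracle", {
  cons <- list(
    F = data.frame(scaffold = "sc1", start = c(100, 1000), end = c(500, 2000)),
    S = data.frame(scaffold = "sc1", start = c(50, 1200), end = c(400, 1800)),
    P = data.frame(scaffold = "sc1", start = 300, end = 360),
    H = data.frame(scaffold = "sc1", start = 300, end = 380))
  map <- c(F = "FS", S = "FS", P = "PH", H = "PH")
  got <- substrain_specific_roh(cons, map)
  want <- oracle_substrain_specific(cons, map, "sc1", 3000)
  fs_iv <- mask_to_intervals(want$FS)
  expect_equal(got$FS$start, fs_iv$start)
  expect_equal(got$FS$end, fs_iv$end)
  ph_iv <- mask_to_intervals(want$PH)
  expect_equal(got$PH$start, ph_iv$start)
  expect_equal(got$PH$end, ph_iv$end)

  # interval present in all four lineages is shared, not specific
  cons2 <- lapply(c("F", "S", "P", "H"), function(l)
    data.frame(scaffold = "sc1", start = 0, end = 1000))
  names(cons2) <- c("F", "S", "P", "H")
  got2 <- substrain_specific_roh(cons2, map)
  expect_equal(nrow(got2$FS), 0L)
  expect_equal(nrow(got2$PH), 0L)
})

test_that("GC content counts G+C over unambiguous bases inside and outside intervals", {
  dna <- Biostrings::DNAStringSet(c(sc1 = paste0(strrep("G", 100),
                                                 "ATAT",
                                                 strrep("N", 10),
                                                 strrep("AACC", 25))))
  iv_allg <- data.frame(scaffold = "sc1", start = 0, end = 100)
  gc <- gc_content(dna, iv_allg)
  expect_equal(gc$gc[gc$scaffold == "sc1" & gc$region == "inside"], 1.0)
  iv_atat <- data.frame(scaffold = "sc1", start = 100, end = 104)
  gc2 <- gc_content(dna, iv_atat)
  expect_equal(gc2$gc[gc2$scaffold == "sc1" & gc2$region == "inside"], 0.0)
  # ambiguous bases excluded from the denominator
  out_row <- gc2[gc2$scaffold == "sc1" & gc2$region == "outside", ]
  expect_equal(out_row$n_bases, 200)

  # random sequence matches a per-base tally oracle
  set.seed(52)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 5000, replace = TRUE,
                    prob = c(.3, .2, .2, .28, .02)), collapse = "")
  dna2 <- Biostrings::DNAStringSet(c(chr = s))
  iv <- data.frame(scaffold = "chr", start = c(100, 2000), end = c(600, 3500))
  gc3 <- gc_content(dna2, iv)
  ch <- strsplit(s, "")[[1]]
  inside <- c(101:600, 2001:3500)
  tally <- function(v) sum(v %in% c("G", "C")) / sum(v %in% c("A", "C", "G", "T"))
  expect_equal(gc3$gc[gc3$scaffold == "chr" & gc3$region == "inside"],
               tally(ch[inside]))
  expect_equal(gc3$gc[gc3$scaffold == "chr" & gc3$region == "outside"],
               tally(ch[-inside]))
})

test_that("a planted LOH block is recovered as a substrain-specific consensus run", {
  cfg <- sim_config_substrains(seed = 53, founder_het_sites = 1500, mu = 10,
                               n_generations = 1, group_specific_sites = 100,
                               n_scaffolds = 2, scaffold_length = 3e6,
                               loh_start = 1e6, loh_end = 2.3e6)
  sim <- simulate_cohort(cfg)
  paths <- emit_vcf(sim, withr::local_tempdir())
  r <- read_vcf(paths$vcf, paths$metadata)
  runs <- detect_roh_all(r$table)
  by_lin <- split(r$pedigree$sample_id, r$pedigree$lineage)
  cons <- lapply(by_lin, function(s) lineage_consensus(runs, s))
  map <- setNames(r$pedigree$substrain, r$pedigree$lineage)
  map <- map[!duplicated(names(map))]
  spec <- substrain_specific_roh(cons, map)
  expect_equal(nrow(spec$PH), 0L)
  expect_equal(nrow(spec$FS), 1L)
  expect_equal(spec$FS$scaffold, "scaffold_1")
  # boundaries within one inter-SNP spacing of the planted block
  sc1 <- r$table$sites[r$table$sites$scaffold == "scaffold_1", ]
  spacing <- max(diff(sort(sc1$pos)))
  expect_lt(abs(spec$FS$start - 1e6), spacing)
  expect_lt(abs(spec$FS$end - 2.3e6), spacing)
})
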