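# Fixture builders: all test data are generated in code.

# Build a variant_table directly from a dosage matrix; read depths are made
# consistent with the genotypes (AF 0.5 for het, ~0/1 for hom) unless
# explicit matrices are supplied.
make_table <- function(gt, pos = NULL, scaffold = NULL, dp = NULL, gq = NULL,
                       ad_alt = NULL, depth = 40) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(scaffold)) scaffold <- rep("sc1", n)
  if (is.null(dp)) dp <- matrix(depth, n, ncol(gt))
  if (is.null(gq)) gq <- matrix(99, n, ncol(gt))
  if (is.null(ad_alt)) {
    ad_alt <- dp * 0
    het <- which(gt == 1)
    hom <- which(gt == 2)
    ad_alt[het] <- round(dp[het] / 2)
    ad_alt[hom] <- dp[hom]
  }
  sites <- data.frame(scaffold = scaffold, pos = as.integer(pos),
                      ref = rep("A", n), alt = rep("T", n),
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, dp - ad_alt, ad_alt, dp, gq)
}

# Random dosage matrix (sites in genomic order on one scaffold).
random_table <- function(n_sites, n_samples, p_missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
               n_sites, n_samples)
  if (p_missing > 0)
    gt[runif(length(gt)) < p_missing] <- NA
  make_table(gt, pos = sort(sample.int(n_sites * 2000L, n_sites)))
}

# Small, fast simulator configuration for unit tests.
quick_config <- function(seed = 1, ...) {
  args <- list(seed = seed, founder_het_sites = 200L, mu = 10,
               n_generations = 2L, n_scaffolds = 2L, scaffold_length = 4e5L,
               mean_depth = 40, log_max_worms = 80L, log_max_days = 250)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Single-sample table at given positions/genotypes for ROH tests.
roh_table <- function(pos, gt_vec, sample = "s1") {
  make_table(matrix(gt_vec, ncol = 1, dimnames = list(NULL, sample)),
             pos = pos)
}

# Five-sample head-line pedigree (g0 -> g1 -> g2, u1 -> u2) over a table.
denovo_fixture <- function(gt, pos = NULL, dp = NULL) {
  if (is.null(colnames(gt))) colnames(gt) <- c("g0", "g1", "g2", "u1", "u2")
  ped <- data.frame(sample_id = colnames(gt),
                    lineage = c("B1", "B1", "B1", "B2", "B2"),
                    substrain = "FSB",
                    generation = c(0L, 1L, 2L, 0L, 1L),
                    parent = c(NA, "g0", "g1", NA, "u1"),
                    offspring_type = c("founder", "head", "head",
                                       "founder", "head"),
                    stringsAsFactors = FALSE)
  list(x = make_table(gt, pos = pos, dp = dp), ped = ped)
}

# Reproduction-log rows for a single worm from explicit division dates.
log_rows <- function(worm_id, birth, division_dates = numeric(),
                     death_date = NULL, offspring_types = NULL,
                     parent = NA_character_) {
  rows <- list()
  if (length(division_dates)) {
    if (is.null(offspring_types))
      offspring_types <- rep("tail", length(division_dates))
    for (i in seq_along(division_dates))
      rows[[length(rows) + 1L]] <- data.frame(
        worm_id = worm_id, parent_id = parent, birth_date = birth,
        event_date = division_dates[i], event_type = "division",
        offspring_id = paste0(worm_id, "_o", i),
        offspring_type = offspring_types[i], stringsAsFactors = FALSE)
  }
  if (!is.null(death_date))
    rows[[length(rows) + 1L]] <- data.frame(
      worm_id = worm_id, parent_id = parent, birth_date = birth,
      event_date = death_date, event_type = "death",
      offspring_id = NA_character_, offspring_type = NA_character_,
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# Write a small VCF from explicit per-sample field strings.
write_toy_vcf <- function(path, records, samples,
                          contigs = c(sc1 = 100000L)) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

toy_metadata <- function(path, sample_ids, lineage = "F", substrain = "FS") {
  meta <- data.frame(sample_id = sample_ids,
                     lineage = rep_len(lineage, length(sample_ids)),
                     substrain = rep_len(substrain, length(sample_ids)),
                     generation = seq_along(sample_ids) - 1L,
                     parent = c(NA, head(sample_ids, -1)),
                     offspring_type = c("founder",
                                        rep("head", length(sample_ids) - 1L)),
                     stringsAsFactors = FALSE)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
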