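#' Write a simulated cohort to VCF, metadata, BED and log files
#'
#' Materialises a [simulate_cohort()] result as the file set the analysis
#' consumes: a multi-sample VCFv4.2 with `GT:AD:DP:GQ` FORMAT fields, a
#' tab-separated sample metadata table, a gene-body BED covering the whole
#' genome model, a (by default empty) repeat BED, the reproduction log, and
#' optionally a reference FASTA whose bases match the REF alleles.
#'
#' Read counts follow the depth model (negative binomial with the configured
#' mean and dispersion; Poisson at dispersion 0).  For a sample carrying a
#' variant at cell fraction f the alternate read count is
#' `Binomial(DP, f/2)` (`Binomial(DP, 1 - error_rate)` for homozygous-
#' alternate carriers), otherwise `Binomial(DP, error_rate)`.  Genotypes are
#' called heterozygous when at least `min_alt_reads` alternate reads are seen
#' and the read allele frequency lies in `[het_af_min, hom_af_min]`,
#' homozygous-alternate above `hom_af_min`, and missing at zero depth; a true
#' heterozygous call is missed (its reads drawn as reference) with
#' probability `dropout_rate`.  GQ is emitted high (99) for calls with depth
#' of at least 8 and low (10) otherwise.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_fasta Also write `reference.fa` (random background bases with
#'   REF alleles patched in).
#' @param repeat_intervals Optional data.frame (`scaffold`, `start`, `end`,
#'   0-based half-open) written as the repeat BED; empty file when `NULL`.
#' @return Named list of file paths (`vcf`, `metadata`, `genes_bed`,
#'   `repeats_bed`, `repro_log`, and `fasta` if written), invisibly.
#' @examples
#' cfg <- sim_config(seed = 1, founder_het_sites = 30, mu = 3,
#'                   n_generations = 1, scaffold_length = 1e5)
#' paths <- emit_vcf(simulate_cohort(cfg), tempfile("sim"))
#' basename(paths$vcf)
#' @export
emit_vcf <- function(sim, dir, write_fasta = FALSE, repeat_intervals = NULL) {
  stopifnot(inherits(sim, "sim_cohort"))
  config <- sim$config
  if (config$mean_depth <= 0) stop("depth model must have a positive mean")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ## independent, seed-derived stream for the read-sampling stage
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)

  v <- sim$truth$variants
  ord <- order(v$scaffold, v$pos)
  v <- v[ord, , drop = FALSE]
  samples <- sim$pedigree$sample_id
  n <- nrow(v)
  m <- length(samples)

  f <- matrix(0, n, m, dimnames = list(v$variant_id, samples))
  state <- matrix("none", n, m, dimnames = dimnames(f))
  car <- sim$truth$carriers
  idx <- cbind(match(car$variant_id, v$variant_id),
               match(car$sample_id, samples))
  f[idx] <- car$f
  state[idx] <- car$state

  dp <- if (config$depth_dispersion == 0)
    matrix(rpois(n * m, config$mean_depth), n, m)
  else
    matrix(rnbinom(n * m, size = 1 / config$depth_dispersion,
                   mu = config$mean_depth), n, m)

  p_alt <- matrix(config$error_rate, n, m)
  p_alt[state == "het"] <- f[state == "het"] / 2
  p_alt[state == "hom_alt"] <- 1 - config$error_rate
  alt <- matrix(rbinom(n * m, as.vector(dp), as.vector(p_alt)), n, m)
  drop <- state == "het" & matrix(runif(n * m), n, m) < config$dropout_rate
  alt[drop] <- 0L
  ref <- dp - alt

  af <- ifelse(dp > 0, alt / dp, NA_real_)
  gt <- matrix("0/0", n, m)
  gt[alt >= config$min_alt_reads & af >= config$het_af_min &
       af <= config$hom_af_min] <- "0/1"
  gt[alt >= config$min_alt_reads & af > config$hom_af_min] <- "1/1"
  gt[dp == 0] <- "./."
  gq <- ifelse(dp >= 8, 99L, 10L)

  body <- matrix(paste0(gt, ":", ref, ",", alt, ":", dp, ":", gq), n, m)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=clonediv_simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$scaffolds), sim$scaffolds),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(v$scaffold, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
          "GT:AD:DP:GQ",
          apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                metadata = file.path(dir, "metadata.tsv"),
                genes_bed = file.path(dir, "genes.bed"),
                repeats_bed = file.path(dir, "repeats.bed"),
                repro_log = file.path(dir, "repro_log.tsv"))
  writeLines(lines, paths$vcf)

  meta <- sim$pedigree
  names(meta) <- c("sample_id", "lineage", "substrain", "generation",
                   "parent", "offspring_type")
  write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(paste(names(sim$scaffolds), 0L,
                   format(sim$scaffolds, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             paths$genes_bed)
  if (is.null(repeat_intervals)) {
    file.create(paths$repeats_bed)
  } else {
    writeLines(paste(repeat_intervals$scaffold,
                     format(repeat_intervals$start, scientific = FALSE, trim = TRUE),
                     format(repeat_intervals$end, scientific = FALSE, trim = TRUE),
                     sep = "\t"),
               paths$repeats_bed)
  }
  write.table(sim$repro_log, paths$repro_log, sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (write_fasta) {
    seqs <- lapply(names(sim$scaffolds), function(sc) {
      s <- sample(c("A", "C", "G", "T"), sim$scaffolds[[sc]], replace = TRUE)
      here <- v$scaffold == sc
      s[v$pos[here]] <- v$ref[here]
      paste(s, collapse = "")
    })
    dna <- Biostrings::DNAStringSet(setNames(unlist(seqs), names(sim$scaffolds)))
    paths$fasta <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(dna, paths$fasta)
  }
  invisible(paths)
}
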