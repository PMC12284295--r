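#' Configuration for the fission-bottleneck forward simulator
#'
#' Bundles and validates every tunable of the synthetic cohort generator.
#' Defaults describe the head-line design used for mutation-rate estimation:
#' four lineages, each a founder followed by consecutive archived head
#' offspring while the tail line keeps dividing.  Somatic mutations arise in
#' neoblast clones carried by a cell fraction `init_cell_fraction` (so a
#' heterozygous mutation in a fraction f of cells is supported by ~f/2 of the
#' reads), and at each fission are transmitted to the regenerating tail either
#' independently with probability `p_transmit` (`"direct"` mode) or when their
#' 1-D body-axis patch intersects the tail segment (`"spatial"` mode).
#'
#' @param seed Integer seed; identical configurations reproduce byte-identical
#'   outputs.
#' @param lineages Character vector of lineage names.
#' @param substrains Substrain label per lineage (`FS`, `PH` or `FSB`).
#' @param n_generations Number of consecutive fissions (archived heads) per
#'   lineage.
#' @param founder_het_sites Number of heterozygous founder variants present in
#'   all cells of every worm (population allele frequency 0.5).
#' @param mu Expected number of new somatic mutations per worm per generation
#'   (Poisson).
#' @param init_cell_fraction Cell fraction f0 in (0, 1] of a newly arisen
#'   somatic variant.
#' @param mean_depth Mean sequencing depth per site per sample (> 0).
#' @param depth_dispersion Non-negative dispersion of the negative-binomial
#'   depth model (variance `mean_depth + depth_dispersion * mean_depth^2`);
#'   0 degenerates to Poisson.
#' @param transmission_mode `"direct"` or `"spatial"`.
#' @param p_transmit Probability (direct mode) that a somatic variant is
#'   transmitted to the tail at fission.
#' @param fission_plane Body-axis fraction in (0, 1) where the worm bisects;
#'   the head is `[0, fission_plane)`, the tail `[fission_plane, 1]`.
#' @param clone_width Width of a somatic clone patch as a fraction of the
#'   body axis, in `[0, 1]` (spatial mode; 0 means a point clone).
#' @param dropout_rate Probability that a true heterozygous call is missed
#'   (read support zeroed), used for false-negative calibration.
#' @param error_rate Per-read probability of a spurious alternate read in a
#'   non-carrier sample (off by default).
#' @param frag_rate Probability that a reproductive event is a fragmentation
#'   rather than a single fission.
#' @param middle_probs Probability vector over 1, 2, ... middle offspring in a
#'   fragmentation.
#' @param waiting_meanlog,waiting_sdlog Log-normal parameters of the
#'   reproductive waiting time (days).
#' @param death_prob_head,death_prob_tail,death_prob_middle Probability that a
#'   worm of the given offspring type dies instead of dividing.
#' @param n_scaffolds,scaffold_length Genome model: number of scaffolds and
#'   their common length in bp.
#' @param group_specific_sites Number of substrain-fixed variants planted per
#'   substrain (heterozygous in every sample of that substrain, absent from
#'   the other); 0 in the head-line default.
#' @param loh_block Optional loss-of-heterozygosity block, a list with
#'   elements `scaffold` (index), `start`, `end` (bp, half-open) and
#'   `substrain`; founder variants inside the block become homozygous (ref or
#'   alt, one ancestral coin flip per variant) in every sample of that
#'   substrain.
#' @param min_alt_reads,het_af_min,hom_af_min Genotype-caller emulation: a
#'   call is heterozygous when the alternate read count is at least
#'   `min_alt_reads` and the read allele frequency lies in
#'   `[het_af_min, hom_af_min]`; homozygous-alternate above `hom_af_min`;
#'   missing at zero depth; homozygous-reference otherwise.
#' @param log_max_worms,log_max_days Caps on the per-lineage reproduction-log
#'   population process.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [emit_vcf()], [simulate_repro_log()]
#' @examples
#' cfg <- sim_config(seed = 1, founder_het_sites = 50, mu = 5,
#'                   n_generations = 2)
#' cfg$p_transmit
#' @export
sim_config <- function(seed = 1L,
                       lineages = c("F", "S", "P", "H"),
                       substrains = c(F = "FS", S = "FS", P = "PH", H = "PH")[lineages],
                       n_generations = 4L,
                       founder_het_sites = 3000L,
                       mu = 111,
                       init_cell_fraction = 0.32,
                       mean_depth = 60,
                       depth_dispersion = 0.02,
                       transmission_mode = c("direct", "spatial"),
                       p_transmit = 0.092,
                       fission_plane = 0.8,
                       clone_width = 0.05,
                       dropout_rate = 0.008,
                       error_rate = 0,
                       frag_rate = 0.3,
                       middle_probs = c(0.75, 0.20, 0.05),
                       waiting_meanlog = log(14),
                       waiting_sdlog = 0.6,
                       death_prob_head = 0.05,
                       death_prob_tail = 0.22,
                       death_prob_middle = 0.05,
                       n_scaffolds = 4L,
                       scaffold_length = 3e6,
                       group_specific_sites = 0L,
                       loh_block = NULL,
                       min_alt_reads = 2L,
                       het_af_min = 0.1,
                       hom_af_min = 0.9,
                       log_max_worms = 400L,
                       log_max_days = 600) {
  transmission_mode <- match.arg(transmission_mode)
  stopifnot(length(lineages) >= 1, !anyDuplicated(lineages),
            length(substrains) == length(lineages))
  if (!all(substrains %in% c("FS", "PH", "FSB")))
    stop("substrains must be one of 'FS', 'PH', 'FSB'")
  probs <- c(p_transmit = p_transmit, dropout_rate = dropout_rate,
             error_rate = error_rate, frag_rate = frag_rate,
             death_prob_head = death_prob_head, death_prob_tail = death_prob_tail,
             death_prob_middle = death_prob_middle)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities must lie in [0, 1]: ", paste(names(probs)[bad], collapse = ", "))
  if (mu < 0) stop("mu must be non-negative")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (depth_dispersion < 0) stop("depth_dispersion must be non-negative")
  if (fission_plane <= 0 || fission_plane >= 1)
    stop("fission_plane must lie in (0, 1)")
  if (clone_width < 0 || clone_width > 1) stop("clone_width must lie in [0, 1]")
  if (init_cell_fraction <= 0 || init_cell_fraction > 1)
    stop("init_cell_fraction must lie in (0, 1]")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (any(middle_probs < 0) || sum(middle_probs) <= 0)
    stop("middle_probs must be a non-negative probability vector")
  if (!is.null(loh_block)) {
    stopifnot(is.list(loh_block),
              all(c("scaffold", "start", "end", "substrain") %in% names(loh_block)))
    if (loh_block$end <= loh_block$start) stop("loh_block end must exceed start")
  }
  cfg <- list(seed = as.integer(seed), lineages = lineages,
              substrains = setNames(substrains, lineages),
              n_generations = as.integer(n_generations),
              founder_het_sites = as.integer(founder_het_sites), mu = mu,
              init_cell_fraction = init_cell_fraction, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              transmission_mode = transmission_mode, p_transmit = p_transmit,
              fission_plane = fission_plane, clone_width = clone_width,
              dropout_rate = dropout_rate, error_rate = error_rate,
              frag_rate = frag_rate, middle_probs = middle_probs / sum(middle_probs),
              waiting_meanlog = waiting_meanlog, waiting_sdlog = waiting_sdlog,
              death_prob_head = death_prob_head, death_prob_tail = death_prob_tail,
              death_prob_middle = death_prob_middle,
              n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              group_specific_sites = as.integer(group_specific_sites),
              loh_block = loh_block, min_alt_reads = as.integer(min_alt_reads),
              het_af_min = het_af_min, hom_af_min = hom_af_min,
              log_max_worms = as.integer(log_max_worms),
              log_max_days = log_max_days)
  class(cfg) <- "sim_config"
  cfg
}

#' Substrain-structure simulation preset
#'
#' Convenience wrapper around [sim_config()] describing the substrain
#' scenario: two FS lineages and two PH lineages with planted substrain-fixed
#' variants and a loss-of-heterozygosity block shared by the FS lineages.
#'
#' @param seed Integer seed.
#' @param group_specific_sites Substrain-fixed variants per substrain.
#' @param loh_scaffold,loh_start,loh_end Block coordinates (bp, half-open).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_substrains <- function(seed = 1L, group_specific_sites = 1000L,
                                  loh_scaffold = 1L, loh_start = 1e6,
                                  loh_end = 2.3e6, ...) {
  sim_config(seed = seed, group_specific_sites = group_specific_sites,
             loh_block = list(scaffold = loh_scaffold, start = loh_start,
                              end = loh_end, substrain = "FS"),
             ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Fission-bottleneck simulator configuration\n")
  cat(sprintf("  lineages: %s (%s)\n", paste(x$lineages, collapse = ", "),
              paste(x$substrains, collapse = ", ")))
  cat(sprintf("  generations: %d, founder het sites: %d, mu: %g\n",
              x$n_generations, x$founder_het_sites, x$mu))
  cat(sprintf("  transmission: %s (p = %g, plane = %g), f0 = %g\n",
              x$transmission_mode, x$p_transmit, x$fission_plane,
              x$init_cell_fraction))
  cat(sprintf("  depth: %g (dispersion %g), dropout: %g, seed: %d\n",
              x$mean_depth, x$depth_dispersion, x$dropout_rate, x$seed))
  invisible(x)
}
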