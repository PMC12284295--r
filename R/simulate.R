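#' Simulate a cohort of fissiparous head-line lineages
#'
#' Forward simulation of the head-line design: each lineage starts from a
#' founder worm; at every generation the current (tail-line) worm acquires
#' `Poisson(mu)` new somatic variants at cell fraction f0, then bisects.  The
#' head offspring is archived (sequenced) and the tail continues the line.
#' Founder variants (and planted substrain-fixed variants) are present in all
#' cells of every descendant; somatic variants reach the tail either
#' independently with probability `p_transmit` (direct mode) or when their
#' clone patch on the 1-D body axis intersects the tail segment (spatial
#' mode), in which case the post-regeneration cell fraction is the parental
#' fraction scaled by the overlap length relative to the tail length (capped
#' at 1).
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: a list with elements
#'   \describe{
#'     \item{pedigree}{data.frame of sequenced samples (`sample_id`,
#'       `lineage`, `substrain`, `generation`, `parent`, `offspring_type`).}
#'     \item{truth}{list with `variants` (one row per variant: id,
#'       coordinates, alleles, origin, generation/lineage of origin, LOH
#'       state), `carriers` (one row per sample x carried variant with cell
#'       fraction `f` and zygosity `state`), and `transmissions` (one row per
#'       somatic variant per fission with the transmission outcome).}
#'     \item{repro_log}{population reproduction log across lineages (see
#'       [simulate_repro_log()]).}
#'     \item{scaffolds}{named integer vector of scaffold lengths.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- sim_config(seed = 1, founder_het_sites = 40, mu = 4,
#'                   n_generations = 2, scaffold_length = 1e5)
#' sim <- simulate_cohort(cfg)
#' head(sim$pedigree)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scaffolds <- setNames(rep(config$scaffold_length, config$n_scaffolds),
                        paste0("scaffold_", seq_len(config$n_scaffolds)))

  vr <- .variant_registry(scaffolds)
  bases <- c("A", "C", "G", "T")

  ## founder variants: heterozygous in all cells of every worm
  founder <- .register_variants(vr, config$founder_het_sites, origin = "founder")
  vr <- founder$registry

  ## planted substrain-fixed variants (outside any LOH block)
  group_ids <- list()
  if (config$group_specific_sites > 0) {
    for (ss in unique(config$substrains)) {
      g <- .register_variants(vr, config$group_specific_sites,
                              origin = "group", substrain = ss,
                              avoid = config$loh_block)
      vr <- g$registry
      group_ids[[ss]] <- g$ids
    }
  }

  ## ancestral LOH resolution: one coin flip per founder variant in the block
  if (!is.null(config$loh_block)) {
    blk <- config$loh_block
    in_blk <- vr$variants$origin == "founder" &
      vr$variants$scaffold == names(scaffolds)[blk$scaffold] &
      vr$variants$pos > blk$start & vr$variants$pos <= blk$end
    vr$variants$loh_state[in_blk] <- sample(c("hom_ref", "hom_alt"),
                                            sum(in_blk), replace = TRUE)
  }

  pedigree <- NULL
  carriers <- NULL
  transmissions <- NULL
  for (ln in config$lineages) {
    res <- .simulate_lineage(config, ln, vr, group_ids)
    vr <- res$registry
    pedigree <- rbind(pedigree, res$pedigree)
    carriers <- rbind(carriers, res$carriers)
    transmissions <- rbind(transmissions, res$transmissions)
  }
  rownames(pedigree) <- NULL

  repro_log <- do.call(rbind, lapply(config$lineages, function(ln)
    simulate_repro_log(config, lineage = ln, set_seed = FALSE)))

  out <- list(pedigree = pedigree,
              truth = list(variants = vr$variants, carriers = carriers,
                           transmissions = transmissions),
              repro_log = repro_log, scaffolds = scaffolds, config = config)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples in %d lineages, %d variants (%d somatic)\n",
              nrow(x$pedigree), length(unique(x$pedigree$lineage)),
              nrow(x$truth$variants),
              sum(x$truth$variants$origin == "somatic")))
  cat(sprintf("  reproduction log: %d records\n", nrow(x$repro_log)))
  invisible(x)
}

## internal registry of variant definitions with collision-free positions
.variant_registry <- function(scaffolds) {
  list(scaffolds = scaffolds,
       taken = new.env(parent = emptyenv()),
       variants = data.frame(variant_id = character(), scaffold = character(),
                             pos = integer(), ref = character(),
                             alt = character(), origin = character(),
                             substrain = character(),
                             origin_generation = integer(),
                             origin_lineage = character(),
                             clone_x = numeric(),
                             loh_state = character(),
                             stringsAsFactors = FALSE))
}

.register_variants <- function(registry, n, origin, substrain = NA_character_,
                               origin_generation = NA_integer_,
                               origin_lineage = NA_character_,
                               clone_x = NA_real_, avoid = NULL) {
  if (n == 0)
    return(list(registry = registry, ids = character()))
  bases <- c("A", "C", "G", "T")
  sc <- sample(names(registry$scaffolds), n, replace = TRUE)
  pos <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      p <- sample.int(registry$scaffolds[[sc[i]]], 1L)
      key <- paste0(sc[i], ":", p)
      in_avoid <- !is.null(avoid) &&
        sc[i] == names(registry$scaffolds)[avoid$scaffold] &&
        p > avoid$start && p <= avoid$end
      if (is.null(registry$taken[[key]]) && !in_avoid) {
        registry$taken[[key]] <- TRUE
        pos[i] <- p
        break
      }
    }
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  start_id <- nrow(registry$variants)
  ids <- sprintf("v%06d", start_id + seq_len(n))
  registry$variants <- rbind(registry$variants, data.frame(
    variant_id = ids, scaffold = sc, pos = pos, ref = ref, alt = unname(alt),
    origin = origin, substrain = substrain,
    origin_generation = origin_generation, origin_lineage = origin_lineage,
    clone_x = if (length(clone_x) == n) clone_x else rep(clone_x, n),
    loh_state = NA_character_,
    stringsAsFactors = FALSE))
  list(registry = registry, ids = ids)
}

## one head-line lineage; returns pedigree/carriers/transmissions rows
.simulate_lineage <- function(config, lineage, registry, group_ids) {
  ss <- config$substrains[[lineage]]
  G <- config$n_generations

  ## constitutive variants of this lineage: founders (possibly LOH-resolved)
  ## plus the substrain-fixed set of its substrain
  constitutive <- registry$variants[registry$variants$origin == "founder", ]
  const_state <- ifelse(ss == .loh_substrain(config) & !is.na(constitutive$loh_state),
                        constitutive$loh_state, "het")
  const_ids <- constitutive$variant_id
  if (length(group_ids) && !is.null(group_ids[[ss]])) {
    const_ids <- c(const_ids, group_ids[[ss]])
    const_state <- c(const_state, rep("het", length(group_ids[[ss]])))
  }

  snapshot <- function(sample_id, som) {
    n_c <- length(const_ids)
    data.frame(sample_id = sample_id,
               variant_id = c(const_ids, som$id),
               f = c(rep(1, n_c), som$f),
               state = c(const_state, rep("het", nrow(som))),
               stringsAsFactors = FALSE)
  }

  ## somatic state of the current (tail-line) body
  som <- data.frame(id = character(), f = numeric(), x = numeric(),
                    hw = numeric(), stringsAsFactors = FALSE)

  ids <- c(paste0(lineage, "_0"),
           if (G > 0) paste0(lineage, "_h", seq_len(G)))
  pedigree <- data.frame(sample_id = ids, lineage = lineage, substrain = ss,
                         generation = 0:G,
                         parent = c(NA_character_, ids[seq_len(G)]),
                         offspring_type = c("founder", rep("head", G)),
                         stringsAsFactors = FALSE)

  carriers <- snapshot(ids[1], som)
  transmissions <- NULL

  for (g in seq_len(G)) {
    n_new <- rpois(1, config$mu)
    if (n_new > 0) {
      reg <- .register_variants(registry, n_new, origin = "somatic",
                                origin_generation = g, origin_lineage = lineage,
                                clone_x = runif(n_new))
      registry <- reg$registry
      new_x <- registry$variants$clone_x[match(reg$ids, registry$variants$variant_id)]
      som <- rbind(som, data.frame(id = reg$ids,
                                   f = rep(config$init_cell_fraction, n_new),
                                   x = new_x,
                                   hw = rep(config$clone_width / 2, n_new),
                                   stringsAsFactors = FALSE))
    }

    ## fission: archive the head (carries the whole pre-fission body state),
    ## tail keeps a subset of somatic variants
    if (config$transmission_mode == "direct") {
      head_som <- som
      kept <- if (nrow(som)) runif(nrow(som)) < config$p_transmit else logical()
      tail_som <- som[kept, , drop = FALSE]
    } else {
      plane <- config$fission_plane
      lo <- pmax(som$x - som$hw, 0)
      hi <- pmin(som$x + som$hw, 1)
      ov_head <- pmax(0, pmin(hi, plane) - lo)
      ov_tail <- pmax(0, hi - pmax(lo, plane))
      point <- som$hw == 0           # point clones: membership by side
      ov_head[point] <- as.numeric(som$x[point] < plane)
      ov_tail[point] <- as.numeric(som$x[point] >= plane)
      in_head <- ov_head > 0
      in_tail <- ov_tail > 0
      rescale <- function(keep, ov, a, b, side_len) {
        s <- som[keep, , drop = FALSE]
        if (!nrow(s)) return(s)
        frac <- ifelse(s$hw == 0, 1, pmin(ov[keep] / side_len, 1))
        s$f <- pmin(s$f * frac, 1)
        mid <- (pmax(pmin(s$x, b), a) - a) / side_len
        s$x <- ifelse(s$hw == 0, mid, (pmin(pmax((s$x - a), 0), side_len) / side_len))
        s$hw <- pmin(s$hw / side_len, 0.5)
        s
      }
      head_som <- rescale(in_head, ov_head, 0, plane, plane)
      tail_som <- rescale(in_tail, ov_tail, plane, 1, 1 - plane)
      kept <- in_tail
    }
    if (nrow(som)) {
      transmissions <- rbind(transmissions, data.frame(
        lineage = lineage, generation = g, variant_id = som$id,
        transmitted = kept, stringsAsFactors = FALSE))
    }
    carriers <- rbind(carriers, snapshot(ids[g + 1], head_som))
    som <- tail_som
  }

  list(registry = registry, pedigree = pedigree, carriers = carriers,
       transmissions = transmissions)
}

.loh_substrain <- function(config) {
  if (is.null(config$loh_block)) "" else config$loh_block$substrain
}

#' Simulate an individual-tracking reproduction log
#'
#' Population process over individually cultured worms: each worm waits a
#' log-normal number of days after its birth, then either dies (with an
#' offspring-type-specific probability) or divides.  A division is a
#' fragmentation with probability `frag_rate`, in which case the body
#' undergoes consecutive bisections less than six days apart: the first sheds
#' the tail, subsequent ones shed middle pieces, and the final remnant is the
#' head.  Every shed piece and the head are recorded as offspring and start
#' their own life.
#'
#' @param config A [sim_config()].
#' @param lineage Lineage name used to prefix worm ids.
#' @param set_seed Seed the RNG from `config$seed` (set to `FALSE` when
#'   called within a larger simulation).
#' @return A data.frame reproduction log with columns `worm_id`, `parent_id`,
#'   `birth_date`, `event_date`, `event_type` (`division`/`death`),
#'   `offspring_id`, `offspring_type` (`head`/`tail`/`middle`; `NA` for death
#'   records).  Dates are integer days from the founder's birth.
#' @export
simulate_repro_log <- function(config, lineage = config$lineages[[1]],
                               set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  death_prob <- c(founder = config$death_prob_head,
                  head = config$death_prob_head,
                  tail = config$death_prob_tail,
                  middle = config$death_prob_middle)
  worms <- data.frame(id = paste0(lineage, ".w1"), parent = NA_character_,
                      birth = 0, type = "founder", stringsAsFactors = FALSE)
  rows <- list()
  n_created <- 1L
  i <- 1L
  while (i <= nrow(worms)) {
    w <- worms[i, ]
    i <- i + 1L
    wait <- max(1, round(rlnorm(1, config$waiting_meanlog, config$waiting_sdlog)))
    ev <- w$birth + wait
    if (ev > config$log_max_days) next      # unresolved at truncation
    if (runif(1) < death_prob[[w$type]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        worm_id = w$id, parent_id = w$parent, birth_date = w$birth,
        event_date = ev, event_type = "death", offspring_id = NA_character_,
        offspring_type = NA_character_, stringsAsFactors = FALSE)
      next
    }
    n_mid <- if (runif(1) < config$frag_rate)
      sample.int(length(config$middle_probs), 1, prob = config$middle_probs)
    else 0L
    n_div <- n_mid + 1L
    gaps <- if (n_div > 1) sample(1:5, n_div - 1L, replace = TRUE) else integer()
    dates <- ev + cumsum(c(0, gaps))
    off_types <- c("tail", rep("middle", n_mid), "head")
    off_dates <- c(dates, dates[n_div])     # head emitted at the last division
    for (k in seq_along(off_types)) {
      n_created <- n_created + 1L
      oid <- paste0(lineage, ".w", n_created)
      rows[[length(rows) + 1L]] <- data.frame(
        worm_id = w$id, parent_id = w$parent, birth_date = w$birth,
        event_date = off_dates[k], event_type = "division",
        offspring_id = oid, offspring_type = off_types[k],
        stringsAsFactors = FALSE)
      if (nrow(worms) < config$log_max_worms)
        worms <- rbind(worms, data.frame(id = oid, parent = w$id,
                                         birth = off_dates[k],
                                         type = off_types[k],
                                         stringsAsFactors = FALSE))
    }
  }
  log <- do.call(rbind, rows)
  log[order(log$event_date, log$worm_id), , drop = FALSE]
}
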