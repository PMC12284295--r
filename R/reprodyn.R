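#' Reproductive waiting times
#'
#' The waiting time of a worm is the number of days from its birth to its
#' first subsequent division.  Worms that died (or were never resolved)
#' without dividing contribute no value.
#'
#' @param records Reproduction log data.frame (see [read_repro_log()]).
#' @return data.frame with columns `worm_id`, `birth_date`, `division_date`,
#'   `waiting_days`.
#' @export
waiting_times <- function(records) {
  div <- records[records$event_type == "division", , drop = FALSE]
  if (nrow(div) == 0)
    return(data.frame(worm_id = character(), birth_date = numeric(),
                      division_date = numeric(), waiting_days = numeric()))
  first <- stats::aggregate(cbind(division_date = event_date) ~ worm_id + birth_date,
                            data = div, FUN = min)
  first$waiting_days <- first$division_date - first$birth_date
  if (any(first$waiting_days < 0))
    stop("division recorded before birth for worm(s): ",
         paste(first$worm_id[first$waiting_days < 0], collapse = ", "))
  first[order(first$worm_id), c("worm_id", "birth_date", "division_date",
                                "waiting_days")]
}

#' Aggregate divisions into fission and fragmentation events
#'
#' Within each worm body, consecutive divisions separated by strictly less
#' than `frag_threshold_days` form one fragmentation event with
#' `n_middles = n_divisions - 1`; an isolated division is a fission.  A gap
#' of exactly the threshold breaks the chain.  Records are sorted internally,
#' so the result does not depend on row order, and simultaneous offspring
#' rows of one bisection count as a single division.
#'
#' @param records Reproduction log data.frame.
#' @param frag_threshold_days Chain threshold in days (strict `<`).
#' @return data.frame with columns `worm_id`, `start_date`, `n_divisions`,
#'   `kind` (`fission`/`fragmentation`), `n_middles`.
#' @export
aggregate_events <- function(records, frag_threshold_days = 6) {
  div <- records[records$event_type == "division", , drop = FALSE]
  out <- list()
  for (w in unique(div$worm_id)) {
    dates <- sort(unique(div$event_date[div$worm_id == w]))
    chain <- cumsum(c(0, diff(dates) >= frag_threshold_days))
    for (ch in split(dates, chain)) {
      nd <- length(ch)
      out[[length(out) + 1L]] <- data.frame(
        worm_id = w, start_date = ch[1], n_divisions = nd,
        kind = if (nd == 1L) "fission" else "fragmentation",
        n_middles = nd - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(worm_id = character(), start_date = numeric(),
                      n_divisions = integer(), kind = character(),
                      n_middles = integer()))
  ev <- do.call(rbind, out)
  ev[order(ev$worm_id, ev$start_date), , drop = FALSE]
}

#' Death rates by offspring type
#'
#' For each offspring type, the proportion of worms that died out of all
#' worms of that type that were resolved as either dying or dividing.  A
#' worm's type is how it was born (`head`, `tail`, `middle`, or `founder`
#' for worms that never appear as offspring); unresolved worms are excluded.
#'
#' @param records Reproduction log data.frame.
#' @return data.frame with columns `offspring_type`, `n_died`, `n_divided`,
#'   `death_rate` (`NA` when no worm of the type was resolved).
#' @export
death_rates <- function(records) {
  type_of <- setNames(records$offspring_type, records$offspring_id)
  type_of <- type_of[!is.na(names(type_of))]
  worms <- unique(records$worm_id)
  wtype <- ifelse(worms %in% names(type_of), type_of[worms], "founder")
  died <- worms %in% records$worm_id[records$event_type == "death"]
  divided <- worms %in% records$worm_id[records$event_type == "division"]
  resolved <- died | divided
  types <- sort(unique(c(wtype[resolved],
                         unique(na.omit(records$offspring_type)))))
  res <- data.frame(offspring_type = types,
                    n_died = vapply(types, function(t)
                      sum(died & wtype == t), integer(1)),
                    n_divided = vapply(types, function(t)
                      sum(divided & !died & wtype == t), integer(1)),
                    stringsAsFactors = FALSE)
  res$death_rate <- ifelse(res$n_died + res$n_divided > 0,
                           res$n_died / (res$n_died + res$n_divided), NA_real_)
  rownames(res) <- NULL
  res
}

#' Per-lineage reproduction summary
#'
#' Convenience wrapper assembling the event-level summaries: waiting-time
#' distribution, fission versus fragmentation frequencies, the middle-count
#' table and death rates.  Lineages are taken from the worm-id prefix
#' (`<lineage>.<id>`) when no `lineage` column is present.  Group comparisons
#' (Kruskal-Wallis on waiting times, Fisher tests on event kinds and deaths,
#' Poisson models for middle counts) are left to standard routines on the
#' returned tables.
#'
#' @param records Reproduction log data.frame.
#' @return A list with `waiting` (per-worm waiting times with lineage),
#'   `events` (aggregated events with lineage), `kind_table` (lineage x
#'   fission/fragmentation counts), `middle_table` (lineage x middle-count),
#'   `deaths` (per-lineage death rates by offspring type).
#' @export
repro_summary <- function(records) {
  lineage_of <- function(ids) sub("\\..*$", "", ids)
  wt <- waiting_times(records)
  wt$lineage <- lineage_of(wt$worm_id)
  ev <- aggregate_events(records)
  ev$lineage <- lineage_of(ev$worm_id)
  kind_table <- table(ev$lineage, ev$kind)
  middle_table <- table(ev$lineage[ev$kind == "fragmentation"],
                        ev$n_middles[ev$kind == "fragmentation"])
  recs <- split(records, lineage_of(records$worm_id))
  deaths <- do.call(rbind, lapply(names(recs), function(ln) {
    d <- death_rates(recs[[ln]])
    d$lineage <- ln
    d
  }))
  list(waiting = wt, events = ev, kind_table = kind_table,
       middle_table = middle_table, deaths = deaths)
}
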