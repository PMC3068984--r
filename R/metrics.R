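#' Canonical analysis time intervals
#'
#' The four Zeitgeber-time intervals over which all group statistics are
#' computed: L1 = ZT0-6 and L2 = ZT6-12 (first and second half of the
#' light period), D1 = ZT12-18 and D2 = ZT18-23 (first and second part of
#' the dark period; D2 spans 5 hours because recordings stop at ZT23).
#' Intervals are half-open `[start, end)`; an epoch belongs to the
#' interval containing its start time.
#'
#' @return Data frame with columns `name`, `start`, `end` (hours).
#' @export
time_intervals <- function() {
  data.frame(name = c("L1", "L2", "D1", "D2"),
             start = c(0, 6, 12, 18), end = c(6, 12, 18, 23))
}

resolve_interval <- function(interval) {
  ti <- time_intervals()
  if (is.character(interval)) {
    i <- match(interval, ti$name)
    if (is.na(i)) stop("unknown interval: ", interval, call. = FALSE)
    return(ti[i, ])
  }
  stopifnot(is.data.frame(interval), all(c("start", "end") %in% names(interval)))
  interval
}

interval_mask <- function(hyp, interval) {
  iv <- resolve_interval(interval)
  zt <- epoch_zt(hyp)
  span_end <- hyp$zt_start + length(hyp$states) * hyp$epoch_seconds / 3600
  if (iv$end <= hyp$zt_start + 1e-9 || iv$start >= span_end - 1e-9)
    stop("interval [", iv$start, ", ", iv$end,
         ") lies outside the recording span", call. = FALSE)
  zt >= iv$start - 1e-9 & zt < iv$end - 1e-9
}

# intervals that overlap the recording span
covered_intervals <- function(hyp) {
  ti <- time_intervals()
  span_end <- hyp$zt_start + length(hyp$states) * hyp$epoch_seconds / 3600
  ti$name[ti$end > hyp$zt_start + 1e-9 & ti$start < span_end - 1e-9]
}

#' Normed state durations in a time interval
#'
#' Fraction of the interval's epochs spent in each vigilance state (the
#' "relative stay": state time divided by interval length).
#'
#' @param hyp A [hypnogram()].
#' @param interval Interval name (`"L1"`, `"L2"`, `"D1"`, `"D2"`) or a
#'   one-row data frame with `start`/`end` in ZT hours.
#' @return Named numeric vector over the three states, summing to 1.
#' @export
normed_durations <- function(hyp, interval) {
  sel <- interval_mask(hyp, interval)
  tab <- table(factor(hyp$states[sel], levels = vigilance_states()))
  stats::setNames(as.vector(tab) / sum(sel), vigilance_states())
}

#' Transition counts and normed transition frequencies
#'
#' A transition is counted at every boundary between consecutive epochs
#' with differing states for which the *later* epoch starts inside the
#' interval. Normed frequencies divide each ordered pair's count by the
#' interval's total transition count; all six ordered pairs are always
#' reported.
#'
#' @inheritParams normed_durations
#' @return List with `counts` and `normed` (both named over the six
#'   ordered pairs, e.g. `"NREMS->REMS"`). When the interval contains no
#'   transition, `normed` is all-`NA`.
#' @export
transition_frequencies <- function(hyp, interval) {
  sel <- interval_mask(hyp, interval)
  n <- length(hyp$states)
  later <- which(sel)
  later <- later[later > 1L]
  from <- hyp$states[later - 1L]
  to <- hyp$states[later]
  chg <- from != to
  lab <- paste(from[chg], to[chg], sep = "->")
  counts <- table(factor(lab, levels = transition_pairs()))
  counts <- stats::setNames(as.integer(counts), transition_pairs())
  tot <- sum(counts)
  normed <- if (tot > 0) counts / tot else
    stats::setNames(rep(NA_real_, 6L), transition_pairs())
  list(counts = counts, normed = normed)
}

#' REMS episode lengths in a time interval
#'
#' An episode is a maximal run of consecutive REMS epochs; it is assigned
#' to the interval containing its first epoch and is never split across
#' interval boundaries. Single-epoch episodes count.
#'
#' @inheritParams normed_durations
#' @return Numeric vector of episode lengths in seconds (possibly empty).
#' @export
rems_episodes <- function(hyp, interval) {
  iv <- resolve_interval(interval)
  r <- rle(hyp$states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_rems <- r$values == "REMS"
  zt0 <- hyp$zt_start + (starts - 1L) * hyp$epoch_seconds / 3600
  keep <- is_rems & zt0 >= iv$start - 1e-9 & zt0 < iv$end - 1e-9
  r$lengths[keep] * hyp$epoch_seconds
}

#' Per-animal interval summary across recording days
#'
#' For each of the four canonical intervals: normed durations and the mean
#' REMS episode length are computed per day and averaged across days with
#' equal weight; transition counts are summed across days and the normed
#' transition frequencies recomputed from the summed counts. The mean
#' REMS episode length is `NA` when no day has an episode in the interval.
#'
#' @param hyps List of [hypnogram()] objects (the animal's recording
#'   days), all of equal epoch count.
#' @return Data frame with one row per interval x metric x key:
#'   columns `animal_id`, `interval`, `metric` (one of `normed_duration`,
#'   `transition_count`, `normed_transition`,
#'   `mean_rems_episode_length`), `key` (state, ordered pair, or `NA`) and
#'   `value`.
#' @export
summarize_animal <- function(hyps) {
  if (inherits(hyps, "hypnogram")) hyps <- list(hyps)
  stopifnot(length(hyps) >= 1L)
  nep <- vapply(hyps, function(h) length(h$states), 0L)
  if (length(unique(nep)) != 1L)
    stop("recording days have unequal epoch counts", call. = FALSE)
  id <- hyps[[1]]$animal_id
  out <- list()
  for (iv in covered_intervals(hyps[[1]])) {
    dur <- rowMeans(sapply(hyps, normed_durations, interval = iv))
    cnt <- rowSums(sapply(hyps, function(h)
      transition_frequencies(h, iv)$counts))
    tot <- sum(cnt)
    nrm <- if (tot > 0) cnt / tot else rep(NA_real_, 6L)
    eplen <- vapply(hyps, function(h) {
      e <- rems_episodes(h, iv)
      if (length(e)) mean(e) else NA_real_
    }, 0)
    mep <- if (all(is.na(eplen))) NA_real_ else mean(eplen, na.rm = TRUE)
    out[[iv]] <- rbind(
      data.frame(interval = iv, metric = "normed_duration",
                 key = vigilance_states(), value = unname(dur)),
      data.frame(interval = iv, metric = "transition_count",
                 key = transition_pairs(), value = unname(cnt)),
      data.frame(interval = iv, metric = "normed_transition",
                 key = transition_pairs(), value = unname(nrm)),
      data.frame(interval = iv, metric = "mean_rems_episode_length",
                 key = NA_character_, value = mep))
  }
  res <- do.call(rbind, out)
  res <- cbind(animal_id = id, res)
  rownames(res) <- NULL
  res
}

#' Cohort-wide interval summaries
#'
#' Runs [summarize_animal()] over every animal of a cohort and attaches
#' the line label.
#'
#' @param cohort An `sr_cohort` from [simulate_cohort()], or a list of
#'   `list(animal_id, line, hypnograms)` records.
#' @return Long data frame: `animal_id`, `line`, `interval`, `metric`,
#'   `key`, `value`.
#' @export
cohort_interval_summaries <- function(cohort) {
  animals <- if (inherits(cohort, "sr_cohort")) cohort$animals else cohort
  res <- lapply(animals, function(a) {
    s <- summarize_animal(a$hypnograms)
    cbind(line = a$line, s)
  })
  out <- do.call(rbind, res)
  out[c("animal_id", "line", "interval", "metric", "key", "value")]
}

#' Hourly transition counts for one hypnogram
#'
#' Counts transitions per ordered state pair within each Zeitgeber-hour
#' bin (hour `h` covers ZT `[h-1, h)`, labelled ZT `h`); the transition
#' belongs to the hour of the later epoch. These per-hour frequencies are
#' the transition-side input of the stability screen.
#'
#' @param hyp A [hypnogram()].
#' @return Data frame `zt_hour`, `pair`, `count`.
#' @export
hourly_transition_frequencies <- function(hyp) {
  n <- length(hyp$states)
  zt <- epoch_zt(hyp)
  later <- 2:n
  chg <- hyp$states[later] != hyp$states[later - 1L]
  hour <- floor(zt[later]) + 1L
  hours <- sort(unique(floor(zt) + 1L))
  lab <- paste(hyp$states[later - 1L], hyp$states[later], sep = "->")
  tab <- table(factor(lab[chg], levels = transition_pairs()),
               factor(hour[chg], levels = hours))
  out <- expand.grid(zt_hour = hours, pair = transition_pairs(),
                     stringsAsFactors = FALSE)
  out$count <- as.integer(t(tab)[cbind(match(out$zt_hour, hours),
                                       match(out$pair, transition_pairs()))])
  out
}
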