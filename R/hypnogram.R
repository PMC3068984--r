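#' Construct a hypnogram
#'
#' A hypnogram is the epoch-resolution time series of vigilance-state
#' labels for one animal-day, aligned to Zeitgeber time (ZT; hours since
#' lights-on).
#'
#' @param states Character vector of states (`WAKE`, `NREMS`, `REMS`), one
#'   per 4-second epoch.
#' @param animal_id Animal identifier.
#' @param day_index Recording day (1-based).
#' @param zt_start ZT of the first epoch, in hours.
#' @param epoch_seconds Epoch length in seconds.
#' @param provenance Per-epoch label origin, `"AUTO"` or `"OVERRIDE"`;
#'   recycled if length 1.
#'
#' @return An object of class `hypnogram`: a list with the fields above.
#'   Epoch `i` starts at ZT `zt_start + (i - 1) * epoch_seconds / 3600`.
#' @export
hypnogram <- function(states, animal_id = "animal", day_index = 1L,
                      zt_start = 0, epoch_seconds = 4,
                      provenance = "AUTO") {
  states <- as.character(states)
  if (length(states) == 0L)
    stop("a hypnogram needs at least one epoch", call. = FALSE)
  bad <- which(!states %in% vigilance_states())
  if (length(bad))
    stop("invalid state label(s) at epoch(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(unique(states[utils::head(bad, 5L)]), collapse = ", "),
         call. = FALSE)
  provenance <- rep_len(as.character(provenance), length(states))
  stopifnot(all(provenance %in% c("AUTO", "OVERRIDE")))
  structure(
    list(animal_id = animal_id, day_index = as.integer(day_index),
         zt_start = zt_start, epoch_seconds = epoch_seconds,
         states = states, provenance = provenance),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = vigilance_states()))
  cat(sprintf("<hypnogram> %s day %d: %d epochs of %gs from ZT%g\n",
              x$animal_id, x$day_index, length(x$states), x$epoch_seconds,
              x$zt_start))
  cat(sprintf("  %s: %d (%.1f%%)\n", names(tab), as.integer(tab),
              100 * as.integer(tab) / length(x$states)), sep = "")
  invisible(x)
}

# ZT (hours) at which each epoch starts
epoch_zt <- function(hyp) {
  hyp$zt_start + (seq_along(hyp$states) - 1) * hyp$epoch_seconds / 3600
}

#' Write / read hypnograms as CSV
#'
#' The CSV dialect is UTF-8, comma-separated with a header row and columns
#' `animal_id, day, epoch_index, zt_hours, state, provenance`; states are
#' spelled exactly `WAKE`, `NREMS`, `REMS`. One file may hold several
#' animal-days.
#'
#' @param hyps A `hypnogram` or list of hypnograms.
#' @param path File path.
#' @return `write_hypnogram_csv()` returns `path` invisibly;
#'   `read_hypnogram_csv()` returns a list of `hypnogram` objects.
#' @export
write_hypnogram_csv <- function(hyps, path) {
  if (inherits(hyps, "hypnogram")) hyps <- list(hyps)
  rows <- lapply(hyps, function(h) {
    data.frame(animal_id = h$animal_id, day = h$day_index,
               epoch_index = seq_along(h$states), zt_hours = epoch_zt(h),
               state = h$states, provenance = h$provenance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "day", "epoch_index", "zt_hours", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hypnogram CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$state %in% vigilance_states())
  if (length(bad))
    stop("invalid state label(s) in ", path, " at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (e.g. ", deparse(df$state[bad[1]]), ")", call. = FALSE)
  if (is.null(df$provenance)) df$provenance <- "AUTO"
  keys <- unique(df[c("animal_id", "day")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$animal_id == keys$animal_id[i] & df$day == keys$day[i], ]
    sub <- sub[order(sub$epoch_index), ]
    out[[i]] <- hypnogram(sub$state, animal_id = keys$animal_id[i],
                          day_index = keys$day[i],
                          zt_start = sub$zt_hours[1],
                          provenance = sub$provenance)
  }
  out
}

#' Apply manual scoring overrides to a hypnogram
#'
#' Replaces the automatic label of the listed epochs, marking them with
#' provenance `OVERRIDE`. This is the file-based stand-in for interactive
#' manual rescoring.
#'
#' @param hyp A `hypnogram`.
#' @param overrides Data frame with columns `epoch_index` (1-based) and
#'   `state`.
#' @return The modified `hypnogram`.
#' @export
apply_overrides <- function(hyp, overrides) {
  stopifnot(inherits(hyp, "hypnogram"), is.data.frame(overrides))
  if (nrow(overrides) == 0L) return(hyp)
  idx <- overrides$epoch_index
  bad <- idx[idx < 1L | idx > length(hyp$states) | idx != floor(idx)]
  if (length(bad))
    stop("override epoch index out of range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  st <- as.character(overrides$state)
  if (!all(st %in% vigilance_states()))
    stop("invalid override state(s): ",
         paste(unique(setdiff(st, vigilance_states())), collapse = ", "),
         call. = FALSE)
  hyp$states[idx] <- st
  hyp$provenance[idx] <- "OVERRIDE"
  hyp
}
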