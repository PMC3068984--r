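#' EEG frequency-band scheme
#'
#' The mouse-specific band scheme used throughout the package. All edges
#' lie on the 0.25 Hz grid of a 256-point FFT at 64 Hz; a bin belongs to a
#' band when its centre frequency falls in `[low, high]` inclusive. The
#' three inter-band gap bins (5.25-5.75, 9.25-9.75 and 15.25-15.75 Hz)
#' contribute to total power only.
#'
#' @param bands Named list of `c(low, high)` pairs in Hz. The default is
#'   delta 0.75-5, theta 6-9, alpha 10-15, eta 16-22.75, beta 23-31.75.
#' @param analysis_range Total-power range `c(low, high)` in Hz.
#' @return Data frame with columns `band`, `low`, `high` and attribute
#'   `analysis_range`.
#' @export
band_scheme <- function(bands = list(delta = c(0.75, 5), theta = c(6, 9),
                                     alpha = c(10, 15), eta = c(16, 22.75),
                                     beta = c(23, 31.75)),
                        analysis_range = c(0.75, 31.75)) {
  edges <- unlist(bands)
  if (any(abs(edges / 0.25 - round(edges / 0.25)) > 1e-9))
    stop("band edges must lie on the 0.25 Hz FFT grid", call. = FALSE)
  lows <- vapply(bands, `[`, 0, 1)
  highs <- vapply(bands, `[`, 0, 2)
  if (any(highs <= lows))
    stop("each band needs high > low", call. = FALSE)
  o <- order(lows)
  if (any(lows[o][-1] <= highs[o][-length(o)]))
    stop("bands must not overlap", call. = FALSE)
  out <- data.frame(band = names(bands), low = lows, high = highs,
                    row.names = NULL)
  attr(out, "analysis_range") <- analysis_range
  out
}

#' Band-pass filter the EEG channel
#'
#' Emulates the recording chain's analog front-end filter as a zero-phase
#' digital Butterworth band-pass of 48 dB/octave roll-off (order-4
#' sections applied forward and backward with [signal::filtfilt()]). The
#' EMG channel is passed through untouched; EMG quantification uses the
#' unfiltered signal.
#'
#' @param recording A [raw_recording()].
#' @param low,high Pass-band edges in Hz; `high` must stay below the
#'   Nyquist frequency.
#' @return The recording with a filtered EEG channel (`filtered = TRUE`).
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 29) {
  stopifnot(inherits(recording, "raw_recording"))
  nyq <- recording$sample_rate / 2
  if (!(0 < low && low < high && high < nyq))
    stop("need 0 < low < high < Nyquist (", nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  recording$eeg <- signal::filtfilt(bf, recording$eeg)
  recording$filtered <- TRUE
  recording
}

# one-sided periodogram of epoch-matrix columns (N x n), bins k = 0..N/2;
# sum over bins 1..N/2 equals the biased epoch variance
epoch_periodogram <- function(mat) {
  N <- nrow(mat)
  X <- stats::mvfft(mat)
  half <- N / 2
  p <- Mod(X[1:(half + 1), , drop = FALSE])^2 / N^2
  p[2:half, ] <- 2 * p[2:half, , drop = FALSE]
  p
}

#' Per-epoch spectral band powers and EMG RMS
#'
#' Cuts the recording into consecutive non-overlapping 4-second epochs and
#' computes, per epoch, an untapered periodogram on the 0.25 Hz grid;
#' absolute band powers (sum of bins with centre frequency inside each
#' band, edges inclusive); total power over the analysis range including
#' the inter-band gap bins; relative powers (band / total); and the EMG
#' root mean square. DC and bins below the analysis range never contribute
#' to any power.
#'
#' @param recording A [raw_recording()] (normally after
#'   [bandpass_filter()]).
#' @param scheme A [band_scheme()].
#' @return Data frame with one row per epoch: `epoch_index`, `zt`,
#'   `total_power`, `emg_rms`, `rel_defined` plus `power_<band>` and
#'   `rel_<band>` columns. For epochs with zero total power, relative
#'   powers are `NA` and `rel_defined` is `FALSE`.
#' @export
epoch_features <- function(recording, scheme = band_scheme()) {
  stopifnot(inherits(recording, "raw_recording"))
  N <- recording$sample_rate * recording$epoch_seconds
  n <- length(recording$eeg) / N
  stopifnot(n == floor(n))
  eegm <- matrix(recording$eeg, N, n)
  p <- epoch_periodogram(eegm)                     # (N/2 + 1) x n
  freqs <- (0:(N / 2)) * recording$sample_rate / N
  ar <- attr(scheme, "analysis_range")

  total <- colSums(p[freqs >= ar[1] & freqs <= ar[2], , drop = FALSE])
  bandp <- sapply(seq_len(nrow(scheme)), function(b)
    colSums(p[freqs >= scheme$low[b] & freqs <= scheme$high[b], ,
              drop = FALSE]))
  if (n == 1L) bandp <- matrix(bandp, nrow = 1L)
  colnames(bandp) <- scheme$band

  defined <- total > 0
  rel <- bandp / ifelse(defined, total, NA_real_)

  emgm <- matrix(recording$emg, N, n)
  emg_rms <- sqrt(colMeans(emgm^2))

  out <- data.frame(
    epoch_index = seq_len(n),
    zt = recording$zt_start + (seq_len(n) - 1) *
      recording$epoch_seconds / 3600,
    total_power = total, emg_rms = emg_rms, rel_defined = defined)
  for (b in scheme$band) {
    out[[paste0("power_", b)]] <- bandp[, b]
    out[[paste0("rel_", b)]] <- rel[, b]
  }
  attr(out, "scheme") <- scheme
  attr(out, "animal_id") <- recording$animal_id
  attr(out, "day_index") <- recording$day_index
  out
}

#' Hourly mean relative-power profile
#'
#' Averages relative band powers over Zeitgeber-hour bins, optionally
#' restricted to epochs scored as one vigilance state. Hour `h` covers
#' ZT `[h - 1, h)` and is labelled ZT `h`, giving points ZT1..ZT23 for a
#' 23-hour recording; this is the grid on which the stability test pairs
#' groups.
#'
#' @param features Output of [epoch_features()].
#' @param hyp Optional [hypnogram()] aligned epoch-by-epoch with
#'   `features`; required when `restrict_to` is a state.
#' @param restrict_to `"ALL"` or one vigilance state.
#' @return Data frame `zt_hour`, `band`, `mean_rel_power`, `n_epochs`;
#'   hours with no qualifying epoch have `NA` mean and `n_epochs = 0`.
#' @export
hourly_band_profile <- function(features, hyp = NULL, restrict_to = "ALL") {
  scheme <- attr(features, "scheme")
  if (is.null(scheme)) scheme <- band_scheme()
  keep <- features$rel_defined
  if (!identical(restrict_to, "ALL")) {
    stopifnot(restrict_to %in% vigilance_states())
    if (is.null(hyp))
      stop("state restriction requires the matching hypnogram",
           call. = FALSE)
    if (length(hyp$states) != nrow(features))
      stop("features and hypnogram are misaligned (", nrow(features),
           " vs ", length(hyp$states), " epochs)", call. = FALSE)
    keep <- keep & hyp$states == restrict_to
  }
  hour <- floor(features$zt) + 1L
  hours <- sort(unique(hour))
  out <- expand.grid(zt_hour = hours, band = scheme$band,
                     stringsAsFactors = FALSE)
  out$mean_rel_power <- NA_real_
  out$n_epochs <- 0L
  for (b in scheme$band) {
    v <- features[[paste0("rel_", b)]]
    for (h in hours) {
      sel <- keep & hour == h
      i <- out$zt_hour == h & out$band == b
      out$n_epochs[i] <- sum(sel)
      if (any(sel)) out$mean_rel_power[i] <- mean(v[sel])
    }
  }
  out
}
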