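#' Scoring thresholds for the rule-based vigilance scorer
#'
#' The scorer works on the same feature space the spectral analysis uses
#' (relative band powers and EMG RMS per 4-second epoch). EMG cutoffs are
#' expressed as quantiles of the recording's own EMG RMS distribution and
#' turned into absolute values by [calibrate_thresholds()]; this
#' per-recording calibration stands in for an experimenter's manual
#' tuning. Absolute cutoffs may also be supplied directly.
#'
#' @param emg_wake_quantile Quantile of the EMG RMS distribution above
#'   which an epoch is scored WAKE.
#' @param emg_sleep_quantile Quantile below which the EMG is compatible
#'   with REMS atonia.
#' @param delta_fraction_min Minimum relative delta power for NREMS.
#' @param theta_delta_ratio_min Minimum theta/delta relative-power ratio
#'   for REMS.
#' @param emg_wake_cutoff,emg_sleep_cutoff Optional absolute EMG cutoffs
#'   (microvolts); when set, calibration is the identity.
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(emg_wake_quantile = 0.60,
                               emg_sleep_quantile = 0.40,
                               delta_fraction_min = 0.35,
                               theta_delta_ratio_min = 1.5,
                               emg_wake_cutoff = NA_real_,
                               emg_sleep_cutoff = NA_real_) {
  stopifnot(emg_wake_quantile > 0, emg_wake_quantile < 1,
            emg_sleep_quantile > 0, emg_sleep_quantile < 1,
            delta_fraction_min > 0, theta_delta_ratio_min > 0)
  structure(
    list(emg_wake_quantile = emg_wake_quantile,
         emg_sleep_quantile = emg_sleep_quantile,
         delta_fraction_min = delta_fraction_min,
         theta_delta_ratio_min = theta_delta_ratio_min,
         emg_wake_cutoff = emg_wake_cutoff,
         emg_sleep_cutoff = emg_sleep_cutoff),
    class = "scoring_thresholds")
}

#' Calibrate EMG cutoffs on a recording
#'
#' Sets the absolute EMG cutoffs to the configured quantiles of the
#' recording's per-epoch EMG RMS distribution. Thresholds that already
#' carry absolute cutoffs are returned unchanged.
#'
#' @param features Output of [epoch_features()] (at least 100 epochs).
#' @param thresholds A [scoring_thresholds()].
#' @return Calibrated `scoring_thresholds` with absolute cutoffs filled.
#' @export
calibrate_thresholds <- function(features, thresholds = scoring_thresholds()) {
  if (!is.na(thresholds$emg_wake_cutoff) &&
      !is.na(thresholds$emg_sleep_cutoff))
    return(thresholds)
  emg <- features$emg_rms
  if (length(emg) < 100L)
    stop("calibration needs at least 100 epochs", call. = FALSE)
  if (diff(range(emg)) == 0)
    stop("EMG RMS distribution is degenerate (constant); supply explicit ",
         "absolute cutoffs via `scoring_thresholds()`", call. = FALSE)
  thresholds$emg_wake_cutoff <-
    unname(stats::quantile(emg, thresholds$emg_wake_quantile))
  thresholds$emg_sleep_cutoff <-
    unname(stats::quantile(emg, thresholds$emg_sleep_quantile))
  thresholds
}

#' Score epochs into vigilance states
#'
#' Deterministic decision cascade per epoch:
#' \enumerate{
#'   \item EMG RMS above the wake cutoff: WAKE (muscle tone dominates).
#'   \item Else, theta/delta relative-power ratio above
#'     `theta_delta_ratio_min` and EMG RMS below the sleep cutoff: REMS
#'     (theta-dominant EEG with atonia).
#'   \item Else, relative delta power above `delta_fraction_min`: NREMS.
#'   \item Else (including epochs with undefined relative powers): carry
#'     the previous epoch's state forward; the first epoch defaults to
#'     WAKE.
#' }
#'
#' @param features Output of [epoch_features()].
#' @param thresholds A calibrated [scoring_thresholds()]; uncalibrated
#'   thresholds are calibrated on `features` first.
#' @return A [hypnogram()] with provenance `AUTO` on every epoch.
#' @export
score_epochs <- function(features, thresholds = scoring_thresholds()) {
  thresholds <- calibrate_thresholds(features, thresholds)
  n <- nrow(features)
  emg <- features$emg_rms
  delta <- features$rel_delta
  ratio <- features$rel_theta / delta
  ok <- features$rel_defined & is.finite(ratio)

  state <- rep(NA_character_, n)
  state[emg > thresholds$emg_wake_cutoff] <- "WAKE"
  rems <- is.na(state) & ok & ratio > thresholds$theta_delta_ratio_min &
    emg < thresholds$emg_sleep_cutoff
  state[rems] <- "REMS"
  nrems <- is.na(state) & ok & delta > thresholds$delta_fraction_min
  state[nrems] <- "NREMS"

  # fall-back: carry last assigned state forward; seed state is WAKE
  if (is.na(state[1])) state[1] <- "WAKE"
  idx <- seq_len(n)
  idx[is.na(state)] <- NA
  filled <- cummax(ifelse(is.na(idx), 0L, idx))
  state <- state[filled]

  hypnogram(state,
            animal_id = attr(features, "animal_id") %||% "animal",
            day_index = attr(features, "day_index") %||% 1L,
            zt_start = features$zt[1], provenance = "AUTO")
}

#' Optional majority smoothing of a hypnogram
#'
#' Width-3 majority filter; ties keep the centre epoch's label. Off by
#' default in the pipeline.
#'
#' @param hyp A [hypnogram()].
#' @return Smoothed `hypnogram`.
#' @export
majority_filter <- function(hyp) {
  s <- hyp$states
  n <- length(s)
  if (n < 3L) return(hyp)
  out <- s
  for (i in 2:(n - 1)) {
    win <- s[(i - 1):(i + 1)]
    tab <- table(win)
    if (max(tab) >= 2L) out[i] <- names(tab)[which.max(tab)]
  }
  hyp$states <- out
  hyp
}

#' Epoch-level agreement between two hypnograms
#'
#' @param a,b Hypnograms of equal length.
#' @return Fraction of epochs with identical labels.
#' @export
hypnogram_agreement <- function(a, b) {
  stopifnot(length(a$states) == length(b$states))
  mean(a$states == b$states)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
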