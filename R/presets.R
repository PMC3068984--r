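#' Construct a breeding-line preset for the synthetic cohort generator
#'
#' A preset bundles everything needed to simulate one mouse line: per-phase
#' Markov transition matrices over the vigilance states, a target spectral
#' band profile per state, and state-dependent EMG and EEG amplitudes.
#'
#' @param line_id Character label, typically one of `"HR"`, `"IR"`, `"LR"`.
#' @param transition Named list with elements `LIGHT` and `DARK`, each a
#'   3x3 row-stochastic matrix of per-epoch transition probabilities with
#'   rows/columns ordered WAKE, NREMS, REMS.
#' @param band_profile 3x5 numeric matrix (rows: states; columns: bands of
#'   the default [band_scheme()]) giving the target fraction of total EEG
#'   power in each band; each row must sum to at most 1 (the remainder is
#'   placed in the inter-band gap bins).
#' @param emg_level Named numeric vector: EMG root-mean-square amplitude
#'   (arbitrary microvolt units) per state. Must respect the atonia
#'   ordering REMS < NREMS < WAKE.
#' @param eeg_amplitude Named numeric vector: overall EEG RMS amplitude per
#'   state (microvolts).
#' @param spectral_jitter Standard deviation of the per-epoch lognormal
#'   perturbation applied to the band profile during signal synthesis;
#'   emulates epoch-to-epoch spectral variability of real EEG.
#'
#' @return An object of class `line_preset`.
#' @export
line_preset <- function(line_id, transition, band_profile, emg_level,
                        eeg_amplitude, spectral_jitter = 0.15) {
  st <- vigilance_states()
  stopifnot(is.character(line_id), length(line_id) == 1L)
  if (!all(c("LIGHT", "DARK") %in% names(transition)))
    stop("`transition` must have elements LIGHT and DARK", call. = FALSE)
  for (ph in c("LIGHT", "DARK")) {
    P <- transition[[ph]]
    if (!is.matrix(P) || any(dim(P) != 3L))
      stop("transition matrix for phase ", ph, " must be 3x3", call. = FALSE)
    if (any(P < 0))
      stop("transition matrix for phase ", ph, " has negative entries",
           call. = FALSE)
    if (any(abs(rowSums(P) - 1) > 1e-12))
      stop("transition matrix for phase ", ph,
           " is not row-stochastic (rows must sum to 1)", call. = FALSE)
    dimnames(transition[[ph]]) <- list(st, st)
  }
  if (!is.matrix(band_profile) || nrow(band_profile) != 3L)
    stop("`band_profile` must be a 3-row matrix (one row per state)",
         call. = FALSE)
  if (any(band_profile < 0) || any(rowSums(band_profile) > 1 + 1e-12))
    stop("band profile rows must be non-negative and sum to <= 1",
         call. = FALSE)
  rownames(band_profile) <- st
  emg_level <- emg_level[st]
  eeg_amplitude <- eeg_amplitude[st]
  if (anyNA(emg_level) || anyNA(eeg_amplitude))
    stop("`emg_level` and `eeg_amplitude` must name all three states",
         call. = FALSE)
  if (!(emg_level[["REMS"]] < emg_level[["NREMS"]] &&
        emg_level[["NREMS"]] < emg_level[["WAKE"]]))
    stop("EMG levels must respect atonia ordering REMS < NREMS < WAKE",
         call. = FALSE)
  structure(
    list(line_id = line_id, transition = transition,
         band_profile = band_profile, emg_level = emg_level,
         eeg_amplitude = eeg_amplitude, spectral_jitter = spectral_jitter),
    class = "line_preset")
}

#' Default HR / IR / LR line presets
#'
#' Shipped presets encode the qualitative differences between the three
#' stress-reactivity breeding lines: the high-reactivity (HR) line has an
#' elevated NREMS-to-REMS transition probability in both light phases
#' (hence more REMS time and more REMS->WAKE exits, with an unchanged REMS
#' episode-length distribution), while the low-reactivity (LR) line has
#' depressed theta and alpha relative power during NREMS. The intermediate
#' (IR) line sits between the two. Transition probabilities are per
#' 4-second epoch and give circadian state fractions typical of nocturnal
#' mice (light phase roughly 45% WAKE / 45% NREMS / 8-12% REMS; dark phase
#' roughly 75% WAKE).
#'
#' @return Named list of three [line_preset()] objects (`HR`, `IR`, `LR`).
#' @export
default_line_presets <- function() {
  st <- vigilance_states()
  tmat <- function(w, n, r) {
    m <- rbind(w, n, r)
    dimnames(m) <- list(st, st)
    m
  }
  light <- function(n2r) tmat(
    w = c(0.960, 0.040, 0.000),
    n = c(0.030, 1 - 0.030 - n2r, n2r),
    r = c(0.045, 0.010, 0.945))
  dark <- function(n2r) tmat(
    w = c(0.985, 0.015, 0.000),
    n = c(0.045, 1 - 0.045 - n2r, n2r),
    r = c(0.050, 0.010, 0.940))

  bands <- c("delta", "theta", "alpha", "eta", "beta")
  profile <- function(wake, nrems, rems) {
    m <- rbind(WAKE = wake, NREMS = nrems, REMS = rems)
    colnames(m) <- bands
    m
  }
  # rows sum to < 1; the remainder is spread over the inter-band gap bins
  prof_std <- profile(
    wake  = c(0.30, 0.30, 0.15, 0.11, 0.07),
    nrems = c(0.55, 0.16, 0.12, 0.07, 0.05),
    rems  = c(0.18, 0.50, 0.12, 0.08, 0.06))
  prof_lr <- profile(                       # depressed theta/alpha in NREMS
    wake  = c(0.30, 0.30, 0.15, 0.11, 0.07),
    nrems = c(0.61, 0.12, 0.09, 0.08, 0.05),
    rems  = c(0.18, 0.50, 0.12, 0.08, 0.06))

  emg <- c(WAKE = 30, NREMS = 10, REMS = 2)
  eeg <- c(WAKE = 40, NREMS = 80, REMS = 50)

  list(
    HR = line_preset("HR",
      list(LIGHT = light(0.016), DARK = dark(0.008)),
      prof_std, emg, eeg),
    IR = line_preset("IR",
      list(LIGHT = light(0.010), DARK = dark(0.005)),
      prof_std, emg, eeg),
    LR = line_preset("LR",
      list(LIGHT = light(0.009), DARK = dark(0.0045)),
      prof_lr, emg, eeg))
}

#' Simulation configuration
#'
#' Recording geometry and cohort layout for the synthetic generator. The
#' defaults mirror the experimental protocol the package targets: 8 animals
#' per line, two 23-hour recording sessions aligned to Zeitgeber time
#' (lights on at ZT0, lights off at ZT12), 4-second epochs sampled at
#' 64 Hz, i.e. 20700 epochs per recording day.
#'
#' @param n_animals_per_line Animals per breeding line. May be a single
#'   count or a named vector (`HR`, `IR`, `LR`) of per-line counts.
#' @param n_days Recording days per animal.
#' @param epoch_seconds Epoch length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param recording_hours Recording length in hours (ZT0 up to ZT
#'   `recording_hours`).
#' @param lights_off_zt Zeitgeber hour at which the dark phase begins.
#' @param seed Master seed; all per-animal seeds derive from it.
#' @param animal_cv Coefficient of variation of the per-animal lognormal
#'   perturbation applied to band profiles and signal amplitudes
#'   (between-animal biological variability).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_animals_per_line = 8, n_days = 2, epoch_seconds = 4,
                       sample_rate = 64, recording_hours = 23,
                       lights_off_zt = 12, seed = 20110324,
                       animal_cv = 0.08) {
  stopifnot(n_days >= 1, epoch_seconds > 0, sample_rate > 0,
            recording_hours > 0, lights_off_zt > 0)
  if ((recording_hours * 3600) %% epoch_seconds != 0)
    stop("recording length must be divisible by the epoch length",
         call. = FALSE)
  structure(
    list(n_animals_per_line = n_animals_per_line, n_days = n_days,
         epoch_seconds = epoch_seconds, sample_rate = sample_rate,
         recording_hours = recording_hours, lights_off_zt = lights_off_zt,
         seed = seed, animal_cv = animal_cv),
    class = "sim_config")
}

# epochs in one recording day
epochs_per_day <- function(config) {
  as.integer(config$recording_hours * 3600 / config$epoch_seconds)
}

#' Stationary distribution of a transition matrix
#'
#' Left Perron eigenvector of a row-stochastic matrix, normalised to sum
#' to 1.
#'
#' @param P Row-stochastic square matrix.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-10))
    stop("matrix is not row-stochastic", call. = FALSE)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(P)
  v
}
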