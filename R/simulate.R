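#' Simulate a hypnogram from a line preset
#'
#' Samples a first-order Markov chain over the vigilance states on the
#' 4-second epoch grid, piecewise-homogeneous by light phase: the LIGHT
#' transition matrix governs epochs starting before `lights_off_zt`, the
#' DARK matrix the rest. The initial state is drawn from the stationary
#' distribution of the LIGHT matrix.
#'
#' @param preset A [line_preset()].
#' @param config A [sim_config()].
#' @param animal_seed Integer seed; identical seeds give identical
#'   hypnograms.
#' @param animal_id,day_index Metadata stored on the result.
#' @param init Optional fixed initial state (`"WAKE"`, `"NREMS"` or
#'   `"REMS"`); by default the initial state is drawn from the LIGHT
#'   stationary distribution.
#' @return A [hypnogram()] with `epochs_per_day` epochs (20700 under the
#'   default 23-h / 4-s geometry).
#' @export
simulate_hypnogram <- function(preset, config = sim_config(),
                               animal_seed = config$seed,
                               animal_id = preset$line_id, day_index = 1L,
                               init = NULL) {
  if (!inherits(preset, "line_preset"))
    preset <- do.call(line_preset, preset)   # re-validates plain lists
  n <- epochs_per_day(config)
  if (n < 1L) stop("zero-length recording", call. = FALSE)
  zt <- (seq_len(n) - 1) * config$epoch_seconds / 3600
  dark <- as.integer(zt >= config$lights_off_zt)
  cum_l <- t(apply(preset$transition$LIGHT, 1, cumsum))
  cum_d <- t(apply(preset$transition$DARK, 1, cumsum))
  set.seed(as.integer(animal_seed %% .Machine$integer.max))
  if (is.null(init)) {
    pi_light <- stationary_distribution(preset$transition$LIGHT)
    init_code <- sample.int(3L, 1L, prob = pmax(pi_light, 0))
  } else {
    init_code <- match(init, vigilance_states())
    if (is.na(init_code)) stop("unknown initial state: ", init, call. = FALSE)
  }
  u <- stats::runif(n - 1L)
  codes <- markov_path_cpp(cum_l, cum_d, dark[-n], init_code, u)
  hypnogram(vigilance_states()[codes], animal_id = animal_id,
            day_index = day_index, zt_start = 0,
            epoch_seconds = config$epoch_seconds)
}

#' Construct a raw two-channel recording
#'
#' @param eeg,emg Numeric sample vectors (microvolts) of equal length,
#'   divisible by one epoch's worth of samples.
#' @param zt_start ZT of the first sample (hours).
#' @param sample_rate Sampling rate (Hz).
#' @param animal_id,day_index Metadata.
#' @param epoch_seconds Epoch length (s).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(eeg, emg, zt_start = 0, sample_rate = 64,
                          animal_id = "animal", day_index = 1L,
                          epoch_seconds = 4) {
  if (length(eeg) != length(emg))
    stop("EEG and EMG channels must have equal length", call. = FALSE)
  spe <- sample_rate * epoch_seconds
  if (length(eeg) %% spe != 0)
    stop("recording length must be divisible by one epoch (",
         spe, " samples)", call. = FALSE)
  structure(
    list(eeg = eeg, emg = emg, zt_start = zt_start,
         sample_rate = sample_rate, epoch_seconds = epoch_seconds,
         animal_id = animal_id, day_index = as.integer(day_index),
         filtered = FALSE),
    class = "raw_recording")
}

# per-state periodogram-bin power templates (fraction of total variance in
# each 0.25 Hz bin, k = 0..128), given a band-fraction matrix
state_bin_templates <- function(band_profile, scheme = band_scheme()) {
  freqs <- (0:128) * 0.25
  ar <- attr(scheme, "analysis_range")
  in_analysis <- freqs >= ar[1] & freqs <= ar[2]
  band_bins <- lapply(seq_len(nrow(scheme)), function(b)
    which(freqs >= scheme$low[b] & freqs <= scheme$high[b]))
  gap_bins <- setdiff(which(in_analysis), unlist(band_bins))
  out <- matrix(0, nrow(band_profile), 129,
                dimnames = list(rownames(band_profile), NULL))
  for (s in seq_len(nrow(band_profile))) {
    for (b in seq_len(nrow(scheme)))
      out[s, band_bins[[b]]] <- band_profile[s, b] / length(band_bins[[b]])
    out[s, gap_bins] <- (1 - sum(band_profile[s, ])) / length(gap_bins)
  }
  list(template = out, band_bins = band_bins, gap_bins = gap_bins)
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' Builds each 4-second EEG epoch by inverse DFT of amplitude targets with
#' independent random phases: the power in each 0.25 Hz bin is set so the
#' epoch's band fractions match the preset's `band_profile` for the
#' epoch's state (perturbed by a per-epoch lognormal jitter of standard
#' deviation `preset$spectral_jitter`), and the epoch RMS equals
#' `eeg_amplitude[state]`. The EMG channel is white noise with standard
#' deviation `emg_level[state]`.
#'
#' @param hyp A [hypnogram()].
#' @param preset The [line_preset()] that supplies spectral and amplitude
#'   targets.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [raw_recording()] with `length(hyp$states) * 256` samples per
#'   channel (under the default 64 Hz / 4 s geometry).
#' @export
synthesize_signals <- function(hyp, preset, config = sim_config(),
                               seed = config$seed) {
  stopifnot(inherits(hyp, "hypnogram"))
  n <- length(hyp$states)
  if (n != epochs_per_day(config))
    stop("hypnogram length does not match the configured recording (",
         n, " vs ", epochs_per_day(config), " epochs)", call. = FALSE)
  N <- config$sample_rate * config$epoch_seconds          # 256
  half <- N / 2                                           # 128
  tpl <- state_bin_templates(preset$band_profile)
  scode <- match(hyp$states, vigilance_states())
  set.seed(as.integer(seed %% .Machine$integer.max))

  # per-epoch band jitter: lognormal factors, renormalised so the in-band
  # power fraction of the state is preserved
  nb <- length(tpl$band_bins)
  sj <- preset$spectral_jitter
  P <- tpl$template[scode, , drop = FALSE]                # n x 129
  if (sj > 0) {
    fac <- matrix(exp(stats::rnorm(n * nb, -sj^2 / 2, sj)), n, nb)
    band_frac <- preset$band_profile[scode, , drop = FALSE] * fac
    tot0 <- rowSums(preset$band_profile)[scode]
    band_frac <- band_frac * (tot0 / rowSums(band_frac))
    for (b in seq_len(nb))
      P[, tpl$band_bins[[b]]] <- band_frac[, b] / length(tpl$band_bins[[b]])
  }

  # complex spectrum: |X_k| = N * sqrt(p_k / 2), random phase, Hermitian
  phases <- matrix(stats::runif(n * (half - 1), 0, 2 * pi), half - 1, n)
  X <- matrix(0 + 0i, N, n)
  amp <- t(sqrt(P[, 2:half, drop = FALSE] / 2)) * N       # (half-1) x n
  X[2:half, ] <- amp * exp(1i * phases)
  X[(N:(half + 2)), ] <- Conj(X[2:half, ])
  eeg <- Re(stats::mvfft(X, inverse = TRUE)) / N          # N x n
  eeg <- eeg * rep(preset$eeg_amplitude[scode], each = N)

  emg_sd <- preset$emg_level[scode]
  emg <- stats::rnorm(n * N) * rep(emg_sd, each = N)

  raw_recording(as.vector(eeg), emg, zt_start = hyp$zt_start,
                sample_rate = config$sample_rate, animal_id = hyp$animal_id,
                day_index = hyp$day_index,
                epoch_seconds = config$epoch_seconds)
}

# apply per-animal biological variability to a preset: lognormal factors
# on band fractions (shared across states), EMG levels and EEG amplitude
jitter_preset <- function(preset, cv) {
  if (cv <= 0) return(preset)
  bp <- preset$band_profile
  fac <- exp(stats::rnorm(ncol(bp), -cv^2 / 2, cv))
  bp2 <- sweep(bp, 2, fac, `*`)
  bp2 <- bp2 * (rowSums(bp) / rowSums(bp2))
  emg <- preset$emg_level * exp(stats::rnorm(3, -cv^2 / 2, cv / 2))
  eeg <- preset$eeg_amplitude * exp(stats::rnorm(3, -cv^2 / 2, cv / 2))
  line_preset(preset$line_id, preset$transition, bp2, emg, eeg,
              spectral_jitter = preset$spectral_jitter)
}

#' Simulate a full HR/IR/LR cohort
#'
#' Generates the study-sized synthetic data set: per line, the configured
#' number of animals, each with `n_days` hypnograms (and, optionally,
#' synthesized EEG/EMG signals). Per-animal seeds and biological jitter
#' are derived deterministically from the master seed, so the whole cohort
#' is reproducible from one integer.
#'
#' @param presets Named list of [line_preset()] objects (one per line).
#' @param config A [sim_config()].
#' @param signals If `TRUE`, synthesize raw signals for every animal-day
#'   (memory- and time-intensive); otherwise only hypnograms are produced.
#' @return An object of class `sr_cohort`: list with `animals` (each a
#'   list with `animal_id`, `line`, `preset`, `hypnograms`, `recordings`),
#'   plus the `config` and `presets` used.
#' @export
simulate_cohort <- function(presets = default_line_presets(),
                            config = sim_config(), signals = FALSE) {
  lines <- names(presets)
  if (is.null(lines) || anyDuplicated(lines))
    stop("`presets` must be a uniquely named list of line presets",
         call. = FALSE)
  counts <- config$n_animals_per_line
  if (length(counts) == 1L) counts <- stats::setNames(rep(counts, length(lines)), lines)
  counts <- counts[lines]
  if (anyNA(counts))
    stop("per-line animal counts must name every line", call. = FALSE)

  total <- sum(counts)
  set.seed(as.integer(config$seed %% .Machine$integer.max))
  seed_pool <- sample.int(.Machine$integer.max - 1L,
                          total * (config$n_days * 2 + 1))
  jit_seeds <- sample.int(.Machine$integer.max - 1L, total)

  animals <- vector("list", total)
  k <- 0L
  for (line in lines) {
    for (a in seq_len(counts[[line]])) {
      k <- k + 1L
      id <- sprintf("%s_%d", line, a)
      set.seed(jit_seeds[k])
      pre_a <- jitter_preset(presets[[line]], config$animal_cv)
      hyps <- vector("list", config$n_days)
      recs <- if (signals) vector("list", config$n_days) else NULL
      for (d in seq_len(config$n_days)) {
        s_h <- seed_pool[(k - 1L) * config$n_days * 2 + 2L * d - 1L]
        s_s <- seed_pool[(k - 1L) * config$n_days * 2 + 2L * d]
        hyps[[d]] <- simulate_hypnogram(pre_a, config, animal_seed = s_h,
                                        animal_id = id, day_index = d)
        if (signals)
          recs[[d]] <- synthesize_signals(hyps[[d]], pre_a, config,
                                          seed = s_s)
      }
      animals[[k]] <- list(animal_id = id, line = line, preset = pre_a,
                           hypnograms = hyps, recordings = recs)
    }
  }
  structure(list(animals = animals, config = config, presets = presets),
            class = "sr_cohort")
}

#' @export
print.sr_cohort <- function(x, ...) {
  lines <- vapply(x$animals, `[[`, "", "line")
  cat(sprintf("<sr_cohort> %d animals (%s), %d day(s), %d epochs/day\n",
              length(x$animals),
              paste(sprintf("%s: %d", names(table(lines)), table(lines)),
                    collapse = ", "),
              x$config$n_days, epochs_per_day(x$config)))
  invisible(x)
}
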