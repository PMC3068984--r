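# shared fixtures and brute-force oracles

# hypnogram from a compact string, e.g. "WWNNRW"
hyp_from_string <- function(s, ...) {
  map <- c(W = "WAKE", N = "NREMS", R = "REMS")
  hypnogram(unname(map[strsplit(s, "")[[1]]]), ...)
}

# an interval covering exactly the first n epochs of a 4-s hypnogram
whole_interval <- function(n) data.frame(name = "ALL", start = 0,
                                         end = n * 4 / 3600)

random_hypnogram <- function(n, seed) {
  set.seed(seed)
  hypnogram(sample(vigilance_states(), n, replace = TRUE,
                   prob = c(0.5, 0.4, 0.1)))
}

# single-phase preset built around one transition matrix
single_phase_preset <- function(P, line_id = "X") {
  line_preset(line_id, list(LIGHT = P, DARK = P),
              default_line_presets()$IR$band_profile,
              c(WAKE = 30, NREMS = 10, REMS = 2),
              c(WAKE = 40, NREMS = 80, REMS = 50))
}

# brute-force per-epoch state counting
oracle_durations <- function(states) {
  out <- c(WAKE = 0, NREMS = 0, REMS = 0)
  for (s in states) out[s] <- out[s] + 1
  out / length(states)
}

# brute-force transition counting over the whole sequence
oracle_transitions <- function(states) {
  out <- stats::setNames(rep(0L, 6L), srsleep:::transition_pairs())
  for (i in 2:length(states)) {
    if (states[i] != states[i - 1]) {
      k <- paste0(states[i - 1], "->", states[i])
      out[k] <- out[k] + 1L
    }
  }
  out
}

# brute-force run-length REMS episode extraction (seconds)
oracle_rems_episodes <- function(states, epoch_seconds = 4) {
  lens <- c()
  run <- 0L
  for (s in c(states, "WAKE")) {
    if (s == "REMS") run <- run + 1L
    else {
      if (run > 0L) lens <- c(lens, run * epoch_seconds)
      run <- 0L
    }
  }
  lens
}

# stationary distribution by power iteration (independent of eigen())
oracle_stationary <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.vector(v %*% P)
  stats::setNames(v, rownames(P))
}

# minimal epoch-features frame for scorer unit tests
features_frame <- function(emg, delta, theta) {
  n <- length(emg)
  data.frame(epoch_index = seq_len(n), zt = (seq_len(n) - 1) * 4 / 3600,
             total_power = 1, emg_rms = emg,
             rel_defined = !is.na(delta),
             power_delta = delta, rel_delta = delta,
             power_theta = theta, rel_theta = theta,
             power_alpha = 0, rel_alpha = 0,
             power_eta = 0, rel_eta = 0,
             power_beta = 0, rel_beta = 0)
}

# 4-s sinusoid sampled at 64 Hz
sinusoid_epoch <- function(freq, amp = 1, n = 256, fs = 64) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs)
}
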