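test_that("unreachable and absorbing states behave as the matrices dictate", {
  st <- vigilance_states()
  # REMS unreachable when P(NREMS->REMS) = 0 and no other route exists
  P <- rbind(c(0.9, 0.1, 0), c(0.1, 0.9, 0), c(0.5, 0.5, 0))
  dimnames(P) <- list(st, st)
  h <- simulate_hypnogram(single_phase_preset(P), sim_config(recording_hours = 1),
                          animal_seed = 7, init = "NREMS")
  expect_false("REMS" %in% h$states)

  # identity matrix: every epoch stays in the initial state
  I3 <- diag(3); dimnames(I3) <- list(st, st)
  h2 <- simulate_hypnogram(single_phase_preset(I3), sim_config(),
                           animal_seed = 7, init = "WAKE")
  expect_equal(length(h2$states), 20700L)
  expect_true(all(h2$states == "WAKE"))
})

test_that("ergodic chains recover the stationary distribution of the matrix", {
  st <- vigilance_states()
  P <- rbind(c(0.96, 0.04, 0.00),
             c(0.03, 0.95, 0.02),
             c(0.05, 0.01, 0.94))
  dimnames(P) <- list(st, st)
  cfg <- sim_config(recording_hours = 1112, lights_off_zt = 1e6)  # ~1e6 epochs
  h <- simulate_hypnogram(single_phase_preset(P), cfg, animal_seed = 11)
  frac <- table(factor(h$states, levels = st)) / length(h$states)
  pi_oracle <- oracle_stationary(P)
  expect_lt(max(abs(as.vector(frac) - pi_oracle)), 0.01)
})

test_that("sampled next-state frequencies match the matrix rows (chi-square GOF)", {
  st <- vigilance_states()
  P <- rbind(c(0.7, 0.2, 0.1),
             c(0.3, 0.5, 0.2),
             c(0.25, 0.25, 0.5))
  dimnames(P) <- list(st, st)
  cfg <- sim_config(recording_hours = 400, lights_off_zt = 1e6)
  h <- simulate_hypnogram(single_phase_preset(P), cfg, animal_seed = 5)
  s <- match(h$states, st)
  for (from in 1:3) {
    idx <- which(s[-length(s)] == from)
    obs <- table(factor(s[idx + 1L], levels = 1:3))
    expect_gt(sum(obs), 5e4)
    gof <- suppressWarnings(chisq.test(obs, p = P[from, ]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("invalid configurations are rejected", {
  st <- vigilance_states()
  bad <- diag(3) * 0.9; dimnames(bad) <- list(st, st)
  expect_error(single_phase_preset(bad), "row-stochastic")
  expect_error(sim_config(recording_hours = 0))
  expect_error(sim_config(epoch_seconds = 7),  "divisible")
})

test_that("a cohort is the configured size and reproducible from one seed", {
  cfg <- sim_config(n_animals_per_line = 8, n_days = 2, seed = 123)
  co1 <- simulate_cohort(config = cfg)
  expect_length(co1$animals, 24L)
  expect_equal(sum(vapply(co1$animals, `[[`, "", "line") == "HR"), 8L)
  expect_true(all(vapply(co1$animals, function(a)
    length(a$hypnograms), 0L) == 2L))
  ids <- vapply(co1$animals, `[[`, "", "animal_id")
  expect_false(anyDuplicated(ids) > 0)
  co2 <- simulate_cohort(config = cfg)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(config = sim_config(seed = 124))
  expect_false(identical(co1$animals[[1]]$hypnograms[[1]]$states,
                         co3$animals[[1]]$hypnograms[[1]]$states))
})

test_that("shipped presets are ordered as the breeding lines require", {
  p <- default_line_presets()
  for (ph in c("LIGHT", "DARK")) {
    n2r <- vapply(p, function(x) x$transition[[ph]]["NREMS", "REMS"], 0)
    expect_gt(n2r[["HR"]], n2r[["IR"]])
    expect_gte(n2r[["IR"]], n2r[["LR"]])
  }
  expect_lt(p$LR$band_profile["NREMS", "theta"],
            min(p$HR$band_profile["NREMS", "theta"],
                p$IR$band_profile["NREMS", "theta"]))
  expect_lt(p$LR$band_profile["NREMS", "alpha"],
            min(p$HR$band_profile["NREMS", "alpha"],
                p$IR$band_profile["NREMS", "alpha"]))
  # atonia ordering enforced by the constructor
  for (x in p)
    expect_true(x$emg_level[["REMS"]] < x$emg_level[["NREMS"]] &&
                  x$emg_level[["NREMS"]] < x$emg_level[["WAKE"]])
})

test_that("signal synthesis hits the requested spectral and amplitude targets", {
  p <- default_line_presets()$HR
  p$spectral_jitter <- 0                    # exact targets for this check
  cfg <- sim_config(recording_hours = 1, lights_off_zt = 2)
  h <- simulate_hypnogram(p, cfg, animal_seed = 3)
  rec <- synthesize_signals(h, p, cfg, seed = 4)
  expect_equal(length(rec$eeg), 900 * 256)
  fe <- epoch_features(rec)

  # direct-DFT oracle on each epoch: measured band fractions vs targets
  scheme <- band_scheme()
  freqs <- (0:128) * 0.25
  err <- c()
  for (i in seq_len(50)) {
    x <- rec$eeg[((i - 1) * 256 + 1):(i * 256)]
    X <- fft(x)
    pw <- Mod(X[1:129])^2 / 256^2
    pw[2:128] <- 2 * pw[2:128]
    tot <- sum(pw[freqs >= 0.75 & freqs <= 31.75])
    target <- p$band_profile[h$states[i], ]
    for (b in seq_len(nrow(scheme))) {
      sel <- freqs >= scheme$low[b] & freqs <= scheme$high[b]
      err <- c(err, abs(sum(pw[sel]) / tot - target[[b]]))
    }
  }
  expect_lt(mean(err), 0.05)

  # epoch RMS equals the state amplitude exactly by construction
  m <- matrix(rec$eeg, 256)
  rms <- sqrt(colMeans(m^2))
  expect_equal(rms, unname(p$eeg_amplitude[h$states]), tolerance = 1e-10)

  # EMG atonia: a zero EMG level produces an exactly silent channel
  p0 <- p; p0$emg_level[["REMS"]] <- 0
  rec0 <- synthesize_signals(h, p0, cfg, seed = 4)
  emg_epochs <- matrix(rec0$emg, 256)
  expect_true(all(emg_epochs[, h$states == "REMS"] == 0))

  # reproducibility and length mismatch error
  expect_identical(rec$eeg, synthesize_signals(h, p, cfg, seed = 4)$eeg)
  expect_error(synthesize_signals(h, p, sim_config(), seed = 4), "match")
})
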