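test_that("toy hypnograms give the forced durations, transitions and episodes", {
  h <- hyp_from_string("WWNNRW")
  iv <- whole_interval(6)
  expect_equal(normed_durations(h, iv),
               c(WAKE = 1/2, NREMS = 1/3, REMS = 1/6))
  tf <- transition_frequencies(h, iv)
  expect_equal(tf$counts[c("WAKE->NREMS", "NREMS->REMS", "REMS->WAKE")],
               c("WAKE->NREMS" = 1L, "NREMS->REMS" = 1L, "REMS->WAKE" = 1L))
  expect_equal(sum(tf$counts), 3L)
  expect_true(all(tf$normed[tf$counts == 1L] == 1/3))

  expect_equal(normed_durations(hyp_from_string("WWWW"), whole_interval(4)),
               c(WAKE = 1, NREMS = 0, REMS = 0))
  tf0 <- transition_frequencies(hyp_from_string("NNNN"), whole_interval(4))
  expect_true(all(tf0$counts == 0L))
  expect_true(all(is.na(tf0$normed)))

  expect_equal(rems_episodes(hyp_from_string("NRRNR"), whole_interval(5)),
               c(8, 4))
  expect_equal(mean(rems_episodes(hyp_from_string("NRRNR"), whole_interval(5))), 6)
  expect_length(rems_episodes(hyp_from_string("WNWN"), whole_interval(4)), 0)
  expect_error(normed_durations(h, data.frame(start = 5, end = 10)),
               "outside")
})

test_that("metrics equal brute-force oracles on random hypnograms", {
  for (s in 1:25) {
    h <- random_hypnogram(300, seed = 1000 + s)
    iv <- whole_interval(300)
    expect_identical(unname(normed_durations(h, iv)),
                     unname(oracle_durations(h$states)))
    expect_identical(unname(transition_frequencies(h, iv)$counts),
                     unname(oracle_transitions(h$states)))
    expect_identical(rems_episodes(h, iv),
                     as.numeric(oracle_rems_episodes(h$states)))
  }
})

test_that("interval accounting conserves mass and splits without loss", {
  h <- random_hypnogram(20700, seed = 77)
  total <- transition_frequencies(h, data.frame(start = 0, end = 23))$counts
  by_iv <- sapply(time_intervals()$name,
                  function(iv) transition_frequencies(h, iv)$counts)
  expect_identical(unname(rowSums(by_iv)), as.numeric(unname(total)))
  for (iv in time_intervals()$name) {
    d <- normed_durations(h, iv)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    tf <- transition_frequencies(h, iv)
    expect_equal(sum(tf$normed), 1, tolerance = 1e-12)
    # entries/exits balance up to boundary effects
    cnt <- tf$counts
    for (st in vigilance_states()) {
      into <- sum(cnt[grepl(paste0("->", st, "$"), names(cnt))])
      outof <- sum(cnt[grepl(paste0("^", st, "->"), names(cnt))])
      expect_lte(abs(into - outof), 1L)
    }
  }
})

test_that("higher REMS time can come from episode count alone", {
  # same episode-length multiset {8 s, 4 s}, tripled count in the second
  base <- "NNNNNNNNRRNNNNNNNNRNNNNNNNNNNNNNNNNNNNNNNNNNNNNN"
  more <- "NNNNRRNNRNNNNRRNNRNNNNRRNNRNNNNNNNNNNNNNNNNNNNNN"
  h1 <- hyp_from_string(base); h2 <- hyp_from_string(more)
  iv <- whole_interval(nchar(base))
  e1 <- rems_episodes(h1, iv); e2 <- rems_episodes(h2, iv)
  expect_equal(mean(e1), mean(e2))
  expect_equal(length(e2), 3L * length(e1))
  expect_gt(normed_durations(h2, iv)[["REMS"]],
            normed_durations(h1, iv)[["REMS"]])
})

test_that("episodes are attributed to the interval of their first epoch", {
  # one REMS run straddling ZT6 (epoch 5400 is the last of L1)
  states <- rep("NREMS", 7200)
  states[5398:5403] <- "REMS"
  h <- hypnogram(states)
  expect_equal(rems_episodes(h, "L1"), 24)   # 6 epochs, assigned to L1
  expect_length(rems_episodes(h, "L2"), 0)
  # transition at the boundary belongs to the later epoch's interval
  tfL2 <- transition_frequencies(h, "L2")
  expect_equal(tfL2$counts[["REMS->NREMS"]], 1L)
})

test_that("per-animal summaries average days and recompute normed transitions", {
  h1 <- hyp_from_string("WWNNRRWWNNNN")
  h2 <- hyp_from_string("WWWWWWNNNNRR")
  # single day equals the direct metrics
  s1 <- summarize_animal(list(h1))
  iv <- whole_interval(12)   # 12 epochs sit inside L1
  d1 <- normed_durations(h1, "L1")
  expect_equal(s1$value[s1$metric == "normed_duration"], unname(d1))
  # two identical days: averaged metrics unchanged, raw counts doubled
  s11 <- summarize_animal(list(h1, h1))
  keep <- s11$metric != "transition_count"
  expect_equal(s11$value[keep], s1$value[keep])
  expect_equal(s11$value[!keep], 2 * s1$value[!keep])
  # two distinct days: durations averaged, counts summed, normed recomputed
  s12 <- summarize_animal(list(h1, h2))
  expect_equal(
    s12$value[s12$metric == "normed_duration"],
    unname((normed_durations(h1, "L1") + normed_durations(h2, "L1")) / 2))
  c1 <- transition_frequencies(h1, "L1")$counts
  c2 <- transition_frequencies(h2, "L1")$counts
  expect_equal(s12$value[s12$metric == "transition_count"],
               as.numeric(unname(c1 + c2)))
  expect_equal(s12$value[s12$metric == "normed_transition"],
               unname((c1 + c2) / sum(c1 + c2)))
  # mean REMS episode length: per-day means averaged with equal weight
  m1 <- mean(rems_episodes(h1, "L1")); m2 <- mean(rems_episodes(h2, "L1"))
  expect_equal(s12$value[s12$metric == "mean_rems_episode_length"][1],
               (m1 + m2) / 2)
  expect_error(summarize_animal(list(h1, hyp_from_string("WWW"))), "unequal")
})

test_that("hourly transition counts agree with whole-interval counts", {
  h <- random_hypnogram(20700, seed = 5)
  ht <- hourly_transition_frequencies(h)
  total <- transition_frequencies(h, data.frame(start = 0, end = 23))$counts
  agg <- tapply(ht$count, ht$pair, sum)
  expect_equal(as.numeric(agg[names(total)]), as.numeric(unname(total)))
  expect_equal(sort(unique(ht$zt_hour)), 1:23)
})
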