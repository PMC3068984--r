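#' Per-group excess over the common median
#'
#' At each ZT point, the common median is the median of the group-level
#' values across all groups; each group's excess is its value minus that
#' median. Points at which every group is missing are dropped for all
#' groups.
#'
#' @param series Numeric matrix: rows = groups (named), columns = ZT
#'   points (named or indexed 1..23). `NA` allowed.
#' @return Matrix of the same shape with the per-point common median
#'   subtracted (all-missing columns removed).
#' @export
common_median_excess <- function(series) {
  stopifnot(is.matrix(series), nrow(series) >= 2L)
  all_na <- apply(series, 2, function(x) all(is.na(x)))
  series <- series[, !all_na, drop = FALSE]
  med <- apply(series, 2, stats::median, na.rm = TRUE)
  sweep(series, 2, med)
}

#' Wilcoxon matched-pairs stability test
#'
#' Tests whether one group's curve lies consistently above or below
#' another's across the experimental time: a Wilcoxon signed-rank test on
#' the paired per-ZT differences of the two groups' excesses over the
#' common median. Zero differences are dropped (Wilcoxon's prescription);
#' with no ties and at most 25 informative pairs the exact null
#' distribution is used, otherwise a normal approximation with tie
#' correction and continuity correction. A pair is labelled *stable* when
#' the test is significant at `alpha` and the sign of the difference is
#' constant over at least `sign_consistency` of the paired points
#' (operationalising "stable and continuously above/below").
#'
#' @param excess_a,excess_b Paired numeric series (same ZT grid).
#' @param alpha Significance level for the direction/stability call.
#' @param sign_consistency Minimum fraction of points sharing the
#'   majority sign for the `stable` flag.
#' @return List: `n_pairs` (informative, non-zero pairs), `statistic`
#'   (W+, the positive-rank sum), `p` (two-sided), `direction` (`"A>B"`,
#'   `"B>A"` or `"none"`), `stable` (logical).
#' @export
stability_test <- function(excess_a, excess_b, alpha = 0.05,
                           sign_consistency = 0.9) {
  ok <- !is.na(excess_a) & !is.na(excess_b)
  d_all <- excess_a[ok] - excess_b[ok]
  if (length(d_all) < 10L)
    stop("need at least 10 paired non-missing points", call. = FALSE)
  d <- d_all[d_all != 0]
  n <- length(d)
  if (n == 0L)
    return(list(n_pairs = 0L, statistic = NA_real_, p = 1,
                direction = "none", stable = FALSE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    p <- exact_signrank_p(r, W)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  direction <- "none"
  if (p < alpha)
    direction <- if (stats::median(d) > 0) "A>B" else "B>A"
  frac_pos <- mean(d_all > 0)
  frac_neg <- mean(d_all < 0)
  stable <- p < alpha && max(frac_pos, frac_neg) >= sign_consistency &&
    ((direction == "A>B" && frac_pos >= frac_neg) ||
       (direction == "B>A" && frac_neg >= frac_pos))
  list(n_pairs = n, statistic = W, p = p, direction = direction,
       stable = stable)
}

# Exact two-sided p of the signed-rank statistic under random sign flips,
# valid with mid-ranked ties: dynamic programming over the doubled ranks
# (integers), counting sign-flip subsets by rank sum. Reduces to
# stats::psignrank when all |d| are distinct.
exact_signrank_p <- function(r, W) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  counts <- numeric(tot + 1L)            # counts[s + 1] = #subsets of sum s
  counts[1L] <- 1
  for (w in r2) {
    idx <- seq.int(tot - w + 1L, 1L)
    counts[idx + w] <- counts[idx + w] + counts[idx]
  }
  cum <- cumsum(counts) / 2^n
  W2 <- as.integer(round(2 * W))
  p_le <- cum[W2 + 1L]
  p_ge <- 1 - (if (W2 >= 1L) cum[W2] else 0)
  min(1, 2 * min(p_le, p_ge))
}

#' Full stability screen over bands and transitions
#'
#' Runs [common_median_excess()] plus [stability_test()] for every
#' quantity and every ordered group pair, and reports the complete table
#' (no selective reporting). Band quantities are hourly group-mean
#' relative powers per vigilance state; transition quantities are hourly
#' group-mean transition counts per ordered state pair. An optional
#' Benjamini-Hochberg column is appended for reference; the `stable` flag
#' itself uses the unadjusted level, matching the nominal p < 0.05
#' convention of the underlying analysis.
#'
#' @param band_series Data frame `group`, `state`, `band`, `zt_hour`,
#'   `value` (group-mean relative power), or `NULL`.
#' @param transition_series Data frame `group`, `pair`, `zt_hour`,
#'   `value` (group-mean transition count), or `NULL`.
#' @param alpha Significance level.
#' @return Data frame: `quantity`, `state`, `band_or_pair`, `group_a`,
#'   `group_b`, `n_pairs`, `W`, `p`, `p_bh`, `direction`, `stable`.
#' @export
stability_screen <- function(band_series = NULL, transition_series = NULL,
                             alpha = 0.05) {
  rows <- list()
  screen_one <- function(df, quantity, state, label) {
    groups <- sort(unique(df$group))
    grid <- sort(unique(df$zt_hour))
    mat <- matrix(NA_real_, length(groups), length(grid),
                  dimnames = list(groups, grid))
    mat[cbind(match(df$group, groups), match(df$zt_hour, grid))] <- df$value
    exc <- common_median_excess(mat)
    res <- list()
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i == j) next
      t <- stability_test(exc[groups[i], ], exc[groups[j], ], alpha = alpha)
      res[[length(res) + 1L]] <- data.frame(
        quantity = quantity, state = state, band_or_pair = label,
        group_a = groups[i], group_b = groups[j], n_pairs = t$n_pairs,
        W = t$statistic, p = t$p, direction = t$direction,
        stable = t$stable)
    }
    do.call(rbind, res)
  }
  if (!is.null(band_series)) {
    for (st in unique(band_series$state)) {
      for (b in unique(band_series$band)) {
        sub <- band_series[band_series$state == st & band_series$band == b, ]
        rows[[length(rows) + 1L]] <-
          screen_one(sub, "band_power", st, b)
      }
    }
  }
  if (!is.null(transition_series)) {
    for (pr in unique(transition_series$pair)) {
      sub <- transition_series[transition_series$pair == pr, ]
      rows[[length(rows) + 1L]] <-
        screen_one(sub, "transition_frequency", NA_character_, pr)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_bh <- stats::p.adjust(out$p, method = "BH")
    out <- out[c("quantity", "state", "band_or_pair", "group_a", "group_b",
                 "n_pairs", "W", "p", "p_bh", "direction", "stable")]
    rownames(out) <- NULL
  }
  out
}

#' Group-mean hourly transition series for a cohort
#'
#' Per line and ordered pair: the mean across animals of per-hour
#' transition counts (days averaged within animal first).
#'
#' @param cohort An `sr_cohort` or list of animal records.
#' @return Data frame `group`, `pair`, `zt_hour`, `value`.
#' @export
cohort_transition_series <- function(cohort) {
  animals <- if (inherits(cohort, "sr_cohort")) cohort$animals else cohort
  per_animal <- lapply(animals, function(a) {
    days <- lapply(a$hypnograms, hourly_transition_frequencies)
    base <- days[[1]][c("zt_hour", "pair")]
    base$value <- rowMeans(sapply(days, `[[`, "count"))
    cbind(line = a$line, base)
  })
  all <- do.call(rbind, per_animal)
  agg <- stats::aggregate(value ~ line + pair + zt_hour, all, mean)
  data.frame(group = agg$line, pair = agg$pair, zt_hour = agg$zt_hour,
             value = agg$value)
}
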