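#' Trapezoid-rule area under an hourly band-power curve
#'
#' Integrates the hourly mean relative power of one band over the ZT
#' points falling inside a time interval (unit spacing, trapezoid rule).
#' Interior missing hours are linearly interpolated; missing endpoint
#' hours are dropped with a warning, shrinking the integration range.
#'
#' @param profile Output of [hourly_band_profile()] (or any data frame
#'   with `zt_hour`, `band`, `mean_rel_power`).
#' @param interval Interval name or `start`/`end` data frame (inclusive ZT
#'   bounds for point selection).
#' @param band Band name; if `NULL`, all bands in `profile`.
#' @return Data frame `band`, `auc` (relative-power x hours); `auc` is
#'   `NA` when fewer than two non-missing points remain.
#' @export
band_auc <- function(profile, interval, band = NULL) {
  iv <- resolve_interval(interval)
  bands <- if (is.null(band)) unique(profile$band) else band
  out <- data.frame(band = bands, auc = NA_real_)
  for (b in bands) {
    sub <- profile[profile$band == b &
                     profile$zt_hour >= iv$start - 1e-9 &
                     profile$zt_hour <= iv$end + 1e-9, ]
    sub <- sub[order(sub$zt_hour), ]
    y <- sub$mean_rel_power
    x <- sub$zt_hour
    if (anyNA(y)) {
      if (is.na(y[1]) || is.na(y[length(y)])) {
        warning("missing endpoint hour(s) dropped for band ", b,
                " in ", iv$name %||% "interval", call. = FALSE)
        ok <- which(!is.na(y))
        if (length(ok) < 2L) next
        x <- x[ok[1]:ok[length(ok)]]
        y <- y[ok[1]:ok[length(ok)]]
      }
      if (anyNA(y))
        y <- stats::approx(x[!is.na(y)], y[!is.na(y)], xout = x)$y
    }
    if (length(y) >= 2L)
      out$auc[out$band == b] <- pracma::trapz(x, y)
  }
  out
}

#' One-way analysis of variance on a group design
#'
#' Standard between/within decomposition via [stats::lm()]. Animals with
#' a missing response are excluded listwise; the exclusion is recorded in
#' the result.
#'
#' @param y Numeric response, one value per animal.
#' @param group Factor or character vector of group labels.
#' @return List with `F`, `df1`, `df2`, `p`, `n`, `n_excluded` and the
#'   per-group means.
#' @export
oneway_anova <- function(y, group) {
  group <- as.factor(group)
  ok <- !is.na(y) & !is.na(group)
  n_excl <- sum(!ok)
  y <- y[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2L)
    stop("need at least 2 groups with data", call. = FALSE)
  if (any(table(group) < 2L))
    stop("need at least 2 observations per group", call. = FALSE)
  a <- stats::anova(stats::lm(y ~ group))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1], n = length(y), n_excluded = n_excl,
       group_means = tapply(y, group, mean),
       mse = a$`Mean Sq`[2])
}

#' Bonferroni-modified LSD pairwise contrasts
#'
#' Fisher's least-significant-difference t tests on all group pairs,
#' using the pooled within-group mean square and its error degrees of
#' freedom, with the decision threshold Bonferroni-divided by the number
#' of pairs. Raw p values are reported alongside the adjusted decision.
#' Callers enforce the omnibus gate (contrasts are only interpreted after
#' a significant global test).
#'
#' @inheritParams oneway_anova
#' @param alpha Nominal familywise level.
#' @param divisor Bonferroni divisor; defaults to the number of pairs.
#' @return Data frame `group_a`, `group_b`, `mean_diff`, `t`, `df`,
#'   `p_raw`, `alpha_adjusted`, `significant`.
#' @export
lsd_contrasts <- function(y, group, alpha = 0.05, divisor = NULL) {
  group <- as.factor(group)
  ok <- !is.na(y) & !is.na(group)
  y <- y[ok]; group <- droplevels(group[ok])
  lev <- levels(group)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  a <- oneway_anova(y, group)
  if (a$mse <= 0) stop("zero within-group mean square", call. = FALSE)
  ns <- table(group)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  if (is.null(divisor)) divisor <- m
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    mean_diff = NA_real_, t = NA_real_,
                    df = a$df2, p_raw = NA_real_,
                    alpha_adjusted = alpha / divisor, significant = NA)
  for (i in seq_len(m)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    d <- a$group_means[[g1]] - a$group_means[[g2]]
    se <- sqrt(a$mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tt <- d / se
    p <- 2 * stats::pt(-abs(tt), a$df2)
    res$mean_diff[i] <- d; res$t[i] <- tt; res$p_raw[i] <- p
    res$significant[i] <- p < alpha / divisor
  }
  res
}

#' MANOVA with Wilks' lambda and Rao's F approximation
#'
#' One-way multivariate analysis of variance: Wilks' lambda from the
#' between- and within-group SSCP matrices (via the eigenvalues of
#' W^-1 B), Rao's F approximation with its standard degrees of freedom,
#' univariate follow-up F tests per response (evaluated at a
#' Bonferroni-adjusted level alpha/m), and pairwise LSD contrasts per
#' response computed only when the global test is significant at `alpha`
#' (the omnibus gate); contrasts are decided at alpha divided by the
#' number of group pairs.
#'
#' Degenerate responses are handled before testing: zero-variance columns
#' are dropped, and while the remaining columns sum to a constant (a
#' compositional constraint, e.g. normed durations summing to 1) the
#' column with the smallest variance is dropped; dropped responses are
#' listed in the result.
#'
#' @param Y Numeric matrix or data frame, one row per animal, one column
#'   per response variable.
#' @param group Group labels, one per animal.
#' @param alpha Nominal level for the omnibus gate.
#' @param univariate_divisor,contrast_divisor Bonferroni divisors for the
#'   follow-up tests; default to the number of (retained) responses and
#'   the number of group pairs.
#' @return Object of class `manova_result`: list with `wilks_lambda`,
#'   `F_approx`, `df1`, `df2`, `p`, `n`, `responses`, `dropped`,
#'   `univariate` (data frame) and `contrasts` (data frame or `NULL`).
#' @export
wilks_manova <- function(Y, group, alpha = 0.05,
                         univariate_divisor = NULL,
                         contrast_divisor = NULL) {
  Y <- as.matrix(Y)
  group <- as.factor(group)
  cc <- stats::complete.cases(Y) & !is.na(group)
  n_excl <- sum(!cc)
  Y <- Y[cc, , drop = FALSE]
  group <- droplevels(group[cc])
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)

  # degeneracy rule: drop constant columns, then break compositional
  # sum-to-constant constraints by dropping the smallest-variance column
  dropped <- character()
  repeat {
    v <- apply(Y, 2, stats::var)
    const <- v <= .Machine$double.eps * 100
    if (any(const)) {
      dropped <- c(dropped, colnames(Y)[const])
      Y <- Y[, !const, drop = FALSE]
      next
    }
    if (ncol(Y) >= 2L && stats::var(rowSums(Y)) <
        1e-10 * mean(apply(Y, 2, stats::var))) {
      i <- which.min(v)
      dropped <- c(dropped, colnames(Y)[i])
      Y <- Y[, -i, drop = FALSE]
      next
    }
    break
  }
  p <- ncol(Y)
  if (p < 1L) stop("no non-degenerate response variables left", call. = FALSE)
  N <- nrow(Y)
  if (N - g < p)
    stop("too few error degrees of freedom (", N - g, ") for ", p,
         " responses", call. = FALSE)

  sscp <- function(Y, group) {
    p <- ncol(Y)
    gm <- colMeans(Y)
    W <- matrix(0, p, p)
    B <- matrix(0, p, p)
    for (lev in levels(group)) {
      Yg <- Y[group == lev, , drop = FALSE]
      mg <- colMeans(Yg)
      W <- W + crossprod(sweep(Yg, 2, mg))
      B <- B + nrow(Yg) * tcrossprod(mg - gm)
    }
    list(W = W, B = B)
  }
  # conditioning guard: a (near-)exact within-group dependency -- e.g. the
  # entry/exit flow balance that ties the transition frequencies of a
  # closed interval together, broken only by interval-boundary effects --
  # sheds the smallest-variance response until the within-SSCP is well
  # conditioned; every shed response is recorded in `dropped`
  repeat {
    m <- sscp(Y, group)
    rc <- rcond(m$W / mean(diag(m$W)))
    if (rc >= 1e-8 || ncol(Y) == 1L) break
    i <- which.min(apply(Y, 2, stats::var))
    dropped <- c(dropped, colnames(Y)[i])
    Y <- Y[, -i, drop = FALSE]
    p <- ncol(Y)
  }
  if (ncol(Y) == 1L && rc < 1e-8)
    stop("within-group SSCP is singular and no response can be dropped; ",
         "degenerate design for response ", colnames(Y), call. = FALSE)
  W <- m$W
  B <- m$B
  eig <- Re(eigen(solve(W, B), only.values = TRUE)$values)
  eig <- pmax(eig, 0)
  lambda <- prod(1 / (1 + eig))

  # Rao's F approximation
  q <- g - 1
  df_res <- N - g
  tmp1 <- df_res - (p - q + 1) / 2
  tmp2 <- p * q - 2
  s <- if (p^2 + q^2 - 5 > 0) sqrt(((p * q)^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- tmp1 * s - tmp2 / 2
  Fap <- (lambda^(-1 / s) - 1) * df2 / df1
  pval <- stats::pf(Fap, df1, df2, lower.tail = FALSE)

  if (is.null(univariate_divisor)) univariate_divisor <- p
  uni <- do.call(rbind, lapply(colnames(Y), function(cn) {
    a <- oneway_anova(Y[, cn], group)
    data.frame(response = cn, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               alpha_adjusted = alpha / univariate_divisor,
               significant = a$p < alpha / univariate_divisor)
  }))

  contrasts <- NULL
  if (!is.na(pval) && pval < alpha) {
    contrasts <- do.call(rbind, lapply(colnames(Y), function(cn) {
      cbind(response = cn,
            lsd_contrasts(Y[, cn], group, alpha = alpha,
                          divisor = contrast_divisor))
    }))
  }

  structure(
    list(wilks_lambda = lambda, F_approx = Fap, df1 = df1, df2 = df2,
         p = pval, n = N, n_excluded = n_excl, groups = levels(group),
         responses = colnames(Y), dropped = dropped,
         univariate = uni, contrasts = contrasts),
    class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA (Wilks): Lambda = %.4f; F_(%g,%g) = %.3f; p = %.4g; N = %d\n",
              x$wilks_lambda, x$df1, round(x$df2, 1), x$F_approx, x$p, x$n))
  if (length(x$dropped))
    cat("  dropped degenerate response(s):",
        paste(x$dropped, collapse = ", "), "\n")
  cat("  univariate follow-up F tests:\n")
  print(x$univariate, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("  pairwise LSD contrasts (Bonferroni-adjusted decisions):\n")
    print(x$contrasts, row.names = FALSE)
  } else {
    cat("  omnibus not significant: contrasts withheld\n")
  }
  invisible(x)
}

# reshape a long cohort summary into an animals x keys response matrix
summary_matrix <- function(summaries, iv, metric) {
  sub <- summaries[summaries$interval == iv & summaries$metric == metric, ]
  keys <- unique(sub$key)
  ids <- unique(sub$animal_id)
  Y <- matrix(NA_real_, length(ids), length(keys),
              dimnames = list(ids, keys))
  Y[cbind(match(sub$animal_id, ids), match(sub$key, keys))] <- sub$value
  line <- sub$line[match(ids, sub$animal_id)]
  list(Y = Y, group = line, ids = ids)
}

#' Interval-wise statistical battery on a cohort summary
#'
#' For every canonical time interval: a MANOVA on the normed state
#' durations (WAKE dropped; the three fractions sum to 1), a MANOVA on
#' the normed transition frequencies (compositional and structurally zero
#' pairs handled by the degeneracy rule of [wilks_manova()]), and a
#' one-way ANOVA on the mean REMS episode length (animals without an
#' episode in an interval excluded listwise).
#'
#' @param summaries Long data frame from [cohort_interval_summaries()].
#' @param alpha Nominal level.
#' @return Named list per interval, each with elements `durations`,
#'   `transitions` (both `manova_result`) and `rems_episode_length`
#'   (list from [oneway_anova()] plus LSD contrasts when significant).
#' @export
group_statistics <- function(summaries, alpha = 0.05) {
  out <- list()
  for (iv in time_intervals()$name) {
    dur <- summary_matrix(summaries, iv, "normed_duration")
    Yd <- dur$Y[, c("NREMS", "REMS"), drop = FALSE]
    trn <- summary_matrix(summaries, iv, "normed_transition")
    ep <- summary_matrix(summaries, iv, "mean_rems_episode_length")
    an <- oneway_anova(ep$Y[, 1], ep$group)
    an$contrasts <- if (an$p < alpha)
      lsd_contrasts(ep$Y[, 1], ep$group, alpha = alpha) else NULL
    out[[iv]] <- list(
      durations = wilks_manova(Yd, dur$group, alpha = alpha),
      transitions = wilks_manova(trn$Y, trn$group, alpha = alpha),
      rems_episode_length = an)
  }
  out
}

#' Band-power AUC statistics per interval
#'
#' Builds per-animal trapezoid AUCs of the hourly relative band powers
#' and runs a five-response MANOVA per interval.
#'
#' @param profiles Data frame of per-animal hourly profiles: columns
#'   `animal_id`, `line`, `zt_hour`, `band`, `mean_rel_power`.
#' @param alpha Nominal level.
#' @return Named list per interval of `manova_result` objects.
#' @export
band_auc_statistics <- function(profiles, alpha = 0.05) {
  ids <- unique(profiles$animal_id)
  bands <- unique(profiles$band)
  out <- list()
  for (iv in time_intervals()$name) {
    Y <- matrix(NA_real_, length(ids), length(bands),
                dimnames = list(ids, bands))
    grp <- character(length(ids))
    for (i in seq_along(ids)) {
      sub <- profiles[profiles$animal_id == ids[i], ]
      grp[i] <- sub$line[1]
      a <- band_auc(sub, iv)
      Y[i, a$band] <- a$auc
    }
    out[[iv]] <- wilks_manova(Y, grp, alpha = alpha)
  }
  out
}
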