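test_that("trapezoid AUC matches closed forms and a summation oracle", {
  prof <- function(zt, y, band = "delta")
    data.frame(zt_hour = zt, band = band, mean_rel_power = y)
  iv06 <- data.frame(name = "X", start = 0, end = 6)
  expect_equal(band_auc(prof(0:6, rep(1, 7)), iv06)$auc, 6)
  expect_equal(band_auc(prof(0:2, c(0, 1, 2)), iv06)$auc, 2)
  set.seed(2)
  y <- runif(6)
  oracle <- sum((y[-6] + y[-1]) / 2)
  expect_equal(band_auc(prof(0:5, y), iv06)$auc, oracle, tolerance = 1e-12)
  # interior missing hour: linear interpolation changes nothing on a line
  y_lin <- c(0, 1, 2, NA, 4, 5)
  expect_equal(band_auc(prof(0:5, y_lin), iv06)$auc, 12.5)
  # missing endpoint dropped with a warning
  expect_warning(a <- band_auc(prof(0:5, c(NA, y[-1])), iv06)$auc, "endpoint")
  expect_equal(a, sum((y[2:5] + y[3:6]) / 2))
  # fewer than two points: undefined
  expect_warning(a1 <- band_auc(prof(0:1, c(NA, 1)), iv06)$auc)
  expect_true(is.na(a1))
})

test_that("one-way ANOVA reproduces the textbook fixture and edge cases", {
  y <- c(2, 4, 4, 6, 6, 8)
  g <- rep(c("a", "b", "c"), each = 2)
  a <- oneway_anova(y, g)
  expect_equal(a$F, 4)
  expect_equal(c(a$df1, a$df2), c(2, 3))
  # identical group means (mirror-symmetric within groups): F is exactly 0
  y0 <- c(1, 3, 1, 3, 1, 3)
  expect_equal(oneway_anova(y0, g)$F, 0)
  # listwise exclusion of missing responses is counted
  a2 <- oneway_anova(c(y, NA), c(g, "a"))
  expect_equal(a2$n_excluded, 1L)
  expect_equal(a2$F, 4)
  expect_error(oneway_anova(c(1, 2), c("a", "a")), "2 groups")
})

test_that("LSD contrasts use the pooled MSE and Bonferroni-divided alpha", {
  y <- c(2, 4, 4, 6, 6, 8)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- lsd_contrasts(y, g)
  expect_equal(nrow(res), 3L)
  expect_equal(res$alpha_adjusted, rep(0.05 / 3, 3), tolerance = 1e-12)
  # hand-computed t for the a-vs-c pair: MSE = 2, diff = -4
  mse <- 2
  t_hand <- -4 / sqrt(mse * (1 / 2 + 1 / 2))
  i <- which(res$group_a == "a" & res$group_b == "c")
  expect_equal(res$t[i], t_hand)
  expect_equal(res$df, rep(3, 3))
})

test_that("equal-mean groups are rarely declared different (type-I check)", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    y <- rnorm(16)
    g <- rep(c("a", "b"), each = 8)
    res <- lsd_contrasts(y, g, divisor = 1)   # nominal alpha, single pair
    if (res$p_raw[1] < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 6L)
})

test_that("Wilks MANOVA equals one-way ANOVA exactly for a single response", {
  set.seed(10)
  y <- rnorm(23)
  g <- rep(c("HR", "IR", "LR"), c(8, 8, 7))
  m <- wilks_manova(matrix(y, dimnames = list(NULL, "y")), g)
  a <- oneway_anova(y, g)
  expect_equal(m$F_approx, a$F, tolerance = 1e-12)
  expect_equal(c(m$df1, m$df2), c(a$df1, a$df2))
  expect_equal(m$p, a$p, tolerance = 1e-12)
})

test_that("Wilks lambda, F and df match the standard MANOVA fit on a 23x5 fixture", {
  set.seed(77)
  g <- factor(rep(c("HR", "IR", "LR"), c(8, 8, 7)))
  Y <- matrix(rnorm(23 * 5), 23, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  Y[g == "HR", 1] <- Y[g == "HR", 1] + 1.5
  m <- wilks_manova(Y, g)
  fit <- summary(stats::manova(Y ~ g), test = "Wilks")$stats
  expect_equal(m$wilks_lambda, fit["g", "Wilks"], tolerance = 1e-10)
  expect_equal(m$F_approx, fit["g", "approx F"], tolerance = 1e-10)
  expect_equal(m$df1, fit["g", "num Df"])
  expect_equal(m$df2, fit["g", "den Df"])
  expect_equal(c(m$df1, m$df2), c(10, 32))
  # eigen-decomposition oracle for lambda
  W <- crossprod(stats::resid(stats::lm(Y ~ g)))
  B <- crossprod(stats::resid(stats::lm(Y ~ 1))) - W
  lam_oracle <- prod(1 / (1 + Re(eigen(solve(W) %*% B)$values)))
  expect_equal(m$wilks_lambda, lam_oracle, tolerance = 1e-10)
})

test_that("MANOVA degeneracy, gatekeeping and invariance rules hold", {
  set.seed(4)
  g <- rep(c("HR", "IR", "LR"), each = 8)
  # identical group mean vectors (same values in every group): lambda 1, F 0
  Y0 <- matrix(rnorm(8 * 2), 8, 2)
  Y0 <- rbind(Y0, Y0, Y0)                          # same values per group
  colnames(Y0) <- c("a", "b")
  m0 <- wilks_manova(Y0, g)
  expect_equal(m0$wilks_lambda, 1, tolerance = 1e-10)
  expect_equal(m0$F_approx, 0, tolerance = 1e-8)
  expect_null(m0$contrasts)                        # omnibus gate holds

  # affine rescaling of one response leaves lambda unchanged
  set.seed(5)
  Y <- matrix(rnorm(24 * 3), 24, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y[g == "HR", ] <- Y[g == "HR", ] + 0.8
  m1 <- wilks_manova(Y, g)
  Y2 <- Y; Y2[, 2] <- 100 * Y2[, 2] - 7
  m2 <- wilks_manova(Y2, g)
  expect_equal(m1$wilks_lambda, m2$wilks_lambda, tolerance = 1e-10)

  # compositional responses: a sum-to-one triple drops one column
  comp <- cbind(Y[, 1], Y[, 2], 1 - Y[, 1] - Y[, 2])
  comp <- abs(comp) / rowSums(abs(comp))
  colnames(comp) <- c("W", "N", "R")
  mc <- wilks_manova(comp, g)
  expect_length(mc$dropped, 1L)
  expect_equal(length(mc$responses), 2L)
  # constant column is dropped too
  mz <- wilks_manova(cbind(Y, const = 1), g)
  expect_true("const" %in% mz$dropped)
  # duplicated response: the collinear copy is shed, the test proceeds
  mdup <- wilks_manova(cbind(a = Y[, 1], b = Y[, 1]), g)
  expect_length(mdup$dropped, 1L)
  expect_equal(mdup$F_approx, oneway_anova(Y[, 1], g)$F, tolerance = 1e-10)
  # gatekeeping: contrasts appear only with a significant omnibus
  if (m1$p < 0.05) expect_false(is.null(m1$contrasts))
})

test_that("univariate follow-ups are Bonferroni-adjusted per response count", {
  set.seed(6)
  g <- rep(c("HR", "IR", "LR"), each = 8)
  Y <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(NULL, paste0("v", 1:4)))
  m <- wilks_manova(Y, g)
  expect_equal(m$univariate$alpha_adjusted, rep(0.05 / 4, 4))
  expect_equal(nrow(m$univariate), 4L)
})
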