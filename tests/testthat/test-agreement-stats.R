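make_mm <- function(...) {
  cols <- list(...)
  method_measurements(data.frame(slide_id = paste0("S", seq_along(cols[[1]])), cols))
}

test_that("summary statistics use sample SD and exact range", {
  mm <- make_mm(a = c(10, 20), b = c(5, 5))
  s <- summarize_methods(mm)
  get <- function(col, stat) s[[col]][s$statistic == stat]
  expect_equal(get("a", "mean"), 15)
  expect_equal(get("a", "median"), 15)
  expect_equal(get("a", "range"), 10)
  expect_equal(get("b", "sd"), 0)
  expect_equal(get("b", "range"), 0)

  mm3 <- make_mm(x = c(0, 0, 100))
  s3 <- summarize_methods(mm3)
  expect_equal(s3$x[s3$statistic == "sd"], 57.735, tolerance = 1e-4)
  expect_equal(s3$x[s3$statistic == "sd"], 100 / sqrt(3))
})

test_that("pathologist mean is derived from the two readings", {
  mm <- method_measurements(data.frame(
    slide_id = c("a", "b"), pathologist_week0 = c(10, 20),
    pathologist_week2 = c(20, 30)))
  expect_equal(mm$pathologist_mean, c(15, 25))
})

test_that("the Pearson matrix matches hand-computed coefficients and flags degeneracy", {
  mm <- make_mm(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3), z = 2 * c(1, 2, 3, 4) + 3)
  cm <- pearson_matrix(mm)
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "z"], 1)           # affine invariance
  expect_equal(cm$r["x", "y"], 0.6)         # hand computation
  expect_equal(cm$r, t(cm$r))
  # p value agrees with cor.test
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(cm$p_value["x", "y"], ct$p.value)

  mm2 <- make_mm(x = c(1, 2, 3, 4), const = c(7, 7, 7, 7))
  expect_warning(cm2 <- pearson_matrix(mm2), "const")
  expect_true(is.na(cm2$r["x", "const"]))
  expect_identical(cm2$undefined, "const")
})

test_that("the Friedman statistic matches the brute-force rank formula and stats::friedman.test", {
  # 3 methods x 3 blocks, ranks enumerated by hand:
  # rows rank to (1,2,3), (2,3,1), (2,1,3); R = (5, 6, 7)
  x <- rbind(c(10, 20, 30), c(15, 25, 5), c(20, 10, 30))
  fr <- friedman_test(x)
  brute <- 12 / (3 * 3 * 4) * sum(c(5, 6, 7)^2) - 3 * 3 * 4
  expect_equal(fr$chi_square, brute)
  expect_equal(fr$df, 2L)

  # identical columns: all ranks tied, statistic 0 by convention
  same <- matrix(5, 4, 3)
  expect_equal(friedman_test(same)$chi_square, 0)

  # tie-free random data agrees with the reference implementation
  set.seed(42)
  y <- matrix(rnorm(60), 15, 4)
  fr4 <- friedman_test(y)
  ref <- stats::friedman.test(y)
  expect_equal(fr4$chi_square, unname(ref$statistic))
  expect_equal(fr4$p_value, ref$p.value)
  expect_equal(fr4$df, 3L)

  # rank-based: invariant to a joint strictly monotone transform
  expect_equal(friedman_test(exp(y / 10))$chi_square, fr4$chi_square)

  expect_error(friedman_test(y[, 1:2]), class = "fq_parameter_error")
})

test_that("Wilcoxon pairs use the signed-rank normal approximation with Bonferroni", {
  mm <- make_mm(a = c(10, 12, 9, 14, 20, 8, 7, 16),
                b = c(9, 15, 9, 10, 22, 5, 9, 11))
  pairs <- list(c("a", "b"), c("b", "a"), c("a", "a"), c("a", "b"))
  pc <- wilcoxon_pairs(mm, pairs, family_alpha = 0.05)
  expect_equal(attr(pc, "adjusted_alpha"), 0.0125)
  # sign flip when the pair is reversed
  expect_equal(pc$z_statistic[1], -pc$z_statistic[2])
  # degenerate pair flagged, not silently zero
  expect_true(pc$degenerate[3])
  # mean/SD of raw differences reported, zeros included
  d <- mm$a - mm$b
  expect_equal(pc$mean_difference[1], mean(d))
  expect_equal(pc$sd_difference[1], sd(d))
  # antisymmetric differences give Z = 0
  mm0 <- make_mm(a = c(1, 3, 2, 6), b = c(2, 2, 4, 4))  # d = -1, 1, -2, 2
  z0 <- wilcoxon_pairs(mm0, list(c("a", "b")))
  expect_equal(z0$z_statistic, 0)
  expect_equal(z0$p_value, 1)

  # normal approximation agrees with wilcox.test's tie-corrected version
  wt <- suppressWarnings(wilcox.test(mm$a, mm$b, paired = TRUE,
                                     exact = FALSE, correct = FALSE))
  expect_equal(pc$p_value[1], wt$p.value)
})

test_that("the normal approximation tracks the exact 2^8 enumeration at n = 8", {
  # documented tolerance: at n = 8 the two-sided normal-approximation p is
  # within 0.06 of the exact sign-enumeration distribution (mid-range p is
  # the worst case; the tails agree much more closely)
  d <- c(3, -1, 4, 6, -2, 5, 7, -8)        # mid-range p
  res <- fibroquant:::signed_rank_z(d)
  expect_lt(abs(res$p - exact_signed_rank_p(d)), 0.06)

  d2 <- c(1.5, 2.5, -0.5, 4, 5, 6, 7, 8)   # tail p
  expect_lt(abs(fibroquant:::signed_rank_z(d2)$p - exact_signed_rank_p(d2)), 0.01)
})

test_that("regression matches closed forms and the normal-equations oracle", {
  # exact lines legitimately trigger lm's perfect-fit warning
  ex <- suppressWarnings(fit_regression(c(0, 1, 2), c(1, 3, 5)))
  expect_equal(ex$slope, 2); expect_equal(ex$intercept, 1)
  expect_equal(ex$r_squared, 1)

  idty <- suppressWarnings(fit_regression(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(idty$slope, 1); expect_equal(idty$intercept, 0)

  set.seed(9)
  x <- runif(10, 0, 50); y <- 3 + 0.8 * x + rnorm(10)
  fit <- fit_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)

  # ln transform applies the zero offset first
  lnfit <- fit_regression(c(0, 10, 30), c(0, 12, 28), transform = "ln")
  expect_equal(lnfit$ln_offset, 1)
  expect_equal(unname(coef(lnfit$fit)[2]),
               unname(coef(lm(log(c(0, 12, 28) + 1) ~ log(c(0, 10, 30) + 1)))[2]))

  expect_error(fit_regression(c(1, 1, 1), c(1, 2, 3)), class = "fq_validation_error")

  band <- predict_band(fit, c(10, 20))
  expect_true(all(band$lower < band$fit & band$fit < band$upper))
})

test_that("Bland-Altman agrees with the worked three-point example to 1e-12", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$differences, c(2, -1, 3))
  expect_equal(ba$mean_difference, 4 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_difference, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, 4 / 3 - 2 * sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 4 / 3 + 2 * sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 2 * ba$sd_difference)
  expect_equal(ba$x_values, c(10, 20, 30))  # reference on the X axis

  # multiplier linearity: widths scale exactly as 1.96 / 2
  ba196 <- bland_altman(c(10, 20, 30), c(12, 19, 33), multiplier = 1.96)
  expect_equal((ba196$loa_high - ba196$loa_low) / (ba$loa_high - ba$loa_low), 0.98)

  # identical methods: zero bias, zero-width limits
  self <- bland_altman(c(5, 10, 20, 40), c(5, 10, 20, 40))
  expect_equal(self$mean_difference, 0)
  expect_equal(self$loa_high - self$loa_low, 0)

  expect_error(bland_altman(1:3, 1:4), class = "fq_validation_error")
})

test_that("p-value formatting never prints literal zero", {
  expect_equal(fibroquant:::format_p(0), "p < 0.001")
  expect_equal(fibroquant:::format_p(0.0004), "p < 0.001")
  expect_equal(fibroquant:::format_p(0.024), "p = 0.024")
})
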