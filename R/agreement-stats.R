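#' Assemble per-slide method measurements
#'
#' Validates the per-slide fibrosis percentages of every evaluation method
#' and derives `pathologist_mean` as the arithmetic mean of the week-0 and
#' week-2 visual scores when both are present.
#'
#' @param df data frame with a `slide_id` column and one numeric column per
#'   method (values in 0-100).
#' @return The data frame with class `method_measurements` prepended.
#' @export
method_measurements <- function(df) {
  if (!"slide_id" %in% names(df)) {
    fq_stop("`df` must contain a slide_id column", "fq_validation_error")
  }
  num <- setdiff(names(df), "slide_id")
  if (!length(num)) fq_stop("no method columns", "fq_validation_error")
  for (cl in num) {
    v <- df[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      fq_stop(sprintf("column '%s' must be numeric without missing values", cl),
              "fq_validation_error")
    }
    if (any(v < 0 | v > 100)) {
      fq_stop(sprintf("column '%s' has values outside [0, 100]", cl),
              "fq_validation_error")
    }
  }
  if (all(c("pathologist_week0", "pathologist_week2") %in% num) &&
      !"pathologist_mean" %in% num) {
    df$pathologist_mean <- (df$pathologist_week0 + df$pathologist_week2) / 2
  }
  class(df) <- unique(c("method_measurements", class(df)))
  df
}

method_columns <- function(data) setdiff(names(data), "slide_id")

#' Summary statistics per method
#'
#' Mean, median (midpoint rule for even n), sample SD (n - 1 denominator),
#' range (= max - min), minimum and maximum for every method column.
#'
#' @param data a [method_measurements()] data frame.
#' @return Data frame with a `statistic` column and one column per method.
#' @export
summarize_methods <- function(data) {
  cols <- method_columns(data)
  if (!nrow(data)) fq_stop("no observations", "fq_validation_error")
  stat_fun <- list(
    n = length, mean = mean, median = stats::median,
    sd = function(v) if (length(v) > 1) stats::sd(v) else 0,
    range = function(v) max(v) - min(v), minimum = min, maximum = max
  )
  out <- data.frame(statistic = names(stat_fun))
  for (cl in cols) out[[cl]] <- vapply(stat_fun, function(f) f(data[[cl]]), numeric(1))
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric correlation matrix over the method columns with two-sided
#' p values from the t distribution with n - 2 degrees of freedom.
#' Zero-variance columns yield flagged NA entries rather than silent NaN.
#'
#' @param data a [method_measurements()] data frame.
#' @param columns method columns to include (default all).
#' @return List of class `correlation_matrix`: `r`, `p_value`, `n`,
#'   `undefined` (character vector of zero-variance columns).
#' @export
pearson_matrix <- function(data, columns = method_columns(data)) {
  x <- as.matrix(data[columns])
  n <- nrow(x)
  if (n < 3) fq_stop("need at least 3 observations", "fq_validation_error")
  vars <- apply(x, 2, stats::var)
  undef <- columns[vars == 0]
  r <- suppressWarnings(stats::cor(x))
  r[undef, ] <- NA_real_; r[, undef] <- NA_real_
  diag(r) <- ifelse(columns %in% undef, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  if (length(undef)) {
    warning("zero-variance columns flagged undefined: ",
            paste(undef, collapse = ", "))
  }
  structure(list(r = r, p_value = p, n = n, undefined = undef),
            class = "correlation_matrix")
}

#' Friedman rank test across matched methods
#'
#' Nonparametric repeated-measures comparison of k methods over n slides.
#' Within-slide average ranks with the tie-corrected (Conover) statistic:
#' with rank sums R_j and A = sum of all squared ranks,
#' `chi2 = (k - 1) * sum((R_j - n(k+1)/2)^2) / (A - n k (k+1)^2 / 4)`,
#' which reduces to the classical `12/(nk(k+1)) sum R_j^2 - 3n(k+1)` when
#' there are no ties. Identical columns (all ranks tied) give chi2 = 0 by
#' convention. df = k - 1.
#'
#' @param data a [method_measurements()] data frame or an n x k numeric
#'   matrix (rows = slides, columns = methods).
#' @param columns columns to compare when `data` is a data frame; at
#'   least 3.
#' @return Object of class `friedman_result`: `chi_square`, `df`,
#'   `p_value`, `n`, `k`.
#' @export
friedman_test <- function(data, columns = NULL) {
  x <- if (is.matrix(data)) data else {
    if (is.null(columns)) columns <- method_columns(data)
    as.matrix(data[columns])
  }
  n <- nrow(x); k <- ncol(x)
  if (k < 3) fq_stop("Friedman test needs at least 3 methods", "fq_parameter_error")
  if (n < 2) fq_stop("Friedman test needs at least 2 slides", "fq_parameter_error")
  r <- t(apply(x, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  chi <- if (A - C <= .Machine$double.eps * A) 0 else {
    (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  }
  structure(list(chi_square = chi, df = k - 1L,
                 p_value = stats::pchisq(chi, k - 1L, lower.tail = FALSE),
                 n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2(%d) = %.3f, %s (n = %d)\n",
              x$df, x$chi_square, format_p(x$p_value), x$n))
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "p undefined" else if (p < 0.001) "p < 0.001" else sprintf("p = %.3f", p)
}

#' Wilcoxon signed-rank post-hoc comparisons with Bonferroni correction
#'
#' For each method pair: the mean and sample SD of the raw differences
#' (first minus second), and the signed-rank test with zero differences
#' dropped, average ranks for ties, and the normal approximation
#' `Z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)` without
#' continuity correction. Significance is judged at the Bonferroni-adjusted
#' level `family_alpha / number of pairs`.
#'
#' @param data a [method_measurements()] data frame.
#' @param pairs list of length-2 character vectors (column pairs).
#' @param family_alpha family-wise significance level (default 0.05).
#' @return Data frame of class `paired_comparisons`: one row per pair with
#'   `pair`, `mean_difference`, `sd_difference`, `n_nonzero`, `z_statistic`,
#'   `p_value`, `significant`, `degenerate`; attribute `adjusted_alpha`.
#' @export
wilcoxon_pairs <- function(data, pairs, family_alpha = 0.05) {
  if (!length(pairs)) fq_stop("`pairs` must be nonempty", "fq_parameter_error")
  adj <- family_alpha / length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- data[[pr[1]]] - data[[pr[2]]]
    res <- signed_rank_z(d)
    data.frame(pair = paste(pr[1], "-", pr[2]),
               mean_difference = mean(d),
               sd_difference = stats::sd(d),
               n_nonzero = res$n,
               z_statistic = res$z,
               p_value = res$p,
               significant = !is.na(res$p) && res$p < adj,
               degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- adj
  class(out) <- c("paired_comparisons", "data.frame")
  out
}

# Signed-rank Z on a difference vector: zeros dropped, tie-corrected
# variance, no continuity correction. Degenerate when all differences are 0.
signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(z = NA_real_, p = NA_real_, n = 0L, degenerate = TRUE))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(list(z = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  z <- (w_plus - mu) / sqrt(sigma2)
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))), n = n, degenerate = FALSE)
}

#' Ordinary least-squares fit of a method against the reference
#'
#' OLS of `y` on `x`, raw or after a natural-log transform. Because the
#' measurements contain exact zeros, the log transform first adds a fixed
#' offset (default +1 percentage point) to both axes. r-squared is the
#' squared Pearson correlation; the 95% confidence band of the mean
#' response is available through [predict_band()].
#'
#' @param x reference measurements (percent).
#' @param y method measurements (percent).
#' @param transform `"raw"` or `"ln"`.
#' @param ln_offset offset added before the log transform (default 1).
#' @return Object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `transformed`, `ln_offset`, `fit` (the underlying `lm`).
#' @export
fit_regression <- function(x, y, transform = c("raw", "ln"), ln_offset = 1) {
  transform <- match.arg(transform)
  if (length(x) != length(y)) fq_stop("x and y lengths differ", "fq_validation_error")
  if (length(x) < 3) fq_stop("need at least 3 points", "fq_validation_error")
  if (transform == "ln") {
    if (any(x + ln_offset <= 0) || any(y + ln_offset <= 0)) {
      fq_stop("values + ln_offset must be positive for the log transform",
              "fq_parameter_error")
    }
    x <- log(x + ln_offset); y <- log(y + ln_offset)
  }
  if (stats::var(x) == 0) fq_stop("zero variance in x", "fq_validation_error")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = summary(fit)$r.squared,
    transformed = transform,
    ln_offset = if (transform == "ln") ln_offset else NA_real_,
    n = length(x),
    fit = fit
  ), class = "regression_fit")
}

#' 95% confidence band of the mean response
#'
#' @param reg a [fit_regression()] result.
#' @param newx x values (on the fitted scale) at which to evaluate.
#' @param level confidence level, default 0.95.
#' @return Data frame `x`, `fit`, `lower`, `upper`.
#' @export
predict_band <- function(reg, newx, level = 0.95) {
  stopifnot(inherits(reg, "regression_fit"))
  pr <- stats::predict(reg$fit, newdata = data.frame(x = newx),
                       interval = "confidence", level = level)
  data.frame(x = newx, fit = pr[, "fit"], lower = pr[, "lwr"], upper = pr[, "upr"])
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS (%s): slope %.3f, intercept %.3f, r2 %.3f (n = %d)\n",
              x$transformed, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Bland-Altman agreement against a reference method
#'
#' Differences are `test - reference` and are plotted against the
#' reference (not the pairwise mean), the appropriate choice when one
#' method is a reference standard. Limits of agreement are
#' `mean difference +/- multiplier * SD` with the sample SD (n - 1) and a
#' default multiplier of 2.
#'
#' @param reference reference measurements (percent).
#' @param test test-method measurements (percent).
#' @param multiplier LoA multiplier (default 2).
#' @return Object of class `bland_altman_result`: `x_values`,
#'   `differences`, `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`, `multiplier`, `histogram` (a `hist()` object of the
#'   differences, not plotted).
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
#' c(ba$mean_difference, ba$loa_low, ba$loa_high)
#' @export
bland_altman <- function(reference, test, multiplier = 2) {
  if (length(reference) != length(test)) {
    fq_stop("reference and test lengths differ", "fq_validation_error")
  }
  if (length(reference) < 2) fq_stop("need at least 2 pairs", "fq_validation_error")
  d <- test - reference
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(
    x_values = reference,
    differences = d,
    mean_difference = m,
    sd_difference = s,
    loa_low = m - multiplier * s,
    loa_high = m + multiplier * s,
    multiplier = multiplier,
    histogram = graphics::hist(d, plot = FALSE)
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f] (mean +/- %g SD, n = %d)\n",
              x$mean_difference, x$loa_low, x$loa_high, x$multiplier,
              length(x$differences)))
  invisible(x)
}
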