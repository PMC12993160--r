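#' @keywords internal
check_paired <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite values in paired volumes")
  if (length(x) < 3) stop("need n >= 3 paired observations")
  if (any(x <= 0) || any(y <= 0))
    warning("non-positive volumes in paired data")
  list(x = x, y = y, n = length(x))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements that simultaneously accounts for
#' correlation and penalizes systematic location/scale shifts:
#' \deqn{\rho_c = \frac{2 S_{xy}}{S_x^2 + S_y^2 + (\bar x - \bar y)^2}}
#' with population-form (1/n) moments. \eqn{\rho_c = 1} indicates perfect
#' concordance, 0 no agreement beyond chance. The confidence interval is
#' obtained by Fisher z transformation of \eqn{\rho_c} with Lin's asymptotic
#' variance, back-transformed.
#'
#' @param x Reference volumes (mL).
#' @param y Method volumes (mL), same subjects.
#' @param alpha CI level is `1 - alpha`, default `0.05`.
#' @return Object of class `ccc_result` with `ccc`, `ci_low`, `ci_high`, `n`.
#' @export
lin_ccc <- function(x, y, alpha = 0.05) {
  p <- check_paired(x, y)
  n <- p$n
  mx <- mean(p$x); my <- mean(p$y)
  sx2 <- mean((p$x - mx)^2)
  sy2 <- mean((p$y - my)^2)
  sxy <- mean((p$x - mx) * (p$y - my))
  if (sx2 <= 0 || sy2 <= 0)
    stop("degenerate input: zero variance in x or y")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  if (1 - ccc^2 < 1e-12 || abs(r) < 1e-12) {
    ci <- c(ccc, ccc)  # exact agreement (or no correlation): z variance degenerate
  } else {
    u <- (mx - my) / sqrt(sqrt(sx2 * sy2))  # scale-free location shift
    u2 <- u^2
    vz <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
             2 * ccc^3 * (1 - ccc) * u2 / (r * (1 - ccc^2)^2) -
             ccc^4 * u2^2 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    vz <- max(vz, 0)
    z <- atanh(ccc)
    zc <- stats::qnorm(1 - alpha / 2) * sqrt(vz)
    ci <- tanh(c(z - zc, z + zc))
  }
  structure(list(ccc = ccc, ci_low = ci[1], ci_high = ci[2], n = n,
                 alpha = alpha),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.4f  [%d%% CI %.4f, %.4f]  (n = %d)\n",
              x$ccc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Single-measure intraclass correlation for two fixed raters
#'
#' Two-way model with the reference and one method as the k = 2 raters.
#' Two forms are computed from the row/rater/error mean-square decomposition:
#'
#' * consistency (primary, the `ICC3` convention):
#'   `(MSR - MSE) / (MSR + (k-1) MSE)` — invariant to an additive shift
#'   between raters;
#' * absolute agreement: `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`
#'   — additionally penalizes the rater mean difference.
#'
#' The two conventions are often conflated in applied reports; both are
#' returned so either can be cited. The 95% CI for the consistency form is
#' the standard F-based interval.
#'
#' @inheritParams lin_ccc
#' @return Object of class `icc_result` with `icc31` (consistency form),
#'   `ci_low`, `ci_high`, `icc_agreement`, mean squares, `n`.
#' @export
icc31 <- function(x, y, alpha = 0.05) {
  p <- check_paired(x, y)
  n <- p$n; k <- 2
  tbl <- cbind(p$x, p$y)
  grand <- mean(tbl)
  rowm <- rowMeans(tbl); colm <- colMeans(tbl)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((tbl - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) stop("degenerate input: all values identical")
  icc3 <- (msr - mse) / (msr + (k - 1) * mse)
  icca <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse <= 0) {
    ci <- c(icc3, icc3)
  } else {
    fobs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc31 = icc3, ci_low = ci[1], ci_high = ci[2],
                 icc_agreement = icca,
                 ms = c(rows = msr, raters = msc, error = mse),
                 n = n, alpha = alpha),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(3,1) consistency = %.4f  [%d%% CI %.4f, %.4f]  (n = %d)\n",
    x$icc31, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  cat(sprintf("  absolute-agreement form = %.4f\n", x$icc_agreement))
  invisible(x)
}

#' Calibration regression of method volume on reference volume
#'
#' OLS fit `y = alpha + beta * x` with the method as outcome and the
#' reference as predictor. The slope is a dynamic-range indicator
#' (`beta = 1` means ideally preserved dynamic range); the residual standard
#' deviation `sd_e` (mL) is a precision metric. Slope CI from the t
#' distribution at 95%.
#'
#' @inheritParams lin_ccc
#' @return Object of class `calibration_fit` with `slope_beta`,
#'   `slope_ci_low`, `slope_ci_high`, `intercept`, `sd_e`, `n`.
#' @export
calibration_regression <- function(x, y, alpha = 0.05) {
  p <- check_paired(x, y)
  if (stats::var(p$x) <= 0) stop("zero variance in reference volumes")
  fit <- stats::lm(y ~ x, data = data.frame(x = p$x, y = p$y))
  ci <- stats::confint(fit, "x", level = 1 - alpha)
  structure(list(slope_beta = unname(stats::coef(fit)[2]),
                 slope_ci_low = ci[1], slope_ci_high = ci[2],
                 intercept = unname(stats::coef(fit)[1]),
                 sd_e = summary(fit)$sigma,
                 n = p$n),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "calibration slope = %.4f [%.4f, %.4f], intercept = %.3f, SDe = %.3f mL (n = %d)\n",
    x$slope_beta, x$slope_ci_low, x$slope_ci_high, x$intercept, x$sd_e, x$n))
  invisible(x)
}

#' Bland-Altman bias analysis
#'
#' Differences are method minus reference (`d = y - x`), so a positive mean
#' bias means the method over-segments. Limits of agreement are
#' `mean_bias +/- 1.96 * SD(d)`. Proportional bias is the OLS slope of the
#' differences on the pair means `(x + y)/2`, with its 95% CI; a nonzero
#' slope means the error depends systematically on the measured magnitude.
#'
#' @inheritParams lin_ccc
#' @return Object of class `bland_altman_result` with `mean_bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `prop_slope_beta`, `prop_slope_ci_low`,
#'   `prop_slope_ci_high`, per-subject `means` and `diffs`, `n`.
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  p <- check_paired(x, y)
  d <- p$y - p$x
  m <- (p$x + p$y) / 2
  mb <- mean(d)
  sdd <- stats::sd(d)
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m, data = data.frame(d = d, m = m))
    slope <- unname(stats::coef(fit)[2])
    ci <- stats::confint(fit, "m", level = 1 - alpha)
  } else {
    slope <- 0; ci <- c(0, 0)
  }
  structure(list(mean_bias = mb, sd_diff = sdd,
                 loa_low = mb - 1.96 * sdd, loa_high = mb + 1.96 * sdd,
                 prop_slope_beta = slope,
                 prop_slope_ci_low = ci[1], prop_slope_ci_high = ci[2],
                 means = m, diffs = d, n = p$n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (method - reference): bias %.3f mL, SD %.3f, LoA [%.3f, %.3f]\n",
    x$mean_bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  proportional slope %.3f [%.3f, %.3f] (n = %d)\n",
              x$prop_slope_beta, x$prop_slope_ci_low, x$prop_slope_ci_high,
              x$n))
  invisible(x)
}

#' All volumetric agreement statistics for one method
#'
#' Convenience wrapper computing Lin's CCC, ICC(3,1), the calibration
#' regression and the Bland-Altman analysis for one (reference, method)
#' volume pairing.
#'
#' @inheritParams lin_ccc
#' @param method Optional method name carried in the result.
#' @return Object of class `volumetric_agreement` holding the four blocks.
#' @export
volumetric_agreement <- function(x, y, method = NULL, alpha = 0.05) {
  structure(list(method = method,
                 ccc = lin_ccc(x, y, alpha),
                 icc = icc31(x, y, alpha),
                 calibration = calibration_regression(x, y, alpha),
                 bland_altman = bland_altman(x, y, alpha)),
            class = "volumetric_agreement")
}

#' @export
print.volumetric_agreement <- function(x, ...) {
  if (!is.null(x$method)) cat("Method:", x$method, "\n")
  print(x$ccc); print(x$icc); print(x$calibration); print(x$bland_altman)
  invisible(x)
}
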