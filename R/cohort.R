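#' Benjamini-Hochberg step-up adjustment
#'
#' Explicit step-up false-discovery-rate procedure: order the m raw p-values
#' increasingly, scale `p_(i)` by `m / i`, enforce monotonicity from the top
#' down, cap at 1, and return in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

#' Z-standardize intracranial volume over the analysis sample
#'
#' Adds a `z_icv` column: `(icv - mean) / sd` over the sample. The default is
#' the population-SD convention (divisor n); set `ddof = 1` for the sample
#' SD. One value per subject is used when the table has repeated timepoint
#' rows (standardization is over subjects, not rows).
#'
#' @param cohort Data frame with columns `subject_id` and `icv`.
#' @param ddof Degrees-of-freedom correction for the SD divisor (`n - ddof`),
#'   default `0`.
#' @return `cohort` with a `z_icv` column appended.
#' @export
zscore_icv <- function(cohort, ddof = 0) {
  stopifnot(all(c("subject_id", "icv") %in% names(cohort)))
  per_subj <- cohort$icv[!duplicated(cohort$subject_id)]
  if (length(unique(per_subj)) < 2) stop("need >= 2 distinct ICV values")
  mu <- mean(per_subj)
  n <- length(per_subj)
  sdv <- sqrt(sum((per_subj - mu)^2) / (n - ddof))
  if (sdv <= 0) stop("zero ICV standard deviation")
  cohort$z_icv <- (cohort$icv - mu) / sdv
  cohort
}

volume_column <- function(cohort, method) {
  col <- paste0("vol_", method)
  if (!col %in% names(cohort))
    stop("no volume column '", col, "' in cohort table")
  col
}

# Shared extraction of a regression_result from an lm fit.
lm_result <- function(fit, term, hc3, transform_tag, alpha = 0.05) {
  if (hc3) {
    vc <- sandwich::vcovHC(fit, type = "HC3")
    ct <- lmtest::coeftest(fit, vcov. = vc)
    est <- ct[term, "Estimate"]; se <- ct[term, "Std. Error"]
    pval <- ct[term, "Pr(>|t|)"]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    pval <- sm[term, "Pr(>|t|)"]
  }
  tq <- stats::qt(1 - alpha / 2, df = fit$df.residual)
  structure(list(beta = unname(est), se = unname(se),
                 ci_low = unname(est - tq * se),
                 ci_high = unname(est + tq * se),
                 p = unname(pval),
                 r2 = summary(fit)$r.squared,
                 n = length(fit$residuals),
                 robust_flag = hc3,
                 transform_tag = transform_tag,
                 term = term,
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "beta[%s] = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.4g, R2 = %.3f, n = %d%s%s\n",
    x$term, x$beta, x$se, x$ci_low, x$ci_high, x$p, x$r2, x$n,
    if (x$robust_flag) ", HC3" else "",
    if (nzchar(x$transform_tag)) paste0(", ", x$transform_tag) else ""))
  invisible(x)
}

#' Cross-sectional clinical association model
#'
#' OLS of a clinical outcome on one method's thalamus volume, adjusted for
#' age at visit (years), biological sex, and z-standardized ICV. `beta` is
#' the change in outcome per 1 mL of volume. Right-skewed outcomes (timed
#' tests) can be natural-log transformed, in which case `beta` is the per-mL
#' change in log outcome (approximately the fractional change).
#' Heteroscedastic outcomes can be fitted with HC3 robust standard errors.
#' Complete cases only; when `z_icv` is absent it is computed over the
#' analysis sample.
#'
#' @param cohort Data frame with columns `subject_id`, `age`, `sex`, `icv`,
#'   the outcome, a `vol_<method>` column, and optionally `timepoint`
#'   (only `"baseline"` rows are used when present).
#' @param outcome Name of the outcome column (e.g. `"edss"`).
#' @param method Method whose `vol_<method>` column is the predictor.
#' @param log_transform Natural-log transform the outcome first (requires
#'   positive values).
#' @param hc3 Use HC3 heteroscedasticity-consistent standard errors.
#' @return A `regression_result` for the volume term.
#' @export
fit_crosssectional <- function(cohort, outcome, method,
                               log_transform = FALSE, hc3 = FALSE) {
  col <- volume_column(cohort, method)
  if ("timepoint" %in% names(cohort))
    cohort <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  d <- data.frame(y = cohort[[outcome]], vol = cohort[[col]],
                  age = cohort$age, sex = cohort$sex,
                  icv = cohort$icv)
  if ("z_icv" %in% names(cohort)) d$z_icv <- cohort$z_icv
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= 5) stop("too few complete cases (n = ", nrow(d), ")")
  if (!"z_icv" %in% names(d))
    d$z_icv <- (d$icv - mean(d$icv)) / sqrt(mean((d$icv - mean(d$icv))^2))
  if (log_transform) {
    if (any(d$y <= 0)) stop("log transform requires positive outcome values")
    d$y <- log(d$y)
  }
  fit <- stats::lm(y ~ vol + age + sex + z_icv, data = d)
  lm_result(fit, "vol", hc3,
            transform_tag = if (log_transform) "log-outcome" else "")
}

#' Longitudinal deltas of volumes and clinical scores
#'
#' For each subject with both a baseline and a year-1 row, computes follow-up
#' minus baseline for every method volume (in mL and in % of baseline) and
#' every requested clinical outcome, carrying forward the longitudinal
#' covariates. Subjects missing either timepoint are excluded and listed in
#' the `excluded` attribute.
#'
#' @param cohort Cohort table (one row per subject-timepoint) with a
#'   `timepoint` column coded `"baseline"` / `"year1"`.
#' @param methods Method names; default: all `vol_*` columns.
#' @param outcomes Clinical outcome columns to difference; default those of
#'   `c("edss", "t25fw", "hpt9", "sdmt")` present in the table.
#' @return Data frame (one row per subject) with `d_vol_<m>_ml`,
#'   `d_vol_<m>_pct`, `d_<outcome>`, and covariates `age`, `sex`, `icv`,
#'   `z_icv` (if present), `steroid_flag`, `interval_years`,
#'   `global_atrophy_pct` (if present), `dx_group` (if present).
#' @export
compute_deltas <- function(cohort, methods = NULL, outcomes = NULL) {
  stopifnot("timepoint" %in% names(cohort))
  if (is.null(methods))
    methods <- sub("^vol_", "", grep("^vol_", names(cohort), value = TRUE))
  if (is.null(outcomes))
    outcomes <- intersect(c("edss", "t25fw", "hpt9", "sdmt"), names(cohort))
  bl <- cohort[cohort$timepoint == "baseline", , drop = FALSE]
  fu <- cohort[cohort$timepoint == "year1", , drop = FALSE]
  keep <- intersect(bl$subject_id, fu$subject_id)
  excluded <- setdiff(unique(cohort$subject_id), keep)
  bl <- bl[match(keep, bl$subject_id), , drop = FALSE]
  fu <- fu[match(keep, fu$subject_id), , drop = FALSE]
  out <- data.frame(subject_id = keep)
  for (m in methods) {
    col <- volume_column(cohort, m)
    base <- bl[[col]]
    if (any(!is.na(base) & base <= 0)) stop("zero baseline volume for ", m)
    out[[paste0("d_vol_", m, "_ml")]] <- fu[[col]] - base
    out[[paste0("d_vol_", m, "_pct")]] <- 100 * (fu[[col]] - base) / base
  }
  for (oc in outcomes) out[[paste0("d_", oc)]] <- fu[[oc]] - bl[[oc]]
  for (cv in intersect(c("age", "sex", "icv", "z_icv", "steroid_flag",
                         "interval_years", "global_atrophy_pct", "dx_group"),
                       names(bl)))
    out[[cv]] <- bl[[cv]]
  attr(out, "excluded") <- excluded
  if (length(excluded))
    message(length(excluded), " subject(s) excluded for missing a timepoint")
  out
}

#' Longitudinal clinical association model
#'
#' OLS of a clinical delta on one method's thalamus volume delta, adjusted
#' for age, sex, z-standardized ICV, inter-session corticosteroid treatment,
#' and the inter-scan interval. `beta` is the clinical-delta change per 1 mL
#' of volume delta (or per percent when `volume_scale = "pct"`).
#'
#' @param deltas Output of [compute_deltas].
#' @param outcome Clinical outcome name (the `d_<outcome>` column is used).
#' @param method Method name (the `d_vol_<method>_ml`/`_pct` column is used).
#' @param hc3 Use HC3 robust standard errors.
#' @param volume_scale `"ml"` (default) or `"pct"`.
#' @return A `regression_result` for the volume-delta term.
#' @export
fit_longitudinal <- function(deltas, outcome, method, hc3 = FALSE,
                             volume_scale = c("ml", "pct")) {
  volume_scale <- match.arg(volume_scale)
  vcol <- paste0("d_vol_", method, "_", volume_scale)
  ycol <- paste0("d_", outcome)
  stopifnot(vcol %in% names(deltas), ycol %in% names(deltas))
  d <- data.frame(y = deltas[[ycol]], dvol = deltas[[vcol]],
                  age = deltas$age, sex = deltas$sex, icv = deltas$icv,
                  steroid_flag = deltas$steroid_flag,
                  interval_years = deltas$interval_years)
  if ("z_icv" %in% names(deltas)) d$z_icv <- deltas$z_icv
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= 7) stop("too few complete cases (n = ", nrow(d), ")")
  if (!"z_icv" %in% names(d))
    d$z_icv <- (d$icv - mean(d$icv)) / sqrt(mean((d$icv - mean(d$icv))^2))
  fit <- stats::lm(y ~ dvol + age + sex + z_icv + steroid_flag +
                     interval_years, data = d)
  lm_result(fit, "dvol", hc3, transform_tag = paste0("delta-", volume_scale))
}

#' Pairwise comparison of methods' longitudinal volume deltas
#'
#' Paired two-sided Wilcoxon signed-rank tests of per-subject volume deltas
#' between every method pair, Benjamini-Hochberg adjusted as one family.
#'
#' @param deltas Output of [compute_deltas].
#' @param volume_scale `"pct"` (default) or `"ml"`.
#' @return Data frame of method pairs with `p` and `p_adj`.
#' @export
delta_method_comparison <- function(deltas, volume_scale = c("pct", "ml")) {
  volume_scale <- match.arg(volume_scale)
  cols <- grep(paste0("^d_vol_.*_", volume_scale, "$"), names(deltas),
               value = TRUE)
  methods <- sub(paste0("_", volume_scale, "$"), "", sub("^d_vol_", "", cols))
  if (length(methods) < 2) stop("need >= 2 methods with paired deltas")
  long <- do.call(rbind, lapply(seq_along(methods), function(i)
    data.frame(subject = deltas$subject_id, method = methods[i],
               value = deltas[[cols[i]]])))
  long <- long[!is.na(long$value), , drop = FALSE]
  pairwise_wilcoxon(long, methods)
}

#' Association of per-method thalamus atrophy with global atrophy
#'
#' Pearson correlation (with p-value) of each method's percent volume delta
#' with a global-atrophy measure (e.g. percentage brain volume change), plus
#' the cross-method pairwise Wilcoxon comparison of the percent deltas.
#'
#' @param deltas Output of [compute_deltas] including `global_atrophy_pct`.
#' @return List with `correlations` (method, r, p, n) and `pairwise`.
#' @export
atrophy_vs_global <- function(deltas) {
  stopifnot("global_atrophy_pct" %in% names(deltas))
  cols <- grep("^d_vol_.*_pct$", names(deltas), value = TRUE)
  methods <- sub("_pct$", "", sub("^d_vol_", "", cols))
  rows <- lapply(seq_along(methods), function(i) {
    v <- deltas[[cols[i]]]; g <- deltas$global_atrophy_pct
    ok <- stats::complete.cases(v, g)
    if (stats::var(v[ok]) <= 0 || stats::var(g[ok]) <= 0)
      stop("zero variance in deltas or global atrophy for ", methods[i])
    ct <- stats::cor.test(v[ok], g[ok], method = "pearson")
    data.frame(method = methods[i], r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  list(correlations = do.call(rbind, rows),
       pairwise = if (length(methods) >= 2)
         delta_method_comparison(deltas, "pct") else NULL)
}

# inverse-ECDF quantiles (type 1): the limits are attained data values, so
# winsorizing twice at the same limits equals winsorizing once
winsorize <- function(v, lo_pct, hi_pct) {
  q <- stats::quantile(v, c(lo_pct, hi_pct) / 100, type = 1, na.rm = TRUE)
  pmin(pmax(v, q[1]), q[2])
}

#' Winsorization sensitivity analysis of a longitudinal model
#'
#' Refits the longitudinal association after clamping the method's volume
#' deltas at the stated percentile limits (conventionally 1-99% and 5-95%),
#' to check that an association is not driven by extreme longitudinal volume
#' changes. Returns the unwinsorized fit paired with one refit per limit.
#'
#' @inheritParams fit_longitudinal
#' @param limits List of two-element percentile vectors, default
#'   `list(c(1, 99), c(5, 95))`.
#' @return List with `unwinsorized` and one `regression_result` per limit
#'   (named e.g. `"win_1_99"`).
#' @export
winsorize_sensitivity <- function(deltas, outcome, method, hc3 = FALSE,
                                  limits = list(c(1, 99), c(5, 95)),
                                  volume_scale = c("ml", "pct")) {
  volume_scale <- match.arg(volume_scale)
  vcol <- paste0("d_vol_", method, "_", volume_scale)
  out <- list(unwinsorized = fit_longitudinal(deltas, outcome, method, hc3,
                                              volume_scale))
  for (lim in limits) {
    dd <- deltas
    dd[[vcol]] <- winsorize(dd[[vcol]], lim[1], lim[2])
    out[[paste0("win_", lim[1], "_", lim[2])]] <-
      fit_longitudinal(dd, outcome, method, hc3, volume_scale)
  }
  out
}

#' Ordinal logistic sensitivity model of EDSS change
#'
#' Recodes the EDSS delta into conventional change categories — worsened
#' (`>= +0.5`), stable, improved (`<= -0.5`) — and fits a proportional-odds
#' model of the category on the volume delta and the longitudinal covariates.
#' Reports whether the ordinal coefficient's direction agrees with the OLS
#' slope, supporting that an association is not an artefact of treating the
#' ordinal scale as continuous. Complete (quasi-)separation is caught and
#' flagged rather than reported as a fit.
#'
#' @inheritParams fit_longitudinal
#' @param cutpoint Half-width of the stable band, default `0.5` (the EDSS
#'   step).
#' @return List with `coef`, `se`, `p` (Wald), `categories` (counts),
#'   `direction_consistent` (vs the OLS fit), `ols_beta`, and `flag`
#'   (`NA` or `"separation"`).
#' @export
ordinal_edss_sensitivity <- function(deltas, method, cutpoint = 0.5,
                                     volume_scale = c("ml", "pct")) {
  volume_scale <- match.arg(volume_scale)
  vcol <- paste0("d_vol_", method, "_", volume_scale)
  stopifnot("d_edss" %in% names(deltas), vcol %in% names(deltas))
  d <- data.frame(d_edss = deltas$d_edss, dvol = deltas[[vcol]],
                  age = deltas$age, sex = deltas$sex,
                  steroid_flag = deltas$steroid_flag,
                  interval_years = deltas$interval_years)
  if ("z_icv" %in% names(deltas)) d$z_icv <- deltas$z_icv else d$z_icv <- 0
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$cat <- cut(d$d_edss,
               breaks = c(-Inf, -cutpoint + 1e-9, cutpoint - 1e-9, Inf),
               labels = c("improved", "stable", "worsened"),
               ordered_result = TRUE)
  counts <- table(d$cat)
  if (sum(counts > 0) < 2)
    stop("need >= 2 non-empty EDSS-change categories")
  ols <- fit_longitudinal(deltas, "edss", method, hc3 = FALSE,
                          volume_scale = volume_scale)
  fit <- tryCatch(
    MASS::polr(cat ~ dvol + age + sex + z_icv + steroid_flag +
                 interval_years, data = d, Hess = TRUE),
    error = function(e) e)
  if (inherits(fit, "error") ||
      !is.finite(summary_se <- tryCatch(
        sqrt(diag(stats::vcov(fit)))["dvol"], error = function(e) NA)))
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_,
                categories = counts, direction_consistent = NA,
                ols_beta = ols$beta, flag = "separation"))
  cf <- stats::coef(fit)["dvol"]
  z <- cf / summary_se
  list(coef = unname(cf), se = unname(summary_se),
       p = unname(2 * stats::pnorm(-abs(z))),
       categories = counts,
       direction_consistent = sign(cf) == sign(ols$beta),
       ols_beta = ols$beta, flag = NA_character_)
}
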