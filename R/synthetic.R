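#' Phantom specification for a bilateral ellipsoid-like structure
#'
#' Describes the synthetic ground-truth thalamus: two disjoint ellipsoids on
#' a common grid, with a smooth random boundary perturbation, optional decoy
#' regions (a medial "ventricle" slab and a "caudate bridge" touching the
#' lateral surface), and a target total-volume distribution. The default
#' volume distribution (9.13 +/- 1.89 mL) matches reference-standard manual
#' thalamus volumes in an MS population; the default grid is 96^3 at 0.8 mm
#' isotropic.
#'
#' @param shape Grid shape, default `c(96, 96, 96)`.
#' @param voxel_mm Isotropic voxel size in mm, default `0.8`.
#' @param semi_axes_mm Base ellipsoid semi-axes (x, y, z) in mm per side.
#' @param center_offset_mm Lateral offset of each ellipsoid center from the
#'   grid center (mm); left at `-offset`, right at `+offset` along x.
#' @param target_volume_mean_ml,target_volume_sd_ml Total (bilateral) volume
#'   distribution the generator draws from, defaults `9.13` / `1.89` mL.
#' @param perturb_amp Relative amplitude of the smooth radial boundary
#'   perturbation, default `0.05`; `0` gives an exact ellipsoid
#'   rasterization.
#' @param decoys Include decoy regions, default `TRUE`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), voxel_mm = 0.8,
                         semi_axes_mm = c(6.5, 16.0, 10.5),
                         center_offset_mm = 11,
                         target_volume_mean_ml = 9.13,
                         target_volume_sd_ml = 1.89,
                         perturb_amp = 0.05,
                         decoys = TRUE) {
  stopifnot(length(shape) == 3, voxel_mm > 0, length(semi_axes_mm) == 3,
            all(semi_axes_mm > 0), center_offset_mm > 0,
            target_volume_mean_ml > 0, target_volume_sd_ml >= 0,
            perturb_amp >= 0)
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 semi_axes_mm = semi_axes_mm,
                 center_offset_mm = center_offset_mm,
                 target_volume_mean_ml = target_volume_mean_ml,
                 target_volume_sd_ml = target_volume_sd_ml,
                 perturb_amp = perturb_amp, decoys = decoys),
            class = "phantom_spec")
}

# World-mm coordinates of every voxel center, relative to the grid center.
grid_coords_mm <- function(shape, voxel_mm) {
  lapply(1:3, function(ax)
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * voxel_mm)
}

# Smooth low-frequency radial perturbation field in [-1, 1], built from a
# handful of random-phase sinusoids of the mm coordinates.
perturb_field <- function(cx, cy, cz) {
  n <- 4L
  kx <- stats::runif(n, 0.02, 0.08); ky <- stats::runif(n, 0.02, 0.08)
  kz <- stats::runif(n, 0.02, 0.08)
  ph <- stats::runif(3 * n, 0, 2 * pi)
  w <- stats::runif(n, 0.5, 1)
  acc <- 0
  for (i in seq_len(n)) {
    sx <- sin(kx[i] * cx + ph[i])
    sy <- sin(ky[i] * cy + ph[n + i])
    sz <- sin(kz[i] * cz + ph[2 * n + i])
    acc <- acc + w[i] * (outer(outer(sx, sy), sz))
  }
  acc / sum(w)
}

#' Generate a phantom ground-truth mask
#'
#' Rasterizes the bilateral ellipsoids of a [phantom_spec], scaled so the
#' analytic ellipsoid volume matches a target drawn from the spec's volume
#' distribution (truncated at 3 SD), with a smooth random boundary
#' perturbation. Also returns a [label_volume] marking left/right structure
#' and the decoy regions, so decoy-seeking segmenter profiles and
#' envelope-intersection have anatomy-like regions to act on.
#'
#' @param spec A [phantom_spec].
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @param target_volume_ml Optional fixed target total volume in mL,
#'   overriding the random draw.
#' @return List with `gt` ([binary_mask]), `labels` ([label_volume]; 1 left,
#'   2 right, 3 ventricle slab, 4 caudate bridge), `true_volume_ml` (measured
#'   from the mask), `target_volume_ml`.
#' @export
generate_phantom_gt <- function(spec = phantom_spec(), seed = NULL,
                                target_volume_ml = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target_volume_ml)) {
    dev <- stats::rnorm(1, 0, spec$target_volume_sd_ml)
    dev <- max(min(dev, 3 * spec$target_volume_sd_ml),
               -3 * spec$target_volume_sd_ml)
    target_volume_ml <- spec$target_volume_mean_ml + dev
  }
  base_ml <- 2 * 4 / 3 * pi * prod(spec$semi_axes_mm) / 1000
  s <- (target_volume_ml / base_ml)^(1 / 3)
  ax <- spec$semi_axes_mm * s
  off <- spec$center_offset_mm
  co <- grid_coords_mm(spec$shape, spec$voxel_mm)
  extent_x <- off + ax[1]
  if (extent_x > max(co[[1]]) || ax[2] > max(co[[2]]) || ax[3] > max(co[[3]]))
    stop("phantom exceeds the grid; enlarge the grid or shrink the spec")
  if (ax[1] >= off)
    stop("left/right components would overlap; increase center_offset_mm")
  eps <- if (spec$perturb_amp > 0)
    spec$perturb_amp * perturb_field(co[[1]], co[[2]], co[[3]]) else 0
  q_side <- function(side) {
    qx <- ((co[[1]] - side * off) / ax[1])^2
    qy <- (co[[2]] / ax[2])^2
    qz <- (co[[3]] / ax[3])^2
    q <- outer(outer(qx, qy, `+`), qz, `+`)
    q <= (1 + eps)^2
  }
  left <- q_side(-1)
  right <- q_side(+1)
  grid <- image_grid(spec$shape, rep(spec$voxel_mm, 3))
  gt <- left | right
  labels <- array(0L, spec$shape)
  labels[left] <- 1L
  labels[right] <- 2L
  if (spec$decoys) {
    vent <- outer(outer(abs(co[[1]]) < 0.35 * off,
                        abs(co[[2]]) < 1.1 * ax[2], `&`),
                  abs(co[[3]]) < 1.1 * ax[3], `&`) & !gt
    bridge <- outer(outer(co[[1]] > off + 0.6 * ax[1] &
                            co[[1]] < off + 1.6 * ax[1],
                          abs(co[[2]] - 0.4 * ax[2]) < 0.25 * ax[2], `&`),
                    abs(co[[3]]) < 0.35 * ax[3], `&`) & !gt
    labels[vent] <- 3L
    labels[bridge] <- 4L
  }
  list(gt = binary_mask(gt, grid),
       labels = label_volume(labels, grid),
       true_volume_ml = sum(gt) * spec$voxel_mm^3 / 1000,
       target_volume_ml = target_volume_ml)
}

#' Simulated segmenter profile
#'
#' Parameterizes a simulated segmentation method's volumetric bias and noise
#' so that concordance statistics can be validated by parameter recovery.
#' The expected measured volume is
#' `true + additive_bias_ml + proportional_slope * (true - cohort_mean_ml)`
#' plus Gaussian boundary noise. Styles shape the spatial error:
#' `"dilate-into-decoys"` keeps the ground truth contained (atlas-like: near-
#' perfect sensitivity, low precision, growing into adjacent decoy regions
#' first); `"erode-uniform"` and `"balanced"` additionally resample a
#' fraction of the boundary (`jitter_frac`, in units of the boundary-voxel
#' count) so the mask is spatially distinct from the truth (CNN-like).
#'
#' @param name Method name.
#' @param additive_bias_ml Constant volumetric bias in mL.
#' @param proportional_slope Bias per mL of true volume about the cohort
#'   mean (negative values compress the dynamic range).
#' @param boundary_noise_sd Volume noise SD in boundary-layer units (one
#'   unit is roughly the volume of a single voxel layer on the surface).
#' @param sensitivity_style One of `"balanced"`, `"dilate-into-decoys"`,
#'   `"erode-uniform"`.
#' @param session_noise_sd Session-to-session volume noise SD in
#'   boundary-layer units, default `0` (the default profiles use 0.06).
#'   The main `boundary_noise_sd`
#'   component is persistent within a subject (a method mis-measures the
#'   same anatomy the same way at both timepoints); only this small session
#'   component varies between scans, which is what keeps longitudinal
#'   percent-change noise at realistic (~2%) levels.
#' @param jitter_frac Boundary resampling fraction, default `0` (values
#'   above 1 resample over multiple passes). The default profiles use 0 for
#'   the atlas-like style and 0.95 / 1.35 for the CNN-like styles.
#' @return Object of class `segmenter_profile`.
#' @export
segmenter_profile <- function(name, additive_bias_ml = 0,
                              proportional_slope = 0,
                              boundary_noise_sd = 0,
                              sensitivity_style = c("balanced",
                                                    "dilate-into-decoys",
                                                    "erode-uniform"),
                              jitter_frac = 0,
                              session_noise_sd = 0) {
  sensitivity_style <- match.arg(sensitivity_style)
  structure(list(name = name, additive_bias_ml = additive_bias_ml,
                 proportional_slope = proportional_slope,
                 boundary_noise_sd = boundary_noise_sd,
                 sensitivity_style = sensitivity_style,
                 jitter_frac = jitter_frac,
                 session_noise_sd = session_noise_sd),
            class = "segmenter_profile")
}

#' Default simulated segmenters
#'
#' Three profiles spanning the behaviours automated thalamus segmenters show
#' against a manual reference: an atlas-like over-segmenter (large positive
#' bias, positive proportional slope, spills into adjacent decoy regions), a
#' CNN-like dynamic-range compressor (small positive bias, strongly negative
#' proportional slope), and a balanced method (moderate bias, near-zero
#' slope). Bias/slope values are anchored to published benchmarking of
#' FreeSurfer-, DBSegment- and MindGlide-style methods.
#'
#' @return Named list of [segmenter_profile]s.
#' @export
default_segmenter_profiles <- function() {
  list(
    atlas_like = segmenter_profile("atlas_like", 5.65, 0.28, 0.77,
                                   "dilate-into-decoys", jitter_frac = 0,
                                   session_noise_sd = 0.06),
    cnn_compressed = segmenter_profile("cnn_compressed", 0.75, -0.43, 0.70,
                                       "erode-uniform", jitter_frac = 0.95,
                                       session_noise_sd = 0.06),
    balanced = segmenter_profile("balanced", 1.11, -0.09, 0.65, "balanced",
                                 jitter_frac = 1.35,
                                 session_noise_sd = 0.06))
}

#' Simulate a segmentation of a ground-truth mask
#'
#' Applies a [segmenter_profile] to a ground-truth mask: optional boundary
#' resampling (jitter), then growth or shrinkage to the profile's target
#' volume by partial-layer morphology. With decoy labels supplied, the
#' dilate-into-decoys style consumes decoy voxels before others.
#'
#' @param gt Ground-truth [binary_mask] (non-empty).
#' @param profile A [segmenter_profile].
#' @param cohort_mean_ml Cohort mean true volume anchoring the proportional
#'   term, default `9.13`.
#' @param decoy_labels Optional [label_volume] whose labels >= 3 mark decoy
#'   regions (as produced by [generate_phantom_gt]).
#' @param seed Optional integer seed.
#' @param noise_ml Optional externally supplied volume-noise value in mL
#'   (replacing the internal draw); [generate_cohort] uses this to make the
#'   subject-level noise component persistent across timepoints while adding
#'   fresh session noise.
#' @return A [binary_mask].
#' @export
simulate_segmentation <- function(gt, profile, cohort_mean_ml = 9.13,
                                  decoy_labels = NULL, seed = NULL,
                                  noise_ml = NULL) {
  stopifnot(inherits(gt, "binary_mask"), inherits(profile, "segmenter_profile"))
  if (!any(gt$data)) stop("ground-truth mask is empty")
  if (!is.null(seed)) set.seed(seed)
  voxml <- voxel_volume_mm3(gt$grid) / 1000
  true_ml <- sum(gt$data) * voxml
  layer_ml <- sum(outer_boundary(gt$data)) * voxml
  if (is.null(noise_ml))
    noise_ml <- stats::rnorm(1, 0, profile$boundary_noise_sd * layer_ml) +
      stats::rnorm(1, 0, profile$session_noise_sd * layer_ml)
  target_ml <- true_ml + profile$additive_bias_ml +
    profile$proportional_slope * (true_ml - cohort_mean_ml) + noise_ml
  target_n <- round(target_ml / voxml)
  if (target_n < 1) stop("profile drives the mask empty")
  a <- gt$data
  prefer <- NULL
  if (profile$sensitivity_style == "dilate-into-decoys" &&
      !is.null(decoy_labels)) {
    assert_same_grid(gt, decoy_labels)
    prefer <- decoy_labels$data >= 3L
  }
  a <- adjust_to_count(a, target_n, prefer = prefer)
  # jitter after volume targeting: it is volume-preserving, and applying it
  # first would be undone by the dilation refilling the holes it punched
  if (profile$jitter_frac > 0)
    a <- jitter_boundary(a, profile$jitter_frac * sum(inner_boundary(a)))
  binary_mask(a, gt$grid)
}

#' Simulate longitudinal atrophy of a mask
#'
#' Uniform boundary erosion (or growth, for positive rates) calibrated so
#' the measured percent volume change equals `rate * interval` up to
#' single-voxel rounding.
#'
#' @param gt_baseline Baseline [binary_mask].
#' @param atrophy_rate_pct_per_year Percent volume change per year (negative
#'   = loss); must satisfy `|rate| < 10`.
#' @param interval_years Inter-scan interval in years.
#' @param seed Optional integer seed.
#' @return Follow-up [binary_mask].
#' @export
simulate_longitudinal <- function(gt_baseline, atrophy_rate_pct_per_year,
                                  interval_years, seed = NULL) {
  stopifnot(inherits(gt_baseline, "binary_mask"))
  if (abs(atrophy_rate_pct_per_year) >= 10)
    stop("implausible atrophy rate (|rate| must be < 10 %/year)")
  if (!is.null(seed)) set.seed(seed)
  n0 <- sum(gt_baseline$data)
  target <- round(n0 * (1 + atrophy_rate_pct_per_year / 100 * interval_years))
  if (target < 1) stop("erosion would empty the mask")
  if (target == n0) return(gt_baseline)
  binary_mask(adjust_to_count(gt_baseline$data, target), gt_baseline$grid)
}

#' Simulation configuration for a synthetic cohort
#'
#' Bundles the demographic, atrophy, and clinical-coupling parameters of the
#' synthetic cohort. Defaults emulate a mixed neuro-immunological cohort:
#' age 43.4 +/- 12.4 years, about two thirds female, diagnosis proportions
#' dominated by relapsing-remitting MS, patient atrophy of -0.5 +/- 0.4
#' %/year versus 0 +/- 0.2 in healthy controls, a global-atrophy (PBVC-like)
#' variable of -0.32 +/- 0.55 % coupled to thalamic atrophy, and clinical
#' outcomes linearly coupled to thalamus volume (EDSS -0.26 per mL, SDMT
#' +2.6 per mL) with age/sex/ICV confounding. Timed tests are generated
#' log-normal (right-skewed by construction).
#'
#' @param n_subjects Number of subjects, >= 10.
#' @param seed Integer seed; all randomness in [generate_cohort] flows from
#'   it.
#' @param age_mean,age_sd Age distribution (years).
#' @param female_prop Proportion female.
#' @param dx_props Named diagnosis-group proportions (must sum to 1).
#' @param atrophy_patient_mean,atrophy_patient_sd,atrophy_hc_mean,atrophy_hc_sd
#'   Atrophy-rate distributions in %/year.
#' @param interval_mean,interval_sd Inter-scan interval (years).
#' @param icv_mean,icv_sd Intracranial volume (mL).
#' @param steroid_prob Probability of inter-session corticosteroid treatment
#'   (patients only).
#' @param pbvc_mean,pbvc_sd,pbvc_coupling Global-atrophy distribution (%)
#'   and its correlation with the subject's thalamic atrophy rate.
#' @param vol_mean,vol_sd True baseline volume distribution (mL); part of
#'   `vol_sd` is explained by age and ICV coupling (`vol_age_slope`,
#'   `vol_icv_slope` per z-ICV).
#' @param vol_age_slope,vol_icv_slope Volume confounding coefficients.
#' @param clinical_betas,clinical_noise Coefficient lists for outcome
#'   generation (see defaults in the function body); betas are on the scale
#'   of the fitted cross-sectional models.
#' @param long_betas,long_noise Coefficients for clinical-delta generation.
#' @param heteroscedastic Make the EDSS noise SD proportional to the fitted
#'   mean.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_subjects = 50, seed = 1,
    age_mean = 43.4, age_sd = 12.4, female_prop = 2 / 3,
    dx_props = c(RRMS = 0.633, PMS = 0.050, NMOSD = 0.131, MOGAD = 0.093,
                 "RIS/CIS/iON" = 0.062, HC = 0.031),
    atrophy_patient_mean = -0.5, atrophy_patient_sd = 0.4,
    atrophy_hc_mean = 0, atrophy_hc_sd = 0.2,
    interval_mean = 0.96, interval_sd = 0.17,
    icv_mean = 1450, icv_sd = 130,
    steroid_prob = 0.25,
    pbvc_mean = -0.32, pbvc_sd = 0.55, pbvc_coupling = 0.5,
    vol_mean = 9.13, vol_sd = 1.89,
    vol_age_slope = -0.03, vol_icv_slope = 0.8,
    clinical_betas = NULL, clinical_noise = NULL,
    long_betas = NULL, long_noise = NULL,
    heteroscedastic = FALSE) {
  if (n_subjects < 10) stop("n_subjects must be >= 10")
  if (abs(sum(dx_props) - 1) > 1e-8) stop("dx_props must sum to 1")
  if (is.null(clinical_betas))
    clinical_betas <- list(
      edss = c(intercept = 3.57, vol = -0.26, age = 0.03, sex = 0.3,
               z_icv = -0.05),
      log_t25fw = c(intercept = 1.67, vol = -0.03, age = 0.005, sex = 0,
                    z_icv = 0),
      log_hpt9 = c(intercept = 3.01, vol = -0.02, age = 0.004, sex = 0,
                   z_icv = 0),
      sdmt = c(intercept = 37.1, vol = 2.6, age = -0.25, sex = 0,
               z_icv = 0.5))
  if (is.null(clinical_noise))
    clinical_noise <- c(edss = 1.2, log_t25fw = 0.25, log_hpt9 = 0.2,
                        sdmt = 8)
  if (is.null(long_betas))
    long_betas <- list(
      d_edss = c(intercept = 0, dvol = 0.6, steroid = 0.2, interval = 0),
      d_t25fw = c(intercept = 0.1, dvol = -0.2, steroid = 0, interval = 0),
      d_hpt9 = c(intercept = 0, dvol = -0.1, steroid = 0, interval = 0),
      d_sdmt = c(intercept = 1.0, dvol = 2.0, steroid = 0, interval = 0))
  if (is.null(long_noise))
    long_noise <- c(d_edss = 0.5, d_t25fw = 0.8, d_hpt9 = 1.0, d_sdmt = 4)
  structure(as.list(environment()), class = "cohort_sim_config")
}

snap_edss <- function(x) pmin(10, pmax(0, round(x * 2) / 2))

#' Simulate clinical outcomes from volumes and demographics
#'
#' Generates EDSS, timed 25-foot walk, 9-hole peg test and SDMT from the
#' linear model the cross-sectional analysis fits, with the configuration's
#' truth coefficients. EDSS is snapped to the 0-10 half-point lattice after
#' generation (the pre-snap values are kept in the truth ledger so exact-
#' recovery checks remain possible); the timed tests are generated
#' log-normal and are therefore right-skewed.
#'
#' @param demo Data frame with `subject_id`, `vol` (true volume, mL), `age`,
#'   `sex` (0/1), `z_icv`.
#' @param config A [cohort_sim_config].
#' @param seed Optional integer seed.
#' @return List with `table` (outcome columns appended) and `truth`
#'   (coefficients, noise SDs, pre-snap EDSS).
#' @export
simulate_clinical <- function(demo, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"),
            all(c("vol", "age", "sex", "z_icv") %in% names(demo)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(demo)
  lin <- function(b)
    b["intercept"] + b["vol"] * demo$vol + b["age"] * demo$age +
    b["sex"] * demo$sex + b["z_icv"] * demo$z_icv
  cb <- config$clinical_betas; cn <- config$clinical_noise
  mu_edss <- lin(cb$edss)
  sd_edss <- if (config$heteroscedastic)
    cn["edss"] * pmax(mu_edss, 0.5) / mean(pmax(mu_edss, 0.5))
  else rep(cn["edss"], n)
  edss_star <- mu_edss + stats::rnorm(n, 0, sd_edss)
  demo$edss <- snap_edss(edss_star)
  demo$t25fw <- exp(lin(cb$log_t25fw) + stats::rnorm(n, 0, cn["log_t25fw"]))
  demo$hpt9 <- exp(lin(cb$log_hpt9) + stats::rnorm(n, 0, cn["log_hpt9"]))
  demo$sdmt <- pmax(0, round(lin(cb$sdmt) + stats::rnorm(n, 0, cn["sdmt"])))
  list(table = demo,
       truth = list(clinical_betas = cb, clinical_noise = cn,
                    heteroscedastic = config$heteroscedastic,
                    edss_star = edss_star))
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator: phantom ground truths at two timepoints per
#' subject, simulated segmentations for each profile, demographics, clinical
#' outcomes and their one-year deltas, and a coupled global-atrophy (PBVC
#' stand-in) variable. Every injected parameter is recorded in the truth
#' ledger, so each pipeline stage can be validated by recovery. All
#' randomness flows from `config$seed`; identical configs give identical
#' cohorts.
#'
#' Because full mask sets are large, masks are processed subject by subject:
#' per-method volumes, voxel agreement against ground truth (baseline), and
#' pairwise containment are computed on the fly. Set `out_dir` to also write
#' every mask as NIfTI plus `cohort.csv` and `truth.json`.
#'
#' @param config A [cohort_sim_config].
#' @param profiles Named list of [segmenter_profile]s, default
#'   [default_segmenter_profiles()].
#' @param spec A [phantom_spec] for the ground-truth phantoms.
#' @param out_dir Optional output directory for NIfTI masks, `cohort.csv`
#'   and `truth.json`.
#' @param mask_level Rasterize phantoms and simulate masks (`TRUE`, default).
#'   With `FALSE`, method volumes are drawn directly from the profile's
#'   volumetric model (same bias/slope/noise structure, boundary-layer
#'   volume approximated from the spec geometry) — orders of magnitude
#'   faster, for large clinical-association cohorts where voxel-wise
#'   metrics are not needed (`metrics` and `containment` are `NULL`).
#' @return List with `cohort` (one row per subject-timepoint; `vol_gt` and
#'   `vol_<method>` columns in mL), `metrics` (per-subject baseline DSC /
#'   precision / sensitivity per method), `containment` (mean directed
#'   containment matrix across GT + methods), and `truth` (the ledger).
#' @export
generate_cohort <- function(config = cohort_sim_config(),
                            profiles = default_segmenter_profiles(),
                            spec = phantom_spec(),
                            out_dir = NULL,
                            mask_level = TRUE) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("sub-%03d", seq_len(n))
  dx <- sample(names(config$dx_props), n, replace = TRUE,
               prob = config$dx_props)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  age <- pmin(pmax(age, 18), 80)
  sex <- stats::rbinom(n, 1, config$female_prop)  # 1 = female
  icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)
  z_icv <- (icv - mean(icv)) / sqrt(mean((icv - mean(icv))^2))
  resid_sd <- sqrt(max(config$vol_sd^2 -
                         (config$vol_age_slope * config$age_sd)^2 -
                         config$vol_icv_slope^2, 0.25))
  vol_true <- config$vol_mean +
    config$vol_age_slope * (age - config$age_mean) +
    config$vol_icv_slope * z_icv + stats::rnorm(n, 0, resid_sd)
  vol_true <- pmax(vol_true, 3)
  is_hc <- dx == "HC"
  rate <- ifelse(is_hc,
                 stats::rnorm(n, config$atrophy_hc_mean, config$atrophy_hc_sd),
                 stats::rnorm(n, config$atrophy_patient_mean,
                              config$atrophy_patient_sd))
  interval <- pmax(stats::rnorm(n, config$interval_mean, config$interval_sd),
                   0.5)
  steroid <- ifelse(is_hc, 0L, stats::rbinom(n, 1, config$steroid_prob))

  mnames <- names(profiles)
  vol_meas <- array(NA_real_, c(n, length(mnames) + 1, 2),
                    dimnames = list(ids, c("gt", mnames), c("bl", "fu")))
  metrics <- list()
  all_m <- c("gt", mnames)
  p <- length(all_m)
  cont_acc <- matrix(0, p, p, dimnames = list(all_m, all_m))
  write_masks <- !is.null(out_dir)
  if (write_masks) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!mask_level) {
    # volumetric model only: expected volume + persistent subject noise +
    # session noise, with the boundary-layer volume approximated from the
    # spec geometry (one voxel-thick shell over an ellipsoid-like surface)
    layer_k <- 0.477 * spec$voxel_mm / 0.8
    for (i in seq_len(n)) {
      bl_true <- vol_true[i]
      fu_true <- bl_true * (1 + rate[i] * interval[i] / 100)
      vol_meas[i, "gt", "bl"] <- bl_true
      vol_meas[i, "gt", "fu"] <- fu_true
      for (m in mnames) {
        pr <- profiles[[m]]
        layer_ml <- layer_k * bl_true^(2 / 3)
        subj_noise <- stats::rnorm(1, 0, pr$boundary_noise_sd * layer_ml)
        sess <- stats::rnorm(2, 0, pr$session_noise_sd * layer_ml)
        expected <- function(true_ml)
          true_ml + pr$additive_bias_ml +
          pr$proportional_slope * (true_ml - config$vol_mean)
        vol_meas[i, m, "bl"] <- expected(bl_true) + subj_noise + sess[1]
        vol_meas[i, m, "fu"] <- expected(fu_true) + subj_noise + sess[2]
      }
    }
  } else for (i in seq_len(n)) {
    ph <- generate_phantom_gt(spec, target_volume_ml = vol_true[i])
    gt_bl <- ph$gt
    gt_fu <- simulate_longitudinal(gt_bl, rate[i], interval[i])
    masks_bl <- list(gt = gt_bl)
    masks_fu <- list(gt = gt_fu)
    voxml <- voxel_volume_mm3(gt_bl$grid) / 1000
    layer_ml <- sum(outer_boundary(gt_bl$data)) * voxml
    for (m in mnames) {
      pr <- profiles[[m]]
      # subject-level noise persists across timepoints; session noise is fresh
      subj_noise <- stats::rnorm(1, 0, pr$boundary_noise_sd * layer_ml)
      sess <- stats::rnorm(2, 0, pr$session_noise_sd * layer_ml)
      masks_bl[[m]] <- simulate_segmentation(gt_bl, pr,
                                             cohort_mean_ml = config$vol_mean,
                                             decoy_labels = ph$labels,
                                             noise_ml = subj_noise + sess[1])
      masks_fu[[m]] <- simulate_segmentation(gt_fu, pr,
                                             cohort_mean_ml = config$vol_mean,
                                             decoy_labels = ph$labels,
                                             noise_ml = subj_noise + sess[2])
    }
    for (m in all_m) {
      vol_meas[i, m, "bl"] <- mask_volume_ml(masks_bl[[m]])
      vol_meas[i, m, "fu"] <- mask_volume_ml(masks_fu[[m]])
    }
    for (m in mnames) {
      va <- voxel_agreement(overlap_counts(gt_bl, masks_bl[[m]]))
      metrics[[length(metrics) + 1L]] <-
        data.frame(subject = ids[i], method = m, dsc = va$dsc,
                   precision = va$precision, sensitivity = va$sensitivity)
    }
    for (a in all_m) for (b in all_m)
      cont_acc[a, b] <- cont_acc[a, b] +
        sum(masks_bl[[a]]$data & masks_bl[[b]]$data) / sum(masks_bl[[a]]$data)
    if (write_masks) {
      for (m in all_m) {
        write_volume(masks_bl[[m]],
                     file.path(out_dir, paste0(ids[i], "_", m, "_bl.nii.gz")))
        write_volume(masks_fu[[m]],
                     file.path(out_dir, paste0(ids[i], "_", m, "_fu.nii.gz")))
      }
    }
  }

  # PBVC-like global atrophy, correlated with the realized thalamic rate
  d_pct_gt <- 100 * (vol_meas[, "gt", "fu"] - vol_meas[, "gt", "bl"]) /
    vol_meas[, "gt", "bl"]
  z_rate <- as.numeric(scale(d_pct_gt))
  rho <- config$pbvc_coupling
  pbvc <- config$pbvc_mean +
    config$pbvc_sd * (rho * z_rate + sqrt(1 - rho^2) * stats::rnorm(n))

  demo <- data.frame(subject_id = ids, dx_group = dx, age = age, sex = sex,
                     icv = icv, z_icv = z_icv,
                     vol = vol_meas[, "gt", "bl"])
  clin <- simulate_clinical(demo, config)
  bl <- clin$table
  # clinical deltas from the longitudinal truth model, driven by measured
  # GT volume change in mL
  d_vol_gt <- vol_meas[, "gt", "fu"] - vol_meas[, "gt", "bl"]
  lb <- config$long_betas; ln <- config$long_noise
  dlin <- function(b, noise)
    b["intercept"] + b["dvol"] * d_vol_gt + b["steroid"] * steroid +
    b["interval"] * (interval - config$interval_mean) +
    stats::rnorm(n, 0, noise)
  d_edss_star <- dlin(lb$d_edss, ln["d_edss"])
  d_t25fw <- dlin(lb$d_t25fw, ln["d_t25fw"])
  d_hpt9 <- dlin(lb$d_hpt9, ln["d_hpt9"])
  d_sdmt <- round(dlin(lb$d_sdmt, ln["d_sdmt"]))

  mk_row <- function(tp) {
    r <- data.frame(subject_id = ids, dx_group = dx, age = age, sex = sex,
                    icv = icv, z_icv = z_icv, timepoint = tp,
                    interval_years = interval, steroid_flag = steroid,
                    global_atrophy_pct = pbvc)
    sl <- if (tp == "baseline") "bl" else "fu"
    r$vol_gt <- vol_meas[, "gt", sl]
    for (m in mnames) r[[paste0("vol_", m)]] <- vol_meas[, m, sl]
    if (tp == "baseline") {
      r$edss <- bl$edss; r$t25fw <- bl$t25fw
      r$hpt9 <- bl$hpt9; r$sdmt <- bl$sdmt
    } else {
      r$edss <- snap_edss(clin$truth$edss_star + d_edss_star)
      r$t25fw <- pmax(bl$t25fw + d_t25fw, 0.5)
      r$hpt9 <- pmax(bl$hpt9 + d_hpt9, 1)
      r$sdmt <- pmax(bl$sdmt + d_sdmt, 0)
    }
    r
  }
  cohort <- rbind(mk_row("baseline"), mk_row("year1"))
  cohort <- cohort[order(cohort$subject_id, cohort$timepoint), ]
  rownames(cohort) <- NULL

  truth <- list(config = unclass(config)[setdiff(names(unclass(config)),
                                                 c("clinical_betas",
                                                   "clinical_noise",
                                                   "long_betas",
                                                   "long_noise"))],
                clinical_betas = config$clinical_betas,
                clinical_noise = as.list(config$clinical_noise),
                long_betas = config$long_betas,
                long_noise = as.list(config$long_noise),
                profiles = lapply(profiles, unclass),
                subjects = data.frame(subject_id = ids, dx_group = dx,
                                      true_volume_ml = vol_true,
                                      atrophy_rate_pct_per_year = rate,
                                      interval_years = interval,
                                      steroid_flag = steroid,
                                      pbvc = pbvc,
                                      edss_star = clin$truth$edss_star,
                                      d_edss_star = d_edss_star))

  out <- list(cohort = cohort,
              metrics = if (mask_level) do.call(rbind, metrics) else NULL,
              containment = if (mask_level) cont_acc / n else NULL,
              truth = truth)
  if (write_masks) {
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  out
}
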