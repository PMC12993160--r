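# Volume-level cohort builder (no masks): clinical truth known exactly.
sim_cohort_tbl <- function(n = 200, beta_vol = -0.26, noise = 1,
                           het = FALSE, seed = 1) {
  set.seed(seed)
  icv <- rnorm(n, 1450, 130)
  z <- (icv - mean(icv)) / sqrt(mean((icv - mean(icv))^2))
  age <- rnorm(n, 43.4, 12.4)
  sex <- rbinom(n, 1, 2 / 3)
  vol <- 9.13 - 0.03 * (age - 43.4) + 0.8 * z + rnorm(n, 0, 1.67)
  mu <- 3.57 + beta_vol * vol + 0.03 * age + 0.3 * sex - 0.05 * z
  sdv <- if (het) noise * pmax(mu, 0.5) / mean(pmax(mu, 0.5)) else noise
  data.frame(subject_id = seq_len(n), age = age, sex = sex, icv = icv,
             vol_gt = vol, edss = mu + rnorm(n, 0, sdv))
}

test_that("BH step-up matches the hand-computed example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(67)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))  # independent route
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in rank
  }
})

test_that("ICV z-scoring centres and scales with the population convention", {
  tab <- data.frame(subject_id = 1:3, icv = c(1400, 1500, 1600))
  z <- zscore_icv(tab)$z_icv
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  # z of z is z
  tab2 <- data.frame(subject_id = 1:3, icv = z)
  expect_equal(zscore_icv(tab2)$z_icv, z, tolerance = 1e-12)
  expect_error(zscore_icv(data.frame(subject_id = 1:3, icv = rep(1, 3))),
               "distinct")
})

test_that("cross-sectional fit recovers an exact log-linear relation", {
  tab <- sim_cohort_tbl(100, seed = 71)
  tab$t25fw <- exp(1.5 - 0.04 * tab$vol_gt)
  f <- fit_crosssectional(tab, "t25fw", "gt", log_transform = TRUE)
  expect_equal(f$beta, -0.04, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_match(f$transform_tag, "log")
})

test_that("cross-sectional fit recovers the injected volume effect", {
  tab <- sim_cohort_tbl(400, beta_vol = -0.26, noise = 1.2, seed = 74)
  f <- fit_crosssectional(tab, "edss", "gt", hc3 = TRUE)
  expect_true(f$ci_low <= -0.26 && -0.26 <= f$ci_high)
  expect_true(f$robust_flag)
  # null: no volume effect -> approximately nominal type-I error
  set.seed(79)
  rej <- mean(replicate(120, {
    tab0 <- sim_cohort_tbl(150, beta_vol = 0, seed = sample.int(1e6, 1))
    fit_crosssectional(tab0, "edss", "gt")$p < 0.05
  }))
  expect_gte(rej, 0.005); expect_lte(rej, 0.12)
})

make_long_cohort <- function(n = 150, gv = 0.6, seed = 83, steroid_only = FALSE) {
  set.seed(seed)
  bl <- sim_cohort_tbl(n, seed = seed)
  bl$timepoint <- "baseline"
  bl$interval_years <- pmax(rnorm(n, 0.96, 0.17), 0.5)
  bl$steroid_flag <- rbinom(n, 1, 0.25)
  fu <- bl
  fu$timepoint <- "year1"
  dvol <- rnorm(n, -0.05, 0.15)
  fu$vol_gt <- bl$vol_gt + dvol
  d_edss <- if (steroid_only) 0.8 * bl$steroid_flag + rnorm(n, 0, 0.3)
  else gv * dvol + 0.2 * bl$steroid_flag + rnorm(n, 0, 0.3)
  fu$edss <- bl$edss + d_edss
  rbind(bl, fu)
}

test_that("delta computation is exact arithmetic with exclusion logging", {
  co <- make_long_cohort(20, seed = 89)
  co$vol_gt[co$subject_id == 1 & co$timepoint == "baseline"] <- 9.0
  co$vol_gt[co$subject_id == 1 & co$timepoint == "year1"] <- 8.91
  co <- co[!(co$subject_id == 2 & co$timepoint == "year1"), ]
  expect_message(d <- compute_deltas(co), "excluded")
  expect_equal(attr(d, "excluded"), 2)
  r <- d[d$subject_id == 1, ]
  expect_equal(r$d_vol_gt_ml, -0.09, tolerance = 1e-12)
  expect_equal(r$d_vol_gt_pct, -1.0, tolerance = 1e-12)
  # identical timepoints give zero deltas
  same <- co[co$timepoint == "baseline", ]
  same2 <- same; same2$timepoint <- "year1"
  d0 <- compute_deltas(rbind(same, same2))
  expect_true(all(d0$d_vol_gt_ml == 0) && all(d0$d_edss == 0))
  # conservation: mean percent delta recomputes from raw volumes
  d <- compute_deltas(make_long_cohort(50, seed = 97))
  co2 <- make_long_cohort(50, seed = 97)
  bl <- co2[co2$timepoint == "baseline", ]; fu <- co2[co2$timepoint == "year1", ]
  expect_equal(mean(d$d_vol_gt_pct),
               mean(100 * (fu$vol_gt - bl$vol_gt) / bl$vol_gt),
               tolerance = 1e-10)
})

test_that("longitudinal fit recovers the injected delta coefficient", {
  co <- make_long_cohort(200, gv = 0.6, seed = 101)
  d <- compute_deltas(co)
  f <- fit_longitudinal(d, "edss", "gt")
  expect_true(f$ci_low <= 0.6 && 0.6 <= f$ci_high)
  # when steroids carry all the signal, the volume slope vanishes
  co2 <- make_long_cohort(300, seed = 103, steroid_only = TRUE)
  f2 <- fit_longitudinal(compute_deltas(co2), "edss", "gt")
  expect_true(f2$ci_low <= 0 && 0 <= f2$ci_high)
})

test_that("pairwise delta comparison flags a uniformly shifted method", {
  co <- make_long_cohort(200, seed = 107)
  d <- compute_deltas(co)
  d$d_vol_b_pct <- d$d_vol_gt_pct - 0.3
  d$d_vol_c_pct <- d$d_vol_gt_pct + rnorm(nrow(d), 0, 1e-3)
  pw <- delta_method_comparison(d, "pct")
  shifted <- pw[pw$method_a == "gt" & pw$method_b == "b", ]
  expect_lt(shifted$p_adj, 0.05)
})

test_that("atrophy-vs-global correlation hits the exact and null anchors", {
  co <- make_long_cohort(100, seed = 109)
  d <- compute_deltas(co)
  d$global_atrophy_pct <- d$d_vol_gt_pct     # exact coupling
  r <- atrophy_vs_global(d)$correlations
  expect_equal(r$r[r$method == "gt"], 1, tolerance = 1e-12)
  set.seed(113)
  d$global_atrophy_pct <- rnorm(nrow(d))     # independent noise
  r2 <- atrophy_vs_global(d)$correlations
  expect_lt(abs(r2$r[r2$method == "gt"]), 0.25)
})

test_that("winsorization clamps outliers, is idempotent, and tames the slope", {
  co <- make_long_cohort(150, seed = 127)
  d <- compute_deltas(co)
  ws <- winsorize_sensitivity(d, "edss", "gt")
  # data within the band: 5-95 limits clamp only the tails
  expect_equal(ws$unwinsorized$n, ws$win_1_99$n)
  d_out <- d
  d_out$d_vol_gt_ml[1] <- 10 * sd(d$d_vol_gt_ml)  # extreme outlier
  d_out$d_edss[1] <- -5
  ws2 <- winsorize_sensitivity(d_out, "edss", "gt")
  bulk <- ws$unwinsorized$beta
  expect_lt(abs(ws2$win_1_99$beta - bulk), abs(ws2$unwinsorized$beta - bulk))
  # winsorizing twice equals once
  v <- d_out$d_vol_gt_ml
  w1 <- thalavol:::winsorize(v, 1, 99)
  expect_equal(thalavol:::winsorize(w1, 1, 99), w1, tolerance = 1e-12)
})

test_that("ordinal EDSS-change model agrees in direction with the OLS", {
  co <- make_long_cohort(250, gv = 1.5, seed = 131)
  d <- compute_deltas(co)
  res <- ordinal_edss_sensitivity(d, "gt")
  expect_true(is.na(res$flag))
  expect_true(res$direction_consistent)
  expect_equal(sign(res$coef), sign(res$ols_beta))
  # single-category data is a contract error
  d1 <- d; d1$d_edss <- 0
  expect_error(ordinal_edss_sensitivity(d1, "gt"), "categories")
})
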