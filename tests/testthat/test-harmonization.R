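make_intensity <- function(values, grid) intensity_volume(values, grid)

test_that("quantitative-map rescaling clips, rescales and zeroes outside", {
  g <- tiny_grid(c(10, 10, 10))
  set.seed(7)
  vals <- array(0, g$shape)
  brain <- array(FALSE, g$shape); brain[1:500] <- TRUE
  vals[1:500] <- sample(0:100, 500, TRUE)
  vals[501:1000] <- 999  # junk outside the brain
  iv <- make_intensity(vals, g)
  bm <- binary_mask(brain, g)
  out <- rescale_quantitative_map(iv, bm, clip_quantile = 0.99)
  expect_true(all(out$data[!brain] == 0))
  expect_equal(max(out$data[brain]), 1000)
  expect_true(min(out$data[brain]) >= 0)
  # rank order preserved for unclipped values (sort-based oracle)
  clip <- quantile(vals[brain], 0.99, type = 7)
  unclipped <- which(brain & vals < clip)
  expect_equal(order(vals[unclipped]), order(out$data[unclipped]))
  # at least as many voxels at out_max as strictly above the clip value
  expect_gte(sum(out$data[brain] == 1000), sum(vals[brain] > clip))
})

test_that("rescaling with clip at the max is an idempotent linear stretch", {
  g <- tiny_grid(c(6, 6, 6))
  brain <- binary_mask(array(TRUE, g$shape), g)
  x <- seq(0, 1000, length.out = prod(g$shape))
  iv <- make_intensity(array(x, g$shape), g)
  once <- rescale_quantitative_map(iv, brain, clip_quantile = 1)
  expect_equal(once$data, iv$data, tolerance = 1e-12)
  twice <- rescale_quantitative_map(once, brain, clip_quantile = 1)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("degenerate in-brain intensity is an error", {
  g <- tiny_grid(c(5, 5, 5))
  brain <- binary_mask(array(TRUE, g$shape), g)
  expect_error(
    rescale_quantitative_map(make_intensity(array(3, g$shape), g), brain),
    "degenerate")
})

test_that("MI of an image with itself equals its binned entropy", {
  g <- tiny_grid(c(12, 12, 12))
  set.seed(11)
  a <- make_intensity(array(rnorm(prod(g$shape)), g$shape), g)
  mask <- binary_mask(array(TRUE, g$shape), g)
  mi <- mutual_information(a, a, mask, bins = 32)
  expect_equal(mi, masked_entropy(a, mask, bins = 32), tolerance = 1e-12)
  # dual route: contingency-table oracle on the bin indices
  idx <- thalavol:::bin_index(a$data[mask$data], 32)
  expect_equal(mi, oracle_mi(idx, idx), tolerance = 1e-10)
})

test_that("MI of independent noise is near zero at 1e5 voxels", {
  g <- image_grid(c(50, 50, 40), c(1, 1, 1))
  set.seed(13)
  a <- make_intensity(array(runif(prod(g$shape)), g$shape), g)
  b <- make_intensity(array(runif(prod(g$shape)), g$shape), g)
  mask <- binary_mask(array(TRUE, g$shape), g)
  expect_lt(mutual_information(a, b, mask), 0.05)
})

test_that("MI is invariant to affine transforms and symmetric", {
  g <- tiny_grid(c(10, 10, 10))
  set.seed(17)
  av <- array(rnorm(prod(g$shape)), g$shape)
  a <- make_intensity(av, g)
  b <- make_intensity(3 * av + 7, g)  # monotone affine map: same binning
  mask <- binary_mask(array(TRUE, g$shape), g)
  expect_equal(mutual_information(a, b, mask),
               mutual_information(a, a, mask), tolerance = 1e-12)
  for (i in 1:5) {
    x <- make_intensity(array(rnorm(prod(g$shape)), g$shape), g)
    y <- make_intensity(array(rnorm(prod(g$shape)), g$shape), g)
    mxy <- mutual_information(x, y, mask)
    expect_identical(mxy, mutual_information(y, x, mask))
    expect_lte(mxy, min(masked_entropy(x, mask), masked_entropy(y, mask)) +
                 1e-9)
    expect_gte(mxy, 0)
  }
})

test_that("MI refuses fewer masked voxels than bins", {
  g <- tiny_grid(c(4, 4, 4))
  a <- make_intensity(array(rnorm(64), g$shape), g)
  m <- mask_from_idx(1:10, g)
  expect_error(mutual_information(a, a, m, bins = 64), "insufficient")
})

test_that("registration selection follows the family-priority rule", {
  th <- qc_thresholds(c(fsl = 0.25, ants = 0.30))
  cands <- function(mis) data.frame(
    tag = c("fsl_rigid", "fsl_affine", "ants"),
    family = c("fsl", "fsl", "ants"), mi = mis)
  # both FSL pass: higher-MI FSL wins even when ANTs has the highest MI
  r <- select_registration(cands(c(0.30, 0.28, 0.35)), th)
  expect_equal(r$chosen, "fsl_rigid")
  expect_false(r$excluded)
  # FSL fail, ANTs passes -> ANTs
  r <- select_registration(cands(c(0.20, 0.22, 0.33)), th)
  expect_equal(r$chosen, "ants")
  # all below cut-offs -> exclusion (a valid outcome, not an error)
  r <- select_registration(cands(c(0.20, 0.22, 0.29)), th)
  expect_true(r$excluded)
  expect_true(is.na(r$chosen))
  # ties within a family break by candidate order
  r <- select_registration(cands(c(0.30, 0.30, 0.10)), th)
  expect_equal(r$chosen, "fsl_rigid")
  # manual visual-review override forces exclusion regardless of MI
  r <- select_registration(cands(c(0.9, 0.9, 0.9)), th, manual_exclude = TRUE)
  expect_true(r$excluded)
  expect_error(select_registration(
    data.frame(tag = "x", family = "spm", mi = 0.4), th), "no cut-off")
})
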