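# Small in-code fixtures shared across test files.

tiny_grid <- function(shape = c(8, 8, 8), vox = 1) {
  image_grid(shape, rep(vox, 3))
}

# mask with foreground at the given linear indices
mask_from_idx <- function(idx, grid = tiny_grid()) {
  a <- array(FALSE, grid$shape)
  a[idx] <- TRUE
  binary_mask(a, grid)
}

random_mask <- function(grid = tiny_grid(), p = 0.3) {
  binary_mask(array(runif(prod(grid$shape)) < p, grid$shape), grid)
}

# fast phantom spec for tests: 1 mm voxels, small ellipsoids
small_spec <- function(...) {
  phantom_spec(shape = c(40, 48, 40), voxel_mm = 1,
               semi_axes_mm = c(4.5, 10, 7), center_offset_mm = 8,
               target_volume_mean_ml = 2.6, target_volume_sd_ml = 0.25,
               ...)
}

# independent entropy/MI oracle from contingency tables (nats)
oracle_entropy <- function(i) {
  p <- table(i) / length(i)
  -sum(p * log(p))
}
oracle_mi <- function(i, j) {
  oracle_entropy(i) + oracle_entropy(j) -
    oracle_entropy(paste(i, j, sep = "_"))
}

# ICC(3,1) oracle via a two-way ANOVA decomposition with stats::aov
oracle_icc3_aov <- function(x, y) {
  n <- length(x)
  long <- data.frame(value = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + mse)
}
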