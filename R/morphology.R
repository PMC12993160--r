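# Vectorised 3D binary morphology on logical arrays (6-connectivity).
# These are the volume-targeting primitives of the synthetic generator:
# iterative single-voxel-layer dilation/erosion with partial-layer random
# selection gives continuous volume control on a discrete grid.

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  dst_x <- sx + dx; dst_y <- sy + dy; dst_z <- sz + dz
  okx <- dst_x >= 1 & dst_x <= d[1]
  oky <- dst_y >= 1 & dst_y <= d[2]
  okz <- dst_z >= 1 & dst_z <= d[3]
  out[dst_x[okx], dst_y[oky], dst_z[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

neighbor_count <- function(a) {
  shift3(a, 1, 0, 0) + shift3(a, -1, 0, 0) +
    shift3(a, 0, 1, 0) + shift3(a, 0, -1, 0) +
    shift3(a, 0, 0, 1) + shift3(a, 0, 0, -1)
}

outer_boundary <- function(a) !a & neighbor_count(a) > 0
inner_boundary <- function(a) a & neighbor_count(a) < 6

# Grow/shrink the mask to an exact foreground voxel count, one layer at a
# time, choosing a random subset of the final partial layer. `prefer` (a
# logical array) makes dilation consume preferred voxels (e.g. decoy
# regions) before others.
adjust_to_count <- function(a, target, prefer = NULL) {
  target <- as.integer(round(target))
  if (target < 1) stop("target voxel count must be >= 1")
  n <- sum(a)
  while (n < target) {
    ob <- outer_boundary(a)
    cand <- which(ob)
    if (length(cand) == 0) stop("cannot grow further: no boundary voxels")
    if (!is.null(prefer)) {
      pref <- cand[prefer[cand]]
      rest <- cand[!prefer[cand]]
      cand <- c(pref[sample.int(length(pref))], rest[sample.int(length(rest))])
    } else {
      cand <- cand[sample.int(length(cand))]
    }
    take <- min(target - n, length(cand))
    a[cand[seq_len(take)]] <- TRUE
    n <- n + take
  }
  while (n > target) {
    ib <- which(inner_boundary(a))
    if (length(ib) == 0) stop("erosion emptied the mask")
    drop <- min(n - target, length(ib))
    a[ib[sample.int(length(ib), drop)]] <- FALSE
    n <- n - drop
  }
  a
}

# Volume-preserving boundary resampling: remove nswap random inner-boundary
# voxels and add the same number of random outer-boundary voxels, in passes
# (a pass cannot exceed the current boundary size). Makes a simulated mask
# spatially distinct from its source without changing its volume.
jitter_boundary <- function(a, nswap, max_passes = 8) {
  remaining <- as.integer(round(nswap))
  pass <- 0
  while (remaining > 0 && pass < max_passes) {
    ib <- which(inner_boundary(a))
    ob <- which(outer_boundary(a))
    k <- min(remaining, floor(length(ib) * 0.9), length(ob))
    if (k < 1) break
    a[ib[sample.int(length(ib), k)]] <- FALSE
    a[ob[sample.int(length(ob), k)]] <- TRUE
    remaining <- remaining - k
    pass <- pass + 1
  }
  a
}
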