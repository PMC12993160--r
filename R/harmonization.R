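#' Rescale a quantitative map to a harmonized intensity range
#'
#' Harmonizes the dynamic range of a quantitative map (e.g. an R1 relaxation
#' rate map) with T1-weighted data before feeding it to a contrast-sensitive
#' segmenter. Within the brain mask, intensities are clipped at the
#' `clip_quantile` quantile of in-brain values and mapped linearly from
#' [in-brain minimum, clip value] onto [0, `out_max`]; all voxels outside the
#' mask are set to exactly 0. The mapping is monotone, so the rank order of
#' unclipped in-brain values is preserved and no histogram-matching artefacts
#' are introduced.
#'
#' @param map An [intensity_volume].
#' @param brain A [binary_mask] on the same grid (non-empty).
#' @param clip_quantile Upper clipping quantile of in-brain intensities,
#'   default `0.99`.
#' @param out_max Upper end of the output range, default `1000`.
#' @return An [intensity_volume] with values in `[0, out_max]`.
#' @export
rescale_quantitative_map <- function(map, brain, clip_quantile = 0.99,
                                     out_max = 1000) {
  stopifnot(inherits(map, "intensity_volume"), inherits(brain, "binary_mask"))
  assert_same_grid(map, brain)
  if (!any(brain$data)) stop("brain mask is empty")
  v <- map$data[brain$data]
  if (any(!is.finite(v))) stop("non-finite map values inside the brain mask")
  lo <- min(v)
  hi <- as.numeric(stats::quantile(v, clip_quantile, type = 7))
  if (hi - lo <= 0)
    stop("degenerate in-brain intensity range: clip value equals minimum")
  out <- array(0, dim = map$grid$shape)
  out[brain$data] <- pmin(pmax(v, lo), hi)
  out[brain$data] <- (out[brain$data] - lo) / (hi - lo) * out_max
  intensity_volume(out, map$grid)
}

#' Mutual information between two images over a mask
#'
#' Joint-histogram mutual information in nats: equal-width binning of each
#' image over its masked intensity range (default 64 bins), then
#' \eqn{\sum p(x,y) \log[p(x,y)/(p(x)p(y))]}. Used as an alignment metric for
#' registration quality control.
#'
#' @param a,b [intensity_volume]s on a shared grid.
#' @param mask A [binary_mask] restricting the computation (non-empty).
#' @param bins Number of equal-width bins per image, default `64`.
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(a, b, mask, bins = 64) {
  stopifnot(inherits(a, "intensity_volume"), inherits(b, "intensity_volume"),
            inherits(mask, "binary_mask"))
  assert_same_grid(a, b)
  assert_same_grid(a, mask)
  va <- a$data[mask$data]
  vb <- b$data[mask$data]
  n <- length(va)
  if (n < bins)
    stop("insufficient sample: ", n, " masked voxels for ", bins, " bins")
  ia <- bin_index(va, bins)
  ib <- bin_index(vb, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / n
  pj <- joint[joint > 0]
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  hj <- -sum(pj * log(pj))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  max(ha + hb - hj, 0)
}

bin_index <- function(x, bins) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(as.integer(i), bins)
}

#' Shannon entropy of a binned image over a mask (nats)
#'
#' Companion to [mutual_information] under identical binning; useful for the
#' bound MI(a, b) <= min(H(a), H(b)).
#'
#' @inheritParams mutual_information
#' @return Entropy in nats.
#' @export
masked_entropy <- function(a, mask, bins = 64) {
  v <- a$data[mask$data]
  p <- tabulate(bin_index(v, bins), nbins = bins) / length(v)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' Registration QC thresholds
#'
#' Per-method-family MI cut-offs below which a registration is flagged as
#' failed. Defaults follow the convention of ~0.25 for an FSL-type strategy
#' and ~0.30 for an ANTs-type strategy; the cut-offs are in the units of this
#' package's MI estimator and should be recalibrated per deployment.
#'
#' @param cutoffs Named numeric vector mapping family tag to MI cut-off
#'   (all > 0).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cutoffs = c(fsl = 0.25, ants = 0.30)) {
  if (is.null(names(cutoffs)) || any(!nzchar(names(cutoffs))))
    stop("'cutoffs' must be a named vector")
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("cut-offs must be positive")
  structure(list(cutoffs = cutoffs), class = "qc_thresholds")
}

#' Select a registration from QC'd candidates
#'
#' Deterministic selection rule for a set of candidate registrations of one
#' subject, each scored by MI: among candidates of the primary family that
#' pass their cut-off, retain the higher-MI one (ties broken by candidate
#' order); if none of the primary family passes, fall back to the alternate
#' family's passing candidate; if every candidate fails, the volume is
#' excluded. A manual visual-review override can force exclusion regardless
#' of the metric values.
#'
#' @param candidates Data frame with columns `tag` (candidate name), `family`
#'   (must match a name in `thresholds`), `mi` (non-negative MI value).
#' @param thresholds A [qc_thresholds] object.
#' @param primary_family Family tried first, default `"fsl"`.
#' @param manual_exclude Visual-review override: if `TRUE`, exclude.
#' @return List with `chosen` (candidate tag or `NA`), `excluded` (logical),
#'   and `qc` (the candidate table with a `passed` column).
#' @export
select_registration <- function(candidates, thresholds = qc_thresholds(),
                                primary_family = "fsl",
                                manual_exclude = FALSE) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1,
            all(c("tag", "family", "mi") %in% names(candidates)),
            inherits(thresholds, "qc_thresholds"))
  if (any(candidates$mi < -1e-12)) stop("MI values must be >= 0")
  cut <- thresholds$cutoffs[candidates$family]
  if (anyNA(cut))
    stop("no cut-off for family: ",
         paste(unique(candidates$family[is.na(cut)]), collapse = ", "))
  candidates$passed <- candidates$mi >= cut
  result <- list(chosen = NA_character_, excluded = TRUE, qc = candidates)
  if (manual_exclude) return(result)
  pick <- function(fam) {
    ok <- candidates[candidates$family == fam & candidates$passed, ,
                     drop = FALSE]
    if (nrow(ok) == 0) return(NA_character_)
    ok$tag[which.max(ok$mi)]  # which.max keeps the earlier candidate on ties
  }
  chosen <- pick(primary_family)
  if (is.na(chosen)) {
    for (fam in setdiff(unique(candidates$family), primary_family)) {
      chosen <- pick(fam)
      if (!is.na(chosen)) break
    }
  }
  if (!is.na(chosen)) {
    result$chosen <- chosen
    result$excluded <- FALSE
  }
  result
}
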