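#' Voxel-wise majority-vote fusion of binary masks
#'
#' Fuses k candidate masks (e.g. the same structure segmented on different
#' MRI contrasts) by voting: a voxel is foreground iff the mean of the input
#' indicators is `>= threshold`. The `>=` comparison (not `>`) is
#' load-bearing: with the default threshold of 0.5 it yields the *union* for
#' k = 2 and the 2-of-3 majority for k = 3. Equivalently, a voxel is kept iff
#' its vote count is at least `ceiling(threshold * k)`. No connected-component
#' or morphological cleanup is applied afterwards: fusion is pure voting.
#'
#' @param masks List of at least two [binary_mask]s on one grid.
#' @param threshold Vote fraction in (0, 1], default `0.5`.
#' @return The fused [binary_mask].
#' @export
majority_vote_fusion <- function(masks, threshold = 0.5) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("fusion needs a list of k >= 2 masks")
  if (!all(vapply(masks, inherits, logical(1), "binary_mask")))
    stop("all inputs must be binary_mask objects")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  g <- masks[[1]]$grid
  for (i in seq_along(masks)[-1]) assert_same_grid(masks[[1]], masks[[i]])
  k <- length(masks)
  votes <- Reduce(`+`, lapply(masks, function(m) m$data))
  binary_mask(votes / k >= threshold - 1e-12, g)
}

#' Isolate a structure from a composite label by envelope intersection
#'
#' When a segmenter emits one composite deep-grey-matter label, thresholding
#' or connected components cannot separate the target structure from
#' neighbours joined by bridge voxels; intersecting with a structure-specific
#' envelope mask from another method does. The result is the voxel-wise AND,
#' so it is contained in both inputs. An empty result is flagged (possible
#' truncation of the structure) but is not an error.
#'
#' @param composite A [binary_mask] containing the structure plus neighbours.
#' @param envelope A structure-specific [binary_mask] on the same grid.
#' @return A [binary_mask]; attribute `empty` is `TRUE` when the intersection
#'   is empty.
#' @export
isolate_structure <- function(composite, envelope) {
  stopifnot(inherits(composite, "binary_mask"),
            inherits(envelope, "binary_mask"))
  assert_same_grid(composite, envelope)
  out <- binary_mask(composite$data & envelope$data, composite$grid)
  if (!any(out$data)) {
    warning("envelope intersection is empty: possible structure truncation")
    attr(out, "empty") <- TRUE
  }
  out
}
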