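#' Voxel-wise overlap counts between reference and prediction
#'
#' True positives, false positives and false negatives of a predicted mask
#' against a reference mask on a shared grid. These counts feed all
#' voxel-wise agreement metrics.
#'
#' @param reference,prediction [binary_mask]s on one grid.
#' @return An object of class `overlap_counts` with fields `tp`, `fp`, `fn`.
#' @export
overlap_counts <- function(reference, prediction) {
  stopifnot(inherits(reference, "binary_mask"),
            inherits(prediction, "binary_mask"))
  assert_same_grid(reference, prediction)
  tp <- sum(reference$data & prediction$data)
  structure(list(tp = tp,
                 fp = sum(prediction$data) - tp,
                 fn = sum(reference$data) - tp),
            class = "overlap_counts")
}

#' Dice, precision and sensitivity from overlap counts
#'
#' * DSC = 2 TP / (2 TP + FP + FN)
#' * precision = TP / (TP + FP)
#' * sensitivity = TP / (TP + FN)
#'
#' Degenerate conventions (flagged in the result): when both masks are empty
#' all three metrics are 1; when exactly one side is empty, the metric whose
#' denominator vanishes is returned as 0 and flagged via `flags`.
#'
#' @param counts An [overlap_counts] object, or a prediction mask (with
#'   `reference` also given) from which counts are computed.
#' @param reference Optional reference [binary_mask] when `counts` is a mask.
#' @return An object of class `voxel_agreement` with fields `dsc`,
#'   `precision`, `sensitivity` and a character vector `flags`.
#' @export
voxel_agreement <- function(counts, reference = NULL) {
  if (inherits(counts, "binary_mask"))
    counts <- overlap_counts(reference, counts)
  stopifnot(inherits(counts, "overlap_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  flags <- character(0)
  if (tp + fp + fn == 0) {
    flags <- "both_empty"
    res <- list(dsc = 1, precision = 1, sensitivity = 1)
  } else {
    res <- list(
      dsc = 2 * tp / (2 * tp + fp + fn),
      precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn))
    if (tp + fp == 0) flags <- c(flags, "empty_prediction")
    if (tp + fn == 0) flags <- c(flags, "empty_reference")
  }
  structure(c(res, list(flags = flags)), class = "voxel_agreement")
}

#' @export
print.voxel_agreement <- function(x, ...) {
  cat(sprintf("DSC %.4f | precision %.4f | sensitivity %.4f",
              x$dsc, x$precision, x$sensitivity))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Directed containment-coefficient matrix across methods
#'
#' Entry (i, j) is the mean over subjects of |Mi intersect Mj| / |Mi| — the
#' fraction of method i's mask contained in method j's. The matrix is
#' asymmetric: light rows flag under-segmentation (small masks sitting inside
#' others), light columns flag over-segmentation. Containment of i in j is
#' mathematically the sensitivity with Mi as reference and Mj as prediction.
#' Coefficients are computed per subject and then averaged; subjects missing
#' either method's mask are excluded from that pair (recorded in the
#' `excluded` attribute).
#'
#' @param cohort_masks List (one element per subject) of named lists of
#'   [binary_mask]s, all methods on that subject's grid.
#' @param methods Optional character vector fixing method order; default is
#'   the union of names across subjects, in first-seen order.
#' @return Square numeric matrix with method names on both dimensions;
#'   attribute `excluded` is a data frame of (subject, method_i, method_j)
#'   pairs skipped for missing masks.
#' @export
containment_matrix <- function(cohort_masks, methods = NULL) {
  stopifnot(is.list(cohort_masks), length(cohort_masks) >= 1)
  if (is.null(methods))
    methods <- unique(unlist(lapply(cohort_masks, names)))
  p <- length(methods)
  acc <- matrix(0, p, p, dimnames = list(methods, methods))
  cnt <- matrix(0L, p, p, dimnames = list(methods, methods))
  excluded <- list()
  subj_ids <- names(cohort_masks)
  if (is.null(subj_ids)) subj_ids <- as.character(seq_along(cohort_masks))
  for (s in seq_along(cohort_masks)) {
    mm <- cohort_masks[[s]]
    for (i in methods) for (j in methods) {
      if (is.null(mm[[i]]) || is.null(mm[[j]])) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(subject = subj_ids[s], method_i = i, method_j = j)
        next
      }
      ni <- sum(mm[[i]]$data)
      if (ni == 0) next  # containment of an empty mask is undefined; skip
      acc[i, j] <- acc[i, j] + sum(mm[[i]]$data & mm[[j]]$data) / ni
      cnt[i, j] <- cnt[i, j] + 1L
    }
  }
  out <- acc / ifelse(cnt > 0, cnt, NA)
  attr(out, "excluded") <- if (length(excluded))
    do.call(rbind, excluded) else NULL
  out
}

#' Summarize per-subject agreement metrics with pairwise tests
#'
#' For a long table of per-subject, per-method metric values, computes the
#' median and IQR (25th/75th percentiles, linear interpolation) per method,
#' and paired two-sided Wilcoxon signed-rank tests for every method pair,
#' Benjamini-Hochberg adjusted within the table. The Wilcoxon convention
#' drops zero differences; the exact distribution is used for n <= 25
#' non-zero pairs, otherwise the normal approximation with continuity
#' correction. All-tied pairs are skipped with a flag (p = NA).
#'
#' @param metrics Data frame with columns `subject`, `method`, and `value`.
#' @return List with `summary` (method, median, iqr_low, iqr_high, n) and
#'   `pairwise` (method_a, method_b, n_pairs, p, p_adj, skipped).
#' @export
summarize_metrics <- function(metrics) {
  stopifnot(all(c("subject", "method", "value") %in% names(metrics)))
  methods <- unique(metrics$method)
  summ <- do.call(rbind, lapply(methods, function(m) {
    v <- metrics$value[metrics$method == m]
    q <- as.numeric(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    data.frame(method = m, median = q[2], iqr_low = q[1], iqr_high = q[3],
               n = length(v))
  }))
  pw <- if (length(methods) >= 2) pairwise_wilcoxon(metrics, methods) else NULL
  list(summary = summ, pairwise = pw)
}

# Paired signed-rank comparisons of each method pair on subject-matched
# values, BH-adjusted as one family.
pairwise_wilcoxon <- function(metrics, methods = unique(metrics$method)) {
  if (length(methods) < 2) stop("need >= 2 methods for pairwise comparison")
  combos <- utils::combn(methods, 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    a <- metrics[metrics$method == pr[1], c("subject", "value")]
    b <- metrics[metrics$method == pr[2], c("subject", "value")]
    m <- merge(a, b, by = "subject")
    d <- m$value.x - m$value.y
    nz <- sum(d != 0)
    if (nz == 0)
      return(data.frame(method_a = pr[1], method_b = pr[2],
                        n_pairs = nrow(m), p = NA_real_, skipped = TRUE))
    p <- suppressWarnings(
      stats::wilcox.test(m$value.x, m$value.y, paired = TRUE,
                         exact = nz <= 25, correct = TRUE)$p.value)
    data.frame(method_a = pr[1], method_b = pr[2], n_pairs = nrow(m),
               p = p, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}
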