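#' Evaluation configuration
#'
#' Holds the similarity thresholds that define TP/FP at instance level, the
#' recall grid of the interpolated average precision, and the bin edges of
#' the CKS histogram.
#'
#' @param cks_thresholds Strictly increasing similarity thresholds; default
#'   the ten standard levels 0.50, 0.55, ..., 0.95.
#' @param recall_grid Recall levels of the interpolated AP; default the 101
#'   levels 0, 0.01, ..., 1 (computed as `(0:100)/100` so the grid values
#'   are exact binary fractions where possible).
#' @param histogram_bins Bin edges on `[0, 1]` for the CKS histogram;
#'   default ten equal bins.
#' @return An `"eval_config"` object.
#' @export
eval_config <- function(cks_thresholds = seq(0.5, 0.95, by = 0.05),
                        recall_grid = (0:100) / 100,
                        histogram_bins = (0:10) / 10) {
  if (length(cks_thresholds) < 1L || any(diff(cks_thresholds) <= 0))
    abort_validation("'cks_thresholds' must be strictly increasing")
  if (any(cks_thresholds < 0) || any(cks_thresholds > 1))
    abort_validation("'cks_thresholds' must lie in [0, 1]")
  if (any(diff(recall_grid) <= 0))
    abort_validation("'recall_grid' must be strictly increasing")
  if (any(diff(histogram_bins) <= 0) || histogram_bins[1] != 0 ||
      histogram_bins[length(histogram_bins)] != 1)
    abort_validation("'histogram_bins' must be increasing edges from 0 to 1")
  structure(list(cks_thresholds = as.numeric(cks_thresholds),
                 recall_grid = as.numeric(recall_grid),
                 histogram_bins = as.numeric(histogram_bins)),
            class = "eval_config")
}

# Pairwise CKS between every GT and predicted instance of one image.
# Rows index GT, columns index predictions. GT instances with no visible
# keypoint (CKS undefined) get NA rows and are flagged ineligible in the
# "eligible" attribute; they are excluded from matching and from the FN
# count, and diagnosed upstream.
cks_matrix <- function(gt_scene, pred_scene, schema) {
  ng <- length(gt_scene$instances)
  np <- length(pred_scene$instances)
  m <- matrix(NA_real_, ng, np)
  eligible <- logical(ng)
  for (i in seq_len(ng)) {
    g <- gt_scene$instances[[i]]
    eligible[i] <- sum(g$keypoints[, "v"]) > 0
    if (!eligible[i]) next
    a <- bbox_area(g$box)
    for (j in seq_len(np))
      m[i, j] <- cks(g, pred_scene$instances[[j]], area = a, schema = schema)
  }
  attr(m, "eligible") <- eligible
  m
}

# Greedy assignment on a precomputed CKS matrix. Predictions are taken in
# descending score order (ties by input order); each takes the unmatched GT
# with the highest CKS (ties by GT input order) and becomes a TP iff that
# CKS >= threshold. A prediction below threshold is an FP and does not
# consume a GT. With threshold = 0 every prediction that has any available
# GT is assigned (used for keypoint-level pairing).
greedy_match_matrix <- function(ckm, scores, threshold) {
  ng <- nrow(ckm); np <- ncol(ckm)
  eligible <- attr(ckm, "eligible") %||% rep(TRUE, ng)
  order_pred <- order(-scores)
  assigned_gt <- rep(NA_integer_, np)
  is_tp <- rep(FALSE, np)
  cks_val <- rep(NA_real_, np)
  gt_taken <- rep(FALSE, ng)
  for (j in order_pred) {
    cand <- which(!gt_taken & eligible)
    if (!length(cand)) next
    sims <- ckm[cand, j]
    best <- cand[which.max(sims)]
    best_sim <- ckm[best, j]
    cks_val[j] <- best_sim
    if (best_sim >= threshold) {
      assigned_gt[j] <- best
      is_tp[j] <- TRUE
      gt_taken[best] <- TRUE
    }
  }
  list(assigned_gt = assigned_gt, is_tp = is_tp, cks = cks_val,
       n_gt_eligible = sum(eligible), fn = sum(eligible) - sum(is_tp))
}

#' Match one image's predictions to its ground truth
#'
#' Greedy matching at one CKS threshold: predictions are processed in
#' descending score order; each is assigned the so-far-unmatched
#' ground-truth instance with the highest CKS and marked a true positive
#' iff that CKS reaches the threshold, otherwise it is a false positive and
#' consumes no ground truth. Ties in score are broken by prediction input
#' order, ties in CKS by ground-truth input order, so the result is
#' deterministic. Ground-truth instances left unmatched count as false
#' negatives. Ground-truth instances with no visible keypoint (CKS
#' undefined) are excluded from matching and reported in `n_gt_skipped`.
#'
#' @param gt A [scene_annotation()].
#' @param pred A [scene_prediction()] for the same image.
#' @param threshold CKS threshold in `[0, 1]`.
#' @param schema A [keypoint_schema()].
#' @return A list with `records` (data frame: one row per prediction with
#'   `image_id`, `score`, `cks`, `matched_gt`, `is_tp`), `n_gt`, `fn`, and
#'   `n_gt_skipped`.
#' @export
match_scene <- function(gt, pred, threshold,
                        schema = default_chicken_schema()) {
  if (as.character(gt$image_id) != as.character(pred$image_id))
    abort_validation("image ids disagree: %s vs %s",
                     format(gt$image_id), format(pred$image_id))
  ckm <- cks_matrix(gt, pred, schema)
  scores <- vapply(pred$instances, function(i) i$score, 0)
  m <- greedy_match_matrix(ckm, scores, threshold)
  n_skip <- length(gt$instances) - m$n_gt_eligible
  records <- data.frame(
    image_id = rep(as.character(gt$image_id), length(scores)),
    score = scores,
    cks = m$cks,
    matched_gt = m$assigned_gt,
    is_tp = m$is_tp,
    stringsAsFactors = FALSE)
  list(records = records, n_gt = m$n_gt_eligible, fn = m$fn,
       n_gt_skipped = n_skip)
}

#' Cumulative precision-recall points
#'
#' Pools the per-image match records of one CKS threshold, sorts by
#' descending score (ties by input order) and computes cumulative precision
#' `P = TP / (TP + FP)` and recall `R = TP / (TP + FN)` at every rank.
#' Recall is non-decreasing along the returned sequence.
#'
#' @param records Data frame of prediction records (from [match_scene()]),
#'   pooled over images: columns `score`, `is_tp`.
#' @param n_gt Total number of (eligible) ground-truth instances.
#' @return Data frame with columns `recall`, `precision` (one row per
#'   prediction rank); zero rows when there are no predictions.
#' @export
precision_recall_points <- function(records, n_gt) {
  if (n_gt <= 0)
    abort_undefined("precision/recall undefined with zero ground truth")
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(recall = numeric(), precision = numeric()))
  ord <- order(-records$score)
  tp <- cumsum(records$is_tp[ord])
  rank <- seq_along(ord)
  data.frame(recall = tp / n_gt, precision = tp / rank)
}

#' 101-point interpolated average precision
#'
#' \deqn{AP = \frac{1}{|G|} \sum_{r \in G} \max\{P(\tilde r): \tilde r \ge r\}}
#'
#' with grid \eqn{G} the 101 recall levels 0, 0.01, ..., 1 by default and
#' the maximum over an empty set taken as 0. This is the plain grid-maximum
#' rule — the best precision achieved at or beyond each recall level — with
#' no further smoothing.
#'
#' @param pr Data frame from [precision_recall_points()].
#' @param recall_grid Recall levels; default `(0:100)/100`.
#' @return AP in `[0, 1]`.
#' @export
#' @examples
#' average_precision(data.frame(recall = 0.5, precision = 1))  # 51/101
average_precision <- function(pr, recall_grid = (0:100) / 100) {
  if (is.null(pr) || nrow(pr) == 0L) return(0)
  best <- vapply(recall_grid, function(r) {
    sel <- pr$recall >= r
    if (any(sel)) max(pr$precision[sel]) else 0
  }, 0)
  mean(best)
}

#' Threshold-averaged summary metrics
#'
#' `mean_ap()` / `mean_ar()` are the unweighted means of the per-threshold
#' AP / AR over the configured CKS thresholds (ten by default).
#' `ar_at_threshold()` is the average recall at one threshold: the maximum
#' attainable recall when every prediction is admitted, i.e.
#' `TP / (TP + FN)` with no detection cap.
#'
#' @param ap_by_threshold,ar_by_threshold Named numeric vector of
#'   per-threshold values; names are the thresholds.
#' @param thresholds The thresholds that must all be present.
#' @return A scalar.
#' @export
mean_ap <- function(ap_by_threshold, thresholds = seq(0.5, 0.95, by = 0.05)) {
  check_thresholds(ap_by_threshold, thresholds)
  mean(ap_by_threshold)
}

#' @rdname mean_ap
#' @export
mean_ar <- function(ar_by_threshold, thresholds = seq(0.5, 0.95, by = 0.05)) {
  check_thresholds(ar_by_threshold, thresholds)
  mean(ar_by_threshold)
}

check_thresholds <- function(x, thresholds) {
  if (length(x) != length(thresholds))
    abort_validation("expected one value per threshold (%d), got %d",
                     length(thresholds), length(x))
  if (!is.null(names(x)) &&
      !isTRUE(all.equal(as.numeric(names(x)), thresholds)))
    abort_validation("values do not cover the configured thresholds")
  invisible(x)
}

#' @rdname mean_ap
#' @param records Pooled match records at one threshold (see
#'   [precision_recall_points()]).
#' @param n_gt Total eligible ground-truth instances.
#' @export
ar_at_threshold <- function(records, n_gt) {
  if (n_gt <= 0) abort_undefined("AR undefined with zero ground truth")
  if (is.null(records) || nrow(records) == 0L) return(0)
  sum(records$is_tp) / n_gt
}

#' CKS histogram
#'
#' Bins matched-instance CKS values into the given edges. Bins are
#' left-closed, right-open, except the last which is closed on both sides
#' so a similarity of exactly 1 is counted.
#'
#' @param values CKS values in `[0, 1]`.
#' @param bins Increasing bin edges from 0 to 1 (default ten equal bins).
#' @return Data frame with columns `lower`, `upper`, `count`; counts sum to
#'   `length(values)`.
#' @export
cks_histogram <- function(values, bins = (0:10) / 10) {
  if (any(values < 0 | values > 1))
    abort_validation("CKS values must lie in [0, 1]")
  k <- length(bins) - 1L
  counts <- integer(k)
  if (length(values)) {
    idx <- findInterval(values, bins, rightmost.closed = TRUE,
                        left.open = FALSE)
    idx[idx > k] <- k
    tab <- tabulate(idx, nbins = k)
    counts <- as.integer(tab)
  }
  data.frame(lower = bins[-length(bins)], upper = bins[-1], count = counts)
}

index_predictions <- function(predictions) {
  out <- list()
  for (p in predictions) {
    iid <- as.character(p$image_id)
    if (!is.null(out[[iid]]))
      abort_validation("duplicate prediction entry for image %s", iid)
    out[[iid]] <- p
  }
  out
}
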