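#' Evaluate predictions against ground truth
#'
#' Runs the full instance- and keypoint-level evaluation: greedy CKS
#' matching at each configured threshold, pooled precision/recall, the
#' 101-point interpolated AP and the maximum-recall AR per threshold, their
#' means over the ten thresholds (mAP, mAR), PCK, per-keypoint pixel error
#' and RMSE, and the histogram of matched-instance CKS values.
#'
#' Keypoint-level metrics (PCK, RMSE, pixel error) and the CKS histogram
#' use the threshold-free assignment of [collect_keypoint_pairs()]: every
#' prediction is paired with its best available ground truth so that
#' localisation error is measured for all assigned detections, not only
#' those above a similarity cut.
#'
#' @param scenes List of [scene_annotation()] (the ground truth).
#' @param predictions List of [scene_prediction()]. Every prediction image
#'   id must exist in `scenes`; images with no prediction entry contribute
#'   false negatives.
#' @param config An [eval_config()].
#' @param pck_cfg A [pck_config()].
#' @param schema A [keypoint_schema()].
#' @return A `"mcp_report"` list: `per_threshold` (data frame with
#'   `threshold`, `ap`, `ar`, `tp`, `fp`, `fn`), `map`, `mar`, `pck`,
#'   `rmse` (per-keypoint table with pooled attribute), `pe` (per-keypoint
#'   mean/median pixel error), `cks_values`, `cks_histogram`,
#'   `diagnostics`, and the configs used.
#' @export
evaluate <- function(scenes, predictions,
                     config = eval_config(),
                     pck_cfg = pck_config(),
                     schema = default_chicken_schema()) {
  if (!length(scenes)) abort_validation("no ground-truth scenes given")
  gt_ids <- vapply(scenes, function(s) as.character(s$image_id), "")
  if (anyDuplicated(gt_ids))
    abort_validation("duplicate ground-truth image id")
  pred_by_id <- index_predictions(predictions)
  unknown <- setdiff(names(pred_by_id), gt_ids)
  if (length(unknown))
    abort_validation("prediction for unknown image id: %s", unknown[1L])

  # CKS matrices are threshold-independent: compute once per image, then
  # re-run the greedy assignment at each threshold.
  empty_pred <- function(s) scene_prediction(s$image_id, list())
  per_image <- lapply(scenes, function(s) {
    pr <- pred_by_id[[as.character(s$image_id)]] %||% empty_pred(s)
    ckm <- cks_matrix(s, pr, schema)
    list(scene = s, pred = pr, ckm = ckm,
         scores = vapply(pr$instances, function(i) i$score, 0))
  })
  n_gt_total <- sum(vapply(per_image, function(x)
    sum(attr(x$ckm, "eligible")), 0))
  n_gt_skipped <- sum(vapply(per_image, function(x)
    sum(!attr(x$ckm, "eligible")), 0))
  if (n_gt_total == 0)
    abort_undefined("evaluation undefined: no eligible ground-truth instance")

  thresholds <- config$cks_thresholds
  ap <- ar <- tp <- fp <- fn <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    recs <- lapply(per_image, function(x) {
      m <- greedy_match_matrix(x$ckm, x$scores, thresholds[t])
      data.frame(score = x$scores, is_tp = m$is_tp)
    })
    pooled <- do.call(rbind, recs)
    ap[t] <- if (nrow(pooled)) {
      pr_pts <- precision_recall_points(pooled, n_gt_total)
      average_precision(pr_pts, config$recall_grid)
    } else 0
    ar[t] <- ar_at_threshold(pooled, n_gt_total)
    tp[t] <- sum(pooled$is_tp)
    fp[t] <- nrow(pooled) - tp[t]
    fn[t] <- n_gt_total - tp[t]
  }
  names(ap) <- names(ar) <- format(thresholds)

  pairs <- collect_keypoint_pairs(scenes, predictions, schema, pck_cfg)
  pck_value <- if (nrow(pairs)) pck(pairs, config = pck_cfg) else NA_real_
  rmse_tab <- rmse_per_keypoint(pairs, schema)
  pe_tab <- pe_summary(pairs, schema)

  cks_values <- unlist(lapply(per_image, function(x) {
    m <- greedy_match_matrix(x$ckm, x$scores, 0)
    m$cks[!is.na(m$assigned_gt)]
  })) %||% numeric()

  structure(list(
    per_threshold = data.frame(threshold = thresholds, ap = ap, ar = ar,
                               tp = tp, fp = fp, fn = fn, row.names = NULL),
    map = mean_ap(ap, thresholds),
    mar = mean_ar(ar, thresholds),
    pck = pck_value,
    rmse = rmse_tab,
    pe = pe_tab,
    cks_values = as.numeric(cks_values),
    cks_histogram = cks_histogram(as.numeric(cks_values),
                                  config$histogram_bins),
    diagnostics = list(
      n_images = length(scenes),
      n_gt = n_gt_total,
      n_gt_skipped_invisible = n_gt_skipped,
      n_predictions = sum(vapply(per_image, function(x)
        length(x$pred$instances), 0L)),
      n_pairs = nrow(pairs),
      n_pairs_dropped_pred_invisible = attr(pairs, "dropped_pred_invisible")),
    eval_config = config,
    pck_config = pck_cfg,
    schema = schema
  ), class = "mcp_report")
}

pe_summary <- function(pairs, schema) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(keypoint = character(), n = integer(),
                      mean_pe = numeric(), median_pe = numeric(),
                      stringsAsFactors = FALSE))
  pe <- pixel_error(cbind(pairs$gt_x, pairs$gt_y),
                    cbind(pairs$pred_x, pairs$pred_y))
  idx <- factor(pairs$keypoint_index, levels = seq_len(schema$n))
  mn <- tapply(pe, idx, mean)
  md <- tapply(pe, idx, stats::median)
  n <- tapply(pe, idx, length)
  keep <- !is.na(mn)
  data.frame(keypoint = schema$names[keep], n = as.integer(n[keep]),
             mean_pe = as.numeric(mn[keep]),
             median_pe = as.numeric(md[keep]), stringsAsFactors = FALSE)
}

#' @export
print.mcp_report <- function(x, ...) {
  cat("<mcp_report>\n")
  cat(sprintf("  images %d, GT instances %d, predictions %d\n",
              x$diagnostics$n_images, x$diagnostics$n_gt,
              x$diagnostics$n_predictions))
  cat(sprintf("  mAP %.3f  mAR %.3f  PCK %s\n", x$map, x$mar,
              ifelse(is.na(x$pck), "NA", sprintf("%.3f", x$pck))))
  pooled <- attr(x$rmse, "pooled")
  if (nrow(x$rmse))
    cat(sprintf("  RMSE: mean-of-keypoints %.2f px, pooled %.2f px\n",
                pooled[["mean_of_rmse"]], pooled[["pooled_rmse"]]))
  invisible(x)
}
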