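#' Chicken keypoint similarity (CKS)
#'
#' Gaussian-kernel similarity between a ground-truth and a predicted pose,
#' the chicken adaptation of COCO's object keypoint similarity (OKS):
#'
#' \deqn{CKS = \sum_i \exp\!\big(-d_i^2 / (2\,\alpha\,\beta_i^2)\big)\, v_i
#'       \;/\; \sum_i v_i}
#'
#' where \eqn{d_i} is the Euclidean distance between ground-truth and
#' predicted keypoint \eqn{i}, \eqn{\alpha} is the object scale (the
#' ground-truth bounding-box area in px^2), \eqn{\beta_i} the per-keypoint
#' normalisation factor from the schema, and \eqn{v_i \in \{0,1\}} the
#' ground-truth visibility. The result lies in `[0, 1]`: 1 means the
#' visible keypoints coincide exactly, values near 0 mean no similarity.
#'
#' Only ground-truth visibility gates a keypoint's inclusion; the
#' prediction's visibility flags are ignored here. Using the ground-truth
#' area (rather than the predicted box) keeps the similarity independent of
#' detector output, as in standard OKS practice.
#'
#' @param gt,pred [pose_instance()] objects over the same schema.
#' @param area Object scale \eqn{\alpha} in px^2; defaults to the area of
#'   the ground-truth box. Must be `> 0`.
#' @param schema A [keypoint_schema()].
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' sch <- default_chicken_schema()
#' kp <- cbind(x = seq(10, 100, 10), y = seq(10, 100, 10), v = 1)
#' gt <- pose_instance(bounding_box(0, 0, 100, 100), kp)
#' cks(gt, gt, schema = sch)  # 1
cks <- function(gt, pred, area = NULL, schema = default_chicken_schema()) {
  area <- area %||% bbox_area(gt$box)
  if (!is_scalar_number(area) || area <= 0)
    abort_validation("'area' must be a positive scalar (got %s)", format(area))
  g <- gt$keypoints
  p <- pred$keypoints
  if (nrow(g) != schema$n || nrow(p) != schema$n)
    abort_validation("instances do not conform to the %d-keypoint schema",
                     schema$n)
  v <- g[, "v"]
  if (sum(v) == 0)
    abort_undefined("CKS undefined: ground truth has no visible keypoint")
  d2 <- (g[, "x"] - p[, "x"])^2 + (g[, "y"] - p[, "y"])^2
  sum(exp(-d2 / (2 * area * schema$betas^2)) * v) / sum(v)
}

#' Pixel error
#'
#' Euclidean distance in pixels between a true and a predicted keypoint.
#' Vectorised over rows when given two-column matrices.
#'
#' @param gt,pred Length-2 vectors `(x, y)` or `n x 2` matrices.
#' @return Non-negative distance(s) in pixels.
#' @export
#' @examples
#' pixel_error(c(0, 0), c(3, 4))  # 5
pixel_error <- function(gt, pred) {
  g <- rbind(gt); p <- rbind(pred)
  if (ncol(g) != 2L || ncol(p) != 2L)
    abort_validation("pixel_error expects (x, y) coordinates")
  if (any(!is.finite(g)) || any(!is.finite(p)))
    abort_validation("pixel_error requires finite coordinates")
  d <- sqrt((g[, 1] - p[, 1])^2 + (g[, 2] - p[, 2])^2)
  if (length(d) == 1L) as.numeric(d) else d
}

#' Per-keypoint RMSE
#'
#' Root-mean-square pixel error per keypoint over a table of matched
#' keypoint pairs, plus two pooled summaries: the arithmetic mean of the
#' per-keypoint RMSEs and the pooled RMSE (root of the mean of all squared
#' errors). Both are reported because published per-keypoint tables do not
#' always state which aggregation their "average" row uses, and the two
#' differ whenever errors are heterogeneous across keypoints.
#'
#' @param pairs A matched-keypoint data frame as produced by
#'   [collect_keypoint_pairs()] (columns `keypoint_index`, `gt_x`, `gt_y`,
#'   `pred_x`, `pred_y`, ...).
#' @param schema A [keypoint_schema()].
#' @return A data frame with one row per keypoint that has at least one
#'   pair (columns `keypoint`, `n`, `rmse`); keypoints with no pairs are
#'   absent, not zero. The pooled summaries are attached as attribute
#'   `"pooled"` (named vector `mean_of_rmse`, `pooled_rmse`).
#' @export
rmse_per_keypoint <- function(pairs, schema = default_chicken_schema()) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- data.frame(keypoint = character(), n = integer(),
                      rmse = numeric(), stringsAsFactors = FALSE)
    attr(out, "pooled") <- c(mean_of_rmse = NA_real_, pooled_rmse = NA_real_)
    return(out)
  }
  pe2 <- (pairs$gt_x - pairs$pred_x)^2 + (pairs$gt_y - pairs$pred_y)^2
  idx <- factor(pairs$keypoint_index, levels = seq_len(schema$n))
  mse <- tapply(pe2, idx, mean)
  n <- tapply(pe2, idx, length)
  keep <- !is.na(mse)
  out <- data.frame(keypoint = schema$names[keep],
                    n = as.integer(n[keep]),
                    rmse = sqrt(as.numeric(mse[keep])),
                    stringsAsFactors = FALSE)
  attr(out, "pooled") <- c(mean_of_rmse = mean(out$rmse),
                           pooled_rmse = sqrt(mean(pe2)))
  out
}

#' PCK configuration
#'
#' PCK (percentage of correct keypoints) counts a keypoint correct when its
#' pixel error, normalised by a per-instance reference length, is strictly
#' below a threshold fraction `tau`. Chickens have no conventional analog
#' of the human head length used by PCKh, so the reference length is
#' configurable; the default is the ground-truth bounding-box diagonal with
#' `tau = 0.05`.
#'
#' @param normalizer One of `"bbox_diagonal"`, `"bbox_max_side"`,
#'   `"reference_segment"`.
#' @param tau Threshold fraction, `> 0`.
#' @param reference_pair Length-2 integer keypoint indices defining the
#'   reference segment (required when `normalizer = "reference_segment"`).
#' @return A `"pck_config"` object.
#' @export
pck_config <- function(normalizer = c("bbox_diagonal", "bbox_max_side",
                                      "reference_segment"),
                       tau = 0.05, reference_pair = NULL) {
  normalizer <- match.arg(normalizer)
  if (!is_scalar_number(tau) || tau <= 0)
    abort_validation("'tau' must be > 0")
  if (normalizer == "reference_segment" &&
      (is.null(reference_pair) || length(reference_pair) != 2L))
    abort_validation("'reference_segment' needs a length-2 'reference_pair'")
  structure(list(normalizer = normalizer, tau = as.numeric(tau),
                 reference_pair = reference_pair),
            class = "pck_config")
}

#' Percentage of correct keypoints (PCK)
#'
#' Fraction of matched keypoint pairs whose pixel error is strictly less
#' than `tau * normalizer`. The normaliser is per pair (it derives from the
#' pair's ground-truth instance, e.g. its box diagonal).
#'
#' @param pairs Matched-pair data frame (see [collect_keypoint_pairs()]).
#' @param normalizer Positive reference length(s) in px: a scalar or one
#'   value per pair. If `NULL`, the `normalizer` column of `pairs` is used.
#' @param config A [pck_config()].
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' pairs <- data.frame(keypoint_index = 1, gt_x = c(0, 0, 0), gt_y = 0,
#'                     pred_x = c(2, 6, 10), pred_y = 0)
#' pck(pairs, normalizer = 100, config = pck_config(tau = 0.05))  # 1/3
pck <- function(pairs, normalizer = NULL, config = pck_config()) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    abort_undefined("PCK undefined on an empty pair set")
  normalizer <- normalizer %||% pairs$normalizer
  if (is.null(normalizer))
    abort_validation("no normalizer given and 'pairs' has no normalizer column")
  if (length(normalizer) == 1L) normalizer <- rep(normalizer, nrow(pairs))
  if (length(normalizer) != nrow(pairs) || any(normalizer <= 0))
    abort_validation("'normalizer' must be positive, one value per pair")
  pe <- pixel_error(cbind(pairs$gt_x, pairs$gt_y),
                    cbind(pairs$pred_x, pairs$pred_y))
  mean(pe < config$tau * normalizer)
}

#' Collect matched keypoint pairs from a dataset
#'
#' Assigns predictions to ground-truth instances image by image (greedy,
#' best CKS first, no similarity threshold so that localisation error is
#' measured for every assigned detection) and emits one row per keypoint
#' that is visible in the ground truth *and* emitted by the prediction.
#' Pairs whose prediction flags the keypoint invisible are dropped and
#' counted in the `"dropped_pred_invisible"` attribute.
#'
#' @param scenes List of [scene_annotation()].
#' @param predictions List of [scene_prediction()].
#' @param schema A [keypoint_schema()].
#' @param pck_cfg A [pck_config()]; decides which per-instance reference
#'   length is stored in the `normalizer` column.
#' @return Data frame with columns `image_id`, `keypoint_index`, `keypoint`,
#'   `gt_x`, `gt_y`, `pred_x`, `pred_y`, `normalizer`.
#' @export
collect_keypoint_pairs <- function(scenes, predictions,
                                   schema = default_chicken_schema(),
                                   pck_cfg = pck_config()) {
  pred_by_id <- index_predictions(predictions)
  buf <- list()
  dropped <- 0L
  for (s in scenes) {
    pr <- pred_by_id[[as.character(s$image_id)]]
    if (is.null(pr) || !length(pr$instances) || !length(s$instances)) next
    m <- greedy_match_matrix(cks_matrix(s, pr, schema),
                             vapply(pr$instances, function(i) i$score, 0),
                             threshold = 0)
    for (j in seq_along(pr$instances)) {
      gi <- m$assigned_gt[j]
      if (is.na(gi)) next
      g <- s$instances[[gi]]$keypoints
      p <- pr$instances[[j]]$keypoints
      keep <- g[, "v"] > 0 & p[, "v"] > 0
      dropped <- dropped + sum(g[, "v"] > 0 & p[, "v"] == 0)
      if (!any(keep)) next
      k <- which(keep)
      buf[[length(buf) + 1L]] <- list(
        image_id = rep(as.character(s$image_id), length(k)),
        keypoint_index = k,
        gt_x = g[k, "x"], gt_y = g[k, "y"],
        pred_x = p[k, "x"], pred_y = p[k, "y"],
        normalizer = rep(instance_normalizer(s$instances[[gi]], pck_cfg),
                         length(k)))
    }
  }
  pull <- function(field, mode) {
    if (!length(buf)) return(vector(mode, 0))
    as.vector(unlist(lapply(buf, `[[`, field)))
  }
  ki <- pull("keypoint_index", "integer")
  out <- data.frame(
    image_id = pull("image_id", "character"),
    keypoint_index = as.integer(ki),
    keypoint = schema$names[ki],
    gt_x = pull("gt_x", "numeric"), gt_y = pull("gt_y", "numeric"),
    pred_x = pull("pred_x", "numeric"), pred_y = pull("pred_y", "numeric"),
    normalizer = pull("normalizer", "numeric"),
    stringsAsFactors = FALSE)
  attr(out, "dropped_pred_invisible") <- dropped
  out
}

instance_normalizer <- function(inst, pck_cfg) {
  switch(pck_cfg$normalizer,
    bbox_diagonal = bbox_diagonal(inst$box),
    bbox_max_side = max(inst$box$w, inst$box$h),
    reference_segment = {
      rp <- pck_cfg$reference_pair
      pixel_error(inst$keypoints[rp[1], c("x", "y")],
                  inst$keypoints[rp[2], c("x", "y")])
    })
}
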