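# Shared fixtures and independent brute-force oracles. The oracles are
# written as plain loops, deliberately sharing no code with the package
# internals they cross-check.

chicken <- default_chicken_schema()

# One pose instance with keypoints at given coordinates (all visible by
# default) inside a box that covers them.
make_instance <- function(xy, v = 1, box = NULL, score = 1,
                          schema = chicken) {
  xy <- rbind(xy)
  if (nrow(xy) == 1L) xy <- xy[rep(1, schema$n), , drop = FALSE]
  if (length(v) == 1L) v <- rep(v, schema$n)
  if (is.null(box)) {
    pad <- 5
    box <- bounding_box(min(xy[, 1]) - pad, min(xy[, 2]) - pad,
                        diff(range(xy[, 1])) + 2 * pad,
                        diff(range(xy[, 2])) + 2 * pad)
  }
  pose_instance(box, cbind(xy, v), score = score, schema = schema)
}

random_instance <- function(schema = chicken, width = 640, height = 640,
                            score = 1) {
  xy <- cbind(runif(schema$n, 50, width - 50),
              runif(schema$n, 50, height - 50))
  make_instance(xy, v = 1, score = score, schema = schema)
}

# Brute-force CKS: one keypoint at a time, scalar arithmetic only.
bf_cks <- function(gt, pred, area, schema = chicken) {
  num <- 0
  den <- 0
  for (i in seq_len(schema$n)) {
    v <- gt$keypoints[i, "v"]
    if (v == 0) next
    dx <- gt$keypoints[i, "x"] - pred$keypoints[i, "x"]
    dy <- gt$keypoints[i, "y"] - pred$keypoints[i, "y"]
    num <- num + exp(-(dx * dx + dy * dy) /
                       (2 * area * schema$betas[[i]]^2)) * v
    den <- den + v
  }
  num / den
}

# Brute-force greedy matching for one image at one threshold, tracing the
# stated rules step by step: descending score (input order on ties), best
# unmatched GT by CKS (GT input order on ties), TP iff CKS >= threshold.
bf_match_scene <- function(gt, pred, threshold, schema = chicken) {
  ng <- length(gt$instances)
  np <- length(pred$instances)
  scores <- if (np) sapply(pred$instances, function(i) i$score) else numeric()
  taken <- rep(FALSE, ng)
  is_tp <- rep(FALSE, np)
  for (j in order(-scores)) {
    best_i <- NA
    best_s <- -Inf
    for (i in seq_len(ng)) {
      if (taken[i]) next
      s <- bf_cks(gt$instances[[i]], pred$instances[[j]],
                  bbox_area(gt$instances[[i]]$box), schema)
      if (s > best_s) { best_s <- s; best_i <- i }
    }
    if (!is.na(best_i) && best_s >= threshold) {
      is_tp[j] <- TRUE
      taken[best_i] <- TRUE
    }
  }
  list(scores = scores, is_tp = is_tp, n_gt = ng)
}

# Brute-force 101-point AP from pooled records: double loop over the grid
# and the ranked predictions.
bf_ap <- function(scores, is_tp, n_gt, grid = (0:100) / 100) {
  if (!length(scores)) return(0)
  ord <- order(-scores)
  tp <- 0
  rec <- prec <- numeric(length(ord))
  for (r in seq_along(ord)) {
    tp <- tp + is_tp[ord[r]]
    rec[r] <- tp / n_gt
    prec[r] <- tp / r
  }
  total <- 0
  for (g in grid) {
    best <- 0
    for (r in seq_along(rec)) if (rec[r] >= g && prec[r] > best)
      best <- prec[r]
    total <- total + best
  }
  total / length(grid)
}

# Full dataset-level brute-force evaluation (mAP / mAR path only).
bf_evaluate <- function(scenes, predictions, thresholds = seq(0.5, 0.95, 0.05),
                        schema = chicken) {
  pred_by <- list()
  for (p in predictions) pred_by[[as.character(p$image_id)]] <- p
  ap <- ar <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    all_scores <- numeric(); all_tp <- logical(); n_gt <- 0
    for (s in scenes) {
      pr <- pred_by[[as.character(s$image_id)]]
      if (is.null(pr)) pr <- scene_prediction(s$image_id, list())
      m <- bf_match_scene(s, pr, thresholds[t], schema)
      all_scores <- c(all_scores, m$scores)
      all_tp <- c(all_tp, m$is_tp)
      n_gt <- n_gt + m$n_gt
    }
    ap[t] <- bf_ap(all_scores, all_tp, n_gt)
    ar[t] <- sum(all_tp) / n_gt
  }
  list(ap = ap, ar = ar, map = mean(ap), mar = mean(ar))
}

# A small random scene + prediction set for matcher stress tests.
random_scene_pair <- function(image_id, max_gt = 3, max_pred = 4,
                              schema = chicken) {
  ng <- sample.int(max_gt, 1)
  np <- sample.int(max_pred + 1, 1) - 1L
  gt <- lapply(seq_len(ng), function(i) random_instance(schema))
  scene <- scene_annotation(image_id, 640, 640, gt)
  preds <- lapply(seq_len(np), function(j) {
    base <- gt[[sample.int(ng, 1)]]
    kp <- base$keypoints
    kp[, c("x", "y")] <- kp[, c("x", "y")] +
      matrix(rnorm(2 * nrow(kp), 0, sample(c(1, 5, 30), 1)), ncol = 2)
    pose_instance(base$box, kp, score = round(runif(1, 0.1, 1), 2),
                  schema = schema)
  })
  list(scene = scene, pred = scene_prediction(image_id, preds))
}
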