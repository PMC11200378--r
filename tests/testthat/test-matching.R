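test_that("match_scene handles the basic TP/FP/FN cases", {
  gt_inst <- random_instance()
  scene <- scene_annotation(1, 640, 640, list(gt_inst))

  exact <- pose_instance(gt_inst$box, gt_inst$keypoints, score = 0.8)
  m <- match_scene(scene, scene_prediction(1, list(exact)), 0.95, chicken)
  expect_equal(sum(m$records$is_tp), 1L)
  expect_equal(m$fn, 0)

  none <- match_scene(scene_annotation(2, 640, 640,
                                       list(random_instance(),
                                            random_instance())),
                      scene_prediction(2, list()), 0.5, chicken)
  expect_equal(nrow(none$records), 0L)
  expect_equal(none$fn, 2)
})

test_that("greedy matching takes predictions in score order", {
  # one GT; the higher-score prediction is slightly off (CKS < 1), the
  # lower-score one exact (CKS = 1). Greedy still gives the GT to the
  # higher score; the exact one becomes FP.
  set.seed(6)
  gt_inst <- random_instance()
  scene <- scene_annotation(1, 640, 640, list(gt_inst))
  kp_off <- gt_inst$keypoints
  kp_off[, "x"] <- kp_off[, "x"] + 3
  off <- pose_instance(gt_inst$box, kp_off, score = 0.9)
  exact <- pose_instance(gt_inst$box, gt_inst$keypoints, score = 0.8)
  m <- match_scene(scene, scene_prediction(1, list(off, exact)), 0.5,
                   chicken)
  expect_true(m$records$is_tp[1])
  expect_false(m$records$is_tp[2])
  expect_lt(m$records$cks[1], 1)
})

test_that("duplicate detections of one GT yield exactly one TP", {
  set.seed(7)
  gt_inst <- random_instance()
  scene <- scene_annotation(1, 640, 640, list(gt_inst))
  dups <- lapply(c(0.9, 0.8, 0.7), function(s)
    pose_instance(gt_inst$box, gt_inst$keypoints, score = s))
  m <- match_scene(scene, scene_prediction(1, dups), 0.5, chicken)
  expect_equal(sum(m$records$is_tp), 1L)
  expect_equal(sum(!m$records$is_tp), 2L)
  expect_equal(m$fn, 0)
})

test_that("a sub-threshold prediction is FP and does not consume GT", {
  gt_inst <- random_instance()
  scene <- scene_annotation(1, 640, 640, list(gt_inst))
  kp_far <- gt_inst$keypoints
  kp_far[, c("x", "y")] <- kp_far[, c("x", "y")] + 500
  far <- pose_instance(gt_inst$box, kp_far, score = 0.99)
  exact <- pose_instance(gt_inst$box, gt_inst$keypoints, score = 0.5)
  m <- match_scene(scene, scene_prediction(1, list(far, exact)), 0.9,
                   chicken)
  # the far (higher-score) prediction fails the threshold, leaving the GT
  # available for the exact one
  expect_equal(m$records$is_tp, c(FALSE, TRUE))
})

test_that("precision/recall points follow the cumulative definitions", {
  one_tp <- data.frame(score = 0.9, is_tp = TRUE)
  expect_equal(precision_recall_points(one_tp, 1),
               data.frame(recall = 1, precision = 1))
  expect_equal(precision_recall_points(one_tp, 2),
               data.frame(recall = 0.5, precision = 1))
  tp_fp <- data.frame(score = c(0.9, 0.8), is_tp = c(TRUE, FALSE))
  expect_equal(precision_recall_points(tp_fp, 1),
               data.frame(recall = c(1, 1), precision = c(1, 0.5)))
  expect_error(precision_recall_points(one_tp, 0),
               class = "mcp_undefined_metric_error")
  set.seed(8)
  rand <- data.frame(score = runif(50), is_tp = runif(50) > 0.5)
  pr <- precision_recall_points(rand, 30)
  expect_true(all(diff(pr$recall) >= 0))
})

test_that("average precision follows the 101-point grid-max rule", {
  expect_equal(average_precision(data.frame(recall = 1, precision = 1)), 1)
  expect_equal(average_precision(data.frame(recall = 0.5, precision = 1)),
               51 / 101)
  expect_equal(average_precision(data.frame(recall = numeric(),
                                            precision = numeric())), 0)
  # matches the explicit double-loop oracle on a random curve
  set.seed(9)
  rand <- data.frame(score = runif(40), is_tp = runif(40) > 0.4)
  pr <- precision_recall_points(rand, 25)
  expect_equal(average_precision(pr),
               bf_ap(rand$score, rand$is_tp, 25), tolerance = 1e-12)
})

test_that("mAP and mAR are unweighted means over the ten thresholds", {
  thr <- seq(0.5, 0.95, by = 0.05)
  aps <- c(rep(1, 5), rep(0, 5))
  expect_equal(mean_ap(aps, thr), 0.5)
  expect_equal(mean_ar(rep(0.3, 10), thr), 0.3)
  expect_error(mean_ap(aps[1:9], thr), class = "mcp_validation_error")
  expect_equal(ar_at_threshold(data.frame(score = 1, is_tp = FALSE), 4), 0)
  expect_error(ar_at_threshold(data.frame(), 0),
               class = "mcp_undefined_metric_error")
})

test_that("the CKS histogram bins correctly at the edges", {
  h <- cks_histogram(c(1, 1, 0.5))
  expect_equal(h$count[10], 2L)  # 1.0 falls in the right-closed last bin
  expect_equal(h$count[6], 1L)   # 0.5 in [0.5, 0.6)
  expect_equal(sum(cks_histogram(numeric())$count), 0L)
  set.seed(10)
  expect_equal(sum(cks_histogram(runif(1000))$count), 1000L)
  expect_error(cks_histogram(c(0.5, 1.2)), class = "mcp_validation_error")
})

test_that("TP+FP and TP+FN identities hold on random scenes", {
  set.seed(11)
  for (rep in 1:25) {
    sp <- random_scene_pair(rep)
    for (thr in c(0.5, 0.75, 0.95)) {
      m <- match_scene(sp$scene, sp$pred, thr, chicken)
      tp <- sum(m$records$is_tp)
      expect_equal(tp + sum(!m$records$is_tp), length(sp$pred$instances))
      expect_equal(tp + m$fn, length(sp$scene$instances))
    }
  }
})

test_that("eval_config validates thresholds, grid and bins", {
  expect_error(eval_config(cks_thresholds = c(0.5, 0.5)),
               class = "mcp_validation_error")
  expect_error(eval_config(cks_thresholds = c(0.5, 1.5)),
               class = "mcp_validation_error")
  expect_error(eval_config(histogram_bins = c(0.1, 0.5, 1)),
               class = "mcp_validation_error")
  cfg <- eval_config()
  expect_equal(cfg$cks_thresholds, seq(0.5, 0.95, by = 0.05))
  expect_length(cfg$recall_grid, 101L)
})
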