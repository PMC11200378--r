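test_that("identical poses have similarity exactly 1", {
  set.seed(1)
  for (rep in 1:5) {
    inst <- random_instance()
    expect_identical(cks(inst, inst, schema = chicken), 1)
    expect_identical(cks(inst, inst, area = 12345, schema = chicken), 1)
  }
})

test_that("cks reproduces scalar hand evaluations", {
  base <- cbind(seq(10, 100, 10), seq(10, 100, 10))
  # single visible beak, area 10000, displacement (3, 4):
  # 25 / (2 * 10000 * 0.025^2) = 2, so similarity is exp(-2)
  v <- rep(0, 10); v[10] <- 1
  gt <- make_instance(base, v = v)
  moved <- base; moved[10, ] <- moved[10, ] + c(3, 4)
  pred <- make_instance(moved, v = v)
  expect_equal(cks(gt, pred, area = 10000, schema = chicken), exp(-2),
               tolerance = 1e-12)

  # beak exact and body_center displaced (3, 4):
  # (1 + exp(-25 / (2 * 10000 * 0.107^2))) / 2
  v2 <- rep(0, 10); v2[c(1, 10)] <- 1
  gt2 <- make_instance(base, v = v2)
  moved2 <- base; moved2[1, ] <- moved2[1, ] + c(3, 4)
  pred2 <- make_instance(moved2, v = v2)
  expected <- (1 + exp(-25 / (2 * 10000 * 0.107^2))) / 2
  expect_equal(cks(gt2, pred2, area = 10000, schema = chicken), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.9483, tolerance = 1e-4)
})

test_that("cks rejects degenerate input", {
  inst <- random_instance()
  expect_error(cks(inst, inst, area = 0, schema = chicken),
               class = "mcp_validation_error")
  blind <- make_instance(cbind(100, 100), v = 0)
  expect_error(cks(blind, blind, area = 100, schema = chicken),
               class = "mcp_undefined_metric_error")
})

test_that("cks is translation invariant and decreasing in displacement", {
  set.seed(2)
  for (rep in 1:20) {
    gt <- random_instance()
    pred <- random_instance()
    s0 <- cks(gt, pred, area = 5000, schema = chicken)
    shift <- runif(2, -200, 200)
    shift_inst <- function(inst) {
      kp <- inst$keypoints
      kp[, "x"] <- kp[, "x"] + shift[1]
      kp[, "y"] <- kp[, "y"] + shift[2]
      pose_instance(inst$box, kp, inst$score)
    }
    expect_equal(cks(shift_inst(gt), shift_inst(pred), area = 5000,
                     schema = chicken), s0, tolerance = 1e-12)
  }
  # one keypoint pushed progressively further: similarity strictly drops
  gt <- random_instance()
  sims <- sapply(c(0, 2, 5, 10, 25), function(d) {
    kp <- gt$keypoints
    kp[4, "x"] <- kp[4, "x"] + d
    cks(gt, pose_instance(gt$box, kp), area = 5000, schema = chicken)
  })
  expect_true(all(diff(sims) < 0))
})

test_that("cks agrees with the brute-force per-point oracle", {
  set.seed(3)
  for (rep in 1:200) {
    gt <- random_instance()
    v <- as.numeric(runif(10) > 0.3)
    if (sum(v) == 0) v[1] <- 1
    kp <- gt$keypoints; kp[, "v"] <- v
    gt <- pose_instance(gt$box, kp)
    pred <- random_instance()
    area <- runif(1, 100, 50000)
    expect_equal(cks(gt, pred, area = area, schema = chicken),
                 unname(bf_cks(gt, pred, area, chicken)),
                 tolerance = 1e-13)
  }
})

test_that("pixel error satisfies metric identities", {
  expect_identical(pixel_error(c(0, 0), c(3, 4)), 5)
  expect_identical(pixel_error(c(2, 7), c(2, 7)), 0)
  expect_identical(pixel_error(c(1, 1), c(4, 5)), 5)
  set.seed(4)
  a <- runif(2, 0, 100); b <- runif(2, 0, 100); c <- runif(2, 0, 100)
  expect_equal(pixel_error(a, b), pixel_error(b, a))
  expect_lte(pixel_error(a, c), pixel_error(a, b) + pixel_error(b, c))
  expect_error(pixel_error(c(Inf, 0), c(0, 0)),
               class = "mcp_validation_error")
})

test_that("per-keypoint RMSE matches hand computations", {
  one <- data.frame(keypoint_index = 10, gt_x = 0, gt_y = 0,
                    pred_x = 3, pred_y = 4)
  tab <- rmse_per_keypoint(one, chicken)
  expect_equal(tab$rmse, 5)
  expect_equal(tab$keypoint, "beak")

  two <- data.frame(keypoint_index = c(1, 1), gt_x = 0, gt_y = 0,
                    pred_x = c(3, 0), pred_y = c(0, 4))
  expect_equal(rmse_per_keypoint(two, chicken)$rmse,
               sqrt((9 + 16) / 2), tolerance = 1e-12)

  exact <- data.frame(keypoint_index = 1:10, gt_x = 1:10, gt_y = 1,
                      pred_x = 1:10, pred_y = 1)
  expect_true(all(rmse_per_keypoint(exact, chicken)$rmse == 0))

  # keypoints with no pairs are absent, not zero
  expect_equal(nrow(rmse_per_keypoint(one, chicken)), 1L)
  empty <- rmse_per_keypoint(one[0, ], chicken)
  expect_equal(nrow(empty), 0L)
  expect_true(all(is.na(attr(empty, "pooled"))))
})

test_that("PCK counts strict threshold crossings and is monotone in tau", {
  pairs <- data.frame(keypoint_index = 1, gt_x = 0, gt_y = 0,
                      pred_x = c(2, 6, 10), pred_y = 0)
  expect_equal(pck(pairs, normalizer = 100, config = pck_config(tau = 0.05)),
               1 / 3)
  # strict "<": a distance exactly at the threshold does not count
  at <- data.frame(keypoint_index = 1, gt_x = 0, gt_y = 0,
                   pred_x = 5, pred_y = 0)
  expect_equal(pck(at, normalizer = 100, config = pck_config(tau = 0.05)), 0)

  zero <- data.frame(keypoint_index = 1, gt_x = 1:3, gt_y = 1,
                     pred_x = 1:3, pred_y = 1)
  expect_equal(pck(zero, normalizer = 10, config = pck_config(tau = 0.01)), 1)
  far <- data.frame(keypoint_index = 1, gt_x = 0, gt_y = 0,
                    pred_x = 50, pred_y = 0)
  expect_equal(pck(far, normalizer = 10, config = pck_config(tau = 0.05)), 0)

  set.seed(5)
  many <- data.frame(keypoint_index = 1, gt_x = 0, gt_y = 0,
                     pred_x = rnorm(200, 0, 10), pred_y = rnorm(200, 0, 10))
  taus <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  vals <- sapply(taus, function(t)
    pck(many, normalizer = 100, config = pck_config(tau = t)))
  expect_true(all(diff(vals) >= 0))

  expect_error(pck(many[0, ], normalizer = 100),
               class = "mcp_undefined_metric_error")
})

test_that("pck_config validates its inputs", {
  expect_error(pck_config(tau = 0), class = "mcp_validation_error")
  expect_error(pck_config(normalizer = "reference_segment"),
               class = "mcp_validation_error")
  cfg <- pck_config(normalizer = "reference_segment", tau = 0.2,
                    reference_pair = c(1L, 2L))
  expect_equal(cfg$reference_pair, c(1L, 2L))
})
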