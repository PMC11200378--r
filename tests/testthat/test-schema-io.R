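test_that("default chicken schema has the canonical 10 keypoints and betas", {
  sch <- default_chicken_schema()
  expect_equal(sch$n, 10L)
  expect_setequal(sch$names,
                  c("body_center", "body_tail", "body_knee_left",
                    "body_knee_right", "body_heel_left", "body_heel_right",
                    "eye_left", "eye_right", "comb", "beak"))
  expect_equal(unname(sch$betas[["body_center"]]), 0.107)
  expect_true(all(sch$betas[setdiff(sch$names, "body_center")] == 0.025))
  heel <- c(match("body_heel_left", sch$names),
            match("body_heel_right", sch$names))
  expect_true(any(vapply(sch$lr_pairs, identical, TRUE, heel)))
  for (e in sch$skeleton)
    expect_true(all(e >= 1 & e <= sch$n))
})

test_that("schema validation rejects bad betas, duplicates and bad indices", {
  expect_error(keypoint_schema(c("a", "b"), betas = c(0.1, 0)),
               class = "mcp_validation_error")
  expect_error(keypoint_schema(c("a", "b"), betas = -0.1),
               class = "mcp_validation_error")
  expect_error(keypoint_schema(c("a", "a")), class = "mcp_validation_error")
  expect_error(keypoint_schema(c("a", "b"), lr_pairs = list(c(1L, 3L))),
               class = "mcp_validation_error")
  expect_error(keypoint_schema(c("a", "b", "c", "d"),
                               lr_pairs = list(c(1L, 2L), c(2L, 3L))),
               class = "mcp_validation_error")
})

test_that("visibility normalization collapses COCO codes and is idempotent", {
  v <- c(0, 1, 2, 2, 0)
  once <- normalize_visibility(v)
  expect_equal(once, c(0, 1, 1, 1, 0))
  expect_equal(normalize_visibility(once), once)
  expect_error(normalize_visibility(c(0, 3)), class = "mcp_validation_error")
})

test_that("instance and scene invariants are enforced", {
  expect_error(bounding_box(0, 0, 0, 5), class = "mcp_validation_error")
  expect_error(bounding_box(0, 0, 5, -1), class = "mcp_validation_error")
  expect_equal(bbox_area(bounding_box(1, 2, 10, 20)), 200)
  inst <- random_instance()
  expect_error(pose_instance(inst$box, inst$keypoints, score = 1.2),
               class = "mcp_validation_error")
  expect_error(pose_instance(inst$box, inst$keypoints[1:3, ],
                             schema = chicken),
               class = "mcp_validation_error")
  # visible keypoint outside the image is rejected
  kp <- inst$keypoints
  kp[1, "x"] <- 10000
  bad <- pose_instance(inst$box, kp)
  expect_error(scene_annotation(1, 640, 640, list(bad)),
               class = "mcp_validation_error")
})

test_that("annotation files round trip structurally", {
  set.seed(42)
  ds <- generate_dataset(synth_config(n_images = 6, seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ds$scenes, chicken, path)
  back <- read_annotations(path)
  expect_equal(back$scenes, ds$scenes)
  expect_equal(back$schema$betas, chicken$betas)
  expect_equal(back$schema$lr_pairs, chicken$lr_pairs)
  # byte-stable for fixed input
  path2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(ds$scenes, chicken, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("prediction files round trip, including scores at full precision", {
  set.seed(43)
  ds <- generate_dataset(synth_config(n_images = 8, seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_predictions(ds$predictions, path)
  back <- read_predictions(path, chicken)
  expect_equal(back, ds$predictions)

  one <- scene_prediction(5, list(make_instance(cbind(100, 100),
                                                score = 0.9)))
  write_predictions(list(one), path)
  expect_identical(read_predictions(path, chicken)[[1]]$instances[[1]]$score,
                   0.9)
})

test_that("empty prediction list writes an empty JSON array", {
  path <- withr::local_tempfile(fileext = ".json")
  write_predictions(list(), path)
  expect_identical(readLines(path), "[]")
  expect_equal(read_predictions(path, chicken), list())
})

test_that("malformed annotation input is rejected with classed errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(read_annotations(path), class = "mcp_io_error")

  # keypoint array of length 27 under a 10-point schema
  doc <- list(
    images = list(list(id = 1, width = 100, height = 100)),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            bbox = c(0, 0, 50, 50),
                            keypoints = rep(1, 27))),
    categories = list(list(id = 1, name = "chicken",
                           keypoints = as.list(chicken$names))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_error(read_annotations(path), class = "mcp_validation_error")

  doc$annotations[[1]]$keypoints <- rep(1, 30)
  doc$annotations[[1]]$image_id <- 99  # no such image
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_error(read_annotations(path), class = "mcp_validation_error")

  expect_error(write_annotations(list(1), chicken, path),
               class = "mcp_validation_error")
  expect_error(read_annotations(tempfile()), class = "mcp_io_error")
})

test_that("out-of-range prediction scores are rejected on read", {
  rec <- list(list(image_id = 1, category_id = 1,
                   bbox = c(0, 0, 10, 10),
                   keypoints = rep(c(1, 1, 1), 10), score = 1.5))
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), path)
  expect_error(read_predictions(path, chicken),
               class = "mcp_validation_error")
})
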