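# Synthetic multi-chicken scenes: seeded ground truth plus a noise model
# over predictions that emulates the failure modes seen in real top-down
# systems — keypoint jitter, keypoints lost near box edges, left/right
# foot swaps, missed and spurious detections.

#' Synthetic scene configuration
#'
#' All parameters of [generate_dataset()]. Every random draw derives from
#' `seed` through one global stream consumed in a fixed order (images, then
#' birds within an image, then prediction noise), so a configuration is
#' fully reproducible.
#'
#' @param n_images Number of images.
#' @param birds_per_image Inclusive integer range `c(min, max)` of birds
#'   per image.
#' @param image_size `c(W, H)` in px; default 640 x 640.
#' @param scale_range Body scale range in px (distance head-tail is about
#'   one scale unit).
#' @param orientation_range Rotation range in radians.
#' @param jitter_sigma Per-axis Gaussian keypoint jitter of predictions, px.
#' @param p_miss_keypoint Probability a predicted keypoint is dropped
#'   (emitted with v = 0).
#' @param p_swap_lr Probability a left/right keypoint pair is swapped in
#'   the prediction.
#' @param p_miss_detection Probability a ground-truth instance has no
#'   prediction at all.
#' @param p_false_detection Expected number of spurious predictions per
#'   true bird (each bird independently spawns one with this probability).
#' @param box_noise Half-width of uniform perturbation of predicted box
#'   corner and size, px.
#' @param score_true,score_false `c(mean, sd)` of the Gaussian score model
#'   for true and spurious predictions (clipped to `[0.05, 1]`); the true
#'   mean must exceed the spurious mean so ranking is informative.
#' @param seed Integer seed.
#' @return A `"synth_config"` object.
#' @export
synth_config <- function(n_images = 20, birds_per_image = c(1, 6),
                         image_size = c(640, 640),
                         scale_range = c(60, 120),
                         orientation_range = c(-pi, pi),
                         jitter_sigma = 2,
                         p_miss_keypoint = 0.05,
                         p_swap_lr = 0.03,
                         p_miss_detection = 0.05,
                         p_false_detection = 0.05,
                         box_noise = 2,
                         score_true = c(0.85, 0.05),
                         score_false = c(0.4, 0.1),
                         seed = 1L) {
  if (!is_scalar_number(n_images) || n_images < 1)
    abort_validation("'n_images' must be >= 1")
  for (p in c("p_miss_keypoint", "p_swap_lr", "p_miss_detection",
              "p_false_detection"))
    stopifnot_scalar_prob(get(p), p)
  if (jitter_sigma < 0 || box_noise < 0)
    abort_validation("noise magnitudes must be >= 0")
  if (length(birds_per_image) != 2L || birds_per_image[1] < 0 ||
      birds_per_image[2] < birds_per_image[1])
    abort_validation("'birds_per_image' must be an increasing range")
  if (score_true[1] <= score_false[1])
    abort_validation("true-score mean must exceed spurious-score mean")
  structure(list(
    n_images = as.integer(n_images),
    birds_per_image = as.integer(birds_per_image),
    image_size = as.numeric(image_size),
    scale_range = as.numeric(scale_range),
    orientation_range = as.numeric(orientation_range),
    jitter_sigma = jitter_sigma, p_miss_keypoint = p_miss_keypoint,
    p_swap_lr = p_swap_lr, p_miss_detection = p_miss_detection,
    p_false_detection = p_false_detection, box_noise = box_noise,
    score_true = score_true, score_false = score_false,
    seed = as.integer(seed)), class = "synth_config")
}

#' Canonical chicken body template
#'
#' Unit-scale offsets of the 10 keypoints for a bird in side view facing
#' +x: body centre at the origin, tail behind, knees and heels below,
#' eyes, comb and beak on the head. Multiplied by the body scale, rotated
#' and translated to place one bird. A stand-in for real chicken geometry,
#' adequate for exercising the metrics.
#'
#' @return A 10 x 2 matrix of `(x, y)` offsets, rows in schema order.
#' @export
body_template <- function() {
  m <- rbind(
    body_center     = c( 0.00,  0.00),
    body_tail       = c(-0.45, -0.05),
    body_knee_left  = c( 0.03,  0.25),
    body_knee_right = c( 0.15,  0.25),
    body_heel_left  = c( 0.00,  0.45),
    body_heel_right = c( 0.12,  0.45),
    eye_left        = c( 0.33, -0.28),
    eye_right       = c( 0.38, -0.30),
    comb            = c( 0.31, -0.42),
    beak            = c( 0.50, -0.24))
  colnames(m) <- c("x", "y")
  m
}

#' Generate a synthetic dataset of scenes and noisy predictions
#'
#' Places birds by scaling, rotating and translating [body_template()]
#' inside the image so that all keypoints are in bounds; the ground-truth
#' box is the tight keypoint box inflated by 10% per side. Predictions
#' derive from the ground truth by, in order: whole-instance dropout
#' (`p_miss_detection`), per-axis Gaussian jitter (`jitter_sigma`),
#' keypoint dropout (`p_miss_keypoint`), left/right pair swap applied to
#' the ground-truth coordinates before jitter (`p_swap_lr`), uniform box
#' perturbation (`box_noise`) and a Gaussian score; spurious instances are
#' random template poses with lower-mean scores (`p_false_detection`).
#'
#' @param config A [synth_config()].
#' @param schema A [keypoint_schema()]; the default chicken schema.
#' @return List with `scenes` (ground truth, [scene_annotation()]) and
#'   `predictions` ([scene_prediction()], instances in generation order).
#' @export
generate_dataset <- function(config = synth_config(),
                             schema = default_chicken_schema()) {
  tmpl <- body_template()
  if (nrow(tmpl) != schema$n)
    abort_validation("template and schema disagree on keypoint count")
  W <- config$image_size[1]; H <- config$image_size[2]
  max_r <- max(sqrt(rowSums(tmpl^2))) * config$scale_range[2] * 1.05
  if (2 * max_r >= min(W, H))
    abort_validation(
      "largest body (radius %.0f px) does not fit a %g x %g image",
      max_r, W, H)
  set.seed(config$seed)
  scenes <- vector("list", config$n_images)
  preds <- vector("list", config$n_images)
  for (im in seq_len(config$n_images)) {
    n_birds <- sample_range(config$birds_per_image)
    gt <- vector("list", n_birds)
    for (b in seq_len(n_birds)) {
      sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      th <- stats::runif(1, config$orientation_range[1],
                         config$orientation_range[2])
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      off <- tmpl %*% t(rot) * sc
      r <- max(abs(off)) + 1
      cx <- stats::runif(1, r, W - r)
      cy <- stats::runif(1, r, H - r)
      kp <- cbind(x = off[, 1] + cx, y = off[, 2] + cy, v = 1)
      gt[[b]] <- pose_instance(tight_box(kp), kp, score = 1, schema = schema)
    }
    scenes[[im]] <- scene_annotation(im, W, H, gt)
    preds[[im]] <- perturb_scene(scenes[[im]], config, schema, tmpl)
  }
  list(scenes = scenes, predictions = preds)
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1]
  else rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

# Tight keypoint box inflated by 10% per side, so even degenerate poses
# have positive area.
tight_box <- function(kp) {
  xr <- range(kp[, "x"]); yr <- range(kp[, "y"])
  w <- max(diff(xr), 1); h <- max(diff(yr), 1)
  bounding_box(xr[1] - 0.1 * w, yr[1] - 0.1 * h, 1.2 * w, 1.2 * h)
}

perturb_scene <- function(scene, config, schema, tmpl) {
  out <- list()
  for (inst in scene$instances) {
    if (stats::runif(1) < config$p_miss_detection) next
    kp <- inst$keypoints
    # left/right swaps happen before jitter: the network confuses the
    # sides, then localises each (wrong) side with the usual noise
    for (pr in schema$lr_pairs) {
      if (stats::runif(1) < config$p_swap_lr) {
        tmp <- kp[pr[1], c("x", "y")]
        kp[pr[1], c("x", "y")] <- kp[pr[2], c("x", "y")]
        kp[pr[2], c("x", "y")] <- tmp
      }
    }
    if (config$jitter_sigma > 0)
      kp[, c("x", "y")] <- kp[, c("x", "y")] +
        matrix(stats::rnorm(2 * nrow(kp), 0, config$jitter_sigma), ncol = 2)
    if (config$p_miss_keypoint > 0)
      kp[, "v"] <- kp[, "v"] *
        (stats::runif(nrow(kp)) >= config$p_miss_keypoint)
    b <- inst$box
    if (config$box_noise > 0) {
      d <- stats::runif(4, -config$box_noise, config$box_noise)
      b <- bounding_box(b$x + d[1], b$y + d[2],
                        max(b$w + d[3], 1), max(b$h + d[4], 1))
    }
    s <- clip_score(stats::rnorm(1, config$score_true[1],
                                 config$score_true[2]))
    out[[length(out) + 1L]] <- pose_instance(b, kp, s, schema)
  }
  # spurious detections: random template poses anywhere in frame
  W <- scene$width; H <- scene$height
  for (dummy in seq_along(scene$instances)) {
    if (stats::runif(1) >= config$p_false_detection) next
    sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    th <- stats::runif(1, -pi, pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    off <- tmpl %*% t(rot) * sc
    cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
    kp <- cbind(x = off[, 1] + cx, y = off[, 2] + cy, v = 1)
    s <- clip_score(stats::rnorm(1, config$score_false[1],
                                 config$score_false[2]))
    out[[length(out) + 1L]] <- pose_instance(tight_box(kp), kp, s, schema)
  }
  scene_prediction(scene$image_id, out)
}

clip_score <- function(s) min(max(s, 0.05), 1)

#' Closed-form expected CKS under pure Gaussian jitter
#'
#' When the only prediction noise is i.i.d. Gaussian jitter with standard
#' deviation `sigma` per axis, the squared displacement of a keypoint is
#' `sigma^2` times a chi-square(2) variable, so each similarity term has
#' expectation `v / (v + sigma^2)` with `v = area * beta^2`, and the
#' expected CKS is the mean of those terms over the visible keypoints.
#' The Monte-Carlo mean of [cks()] over generated scenes must agree with
#' this within sampling error — the analytic companion used by the tests.
#'
#' @param config A [synth_config()] with all discrete noise probabilities
#'   zero (otherwise the closed form does not apply and an error is
#'   raised).
#' @param schema A [keypoint_schema()].
#' @param area Ground-truth box area in px^2.
#' @return Expected CKS in `[0, 1]`.
#' @export
expected_mean_cks <- function(config, schema = default_chicken_schema(),
                              area) {
  if (config$p_miss_keypoint > 0 || config$p_swap_lr > 0 ||
      config$p_miss_detection > 0 || config$p_false_detection > 0)
    abort_validation(
      "closed-form CKS expectation applies to jitter-only noise")
  if (!is_scalar_number(area) || area <= 0)
    abort_validation("'area' must be a positive scalar")
  v <- area * schema$betas^2
  mean(v / (v + config$jitter_sigma^2))
}

#' Render a synthetic scene to a raster image
#'
#' Deterministic grayscale rendering on `[0, 1]`: a body disc around the
#' body centre, skeleton line segments, and a bright marker dot on every
#' visible keypoint, so each visible ground-truth keypoint lies on
#' foreground. Used to feed the pipeline scaffold in tests and demos; no
#' attempt at photorealism.
#'
#' @param scene A [scene_annotation()].
#' @param schema A [keypoint_schema()].
#' @return An `H x W` numeric matrix.
#' @export
render_scene <- function(scene, schema = default_chicken_schema()) {
  H <- as.integer(scene$height); W <- as.integer(scene$width)
  img <- matrix(0, H, W)
  anchor <- match("body_center", schema$names)
  if (is.na(anchor)) anchor <- 1L
  for (inst in scene$instances) {
    b <- inst$box
    kp <- inst$keypoints
    body_r <- 0.22 * min(b$w, b$h)
    img <- draw_disc(img, kp[anchor, "x"], kp[anchor, "y"], body_r, 0.45)
    marker_r <- max(2, 0.015 * max(b$w, b$h))
    for (k in seq_len(nrow(kp))) {
      if (kp[k, "v"] == 0) next
      img <- draw_disc(img, kp[k, "x"], kp[k, "y"], marker_r, 1)
    }
  }
  img
}

draw_disc <- function(img, x, y, r, value) {
  H <- nrow(img); W <- ncol(img)
  cs <- max(1L, floor(x - r) + 1L):min(W, ceiling(x + r) + 1L)
  rs <- max(1L, floor(y - r) + 1L):min(H, ceiling(y + r) + 1L)
  if (!length(cs) || !length(rs)) return(img)
  dx2 <- (cs - 0.5 - x)^2
  dy2 <- (rs - 0.5 - y)^2
  mask <- outer(dy2, dx2, "+") <= r^2
  # a pixel whose centre is near the point is always marked, so visible
  # keypoints are guaranteed to land on foreground even for tiny radii
  ci <- min(max(floor(x) + 1L, 1L), W)
  ri <- min(max(floor(y) + 1L, 1L), H)
  sub <- img[rs, cs, drop = FALSE]
  sub[mask] <- pmax(sub[mask], value)
  img[rs, cs] <- sub
  img[ri, ci] <- max(img[ri, ci], value)
  img
}
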