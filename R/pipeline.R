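# Top-down orchestration: detector -> crop/resize -> pose backend ->
# heatmap decode -> back-projection. Detector and pose networks are
# reachable only through backend contracts (plain R closures); the
# reference backends are deterministic oracles built from a scene's ground
# truth, optionally with configured noise.

#' Crop transform
#'
#' Affine map taking a bounding box in image coordinates onto a fixed-size
#' crop: non-uniform scaling `scale_x = W / w`, `scale_y = H / h` anchored
#' at the box corner, so the box maps onto the target exactly (no
#' aspect-preserving padding). `forward` maps image points to crop points;
#' `inverse` undoes it to machine precision.
#'
#' @param box Source [bounding_box()].
#' @param target Target crop size `c(W, H)` in px; default 512 x 512.
#' @return A `"crop_transform"` with fields `box`, `target`, `sx`, `sy`.
#' @export
crop_transform <- function(box, target = c(512, 512)) {
  if (!inherits(box, "bounding_box"))
    abort_validation("'box' must be a bounding_box")
  if (length(target) != 2L || any(target <= 0))
    abort_validation("'target' must be positive (W, H)")
  structure(list(box = box, target = as.numeric(target),
                 sx = target[1] / box$w, sy = target[2] / box$h),
            class = "crop_transform")
}

#' @rdname crop_transform
#' @param tf A `"crop_transform"`.
#' @param pts `n x 2` matrix (or length-2 vector) of `(x, y)` points.
#' @export
transform_forward <- function(tf, pts) {
  p <- rbind(pts)
  out <- cbind((p[, 1] - tf$box$x) * tf$sx, (p[, 2] - tf$box$y) * tf$sy)
  dimnames(out) <- NULL
  out
}

#' @rdname crop_transform
#' @export
transform_inverse <- function(tf, pts) {
  p <- rbind(pts)
  out <- cbind(p[, 1] / tf$sx + tf$box$x, p[, 2] / tf$sy + tf$box$y)
  dimnames(out) <- NULL
  out
}

#' Crop a box out of an image and resize it
#'
#' Images are numeric matrices (rows = y, cols = x, values in `[0, 1]`);
#' pixel `(r, c)` covers the square `[c-1, c) x [r-1, r)` so the image
#' occupies `[0, W) x [0, H)`. The crop is sampled at target pixel centres
#' with nearest-neighbour lookup; regions outside the image are zero.
#'
#' @param image Numeric matrix.
#' @param box [bounding_box()] to crop (must intersect the image).
#' @param target Target size `c(W, H)`; default 512 x 512.
#' @return List with `crop` (target-size matrix) and `transform`
#'   (the [crop_transform()]).
#' @export
crop_and_resize <- function(image, box, target = c(512, 512)) {
  if (!is.matrix(image)) abort_validation("'image' must be a matrix")
  H <- nrow(image); W <- ncol(image)
  if (box$x + box$w <= 0 || box$y + box$h <= 0 || box$x >= W || box$y >= H)
    abort_validation("box does not intersect the image")
  tf <- crop_transform(box, target)
  tw <- as.integer(target[1]); th <- as.integer(target[2])
  # source coordinates of each target pixel centre
  sx <- box$x + (seq_len(tw) - 0.5) / tf$sx
  sy <- box$y + (seq_len(th) - 0.5) / tf$sy
  ci <- floor(sx) + 1  # source column index, 1-based
  ri <- floor(sy) + 1
  ok_c <- ci >= 1 & ci <= W
  ok_r <- ri >= 1 & ri <= H
  crop <- matrix(0, th, tw)
  if (any(ok_r) && any(ok_c))
    crop[ok_r, ok_c] <- image[ri[ok_r], ci[ok_c], drop = FALSE]
  list(crop = crop, transform = tf)
}

#' Heatmap stack
#'
#' Per-keypoint score maps at reduced resolution. `stride` is the number
#' of crop pixels per heatmap cell; cell `(r, c)` (1-based) samples the
#' crop point `((c-1) * stride, (r-1) * stride)`.
#'
#' @param maps List of K equal-size numeric matrices with finite entries.
#' @param stride Pixels of crop per heatmap cell.
#' @param crop_size Crop size `c(W, H)`; must equal heatmap size times
#'   stride.
#' @return A `"heatmap_stack"`.
#' @export
heatmap_stack <- function(maps, stride, crop_size) {
  if (!length(maps) || !all(vapply(maps, is.matrix, TRUE)))
    abort_validation("'maps' must be a non-empty list of matrices")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims != dims[, 1]))
    abort_validation("all heatmaps must share one size")
  if (any(!vapply(maps, function(m) all(is.finite(m)), TRUE)))
    abort_validation("heatmap scores must be finite")
  if (dims[2, 1] * stride != crop_size[1] ||
      dims[1, 1] * stride != crop_size[2])
    abort_validation("heatmap size %d x %d times stride %g != crop %g x %g",
                     dims[2, 1], dims[1, 1], stride,
                     crop_size[1], crop_size[2])
  structure(list(maps = maps, stride = as.numeric(stride),
                 crop_size = as.numeric(crop_size)),
            class = "heatmap_stack")
}

#' Decode a heatmap stack to keypoints
#'
#' Per keypoint: the argmax cell (ties broken by lowest row-major index)
#' gives the coarse location `x = (col-1) * stride`, `y = (row-1) * stride`
#' in crop coordinates; an optional quarter-stride shift toward the larger
#' of the two axial neighbours refines it (the standard simple-baselines
#' rule). Confidence is the peak value; keypoints whose peak falls below
#' `vis_floor` are emitted with visibility 0. A completely flat map decodes
#' to its first cell with a warning.
#'
#' @param stack A [heatmap_stack()].
#' @param schema A [keypoint_schema()]; `length(stack$maps)` must equal
#'   `schema$n`.
#' @param refine Apply the quarter-stride neighbour shift? Default TRUE.
#' @param vis_floor Peak value below which a keypoint is marked invisible;
#'   default 0.05.
#' @return List with `keypoints` (`n x 3` matrix x, y, v in crop
#'   coordinates) and `confidence` (peak value per keypoint).
#' @export
decode_heatmaps <- function(stack, schema = default_chicken_schema(),
                            refine = TRUE, vis_floor = 0.05) {
  if (length(stack$maps) != schema$n)
    abort_validation("stack has %d maps, schema expects %d",
                     length(stack$maps), schema$n)
  s <- stack$stride
  kp <- matrix(0, schema$n, 3, dimnames = list(schema$names, c("x", "y", "v")))
  conf <- numeric(schema$n)
  for (k in seq_len(schema$n)) {
    m <- stack$maps[[k]]
    if (max(m) == min(m))
      warning(sprintf("flat heatmap for keypoint '%s': argmax is first cell",
                      schema$names[k]))
    # column-major which.max would break the row-major tie rule; scan by row
    best <- arrayInd(which.max(t(m)), c(ncol(m), nrow(m)))
    r <- best[2]; cl <- best[1]
    x <- (cl - 1) * s
    y <- (r - 1) * s
    if (refine) {
      left  <- if (cl > 1) m[r, cl - 1] else -Inf
      right <- if (cl < ncol(m)) m[r, cl + 1] else -Inf
      up    <- if (r > 1) m[r - 1, cl] else -Inf
      down  <- if (r < nrow(m)) m[r + 1, cl] else -Inf
      if (right > left) x <- x + s / 4 else if (left > right) x <- x - s / 4
      if (down > up) y <- y + s / 4 else if (up > down) y <- y - s / 4
    }
    conf[k] <- m[r, cl]
    kp[k, ] <- c(x, y, as.numeric(conf[k] >= vis_floor))
  }
  list(keypoints = kp, confidence = conf)
}

#' Run the top-down pipeline on one image
#'
#' For every detection at or above the score floor: crop and resize the
#' box, call the pose backend for a heatmap stack, decode it, map the
#' keypoints back to image coordinates through the inverse crop transform,
#' and assemble a [pose_instance()] whose score is the detection score.
#' A backend failure on one detection is logged as a warning and that
#' instance is skipped; the pipeline continues. Instances are returned in
#' descending score order.
#'
#' @param image Numeric matrix (see [crop_and_resize()]).
#' @param image_id Identifier for the output [scene_prediction()].
#' @param detector Closure `(image, image_id) ->` data frame with columns
#'   `x`, `y`, `w`, `h`, `score` (scores in `[0, 1]`, boxes clipped to the
#'   image).
#' @param pose Closure `(crop, transform, image_id) ->` [heatmap_stack()].
#' @param schema A [keypoint_schema()].
#' @param score_floor Minimum detection score; default 0.3.
#' @param target Crop size; default 512 x 512.
#' @param refine,vis_floor Passed to [decode_heatmaps()].
#' @return A [scene_prediction()].
#' @export
run_pipeline <- function(image, image_id, detector, pose,
                         schema = default_chicken_schema(),
                         score_floor = 0.3, target = c(512, 512),
                         refine = TRUE, vis_floor = 0.05) {
  det <- detector(image, image_id)
  instances <- list()
  if (!is.null(det) && nrow(det)) {
    det <- det[det$score >= score_floor, , drop = FALSE]
    if (nrow(det)) det <- det[order(-det$score), , drop = FALSE]
    for (i in seq_len(nrow(det))) {
      inst <- tryCatch({
        box <- bounding_box(det$x[i], det$y[i], det$w[i], det$h[i])
        cr <- crop_and_resize(image, box, target)
        stack <- pose(cr$crop, cr$transform, image_id)
        dec <- decode_heatmaps(stack, schema, refine, vis_floor)
        img_xy <- transform_inverse(cr$transform, dec$keypoints[, c("x", "y")])
        pose_instance(box,
                      cbind(img_xy, dec$keypoints[, "v"]),
                      score = det$score[i], schema = schema)
      }, error = function(e) {
        warning(sprintf("pipeline: detection %d on image %s skipped: %s",
                        i, format(image_id), conditionMessage(e)))
        NULL
      })
      if (!is.null(inst)) instances[[length(instances) + 1L]] <- inst
    }
  }
  scene_prediction(image_id, instances)
}

#' Compound model scaling
#'
#' The compound-scaling rule balances network depth, width and input
#' resolution from one coefficient `phi`: depth multiplier
#' `d = alpha^phi`, width `w = beta^phi`, resolution `r = gamma^phi`,
#' subject to `alpha * beta^2 * gamma^2 ~ 2` (width and resolution are
#' squared because doubling either quadruples the computation, while
#' doubling depth only doubles it) with `alpha, beta, gamma >= 1`.
#'
#' @param phi Compound coefficient.
#' @param alpha,beta,gamma Per-dimension scaling bases, all `>= 1`.
#' @param tol Tolerance on the constraint residual; default 0.1.
#' @return List with `depth`, `width`, `resolution`, `residual`
#'   (`|alpha * beta^2 * gamma^2 - 2|`) and `constraint_ok`.
#' @export
#' @examples
#' compound_scaling(1, alpha = 2, beta = 1, gamma = 1)  # depth 2, residual 0
compound_scaling <- function(phi, alpha, beta, gamma, tol = 0.1) {
  for (v in list(alpha = alpha, beta = beta, gamma = gamma))
    if (!is_scalar_number(v) || v < 1)
      abort_validation("alpha, beta and gamma must all be >= 1")
  if (!is_scalar_number(phi)) abort_validation("'phi' must be a scalar")
  residual <- abs(alpha * beta^2 * gamma^2 - 2)
  list(depth = alpha^phi, width = beta^phi, resolution = gamma^phi,
       residual = residual, constraint_ok = residual <= tol)
}

# -- reference (oracle) backends --------------------------------------------

#' Oracle backends built from ground truth
#'
#' Reference implementations of the backend contracts, used for end-to-end
#' pipeline tests and the bundled `infer` command. The detector returns the
#' ground-truth boxes of the requested image (optionally perturbed by
#' uniform noise) with a fixed score; the pose backend projects the
#' ground-truth keypoints of the best-overlapping instance into crop
#' coordinates (optionally jittered) and renders one Gaussian peak per
#' visible keypoint. Invisible keypoints get an all-zero map, which decodes
#' back to visibility 0.
#'
#' Noise draws consume the global R random stream at call time; seed it for
#' reproducibility.
#'
#' @param scenes List of [scene_annotation()] the oracle may consult.
#' @param score Detection score assigned to every box; default 0.9.
#' @param box_noise Half-width of uniform perturbation of box corners in
#'   px; default 0.
#' @return `oracle_detector()`: a detector closure; `oracle_pose_backend()`:
#'   a pose closure (see [run_pipeline()]).
#' @export
oracle_detector <- function(scenes, score = 0.9, box_noise = 0) {
  by_id <- stats::setNames(scenes,
                           vapply(scenes, function(s)
                             as.character(s$image_id), ""))
  function(image, image_id) {
    s <- by_id[[as.character(image_id)]]
    if (is.null(s) || !length(s$instances))
      return(data.frame(x = numeric(), y = numeric(), w = numeric(),
                        h = numeric(), score = numeric()))
    boxes <- do.call(rbind, lapply(s$instances, function(i) {
      b <- i$box
      if (box_noise > 0) {
        d <- stats::runif(4, -box_noise, box_noise)
        data.frame(x = b$x + d[1], y = b$y + d[2],
                   w = max(b$w + d[3], 1), h = max(b$h + d[4], 1))
      } else data.frame(x = b$x, y = b$y, w = b$w, h = b$h)
    }))
    # clip to image bounds per the detector contract
    W <- s$width; H <- s$height
    x2 <- pmin(boxes$x + boxes$w, W); y2 <- pmin(boxes$y + boxes$h, H)
    boxes$x <- pmax(boxes$x, 0); boxes$y <- pmax(boxes$y, 0)
    boxes$w <- pmax(x2 - boxes$x, 1); boxes$h <- pmax(y2 - boxes$y, 1)
    boxes$score <- score
    boxes
  }
}

#' @rdname oracle_detector
#' @param schema A [keypoint_schema()].
#' @param stride Heatmap stride in crop px per cell; default 4.
#' @param peak_sigma Standard deviation of the rendered Gaussian peaks in
#'   crop px; default `2 * stride`.
#' @param jitter_sigma Gaussian jitter (crop px) added to the projected
#'   keypoints before rendering; default 0 (exact oracle).
#' @export
oracle_pose_backend <- function(scenes, schema = default_chicken_schema(),
                                stride = 4, peak_sigma = 2 * stride,
                                jitter_sigma = 0) {
  by_id <- stats::setNames(scenes,
                           vapply(scenes, function(s)
                             as.character(s$image_id), ""))
  function(crop, transform, image_id) {
    s <- by_id[[as.character(image_id)]]
    if (is.null(s) || !length(s$instances))
      abort_validation("oracle pose backend: unknown image %s",
                       format(image_id))
    overlaps <- vapply(s$instances, function(i)
      box_iou(i$box, transform$box), 0)
    g <- s$instances[[which.max(overlaps)]]
    uv <- transform_forward(transform, g$keypoints[, c("x", "y")])
    if (jitter_sigma > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, jitter_sigma),
                        ncol = 2)
    W <- transform$target[1]; H <- transform$target[2]
    nc <- as.integer(W / stride); nr <- as.integer(H / stride)
    cx <- (seq_len(nc) - 1) * stride
    cy <- (seq_len(nr) - 1) * stride
    maps <- lapply(seq_len(schema$n), function(k) {
      if (g$keypoints[k, "v"] == 0) return(matrix(0, nr, nc))
      dx2 <- outer(rep(1, nr), (cx - uv[k, 1])^2)
      dy2 <- outer((cy - uv[k, 2])^2, rep(1, nc))
      exp(-(dx2 + dy2) / (2 * peak_sigma^2))
    })
    heatmap_stack(maps, stride, transform$target)
  }
}

box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (bbox_area(a) + bbox_area(b) - inter)
}
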