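#' Bounding box
#'
#' Axis-aligned box in image pixel coordinates: origin at the top-left of
#' the image, x rightward, y downward, continuous and 0-based. The box
#' covers the half-open region `[x, x + w) x [y, y + h)`.
#'
#' @param x,y Top-left corner (pixels).
#' @param w,h Width and height (pixels, both `> 0`).
#' @return A `"bounding_box"` object.
#' @export
#' @examples
#' b <- bounding_box(10, 20, 100, 50)
#' bbox_area(b)  # 5000
bounding_box <- function(x, y, w, h) {
  if (!all(vapply(list(x, y, w, h), is_scalar_number, TRUE)))
    abort_validation("bounding box fields must be finite scalars")
  if (w <= 0 || h <= 0)
    abort_validation("bounding box must have w > 0 and h > 0 (got %g x %g)",
                     w, h)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)),
            class = "bounding_box")
}

#' @rdname bounding_box
#' @param box A `"bounding_box"`.
#' @export
bbox_area <- function(box) box$w * box$h

#' @rdname bounding_box
#' @export
bbox_diagonal <- function(box) sqrt(box$w^2 + box$h^2)

#' One pose instance
#'
#' A single animal in one image: its bounding box, its keypoints, and a
#' confidence score. Keypoints are stored as an `n x 3` numeric matrix with
#' columns `x`, `y`, `v`; `v` is the binary visibility flag (1 = visible /
#' annotated, 0 = invisible). Invisible keypoints take no part in [cks()]
#' or any keypoint-level metric. Ground-truth instances carry `score = 1`.
#'
#' @param box A [bounding_box()].
#' @param keypoints `n x 3` matrix (or data frame) with columns x, y, v.
#'   COCO-style visibility 2 ("visible") is collapsed to 1.
#' @param score Confidence in `[0, 1]`; default 1 (ground truth).
#' @param schema Optional [keypoint_schema()]; when given, the number of
#'   keypoint rows is checked against it.
#' @return A `"pose_instance"` object.
#' @export
pose_instance <- function(box, keypoints, score = 1, schema = NULL) {
  if (!inherits(box, "bounding_box"))
    abort_validation("'box' must be a bounding_box")
  kp <- as.matrix(keypoints)
  if (ncol(kp) != 3L)
    abort_validation("'keypoints' must have 3 columns (x, y, v)")
  storage.mode(kp) <- "double"
  colnames(kp) <- c("x", "y", "v")
  kp[, "v"] <- normalize_visibility(kp[, "v"])
  if (!is.null(schema)) {
    if (nrow(kp) != schema$n)
      abort_validation("instance has %d keypoints, schema expects %d",
                       nrow(kp), schema$n)
    rownames(kp) <- schema$names
  }
  stopifnot_scalar_prob(score, "score")
  structure(list(box = box, keypoints = kp, score = as.numeric(score)),
            class = "pose_instance")
}

#' Collapse COCO visibility codes to the binary flag
#'
#' COCO annotates v = 0 (not labeled), 1 (labeled, occluded) and
#' 2 (labeled, visible). The similarity kernel only distinguishes
#' labeled from unlabeled, so both 1 and 2 map to 1. Idempotent.
#'
#' @param v Numeric vector of visibility codes.
#' @return Numeric vector of 0/1 flags.
#' @export
normalize_visibility <- function(v) {
  if (any(!is.finite(v)) || any(!v %in% c(0, 1, 2)))
    abort_validation("visibility flags must be 0, 1 or 2")
  as.numeric(v > 0)
}

#' Scene containers
#'
#' A `scene_annotation` holds the ground truth for one image: its id, pixel
#' dimensions and the list of annotated [pose_instance()]s. A
#' `scene_prediction` holds the predicted instances (with scores) for one
#' image. For evaluation, every prediction's `image_id` must exist in the
#' annotation set.
#'
#' @param image_id Image identifier (kept as given; compared as character).
#' @param width,height Image size in pixels.
#' @param instances List of [pose_instance()].
#' @return A `"scene_annotation"` / `"scene_prediction"` object.
#' @export
scene_annotation <- function(image_id, width, height, instances = list()) {
  if (!is_scalar_number(width) || !is_scalar_number(height) ||
      width <= 0 || height <= 0)
    abort_validation("scene dimensions must be positive scalars")
  if (!all(vapply(instances, inherits, TRUE, "pose_instance")))
    abort_validation("'instances' must be a list of pose_instance")
  for (inst in instances) {
    kp <- inst$keypoints
    vis <- kp[, "v"] > 0
    if (any(vis) && (any(kp[vis, "x"] < 0) || any(kp[vis, "x"] >= width) ||
                     any(kp[vis, "y"] < 0) || any(kp[vis, "y"] >= height)))
      abort_validation(
        "visible ground-truth keypoints must lie inside [0,%g) x [0,%g)",
        width, height)
  }
  structure(list(image_id = image_id, width = as.numeric(width),
                 height = as.numeric(height), instances = instances),
            class = "scene_annotation")
}

#' @rdname scene_annotation
#' @export
scene_prediction <- function(image_id, instances = list()) {
  if (!all(vapply(instances, inherits, TRUE, "pose_instance")))
    abort_validation("'instances' must be a list of pose_instance")
  structure(list(image_id = image_id, instances = instances),
            class = "scene_prediction")
}

#' @export
print.pose_instance <- function(x, ...) {
  cat(sprintf("<pose_instance> box (%.1f,%.1f,%.1f,%.1f) score %.3f, %d keypoints (%d visible)\n",
              x$box$x, x$box$y, x$box$w, x$box$h, x$score,
              nrow(x$keypoints), sum(x$keypoints[, "v"] > 0)))
  invisible(x)
}

#' @export
print.scene_annotation <- function(x, ...) {
  cat(sprintf("<scene_annotation> image %s (%g x %g), %d instances\n",
              format(x$image_id), x$width, x$height, length(x$instances)))
  invisible(x)
}

#' @export
print.scene_prediction <- function(x, ...) {
  cat(sprintf("<scene_prediction> image %s, %d instances\n",
              format(x$image_id), length(x$instances)))
  invisible(x)
}
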