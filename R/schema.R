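#' Keypoint schema
#'
#' A keypoint schema names the landmarks of one animal category and carries
#' the per-keypoint normalisation constants used by the chicken keypoint
#' similarity ([cks()]), the left/right keypoint pairing (used to simulate
#' and detect lateral swaps), and the skeleton edges used for rendering.
#'
#' @param names Character vector of unique keypoint labels, in canonical
#'   order. All indices elsewhere in the package refer to this order.
#' @param betas Numeric vector of per-keypoint normalisation factors
#'   (dimensionless, all `> 0`), recycled to `length(names)` if scalar.
#'   Larger values make the similarity kernel more forgiving for that
#'   keypoint.
#' @param lr_pairs List of length-2 integer vectors `(left, right)` giving
#'   laterally symmetric keypoint pairs. Indices must be valid and disjoint
#'   across pairs. May be empty.
#' @param skeleton List of length-2 integer vectors: edges drawn between
#'   keypoints. May be empty.
#'
#' @return An object of class `"keypoint_schema"`: a list with elements
#'   `names`, `betas`, `lr_pairs`, `skeleton`, and `n` (number of keypoints).
#' @seealso [default_chicken_schema()]
#' @export
#' @examples
#' keypoint_schema(c("head", "tail"), betas = 0.05)
keypoint_schema <- function(names, betas = 0.025, lr_pairs = list(),
                            skeleton = list()) {
  if (!is.character(names) || length(names) < 1L)
    abort_validation("a schema needs at least one keypoint name")
  if (anyDuplicated(names))
    abort_validation("duplicate keypoint name: %s",
                     names[duplicated(names)][1L])
  n <- length(names)
  if (length(betas) == 1L) betas <- rep(betas, n)
  if (length(betas) != n)
    abort_validation("'betas' must have length 1 or %d", n)
  if (!is.numeric(betas) || any(!is.finite(betas)) || any(betas <= 0))
    abort_validation("all 'betas' must be finite and > 0")
  betas <- as.numeric(betas)
  names(betas) <- names

  check_pairs <- function(pairs, what) {
    for (p in pairs) {
      p <- as.integer(p)
      if (length(p) != 2L || any(is.na(p)) || any(p < 1L) || any(p > n))
        abort_validation("invalid %s entry: indices must be in 1..%d", what, n)
    }
    lapply(pairs, as.integer)
  }
  lr_pairs <- check_pairs(lr_pairs, "lr_pairs")
  if (length(lr_pairs)) {
    idx <- unlist(lr_pairs)
    if (anyDuplicated(idx))
      abort_validation("lr_pairs indices must be disjoint")
  }
  skeleton <- check_pairs(skeleton, "skeleton")

  structure(list(names = names, betas = betas, lr_pairs = lr_pairs,
                 skeleton = skeleton, n = n),
            class = "keypoint_schema")
}

#' The canonical 10-keypoint chicken schema
#'
#' Ten landmarks on one broiler chicken: the body centre and tail, left and
#' right knee and heel, left and right eye, comb and beak. The body centre
#' carries normalisation factor `beta = 0.107`; all other keypoints carry
#' `beta = 0.025`, i.e. the kernel of [cks()] tolerates far larger
#' displacement of the (hard to annotate) body centre than of the small,
#' well-localised head and leg points.
#'
#' The skeleton edge set connects the body centre to tail, knees and head
#' points in a star-plus-limbs layout; it is a rendering convention of this
#' package (the edge set is configurable via [keypoint_schema()]).
#'
#' @return A [keypoint_schema()] with `n = 10`.
#' @export
#' @examples
#' sch <- default_chicken_schema()
#' sch$betas[["body_center"]]  # 0.107
default_chicken_schema <- function() {
  nm <- c("body_center", "body_tail", "body_knee_left", "body_knee_right",
          "body_heel_left", "body_heel_right", "eye_left", "eye_right",
          "comb", "beak")
  betas <- c(0.107, rep(0.025, 9L))
  lr <- list(c(3L, 4L), c(5L, 6L), c(7L, 8L))
  skel <- list(
    c(1L, 2L),           # body_center - body_tail
    c(1L, 3L), c(3L, 5L),  # left leg
    c(1L, 4L), c(4L, 6L),  # right leg
    c(1L, 7L), c(1L, 8L),  # eyes
    c(7L, 9L), c(8L, 9L),  # comb
    c(7L, 10L), c(8L, 10L) # beak
  )
  keypoint_schema(nm, betas, lr, skel)
}

#' @export
print.keypoint_schema <- function(x, ...) {
  cat(sprintf("<keypoint_schema> %d keypoints\n", x$n))
  cat(paste0("  ", format(x$names), "  beta=", format(x$betas)), sep = "\n")
  if (length(x$lr_pairs))
    cat("  left/right pairs:",
        paste(vapply(x$lr_pairs, function(p)
          paste0("(", x$names[p[1]], ",", x$names[p[2]], ")"), ""),
          collapse = " "), "\n")
  invisible(x)
}
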