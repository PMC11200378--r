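# COCO-keypoints JSON dialect: annotations files carry top-level "images",
# "annotations" and "categories" blocks; prediction (results) files are a
# flat list of {"image_id", "category_id", "keypoints", "score", "bbox"}.
# The schema is embedded in the category block; per-keypoint normalisation
# factors travel in a non-standard "betas" field (COCO keeps its OKS sigmas
# in code, not in the file).

#' Read a COCO-keypoints annotation file
#'
#' Parses the COCO keypoints dialect: each annotation carries a
#' `bbox = [x, y, w, h]` and a flat `keypoints = [x1, y1, v1, ...]` vector.
#' COCO visibility codes are collapsed to the binary flag (see
#' [normalize_visibility()]). The keypoint schema is taken from the first
#' category block: its `keypoints` names, its `skeleton`, and its `betas`
#' if present; when the names are exactly the canonical chicken names the
#' defaults of [default_chicken_schema()] fill any missing pieces,
#' otherwise missing betas fall back to 0.025 for every keypoint.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `schema` (a [keypoint_schema()]) and
#'   `scenes` (a list of [scene_annotation()], in file order).
#' @export
read_annotations <- function(path) {
  doc <- read_json_file(path)
  for (block in c("images", "annotations", "categories"))
    if (is.null(doc[[block]]))
      abort_validation("annotation file lacks the '%s' block", block)
  schema <- schema_from_category(doc$categories[[1]])

  images <- doc$images
  ids <- vapply(images, function(im) as.character(im$id), "")
  if (anyDuplicated(ids))
    abort_validation("duplicate image id: %s", ids[duplicated(ids)][1L])
  inst_by_image <- stats::setNames(vector("list", length(ids)), ids)

  for (ann in doc$annotations) {
    iid <- as.character(ann$image_id)
    if (!iid %in% ids)
      abort_validation("annotation refers to unknown image id %s", iid)
    inst_by_image[[iid]] <- c(inst_by_image[[iid]],
                              list(instance_from_record(ann, schema)))
  }

  scenes <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    scene_annotation(im$id, im$width, im$height,
                     inst_by_image[[ids[i]]] %||% list())
  })
  list(schema = schema, scenes = scenes)
}

#' Write a COCO-keypoints annotation file
#'
#' Inverse of [read_annotations()]: serialisation is deterministic (stable
#' key order, full float precision), so a fixed dataset always produces the
#' same bytes and `read_annotations(write_annotations(x))` is structurally
#' the identity.
#'
#' @param scenes List of [scene_annotation()].
#' @param schema The [keypoint_schema()] to embed in the category block.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(scenes, schema, path) {
  if (!all(vapply(scenes, inherits, TRUE, "scene_annotation")))
    abort_validation("'scenes' must be a list of scene_annotation")
  images <- lapply(scenes, function(s)
    list(id = s$image_id, width = s$width, height = s$height))
  anns <- list()
  k <- 0L
  for (s in scenes) {
    for (inst in s$instances) {
      k <- k + 1L
      anns[[k]] <- c(list(id = k, image_id = s$image_id, category_id = 1L),
                     record_from_instance(inst))
    }
  }
  doc <- list(
    images = images,
    annotations = anns,
    categories = list(list(
      id = 1L, name = "chicken",
      keypoints = as.list(schema$names),
      skeleton = schema$skeleton,
      betas = as.list(unname(schema$betas))
    ))
  )
  write_json_file(doc, path)
}

#' Read / write COCO-results prediction files
#'
#' Predictions use the flat COCO results dialect: a JSON array of
#' `{"image_id", "category_id", "keypoints", "score", "bbox"}` records.
#' Records are grouped into one [scene_prediction()] per image id, in
#' first-appearance order; record order within an image is preserved
#' (it is the tie-break for equal scores during matching).
#'
#' @param path JSON file path.
#' @param schema [keypoint_schema()] used to check keypoint counts.
#' @return `read_predictions`: a list of [scene_prediction()].
#' @export
read_predictions <- function(path, schema) {
  recs <- read_json_file(path)
  out <- list()
  order_ids <- character()
  for (rec in recs) {
    iid <- as.character(rec$image_id)
    if (!iid %in% order_ids) {
      order_ids <- c(order_ids, iid)
      out[[iid]] <- list(image_id = rec$image_id, instances = list())
    }
    out[[iid]]$instances <- c(out[[iid]]$instances,
                              list(instance_from_record(rec, schema)))
  }
  lapply(order_ids, function(iid)
    scene_prediction(out[[iid]]$image_id, out[[iid]]$instances))
}

#' @rdname read_predictions
#' @param predictions List of [scene_prediction()].
#' @export
write_predictions <- function(predictions, path) {
  if (!all(vapply(predictions, inherits, TRUE, "scene_prediction")))
    abort_validation("'predictions' must be a list of scene_prediction")
  recs <- list()
  k <- 0L
  for (p in predictions) {
    for (inst in p$instances) {
      k <- k + 1L
      recs[[k]] <- c(list(image_id = p$image_id, category_id = 1L),
                     record_from_instance(inst))
    }
  }
  write_json_file(recs, path, force_array = TRUE)
}

# -- internals ---------------------------------------------------------------

read_json_file <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e) abort_io("cannot parse JSON in %s: %s",
                                        path, conditionMessage(e)))
}

write_json_file <- function(x, path, force_array = FALSE) {
  txt <- tryCatch(
    jsonlite::toJSON(x, auto_unbox = !force_array || length(x) > 0,
                     digits = NA, null = "null"),
    error = function(e) abort_io("cannot serialise JSON: %s",
                                 conditionMessage(e)))
  if (force_array && length(x) == 0) txt <- "[]"
  ok <- tryCatch({ writeLines(txt, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort_io("cannot write %s", path)
  invisible(path)
}

schema_from_category <- function(cat) {
  nm <- as.character(unlist(cat$keypoints))
  if (!length(nm)) abort_validation("category block has no keypoint names")
  default <- default_chicken_schema()
  is_default <- identical(nm, default$names)
  betas <- if (!is.null(cat$betas)) as.numeric(unlist(cat$betas))
           else if (is_default) unname(default$betas)
           else rep(0.025, length(nm))
  skeleton <- if (!is.null(cat$skeleton))
    lapply(cat$skeleton, function(e) as.integer(unlist(e)))
  else if (is_default) default$skeleton else list()
  keypoint_schema(nm, betas, lr_pairs_from_names(nm), skeleton)
}

# Lateral pairs are recovered from the *_left / *_right naming convention.
lr_pairs_from_names <- function(nm) {
  left <- grep("_left$", nm)
  pairs <- list()
  for (i in left) {
    j <- match(sub("_left$", "_right", nm[i]), nm)
    if (!is.na(j)) pairs <- c(pairs, list(c(i, j)))
  }
  pairs
}

instance_from_record <- function(rec, schema) {
  kp_flat <- as.numeric(unlist(rec$keypoints))
  if (length(kp_flat) != 3L * schema$n)
    abort_validation("keypoint array has length %d, expected %d (3 x %d)",
                     length(kp_flat), 3L * schema$n, schema$n)
  kp <- matrix(kp_flat, ncol = 3L, byrow = TRUE)
  bb <- as.numeric(unlist(rec$bbox))
  if (length(bb) != 4L)
    abort_validation("bbox must have 4 entries [x, y, w, h]")
  score <- rec$score %||% 1
  if (!is_scalar_number(score) || score < 0 || score > 1)
    abort_validation("prediction score %s outside [0, 1]", format(score))
  pose_instance(bounding_box(bb[1], bb[2], bb[3], bb[4]), kp,
                score = score, schema = schema)
}

record_from_instance <- function(inst) {
  kp <- inst$keypoints
  list(bbox = c(inst$box$x, inst$box$y, inst$box$w, inst$box$h),
       keypoints = as.vector(t(kp)),
       num_keypoints = sum(kp[, "v"] > 0),
       score = inst$score,
       area = bbox_area(inst$box))
}
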