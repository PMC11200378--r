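#' Serialise and render evaluation reports
#'
#' `report_to_list()` flattens an `"mcp_report"` (from [evaluate()]) into a
#' plain list ready for JSON; `write_report()` writes it; `load_report()`
#' reads such a JSON file back; `render_report()` renders a report (either
#' the live object or a loaded list) as a JSON string, a CSV document with
#' one row per keypoint plus summary rows, or a plain-text table mirroring
#' the usual benchmark layout (summary line with mAP / mAR / PCK, then a
#' per-keypoint RMSE table — no speed column, which is hardware-bound and
#' out of scope).
#'
#' @param report An `"mcp_report"` or a list from [load_report()].
#' @param provenance Optional named list (e.g. seed, config hash) embedded
#'   verbatim under `"provenance"`, alongside the package version.
#' @return `report_to_list()`: a list. `render_report()`: a character
#'   string. `write_report()`/`load_report()`: the path / the list.
#' @export
report_to_list <- function(report, provenance = list()) {
  pooled <- attr(report$rmse, "pooled")
  list(
    summary = list(map = report$map, mar = report$mar, pck = report$pck,
                   rmse_mean_of_keypoints = unname(pooled["mean_of_rmse"]),
                   rmse_pooled = unname(pooled["pooled_rmse"])),
    per_threshold = report$per_threshold,
    rmse = report$rmse,
    pixel_error = report$pe,
    cks_histogram = report$cks_histogram,
    diagnostics = report$diagnostics,
    config = list(
      cks_thresholds = report$eval_config$cks_thresholds,
      histogram_bins = report$eval_config$histogram_bins,
      pck_normalizer = report$pck_config$normalizer,
      pck_tau = report$pck_config$tau),
    provenance = c(list(package = "mcpose",
                        version = as.character(utils::packageVersion("mcpose"))),
                   provenance)
  )
}

#' @rdname report_to_list
#' @param path File path.
#' @export
write_report <- function(report, path, provenance = list()) {
  x <- if (inherits(report, "mcp_report"))
    report_to_list(report, provenance) else report
  write_json_file(x, path)
}

#' @rdname report_to_list
#' @export
load_report <- function(path) {
  jsonlite::fromJSON(read_json_text(path), simplifyDataFrame = TRUE)
}

read_json_text <- function(path) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' @rdname report_to_list
#' @param format One of `"json"`, `"csv"`, `"text"`.
#' @export
render_report <- function(report, format = c("text", "json", "csv"),
                          provenance = list()) {
  format <- match.arg(format)
  x <- if (inherits(report, "mcp_report"))
    report_to_list(report, provenance) else report
  switch(format,
    json = as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)),
    csv = render_csv(x),
    text = render_text(x))
}

render_csv <- function(x) {
  rmse <- as.data.frame(x$rmse)
  rows <- data.frame(row_type = "summary",
                     name = c("mAP", "mAR", "PCK",
                              "RMSE_mean_of_keypoints", "RMSE_pooled"),
                     n = NA_integer_,
                     value = c(x$summary$map, x$summary$mar,
                               null_na(x$summary$pck),
                               null_na(x$summary$rmse_mean_of_keypoints),
                               null_na(x$summary$rmse_pooled)),
                     stringsAsFactors = FALSE)
  if (!is.null(rmse) && nrow(rmse))
    rows <- rbind(rows, data.frame(row_type = "keypoint_rmse",
                                   name = rmse$keypoint, n = rmse$n,
                                   value = rmse$rmse,
                                   stringsAsFactors = FALSE))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(rows, con, row.names = FALSE)
  close(con)
  paste(out, collapse = "\n")
}

null_na <- function(v) if (is.null(v) || !length(v)) NA_real_ else v

render_text <- function(x) {
  fmt3 <- function(v) ifelse(is.na(null_na(v)), "   NA", sprintf("%.3f", v))
  lines <- c(
    "Pose estimation evaluation",
    "==========================",
    sprintf("%-10s %-10s %-10s", "mAP", "mAR", "PCK"),
    sprintf("%-10s %-10s %-10s", fmt3(x$summary$map), fmt3(x$summary$mar),
            fmt3(x$summary$pck)),
    "")
  rmse <- as.data.frame(x$rmse)
  if (!is.null(rmse) && nrow(rmse)) {
    lines <- c(lines, "Per-keypoint RMSE (px)",
               sprintf("%-18s %6s %10s", "Keypoint", "n", "RMSE"))
    for (i in seq_len(nrow(rmse)))
      lines <- c(lines, sprintf("%-18s %6d %10.2f", rmse$keypoint[i],
                                rmse$n[i], rmse$rmse[i]))
    lines <- c(lines,
               sprintf("%-18s %6s %10.2f", "Mean of keypoints", "",
                       null_na(x$summary$rmse_mean_of_keypoints)),
               sprintf("%-18s %6s %10.2f", "Pooled", "",
                       null_na(x$summary$rmse_pooled)))
  }
  hist <- as.data.frame(x$cks_histogram)
  if (!is.null(hist) && nrow(hist) && sum(hist$count) > 0) {
    lines <- c(lines, "", "Matched-instance CKS histogram")
    for (i in seq_len(nrow(hist)))
      lines <- c(lines, sprintf("[%.2f, %.2f%s %5d %s", hist$lower[i],
                                hist$upper[i],
                                if (i == nrow(hist)) "]" else ")",
                                hist$count[i],
                                strrep("#", min(hist$count[i], 60))))
  }
  paste(lines, collapse = "\n")
}
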