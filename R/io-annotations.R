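# Sidecar annotation CSV (time_s,label) and JSON run manifests.

#' Write S1/S2 event annotations to CSV
#'
#' Columns `time_s` (microsecond precision) and `label`; an optional
#' `amplitude` column is included when present.
#'
#' @param events data frame with `time_s` and `label` (and optionally
#'   `amplitude`), or an `fpcg_signal` (its events are written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  if (inherits(events, "fpcg_signal")) events <- events$events
  stopifnot(all(c("time_s", "label") %in% names(events)))
  if (nrow(events) && !all(events$label %in% c("S1", "S2")))
    stop("labels must be S1 or S2")
  out <- events
  out$time_s <- sprintf("%.6f", out$time_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read S1/S2 event annotations from CSV
#'
#' Rows are validated (labels must be S1/S2) and sorted by time with a
#' warning if they arrive out of order.
#'
#' @param path CSV path as written by [write_annotations()].
#' @return Data frame with `time_s` (numeric) and `label`.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "label") %in% names(df)))
  if (nrow(df) && !all(df$label %in% c("S1", "S2")))
    stop("unknown label(s): ",
         paste(setdiff(unique(df$label), c("S1", "S2")), collapse = ", "))
  if (nrow(df) && is.unsorted(df$time_s)) {
    warning("annotation rows out of order; sorting by time")
    df <- df[order(df$time_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$time_s <- as.numeric(df$time_s)
  df
}

#' Write a JSON run manifest
#'
#' Records the package version, seeds and resolved configuration of a
#' pipeline run next to its outputs, so every result row is traceable.
#'
#' @param manifest named list (seeds, configs, file names, ...).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$tool_version <-
    as.character(utils::packageVersion("fpcgbench"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
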