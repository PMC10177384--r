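# Tabular interchange: spike/unit tables as CSV, waveform sidecars, run
# manifests.
#
# Spike-table schema (CSV, UTF-8, '.' decimal, header row):
#   well      integer >= 1
#   electrode integer >= 1
#   phase     character phase label
#   time_s    seconds from phase start, strictly increasing within
#             (well, electrode, phase)
#   amplitude optional, trough depth (positive)
#   unit_id   optional, integer or empty (outlier pool)
# Numeric columns are written with 17 significant digits so a write/read
# round trip reproduces the table exactly.

spike_table_columns <- c("well", "electrode", "phase", "time_s")

#' Write a spike table to CSV
#'
#' @param table A `spike_table` (or plain data frame with the schema
#'   columns).
#' @param path Output CSV path.
#' @param waveform_path Optional path for the waveform sidecar (plain CSV
#'   matrix, one row per event).
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(table, path, waveform_path = NULL) {
  df <- as.data.frame(table)
  for (col in intersect(c("time_s", "amplitude"), names(df)))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  wf <- attr(table, "waveforms")
  if (!is.null(waveform_path) && !is.null(wf)) {
    utils::write.table(matrix(sprintf("%.8g", wf), nrow(wf)), waveform_path,
                       row.names = FALSE, col.names = FALSE, sep = ",",
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a spike table from CSV
#'
#' Validates the documented schema: required columns present, times finite,
#' non-negative, and strictly increasing within each (well, electrode,
#' phase); violations raise a schema error naming the row and column.
#'
#' @param path CSV path written by [write_spike_table()] (or matching the
#'   schema).
#' @param waveform_path Optional waveform sidecar to attach.
#' @param phases Optional character vector of known phase labels; rows with
#'   other labels are rejected.
#' @return A `spike_table`.
#' @export
read_spike_table <- function(path, waveform_path = NULL, phases = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spike_table_columns, names(df))
  if (length(missing))
    stop_schema("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    bad <- which(!is.finite(df$time_s) | df$time_s < 0)
    if (length(bad))
      stop_schema("invalid time_s at row ", bad[1], " (column time_s): ",
                  df$time_s[bad[1]])
    if (!is.null(phases)) {
      bad <- which(!(df$phase %in% phases))
      if (length(bad))
        stop_schema("unknown phase label at row ", bad[1],
                    " (column phase): '", df$phase[bad[1]], "'")
    }
    key <- paste(df$well, df$electrode, df$phase)
    for (k in unique(key)) {
      idx <- which(key == k)
      tt <- df$time_s[idx]
      nm <- which(diff(tt) <= 0)
      if (length(nm))
        stop_schema("non-monotone time_s at row ", idx[nm[1] + 1],
                    " (column time_s) for well ", df$well[idx[1]],
                    " electrode ", df$electrode[idx[1]],
                    " phase ", df$phase[idx[1]])
    }
  }
  wf <- if (!is.null(waveform_path))
    as.matrix(utils::read.csv(waveform_path, header = FALSE))
  spike_table(df, wf)
}

#' Write a run manifest
#'
#' Serializes the stage name, all parameter values, input/output paths, the
#' seed, the package version, and a timestamp as JSON, so every pipeline
#' output is traceable to the exact settings that produced it.
#'
#' @param stage Stage name.
#' @param params Named list of parameter values (S3 parameter objects are
#'   unclassed).
#' @param inputs,outputs Character vectors of paths.
#' @param seed Integer seed.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(stage, params, inputs = character(0),
                           outputs = character(0), seed = NA_integer_,
                           path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  manifest <- list(stage = stage, params = strip(params),
                   inputs = inputs, outputs = outputs, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("hmnr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
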