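#' Annotations: time-frequency bounding boxes
#'
#' Analyst annotations and detector output share one vocabulary: a
#' time-frequency bounding box with a label. Annotations are kept as a
#' tibble with columns `begin_time_s`, `end_time_s`, `low_freq_hz`,
#' `high_freq_hz`, `label` and `source`; times are seconds from stream
#' start (half-open `[begin, end)`), frequencies in Hz.
#'
#' @param begin_time_s,end_time_s Event bounds in seconds, `end > begin`.
#' @param low_freq_hz,high_freq_hz Frequency bounds in Hz,
#'   `high > low >= 0`.
#' @param label Category string, e.g. `"upcall"`.
#' @param source Free text provenance.
#' @return A tibble of class `annotations`, sorted by begin time.
#' @export
annotations <- function(begin_time_s = numeric(), end_time_s = numeric(),
                        low_freq_hz = numeric(), high_freq_hz = numeric(),
                        label = character(), source = character()) {
  n <- length(begin_time_s)
  if (length(label) %in% c(0L, 1L)) {
    label <- rep(if (length(label)) label else "upcall", n)
  }
  if (length(source) %in% c(0L, 1L)) {
    source <- rep(if (length(source)) source else "", n)
  }
  bad <- which(end_time_s <= begin_time_s)
  if (length(bad)) {
    abort_upcallr(
      sprintf("annotation row %d has end_time <= begin_time", bad[1]),
      "upcallr_error_bad_annotation")
  }
  bad <- which(high_freq_hz <= low_freq_hz | low_freq_hz < 0)
  if (length(bad)) {
    abort_upcallr(
      sprintf("annotation row %d has invalid frequency bounds", bad[1]),
      "upcallr_error_bad_annotation")
  }
  out <- tibble::tibble(
    begin_time_s = as.numeric(begin_time_s),
    end_time_s = as.numeric(end_time_s),
    low_freq_hz = as.numeric(low_freq_hz),
    high_freq_hz = as.numeric(high_freq_hz),
    label = as.character(label),
    source = as.character(source)
  )
  out <- out[order(out$begin_time_s), ]
  class(out) <- c("annotations", class(out))
  out
}

.raven_required <- c(
  begin_time_s = "Begin Time (s)",
  end_time_s   = "End Time (s)",
  low_freq_hz  = "Low Freq (Hz)",
  high_freq_hz = "High Freq (Hz)"
)

#' Read a Raven-style selection table
#'
#' Selection tables are tab-separated files with header columns
#' `"Begin Time (s)"`, `"End Time (s)"`, `"Low Freq (Hz)"`,
#' `"High Freq (Hz)"` and an optional label column (`"Label"` or
#' `"Annotation"`). Unknown extra columns are preserved and written back by
#' [write_selection_table()].
#'
#' @param path Path to a tab-separated selection table.
#' @return An [annotations()] tibble; extra columns are carried along.
#' @export
read_selection_table <- function(path) {
  if (!file.exists(path)) {
    abort_upcallr(sprintf("selection table not found: %s", path),
                  "upcallr_error_missing_file")
  }
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(.raven_required), names(df))
  if (length(missing_cols)) {
    abort_upcallr(
      sprintf("selection table missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "upcallr_error_missing_column")
  }
  for (col in unname(.raven_required)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort_upcallr(
          sprintf("non-numeric value in column '%s', row %d", col, bad[1]),
          "upcallr_error_bad_cell")
      }
      df[[col]] <- vn
    }
  }
  bad <- which(df[[.raven_required[["begin_time_s"]]]] >=
                 df[[.raven_required[["end_time_s"]]]])
  if (length(bad)) {
    abort_upcallr(
      sprintf("begin time >= end time in row %d", bad[1]),
      "upcallr_error_bad_annotation")
  }
  label_col <- intersect(c("Label", "Annotation"), names(df))[1]
  ann <- annotations(
    begin_time_s = df[[.raven_required[["begin_time_s"]]]],
    end_time_s = df[[.raven_required[["end_time_s"]]]],
    low_freq_hz = df[[.raven_required[["low_freq_hz"]]]],
    high_freq_hz = df[[.raven_required[["high_freq_hz"]]]],
    label = if (!is.na(label_col)) as.character(df[[label_col]]) else character(),
    source = basename(path)
  )
  extra <- setdiff(names(df), c(unname(.raven_required), label_col))
  if (length(extra) && nrow(df)) {
    ord <- order(df[[.raven_required[["begin_time_s"]]]])
    for (col in extra) ann[[col]] <- df[[col]][ord]
  }
  ann
}

#' Write annotations as a Raven-style selection table
#'
#' Rows are sorted by begin time; numeric fields are written with enough
#' digits that a read/write round trip preserves them. Extra (non-core)
#' columns on the annotations tibble are written through.
#'
#' @param ann An [annotations()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(ann, path) {
  ann <- ann[order(ann$begin_time_s), ]
  out <- data.frame(
    `Selection` = seq_len(nrow(ann)),
    check.names = FALSE
  )
  out[[.raven_required[["begin_time_s"]]]] <- ann$begin_time_s
  out[[.raven_required[["end_time_s"]]]] <- ann$end_time_s
  out[[.raven_required[["low_freq_hz"]]]] <- ann$low_freq_hz
  out[[.raven_required[["high_freq_hz"]]]] <- ann$high_freq_hz
  out[["Label"]] <- ann$label
  extra <- setdiff(names(ann),
                   c("begin_time_s", "end_time_s", "low_freq_hz",
                     "high_freq_hz", "label", "source"))
  for (col in extra) out[[col]] <- ann[[col]]
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 10, format = "g") else as.character(x)
  }
  out[] <- lapply(out, fmt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
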