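#' Unblind a completed session
#'
#' Joins the blinded-ID-keyed scores back to segment labels and source
#' files, producing one row per segment with the label, the original source
#' filename, and one note column per stage (in stage definition order).
#' Rows are sorted by source file, then by natural well order (letter, then
#' numeric value: `A2` before `A10`). The join is shuffle-invariant: each
#' row's notes are exactly what was entered under that segment's blinded
#' ID, whatever its presentation rank.
#'
#' @param session A `blindcut_session`.
#' @param partial Allow exporting an incomplete session; unscored segments
#'   get `"pending"` in every stage column. Without it an incomplete
#'   session is an error.
#' @return A `data.frame` with columns `label`, `source_file`, then the
#'   stage names.
#' @export
unblind <- function(session, partial = FALSE) {
  stopifnot(inherits(session, "blindcut_session"))
  n <- session_n(session)
  if (session$cursor < n && !isTRUE(partial)) {
    stop_blindcut("blindcut_incomplete_session_error",
                  sprintf("session is incomplete (%d of %d scored); use partial export to override",
                          session$cursor, n))
  }
  labels <- vapply(session$segments, function(s) s$label, "")
  sources <- vapply(session$segments, function(s) basename(s$source$path), "")
  stages <- session$stage_names

  note_cols <- lapply(stages, function(st) {
    vapply(seq_len(n), function(i) {
      sc <- session$scores[[session$blinded_ids[i]]]
      if (is.null(sc)) "pending" else sc$notes[[st]]
    }, "")
  })
  df <- data.frame(label = labels, source_file = sources, stringsAsFactors = FALSE)
  for (k in seq_along(stages)) df[[stages[k]]] <- note_cols[[k]]

  ord <- order(sources, substr(labels, 1L, 1L), as.integer(substring(labels, 2L)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("blindcut_results", "data.frame")
  df
}

#' Write the unblinded results table
#'
#' Writes `results.csv` (UTF-8, header `label,source_file,<stages...>`,
#' RFC-4180 quoting so commas, quotes and newlines in notes round-trip)
#' and `results.xlsx` with cell-for-cell identical content. The CSV is the
#' canonical, diffable output; the spreadsheet is emitted alongside for
#' downstream analysis.
#'
#' @param table A results `data.frame` from [unblind()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector `c(csv =, xlsx =)` of written paths.
#' @export
write_results <- function(table, out_dir) {
  stopifnot(is.data.frame(table))
  if (!dir.exists(out_dir)) {
    ok <- tryCatch(dir.create(out_dir, recursive = TRUE), warning = function(w) FALSE)
    if (!isTRUE(ok)) {
      stop_blindcut("blindcut_io_error", sprintf("cannot create output directory '%s'", out_dir))
    }
  }
  csv_path <- file.path(out_dir, "results.csv")
  xlsx_path <- file.path(out_dir, "results.xlsx")
  ok <- tryCatch({
    utils::write.csv(table, csv_path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_blindcut("blindcut_io_error", sprintf("cannot write '%s'", csv_path))
  write_xlsx_minimal(as.data.frame(table), xlsx_path)
  c(csv = csv_path, xlsx = xlsx_path)
}

#' Read back a results CSV
#'
#' Reads `results.csv` with every column as character, reproducing the
#' table exactly as written (the round-trip contract of [write_results()]).
#'
#' @param path Path to `results.csv`.
#' @return A character `data.frame`.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
}
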