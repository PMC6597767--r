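# CSV dialect for visit tables.
#
# Columns: patient_id, visit, dose_prev_mg, interval_days, ft4_pmol_per_l.
# Cumulative time is always derived from intervals, never stored; storing
# intervals sidesteps the ambiguity between per-interval and cumulative
# time conventions found in published visit tables.

.visit_cols <- c("patient_id", "visit", "dose_prev_mg", "interval_days",
                 "ft4_pmol_per_l")

#' Read a visit table into patient series
#'
#' Reads a UTF-8 CSV with header columns `patient_id`, `visit`,
#' `dose_prev_mg`, `interval_days`, `ft4_pmol_per_l`; rows are grouped by
#' patient and ordered by visit. All series invariants (visit-1 zero rules,
#' positive follow-up intervals, positive FT4, contiguous visit indices)
#' are validated on load, with errors naming the patient and rule.
#'
#' @param path CSV file path.
#' @return Named list of [patient_series] objects (names = patient ids).
#'   An empty (header-only) file yields an empty list with a warning.
#' @export
read_visits <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.visit_cols, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("%s: no visit rows", path), call. = FALSE)
    return(list())
  }
  for (col in c("visit", "dose_prev_mg", "interval_days", "ft4_pmol_per_l")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("%s: malformed value in column %s at data row %d",
                   path, col, bad[1]), call. = FALSE)
  }
  out <- list()
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    rows <- rows[order(rows$visit), , drop = FALSE]
    if (!identical(as.integer(rows$visit), seq_len(nrow(rows))))
      stop(sprintf("patient %s: visit indices must be contiguous from 1",
                   pid), call. = FALSE)
    if (any(rows$interval_days < 0))
      stop(sprintf("patient %s: interval_days must be non-negative", pid),
           call. = FALSE)
    out[[as.character(pid)]] <- patient_series(
      patient_id = pid,
      dose_prev = rows$dose_prev_mg,
      interval_days = rows$interval_days,
      ft4 = rows$ft4_pmol_per_l)
  }
  out
}

#' Write patient series to the visit-table CSV dialect
#'
#' Inverse of [read_visits()]: the round trip is lossless.
#'
#' @param series A single [patient_series] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(series, path) {
  if (inherits(series, "patient_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(patient_id = s$patient_id,
               visit = s$visits$visit,
               dose_prev_mg = s$visits$dose_prev,
               interval_days = s$visits$interval_days,
               ft4_pmol_per_l = s$visits$ft4,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- stats::setNames(
      data.frame(character(), numeric(), numeric(), numeric(), numeric()),
      .visit_cols)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
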