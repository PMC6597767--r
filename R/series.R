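# Patient visit series: the (d_{i-1}, t_i, y_i) convention.
#
# Visit i carries the dose prescribed at the *preceding* review (taken
# during the interval ending at visit i), the cumulative time since the
# initial review, and the FT4 measured at visit i. Visit 1 is the
# untreated baseline: dose_prev = 0, interval = 0, cumulative = 0.

#' Construct a patient visit series
#'
#' @param patient_id Opaque patient label.
#' @param dose_prev Vector of doses (mg/day) prescribed at the preceding
#'   review; element 1 must be 0.
#' @param interval_days Days since the previous visit; element 1 must be 0,
#'   later elements positive.
#' @param ft4 Measured FT4 at each visit, pmol/l (positive).
#' @return An object of class `patient_series`: list with `patient_id` and
#'   `visits`, a data frame with columns `visit`, `dose_prev`,
#'   `interval_days`, `cumulative_days`, `ft4`.
#' @examples
#' s <- patient_series("16", dose_prev = c(0, 15, 17.5),
#'                     interval_days = c(0, 90, 78),
#'                     ft4 = c(14, 13, 10))
#' s$visits$cumulative_days  # 0 90 168
#' @export
patient_series <- function(patient_id, dose_prev, interval_days, ft4) {
  m <- length(ft4)
  if (length(dose_prev) != m || length(interval_days) != m)
    stop("dose_prev, interval_days and ft4 must have equal length",
         call. = FALSE)
  if (m < 2)
    stop(sprintf("patient %s: a series needs at least 2 visits", patient_id),
         call. = FALSE)
  if (dose_prev[1] != 0)
    stop(sprintf("patient %s: visit 1 must have dose_prev = 0", patient_id),
         call. = FALSE)
  if (interval_days[1] != 0)
    stop(sprintf("patient %s: visit 1 must have interval_days = 0",
                 patient_id), call. = FALSE)
  if (any(!is.finite(dose_prev)) || any(dose_prev < 0))
    stop(sprintf("patient %s: doses must be finite and non-negative",
                 patient_id), call. = FALSE)
  if (m > 1 && any(interval_days[-1] <= 0))
    stop(sprintf("patient %s: follow-up intervals must be positive",
                 patient_id), call. = FALSE)
  if (any(!is.finite(ft4)) || any(ft4 <= 0))
    stop(sprintf("patient %s: FT4 values must be positive", patient_id),
         call. = FALSE)
  structure(list(
    patient_id = as.character(patient_id),
    visits = data.frame(
      visit = seq_len(m),
      dose_prev = as.numeric(dose_prev),
      interval_days = as.numeric(interval_days),
      cumulative_days = cumsum(as.numeric(interval_days)),
      ft4 = as.numeric(ft4))
  ), class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("Patient %s: %d visits over %g days\n",
              x$patient_id, nrow(x$visits),
              max(x$visits$cumulative_days)))
  print(x$visits, row.names = FALSE)
  invisible(x)
}

#' Number of visits in a series
#' @param s A `patient_series`.
#' @return Integer visit count.
#' @export
n_visits <- function(s) {
  stopifnot(inherits(s, "patient_series"))
  nrow(s$visits)
}
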