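# Cohort evaluation protocol: slice each patient's series to the first x
# visits, fit, apply the acceptance tolerance, report the accuracy rate.

#' Slicing scheme for cohort evaluation
#'
#' @param x Number of leading visits kept (>= 2).
#' @param mode `"exact_first_x"` keeps only patients with at least `x`
#'   visits (truncated to `x`); `"at_most_first_x"` keeps every patient,
#'   truncated to `min(m, x)`.
#' @return An object of class `slice_scheme`.
#' @export
slice_scheme <- function(x, mode = c("exact_first_x", "at_most_first_x")) {
  mode <- match.arg(mode)
  stopifnot(x >= 2)
  structure(list(x = as.integer(x), mode = mode), class = "slice_scheme")
}

#' Slice a patient series to its leading visits
#'
#' @param s A [patient_series].
#' @param scheme A [slice_scheme].
#' @return A truncated `patient_series`, or `NULL` when the patient is
#'   excluded by an `exact_first_x` scheme (fewer than `x` visits).
#'   Cumulative times of retained visits are unchanged by truncation.
#' @export
slice_series <- function(s, scheme) {
  stopifnot(inherits(s, "patient_series"), inherits(scheme, "slice_scheme"))
  m <- n_visits(s)
  if (scheme$mode == "exact_first_x" && m < scheme$x) return(NULL)
  k <- min(m, scheme$x)
  if (k == m) return(s)
  patient_series(s$patient_id,
                 dose_prev = s$visits$dose_prev[seq_len(k)],
                 interval_days = s$visits$interval_days[seq_len(k)],
                 ft4 = s$visits$ft4[seq_len(k)])
}

#' Fit and score a whole cohort under a slicing scheme
#'
#' Every retained (sliced) series is fitted with [fit_patient()]; fits are
#' attempted down to 2 visits (flagged weakly determined below 3), and
#' non-convergent fits count as not accepted while staying in the
#' denominator. Per-patient seeds are derived deterministically from
#' `cfg$seed`.
#'
#' @param dataset List of [patient_series].
#' @param scheme A [slice_scheme].
#' @param cfg A [fit_config].
#' @return An object of class `cohort_report`: list with `n_patients`
#'   (entering after slicing), `n_accepted`, `accuracy_rate`, and
#'   `per_patient` (data frame: patient_id, m, converged, accepted,
#'   objective, weak_identifiability).
#' @export
evaluate_cohort <- function(dataset, scheme, cfg = fit_config()) {
  stopifnot(length(dataset) > 0, inherits(scheme, "slice_scheme"))
  rows <- list()
  for (i in seq_along(dataset)) {
    sl <- slice_series(dataset[[i]], scheme)
    if (is.null(sl)) next
    cfg_i <- cfg
    cfg_i$min_visits <- 2L
    cfg_i$seed <- (cfg$seed + 7919L * i) %% 2147483647L
    fr <- tryCatch(fit_patient(sl, cfg_i), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = dataset[[i]]$patient_id,
      m = n_visits(sl),
      converged = !is.null(fr) && fr$converged,
      accepted = !is.null(fr) && fr$accepted,
      objective = if (!is.null(fr)) fr$objective else NA_real_,
      weak_identifiability = is.null(fr) || fr$weak_identifiability ||
        n_visits(sl) < 3,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  n <- if (is.null(per)) 0L else nrow(per)
  acc <- if (is.null(per)) 0L else sum(per$accepted)
  structure(list(n_patients = n, n_accepted = acc,
                 accuracy_rate = if (n > 0) acc / n else NA_real_,
                 per_patient = per),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort evaluation: %d/%d accepted (accuracy %.1f%%)\n",
              x$n_accepted, x$n_patients, 100 * x$accuracy_rate))
  invisible(x)
}

#' Actual vs predicted FT4 table for one patient
#'
#' Per-visit comparison in the layout of published follow-up tables:
#' predictions at 1 decimal, with the baseline visit left blank (its FT4
#' anchors the initial condition rather than being predicted).
#'
#' @param s A [patient_series].
#' @param p An [atd_params] object.
#' @return Data frame with columns `visit`, `dose_prev`, `interval_days`,
#'   `actual`, `predicted`.
#' @export
actual_vs_predicted <- function(s, p) {
  stopifnot(inherits(s, "patient_series"))
  pred <- round(predicted_series(p, s), 1)
  pred[1] <- NA_real_
  data.frame(visit = s$visits$visit,
             dose_prev = s$visits$dose_prev,
             interval_days = s$visits$interval_days,
             actual = s$visits$ft4,
             predicted = pred)
}

#' Descriptive statistics of a visit dataset
#'
#' Mean, standard deviation, median, minimum and maximum of per-patient
#' visit counts, of all FT4 measurements, and of follow-up review
#' intervals.
#'
#' @param dataset Non-empty list of [patient_series].
#' @return Data frame with one row per item (`visits`, `ft4`,
#'   `interval_days`) and columns `mean`, `sd`, `median`, `min`, `max`.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(length(dataset) > 0)
  visits <- vapply(dataset, n_visits, integer(1))
  ft4 <- unlist(lapply(dataset, function(s) s$visits$ft4))
  intervals <- unlist(lapply(dataset,
                             function(s) s$visits$interval_days[-1]))
  if (!length(ft4)) stop("no FT4 values in dataset", call. = FALSE)
  stat_row <- function(x) c(mean = mean(x), sd = stats::sd(x),
                            median = stats::median(x), min = min(x),
                            max = max(x))
  out <- rbind(visits = stat_row(visits), ft4 = stat_row(ft4),
               interval_days = stat_row(intervals))
  as.data.frame(out)
}

#' Write a cohort report to disk
#'
#' @param report A `cohort_report`.
#' @param csv_path Per-patient table CSV path.
#' @param json_path Optional summary JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_cohort_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  utils::write.csv(report$per_patient, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(n_patients = report$n_patients,
                              n_accepted = report$n_accepted,
                              accuracy_rate = report$accuracy_rate),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
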