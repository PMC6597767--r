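# Virtual-patient generator.
#
# Emulates the structure of a Graves' disease titration cohort: an
# untreated baseline visit, then follow-up visits at irregular intervals
# under a stepped-down dose sequence, with FT4 generated from the
# closed-form kinetic model plus optional Gaussian assay noise. Ground
# truth is sampled so the initial-condition identity holds exactly:
# c1 = 1/y1 - c/a, which also guarantees the validity conditions at every
# non-negative (t, d) because c*(ic50+d)/(a*ic50) >= c/a > 1/y1 = -(c1) +
# c/a ... i.e. 1/y(t,d) >= 1/y1 > 0.

#' Specification of a synthetic titration cohort
#'
#' Ranges mirror the structure of real thyroid-function-test series:
#' untreated baseline FT4 20-90 pmol/l, steady-state (fully treated
#' asymptote at dose 0) 9-18 pmol/l, 2-10 visits per patient at 28-180 day
#' intervals, doses stepped down from 30 or 15 mg.
#'
#' @param n_patients Cohort size.
#' @param a_range Log-uniform sampling range for the synthesis rate,
#'   day^-1.
#' @param ic50_range Uniform sampling range for IC50, mg.
#' @param asymptote_range Uniform range for the untreated steady state
#'   `a/c`, pmol/l; the decay rate is derived as `c = a / asymptote`.
#' @param initial_ft4_range Uniform range for the baseline FT4, pmol/l.
#' @param visits_range Integer range of visits per patient.
#' @param interval_range Uniform range of review intervals, days.
#' @param noise_sd Additive Gaussian noise on measured FT4, pmol/l
#'   (0 = noiseless). Values are floored at 0.5 pmol/l.
#' @param policy Titration policy: `"step_down"` starts at 30 mg when the
#'   baseline exceeds 40 pmol/l (else 15 mg) and halves the dose (floor
#'   2.5 mg) whenever the model-predicted next FT4 falls below 20 pmol/l;
#'   `"none"` prescribes 0 mg throughout.
#' @param seed Master seed for the cohort.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 20L,
                           a_range = c(0.03, 8),
                           ic50_range = c(20, 120),
                           asymptote_range = c(9, 18),
                           initial_ft4_range = c(20, 90),
                           visits_range = c(2L, 10L),
                           interval_range = c(28, 180),
                           noise_sd = 0,
                           policy = c("step_down", "none"),
                           seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(n_patients >= 1, noise_sd >= 0,
            visits_range[1] >= 2, diff(initial_ft4_range) >= 0,
            asymptote_range[2] < initial_ft4_range[1])
  structure(list(n_patients = as.integer(n_patients), a_range = a_range,
                 ic50_range = ic50_range, asymptote_range = asymptote_range,
                 initial_ft4_range = initial_ft4_range,
                 visits_range = as.integer(visits_range),
                 interval_range = interval_range, noise_sd = noise_sd,
                 policy = policy, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample ground-truth parameters and a baseline FT4
#'
#' Draws `(a, ic50)` and the untreated steady state from the spec ranges,
#' derives `c = a / asymptote` and pins `c1` to the sampled baseline via
#' the initial-condition identity `c1 = 1/y1 - c/a`. Draws violating any
#' parameter invariant are rejected and resampled (a bounded budget
#' guards against degenerate specs).
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer seed for this draw.
#' @return List with `params` (an [atd_params]) and `y1` (baseline FT4,
#'   pmol/l).
#' @export
sample_truth <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    for (i in 1:1000) {
      a <- exp(stats::runif(1, log(spec$a_range[1]), log(spec$a_range[2])))
      ic50 <- stats::runif(1, spec$ic50_range[1], spec$ic50_range[2])
      yinf <- stats::runif(1, spec$asymptote_range[1],
                           spec$asymptote_range[2])
      y1 <- stats::runif(1, spec$initial_ft4_range[1],
                         spec$initial_ft4_range[2])
      cc <- a / yinf
      c1 <- 1 / y1 - cc / a
      p <- tryCatch(atd_params(a = a, c = cc, ic50 = ic50, c1 = c1),
                    error = function(e) NULL)
      if (!is.null(p) &&
          check_validity(p, t = c(0, 400), d = c(0, 60))$pass)
        return(list(params = p, y1 = y1))
    }
    stop("sample_truth: rejection budget exceeded; check spec ranges",
         call. = FALSE)
  })
}

#' Simulate one patient's visit series from known truth
#'
#' Visit 1 is the baseline `(d = 0, t = 0, y1 + noise)`; each follow-up
#' visit carries the dose chosen at the preceding review, the cumulative
#' time, and the model FT4 plus noise. The visit schedule and dose
#' sequence derive only from `schedule_seed` and the (noiseless) model,
#' so two simulations differing only in `noise_seed` share identical
#' doses and times.
#'
#' @param truth A list as returned by [sample_truth()] (`params`, `y1`),
#'   or an [atd_params] (then `y1 = initial_ft4(truth)`).
#' @param spec A [synthetic_spec] (schedule, policy and noise settings).
#' @param schedule_seed Seed for visit count, intervals and titration.
#' @param noise_seed Seed for the measurement-noise stream.
#' @param patient_id Label for the generated series.
#' @return A [patient_series]; the truth is attached as attribute
#'   `"truth"`.
#' @export
simulate_series <- function(truth, spec, schedule_seed, noise_seed,
                            patient_id = "sim") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(truth, "atd_params"))
    truth <- list(params = truth, y1 = initial_ft4(truth))
  p <- truth$params
  sched <- with_seed(schedule_seed, {
    mm <- seq(spec$visits_range[1], spec$visits_range[2])
    m <- if (length(mm) == 1L) mm else sample(mm, 1)
    intervals <- c(0, round(stats::runif(m - 1, spec$interval_range[1],
                                         spec$interval_range[2])))
    list(m = m, intervals = intervals)
  })
  m <- sched$m
  tcum <- cumsum(sched$intervals)
  doses <- numeric(m)  # doses[i] = dose prescribed at visit i-1
  if (spec$policy == "step_down") {
    current <- if (truth$y1 > 40) 30 else 15
    for (i in 2:m) {
      doses[i] <- current
      pred_next <- ft4_solution(p, tcum[i], doses[i])
      if (pred_next < 20) current <- max(current / 2, 2.5)
    }
  }
  y_true <- c(truth$y1,
              ft4_solution(p, tcum[-1], doses[-1]))
  y_obs <- if (spec$noise_sd > 0)
    with_seed(noise_seed,
              pmax(y_true + stats::rnorm(m, 0, spec$noise_sd), 0.5))
  else y_true
  s <- patient_series(patient_id, dose_prev = doses,
                      interval_days = sched$intervals, ft4 = y_obs)
  attr(s, "truth") <- truth
  s
}

#' Simulate a whole cohort
#'
#' Per-patient seeds are derived deterministically from `spec$seed`, with
#' disjoint schedule and noise streams; regeneration under the same spec
#' is byte-identical after serialization.
#'
#' @param spec A [synthetic_spec].
#' @return List with `series` (named list of [patient_series]) and
#'   `truths` (parallel list of truth objects).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  series <- list()
  truths <- list()
  for (i in seq_len(spec$n_patients)) {
    base <- (spec$seed + 104729L * i) %% 2147483647L
    truth <- sample_truth(spec, seed = base)
    id <- sprintf("sim%03d", i)
    series[[id]] <- simulate_series(truth, spec,
                                    schedule_seed = (base + 1L),
                                    noise_seed = (base + 2L),
                                    patient_id = id)
    truths[[id]] <- truth
  }
  list(series = series, truths = truths)
}

#' Load a synthetic-cohort specification from a YAML file
#'
#' Recognized keys match the arguments of [synthetic_spec()].
#'
#' @param path YAML file path.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_spec))
  vals <- vals[intersect(names(vals), known)]
  for (k in c("a_range", "ic50_range", "asymptote_range",
              "initial_ft4_range", "visits_range", "interval_range"))
    if (k %in% names(vals)) vals[[k]] <- as.numeric(unlist(vals[[k]]))
  do.call(synthetic_spec, vals)
}
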