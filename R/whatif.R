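# What-if solvers on F(t, d, y) = y - y(t, d) = 0.
#
# Given any two of {treatment time, daily dose, FT4 level} the third is
# solved for. Dose solving uses a uniform sign-change scan followed by
# bisection (monotonicity in d is not assumed; the first, i.e. smallest,
# root is returned -- the lowest effective dose matches the titration
# goal). Time solving inverts the reciprocal form in closed form.
# Infeasibility is part of the answer, never an exception. Rounding for
# report parity (1 dp FT4/dose, whole days) happens only in the table
# layer, never inside solvers.

.atd_answer <- function(value, residual, status,
                        bound_hit = NA_character_, reason = NA_character_,
                        unknown) {
  structure(list(value = value, residual = residual, status = status,
                 bound_hit = bound_hit, reason = reason, unknown = unknown),
            class = "atd_whatif")
}

#' @export
print.atd_whatif <- function(x, ...) {
  unit <- switch(x$unknown, y = "pmol/l", d = "mg", t = "days")
  if (x$status == "infeasible")
    cat(sprintf("what-if (%s): infeasible -- %s\n", x$unknown, x$reason))
  else
    cat(sprintf("what-if (%s): %.4g %s [%s, |F| = %.2g]\n",
                x$unknown, x$value, unit, x$status, x$residual))
  invisible(x)
}

#' Predict FT4 for a given time and dose
#'
#' @param p An [atd_params] object.
#' @param t Days since the initial review.
#' @param d Daily dose, mg.
#' @return An `atd_whatif` answer with the predicted FT4 (pmol/l);
#'   always `status = "solved"`.
#' @export
predict_ft4 <- function(p, t, d) {
  y <- ft4_solution(p, t, d)
  .atd_answer(y, 0, "solved", unknown = "y")
}

#' Solve for the daily dose reaching a target FT4 at a given time
#'
#' Scans `[0, dose_cap]` on a uniform grid for a sign change of
#' `F(t, ., y)` and refines the first bracket by bisection. If the target
#' lies outside the achievable FT4 range over the interval the answer is
#' infeasible and reports that range.
#'
#' @param p An [atd_params] object.
#' @param t Days since the initial review (positive).
#' @param y Target FT4, pmol/l.
#' @param dose_cap Maximum allowed dose, mg. Default 60 (carbimazole
#'   prescription cap).
#' @param grid_n Scan resolution (>= 64). Default 128.
#' @param tol Bisection half-width on the dose, mg. Default 1e-7.
#' @return An `atd_whatif` answer (`status` solved / infeasible /
#'   at_bound; the returned dose never exceeds `dose_cap`).
#' @examples
#' p2 <- atd_params(a_ic50 = 3.024, c = 0.003, a_ic50_c1 = -0.154,
#'                  ic50 = 58.151)
#' round(solve_dose(p2, t = 35, y = 12)$value, 1)  # 44.1
#' @export
solve_dose <- function(p, t, y, dose_cap = 60, grid_n = 128, tol = 1e-7) {
  stopifnot(t > 0, y > 0, dose_cap > 0, grid_n >= 64)
  dg <- seq(0, dose_cap, length.out = grid_n)
  fg <- ft4_solution(p, t, dg) - y
  hit <- which(fg == 0)
  if (length(hit)) {
    d0 <- dg[hit[1]]
    st <- if (abs(d0 - dose_cap) <= tol) "at_bound" else "solved"
    return(.atd_answer(d0, 0, st,
                       bound_hit = if (st == "at_bound") "dose_cap" else NA,
                       unknown = "d"))
  }
  sgn <- sign(fg)
  k <- which(sgn[-1] != sgn[-grid_n])
  if (!length(k)) {
    rng <- range(fg + y)
    return(.atd_answer(NA_real_, NA_real_, "infeasible",
                       reason = sprintf(
                         "target %.3g outside achievable FT4 range [%.3g, %.3g] at t = %g with dose cap %g",
                         y, rng[1], rng[2], t, dose_cap),
                       unknown = "d"))
  }
  lo <- dg[k[1]]; hi <- dg[k[1] + 1L]
  flo <- fg[k[1]]
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    fmid <- ft4_solution(p, t, mid) - y
    if (fmid == 0) { lo <- mid; hi <- mid; break }
    if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid } else hi <- mid
  }
  d0 <- (lo + hi) / 2
  res <- abs(ft4_solution(p, t, d0) - y)
  st <- if (d0 >= dose_cap - max(tol, 1e-6)) "at_bound" else "solved"
  .atd_answer(min(d0, dose_cap), res, st,
              bound_hit = if (st == "at_bound") "dose_cap" else NA,
              unknown = "d")
}

#' Solve for the time to reach a target FT4 under a given dose
#'
#' Closed-form inversion of the reciprocal identity:
#' `t = -(ic50+d)/(a*ic50) * log((1/y - c*(ic50+d)/(a*ic50)) / c1)`,
#' valid when the log argument lies in `(0, 1]`. A target at or below the
#' dose's steady state is never attained; a target above the starting
#' level `y(0, d)` lies in the past. Both are reported infeasible.
#'
#' @param p An [atd_params] object.
#' @param d Daily dose, mg.
#' @param y Target FT4, pmol/l.
#' @param time_cap Reporting horizon, days. Default 730; solutions beyond
#'   it are flagged `at_bound` (value still returned).
#' @return An `atd_whatif` answer with the time in days.
#' @examples
#' p2 <- atd_params(a_ic50 = 3.024, c = 0.003, a_ic50_c1 = -0.154,
#'                  ic50 = 58.151)
#' round(solve_time(p2, d = 60, y = 10)$value)  # 42
#' @export
solve_time <- function(p, d, y, time_cap = 730) {
  stopifnot(inherits(p, "atd_params"), d >= 0, y > 0)
  ab <- p$a * p$ic50 / (p$ic50 + d)
  arg <- (1 / y - p$c * (p$ic50 + d) / (p$a * p$ic50)) / p$c1
  if (arg <= 0)
    return(.atd_answer(NA_real_, NA_real_, "infeasible",
                       reason = sprintf(
                         "target %.3g is at or below the steady state %.3g at dose %g",
                         y, ft4_asymptote(p, d), d),
                       unknown = "t"))
  if (arg > 1)
    return(.atd_answer(NA_real_, NA_real_, "infeasible",
                       reason = sprintf(
                         "target %.3g exceeds the starting level %.3g at dose %g",
                         y, ft4_solution(p, 0, d), d),
                       unknown = "t"))
  t0 <- -log(arg) / ab
  res <- abs(ft4_solution(p, t0, d) - y)
  if (t0 > time_cap)
    return(.atd_answer(t0, res, "at_bound", bound_hit = "time_cap",
                       unknown = "t"))
  .atd_answer(t0, res, "solved", unknown = "t")
}

#' Predicted-FT4 grid over doses and review periods
#'
#' One row per (dose, time) pair, FT4 rounded to 1 decimal for report
#' parity with published dose-by-period tables.
#'
#' @param p An [atd_params] object.
#' @param times Review periods, days (non-empty).
#' @param doses Daily doses, mg (non-empty).
#' @return Data frame with columns `dose_mg`, `time_days`, `ft4`.
#' @export
dose_grid <- function(p, times, doses) {
  stopifnot(length(times) > 0, length(doses) > 0)
  g <- expand.grid(time_days = times, dose_mg = doses,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(match(g$dose_mg, doses), match(g$time_days, times)), ]
  g$ft4 <- round(ft4_solution(p, g$time_days, g$dose_mg), 1)
  rownames(g) <- NULL
  g[, c("dose_mg", "time_days", "ft4")]
}

#' Optimal-dose grid over FT4 targets and review periods
#'
#' One row per (target, time) pair with the [solve_dose()] result rounded
#' to 0.1 mg; infeasible cells carry `NA` and their status.
#'
#' @param p An [atd_params] object.
#' @param targets Target FT4 values, pmol/l (non-empty).
#' @param times Review periods, days (non-empty).
#' @param dose_cap Maximum dose, mg. Default 60.
#' @return Data frame with columns `target_ft4`, `time_days`, `dose_mg`,
#'   `status`.
#' @export
target_grid <- function(p, targets, times, dose_cap = 60) {
  stopifnot(length(targets) > 0, length(times) > 0)
  rows <- expand.grid(time_days = times, target_ft4 = targets,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(match(rows$target_ft4, targets),
                     match(rows$time_days, times)), ]
  ans <- Map(function(y, t) solve_dose(p, t, y, dose_cap = dose_cap),
             rows$target_ft4, rows$time_days)
  rows$dose_mg <- round(vapply(ans, function(a) a$value, numeric(1)), 1)
  rows$status <- vapply(ans, function(a) a$status, character(1))
  rownames(rows) <- NULL
  rows[, c("target_ft4", "time_days", "dose_mg", "status")]
}

#' Predicted FT4 trajectory under a constant dose
#'
#' Samples the closed-form solution on a regular time grid, for curve
#' export and plotting. Strictly decreasing whenever `c1 < 0`.
#'
#' @param p An [atd_params] object.
#' @param d Daily dose, mg.
#' @param horizon Final day of the grid.
#' @param step Grid step, days (positive). Default 1.
#' @return Data frame of class `atd_trajectory` with columns `day`, `ft4`.
#' @export
trajectory <- function(p, d, horizon, step = 1) {
  stopifnot(step > 0, horizon > 0)
  days <- seq(0, horizon, by = step)
  out <- data.frame(day = days, ft4 = ft4_solution(p, days, d))
  attr(out, "dose") <- d
  class(out) <- c("atd_trajectory", "data.frame")
  out
}

#' @export
plot.atd_trajectory <- function(x, ...) {
  plot(x$day, x$ft4, type = "l", xlab = "time (days)",
       ylab = "FT4 (pmol/l)",
       main = sprintf("Predicted FT4, dose %g mg/day", attr(x, "dose")),
       ...)
  invisible(x)
}
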