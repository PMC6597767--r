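# Closed-form FT4 kinetics under Hill-type dose inhibition.
#
# State equation: dy/dt = A*B(d)*y - C*y^2 with B(d) = ic50/(ic50+d),
# a Bernoulli ODE (n = 2) linearized by u = 1/y. All evaluation routes
# through the reciprocal identity
#   1/y(t,d) = c*(ic50+d)/(a*ic50) + c1*exp(-a*ic50*t/(ic50+d)),
# which is algebraically equivalent to the direct exponential solution but
# cannot overflow: realistic visit times give exponents a*ic50*t/(ic50+d)
# beyond 700, where exp() in the direct form exceeds double range while
# exp(-x) here underflows harmlessly to 0.

#' Hill-type synthesis inhibition factor
#'
#' Fraction of the FT4 synthesis rate that survives a daily dose `d` of an
#' anti-thyroid drug: `ic50 / (ic50 + d)`, i.e. one minus the Hill effect
#' `d/(ic50 + d)`. Equal to 1 with no drug, 0.5 at `d = ic50`, and tends to
#' 0 as the dose grows.
#'
#' @param d Daily dose, mg (non-negative; vectorized).
#' @param ic50 Half-maximal inhibitory dose, mg (positive scalar).
#' @return Numeric vector of fractions in `(0, 1]`, strictly decreasing
#'   in `d`.
#' @export
inhibition_factor <- function(d, ic50) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative", call. = FALSE)
  if (!is.numeric(ic50) || length(ic50) != 1L || !is.finite(ic50) ||
      ic50 <= 0)
    stop("`ic50` must be a positive scalar", call. = FALSE)
  ic50 / (ic50 + d)
}

# reciprocal of y(t,d); core primitive shared by the public operations
.inv_ft4 <- function(p, t, d) {
  ab <- p$a * p$ic50 / (p$ic50 + d)
  p$c * (p$ic50 + d) / (p$a * p$ic50) + p$c1 * exp(-ab * t)
}

#' FT4 concentration at time t under a constant daily dose
#'
#' Evaluates the closed-form solution of the kinetic ODE through its
#' overflow-safe reciprocal form. `t` and `d` are recycled to a common
#' length.
#'
#' @param p An [atd_params] object.
#' @param t Days since the initial review (non-negative).
#' @param d Daily dose, mg (non-negative).
#' @return FT4 concentration(s), pmol/l.
#' @seealso [ft4_asymptote()], [ft4_derivative()], [taylor_ft4()]
#' @examples
#' p2 <- atd_params(a_ic50 = 3.024, c = 0.003, a_ic50_c1 = -0.154,
#'                  ic50 = 58.151)
#' round(ft4_solution(p2, t = 35, d = 3), 1)  # 19.4
#' @export
ft4_solution <- function(p, t, d) {
  stopifnot(inherits(p, "atd_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative", call. = FALSE)
  n <- max(length(t), length(d))
  t <- rep_len(t, n); d <- rep_len(d, n)
  inv <- .inv_ft4(p, t, d)
  bad <- which(inv <= 0)
  if (length(bad))
    stop(sprintf(
      "validity condition violated at point %d (t = %g, d = %g): %s",
      bad[1], t[bad[1]], d[bad[1]],
      "denominator of the closed-form solution is non-positive"),
      call. = FALSE)
  1 / inv
}

#' Initial FT4 implied by a parameter set
#'
#' The untreated level at `t = 0`: `a / (c + a*c1)`.
#'
#' @param p An [atd_params] object.
#' @return FT4 at `(t = 0, d = 0)`, pmol/l.
#' @export
initial_ft4 <- function(p) {
  stopifnot(inherits(p, "atd_params"))
  p$a / (p$c + p$a * p$c1)
}

#' Steady-state FT4 under a constant dose
#'
#' The large-time limit `a*ic50 / (c*(ic50 + d))`, strictly decreasing in
#' the dose. FT4 approaches, but never attains, this level.
#'
#' @param p An [atd_params] object.
#' @param d Daily dose, mg (non-negative; vectorized).
#' @return Asymptotic FT4 concentration(s), pmol/l.
#' @export
ft4_asymptote <- function(p, d) {
  stopifnot(inherits(p, "atd_params"))
  if (any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative", call. = FALSE)
  p$a * p$ic50 / (p$c * (p$ic50 + d))
}

#' Rate of change of FT4
#'
#' `dy/dt` evaluated at the closed-form solution, i.e. the right-hand side
#' `a*B(d)*y - c*y^2` of the kinetic ODE. Negative at every `t >= 0`
#' whenever `c1 < 0`.
#'
#' @inheritParams ft4_solution
#' @return Rate(s) in pmol/l/day.
#' @export
ft4_derivative <- function(p, t, d) {
  y <- ft4_solution(p, t, d)
  d <- rep_len(d, length(y))
  p$a * inhibition_factor(d, p$ic50) * y - p$c * y^2
}

#' Check the validity conditions of the closed-form solution
#'
#' The solution is well defined at `(t, d)` when
#' `C*exp(A*B(d)*t) + A*B(d)*C1 > 0` and `c1 < 0`. The exponential
#' condition is evaluated in log form,
#' `(ic50+d)*log(a*ic50*(-c1)) - t*a*ic50 - (ic50+d)*log(c*(ic50+d)) < 0`,
#' so that no overflow can occur. This is a reporting operation: it never
#' throws for invalid points.
#'
#' @param p An [atd_params] object (or a bare list with the same fields,
#'   so candidate parameter sets can be screened before construction).
#' @param t,d Evaluation grid, recycled to a common length.
#' @return An object of class `atd_validity`: list with `points` (data
#'   frame of `t`, `d`, `log_condition`, `ok`, `reason`), `c1_ok` and
#'   overall `pass`.
#' @export
check_validity <- function(p, t, d) {
  stopifnot(is.list(p), all(c("a", "c", "ic50", "c1") %in% names(p)))
  n <- max(length(t), length(d))
  t <- rep_len(t, n); d <- rep_len(d, n)
  c1_ok <- is.finite(p$c1) && p$c1 < 0
  if (c1_ok) {
    lc <- (p$ic50 + d) * log(p$a * p$ic50 * (-p$c1)) -
      t * p$a * p$ic50 -
      (p$ic50 + d) * log(p$c * (p$ic50 + d))
    ok <- lc < 0
    reason <- ifelse(ok, "", "positivity condition fails")
  } else {
    lc <- rep(NA_real_, n)
    ok <- rep(FALSE, n)
    reason <- rep("c1 must be negative", n)
  }
  structure(list(
    points = data.frame(t = t, d = d, log_condition = lc, ok = ok,
                        reason = reason, stringsAsFactors = FALSE),
    c1_ok = c1_ok,
    pass = c1_ok && all(ok)
  ), class = "atd_validity")
}

#' @export
print.atd_validity <- function(x, ...) {
  cat(sprintf("Validity check: %s (%d/%d points ok, c1 %s)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$points$ok), nrow(x$points),
              if (x$c1_ok) "negative" else "NOT negative"))
  invisible(x)
}

#' Second-order Taylor shortcut for FT4
#'
#' Bedside approximation replacing the exponential in the reciprocal form
#' by its quadratic truncation:
#' `y ~ 1/z` with
#' `z = c1 + c*(ic50+d)/(a*ic50) - a*c1*B(d)*t + 0.5*c1*a^2*B(d)^2*t^2`.
#' Exact at `t = 0`; useful while `a*B(d)*t` stays small. When the
#' truncation drives `z` non-positive the approximation has diverged --
#' this is flagged, not an error.
#'
#' @inheritParams ft4_solution
#' @return A list with `value` (FT4 in pmol/l, `NA` where diverged) and
#'   `diverged` (logical), both of the recycled common length.
#' @export
taylor_ft4 <- function(p, t, d) {
  stopifnot(inherits(p, "atd_params"))
  n <- max(length(t), length(d))
  t <- rep_len(t, n); d <- rep_len(d, n)
  b <- inhibition_factor(d, p$ic50)
  x <- p$a * b * t
  z <- p$c * (p$ic50 + d) / (p$a * p$ic50) +
    p$c1 * (1 - x + 0.5 * x^2)
  diverged <- z <= 0
  value <- ifelse(diverged, NA_real_, 1 / z)
  list(value = value, diverged = diverged)
}
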