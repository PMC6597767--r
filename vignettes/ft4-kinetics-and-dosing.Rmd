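---
title: "FT4 kinetics and personalized anti-thyroid dosing: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FT4 kinetics and personalized anti-thyroid dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ft4dose)
```

## The kinetic model

Free thyroxine (FT4, `y`, pmol/l) in a hyperthyroid patient treated with a
thionamide anti-thyroid drug at a constant daily dose `d` (mg) is modelled
by

$$\frac{dy}{dt} = A\,B(d)\,y - C\,y^2, \qquad
  B(d) = \frac{IC_{50}}{IC_{50}+d},$$

where `A` (/day) is the synthesis/secretion rate constant, `C`
(l/pmol/day) the decay rate constant, and `B(d)` the fraction of synthesis
surviving the drug — one minus the Hill effect `d/(IC50+d)`, equal to 1/2
at `d = IC50`. Second-order decay reflects thyroxine inducing its own
catabolism (its half-life shortens in thyrotoxicosis and lengthens in
hypothyroidism). This is a Bernoulli equation of order 2: the substitution
`u = 1/y` makes it linear, and the solution with integration constant
`C1` is, in the form this package evaluates,

$$\frac{1}{y(t,d)} = \frac{C\,(IC_{50}+d)}{A\,IC_{50}}
   + C_1\, e^{-A\,IC_{50}\,t/(IC_{50}+d)}.$$

For `C1 < 0`, `y` is positive, strictly decreasing in `t`, and tends to
the steady state `A·IC50/(C(IC50+d))` — the lowest level a given dose can
ever achieve. The model deliberately excludes TSH and
hypothalamus–pituitary feedback (hysteresis), relapse dynamics and
block-and-replace regimens.

### Why the reciprocal form

The textbook way to write the solution multiplies numerator and
denominator by `exp(A·B·t)`. That form overflows IEEE doubles in entirely
routine use: a follow-up visit at `t = 203` days on 7.5 mg with one of the
fitted parameter sets shipped in the test suite gives an exponent of about
708.6, just past the largest representable double. The reciprocal form is
bit-for-bit algebraically identical (the equivalence is property-tested to
relative 1e-10 against the direct form at safe exponents) and only ever
*under*flows, harmlessly, to the asymptote. Every operation in the package
routes through it; `check_validity()` likewise evaluates the positivity
condition in log form.

A consequence worth knowing: past roughly 36 relaxation constants
(`A·B(d)·t` ≳ 36) the solution saturates at the asymptote *to machine
precision*. Strict monotonicity and inverse solves are then no longer
numerically meaningful, which is why the property tests sample times on
the kinetic scale, and why `solve_time()` reports a target at or below the
asymptote as infeasible rather than returning an astronomically large
time.

### Validity conditions and strictness margins

The solution is well defined where
`C e^{A B t} + A B C_1 > 0` and `C1 < 0`. Strict inequalities have no
width in floating point, so they are enforced with a configurable margin
`eps = 1e-8` (`c1 <= -eps`; positivity `>= eps` inside the fitter).
The margin is far below any physiologically distinguishable difference at
the 0.1 pmol/l reporting resolution.

### The data convention

Visit `i` of a series carries `(d_{i-1}, t_i, y_i)`: the dose prescribed at
the *previous* review, the *cumulative* days since the initial review, and
the measured FT4. Visit 1 is the untreated baseline (`d_0 = 0`,
`t_1 = 0`). Predictions plug the cumulative time and the latest dose into
the single-dose closed form — there is deliberately *no* piecewise
integration across dose changes. This reproduces the established
evaluation convention for this model family faithfully; it is a modelling
quirk, not an oversight, and "fixing" it would change every downstream
number. CSV storage keeps intervals, never cumulative time, which is
derived on load (this avoids a genuine ambiguity we observed in published
visit tables).

## Parameter estimation

For one patient with `m` visits the fitted criterion is

$$\min_{A, C, IC_{50}, C_1} \frac{1}{m-1}\sum_{i=2}^{m}
  \bigl(f(A,IC_{50},C,C_1,d_{i-1},t_i) - y_i\bigr)^2$$

subject to the initial condition `A − y₁(C + A·C1) = 0`, the validity
inequalities at every visit (log form), `A, C > 0 > C1`, and
`0 < IC50 ≤ 150` mg (the accepted prescription bound). The baseline visit
anchors the equality constraint and is excluded from the objective.

Design choices, each genuinely open and decided once:

* **Equality elimination.** The initial condition is solved exactly for
  `C1 = 1/y₁ − C/A`, removing one degree of freedom and making the
  equality residual identically zero for every returned fit. A useful
  corollary (property-tested): once the equality holds, the baseline
  validity inequality holds automatically, since
  `C + A·C1 = A/y₁ > 0`.
* **Log-space box constraints.** The remaining `(A, C, IC50)` are
  optimized as logarithms, so positivity and the IC50 cap become box
  bounds rather than fragile penalties; only the validity inequalities and
  the `C1` sign carry smooth quadratic penalties (weight 1e8).
* **Solver.** `stats::nlminb` (quasi-Newton PORT with box bounds),
  gradients by its internal finite differences — with three parameters
  and at most a couple of dozen residuals, analytic gradients buy nothing
  measurable.
* **Multistart.** Up to `multistart_count` (default 40) starts: a
  deterministic heuristic grid (steady-state guesses from the observed FT4
  floor crossed with spanning values of `A` and `IC50`) topped up with
  seeded random draws — `A` log-uniform on [1e-3, 1e2], `IC50` uniform on
  (0, 150], `C` log-uniform on [1e-4, 10], redrawn until the pinned `C1`
  is negative. The feasible converged candidate with the lowest objective
  wins; ties and candidate objectives are recorded so dominance is
  testable. Same series + same seed ⇒ identical result.
* **Convergence acceptance.** Solver success *and* post-hoc constraint
  violation below 1e-6 *and* finite objective. Non-convergence is a
  result (`converged = FALSE`), never an exception.
* **Tolerance statistic.** A fit is *accepted* when its deviation
  statistic over follow-up visits is ≤ 4.5 pmol/l (inclusive). "Average
  deviation" is ambiguous between mean absolute error, maximum error and
  RMSE; the default is the mean absolute deviation, configurable via
  `fit_config(tolerance_stat = )`.
* **Identifiability.** With fewer than two distinct nonzero doses only
  the lumped `A·IC50/(IC50+d)` is informed per dose level, so `A` and
  `IC50` are weakly identified; the fit proceeds but carries
  `weak_identifiability = TRUE`. Predictions (what the tolerance test
  measures) remain well determined.

Exact reproduction of any particular published parameter estimate is not a
goal: the problem has local optima and the original solver and starting
points are unknowable. What is reproducible — and tested — is the
*predicted trajectory*: on model-true (noiseless) synthetic patients the
fitted predictions match the generating series to well under 0.1 pmol/l at
every observation time.

## What-if solvers

With fitted parameters, `F(t, d, y) = y − y(t, d) = 0` links the three
clinical quantities; any two determine the third.

* `predict_ft4(p, t, d)` — direct evaluation.
* `solve_dose(p, t, y)` — scans `[0, dose_cap]` (default cap 60 mg, a
  default rather than a hard-coded limit) on a ≥64-point grid for a sign
  change, then bisects (as the defining equation suggests) to well below
  0.001 mg. Monotonicity in `d` is *not* assumed; if several roots exist
  the smallest dose is returned, matching the titration goal of the lowest
  effective dose. Targets outside the achievable range come back
  `status = "infeasible"` with that range; roots at the cap are
  `at_bound`.
* `solve_time(p, d, y)` — closed-form inversion of the reciprocal form,
  `t = −(IC50+d)/(A·IC50) · \log[(1/y − C(IC50+d)/(A·IC50))/C_1]`, valid
  when the log argument is in (0, 1]; below-asymptote and above-baseline
  targets are infeasible. Cross-validated against bisection to 1e-4 days
  in the tests.

Report-layer tables (`dose_grid()`, `target_grid()`, `trajectory()`) round
FT4 and dose to one decimal and days to integers — rounding never happens
inside solvers. One published target row (target FT4 15) is internally
inconsistent with its own formula constants — its printed doses reproduce
FT4 15.1, and exact inversion gives 14.0 mg where 13.4 is printed — so
tests pin the verified rows and document the discrepancy rather than
matching it.

### The Taylor shortcut

For mental arithmetic at the bedside, `taylor_ft4()` replaces the
exponential by its second-order truncation. It is exact at `t = 0`, and
its relative error grows as the cube of `A·B(d)·t` (bounded by
`K·(ABt)³` with `K = 1.3` fitted once on the reference grid and frozen in
the tests). Beyond `ABt ≈ 1.5–2` the truncated reciprocal can go negative;
that is flagged as divergence — a non-exceptional outcome — rather than
returning a nonsense concentration.

## Virtual patients and the evaluation protocol

The generator emulates the *structure* of a titration cohort so the whole
pipeline is testable without patient data: baseline FT4 uniform on 20–90
pmol/l, untreated steady state on 9–18 pmol/l (so every virtual patient
genuinely declines under observation), `A` log-uniform on 0.03–8 /day,
`IC50` uniform on 20–120 mg — ranges bracketing the fitted parameter sets
shipped in the test fixtures. Pinning `C1 = 1/y₁ − C/A` makes every draw
globally valid for all `t, d ≥ 0`, so rejection sampling almost never
rejects. Visits (2–10 per patient) fall at 28–180-day intervals; the
default titration policy starts at 30 mg when baseline FT4 exceeds 40
pmol/l (else 15 mg) and halves the dose (floor 2.5 mg) whenever the
model-predicted next FT4 drops below 20 pmol/l — a plausible step-down
fixture, not a clinical recommendation. Measurement noise is additive
Gaussian (default sd 0) floored at 0.5 pmol/l, with the noise stream
seeded separately from the schedule stream so noise replicates share
schedules.

What the generator does *not* emulate: assay-specific error structure,
dose non-adherence, TSH feedback, relapse, or the irregular opportunistic
scheduling of real clinics. Passing recovery tests therefore demonstrates
correctness of the estimation machinery on model-true data, not clinical
validity on real cohorts.

`evaluate_cohort()` implements the slice-and-check protocol: truncate each
series to its first `x` visits (`exact_first_x` drops patients with fewer
than `x`; `at_most_first_x` keeps everyone), fit, and report the fraction
of accepted fits. Two-visit patients under at-most schemes are fitted but
flagged under-determined; non-convergent fits count against the rate while
staying in the denominator. On noiseless cohorts of 20 virtual patients
with ≥4 visits the accuracy rate is 1.0; at noise sd 2.25 pmol/l (half the
acceptance tolerance) it stays above 0.8. Cohort-level accuracy against
the original 49-patient clinical dataset cannot be recomputed here — that
data is not redistributable with the package — so those figures are
treated as soft, structurally analogous checks via the synthetic cohort.

## Problem sizes and runtime

Default test problem sizes were chosen to exercise every code path at
interactive speeds: 1e4 random parameter draws for algebraic and
monotonicity sweeps, 20–25 draws for ODE-integrator cross-checks
(`deSolve::lsoda` at rtol 1e-10), 50–60 round-trip inversions, and 20-patient
cohorts for recovery (noiseless) and noise-envelope runs. A full
`fit_patient()` with 40 starts takes well under a second; the complete
suite runs in about a minute.

## Known limitations

* One patient at a time: no pooling, no mixed-effects estimation, and no
  uncertainty quantification (confidence intervals, bootstrap) on the
  fitted parameters.
* The dose enters as a constant between consecutive visits through the
  plug-in convention above; rapidly alternating regimens are outside the
  model's vocabulary.
* Weak identifiability with monotone dose sequences is flagged, not
  resolved; resolving it would need design changes (two well-separated
  nonzero doses), which is a clinical matter.
* The untreated (`d = 0`) trajectory still declines toward `A/C` — this
  model describes treated dynamics anchored at a hyperthyroid baseline,
  not disease progression off therapy.
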