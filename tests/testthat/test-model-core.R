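test_that("inhibition factor follows the Hill effect", {
  expect_equal(inhibition_factor(50, 50), 0.5)
  expect_equal(inhibition_factor(0, 50), 1.0)
  expect_lt(inhibition_factor(1e6 * 50, 50), 1e-5)
  d <- seq(0, 60, by = 5)
  expect_true(all(diff(inhibition_factor(d, 58.151)) < 0))
  expect_error(inhibition_factor(-1, 50), "non-negative")
  expect_error(inhibition_factor(10, 0), "positive")
})

test_that("closed-form FT4 reproduces worked values and the t = 0 identity", {
  p2 <- patient2_params()
  expect_equal(round(ft4_solution(p2, 35, 3), 1), 19.4)
  expect_equal(ft4_solution(p2, 0, 0), p2$a / (p2$c + p2$a * p2$c1))
  expect_equal(round(ft4_solution(p2, 7, 30), 1), 21.1)
})

test_that("evaluation is overflow-safe at exponents near 708", {
  p23 <- patient23_params()
  # a*ic50*t/(ic50+d) ~ 708.6 here; the direct exponential form overflows
  ab <- p23$a * p23$ic50 / (p23$ic50 + 7.5)
  expect_gt(ab * 203, 700)
  y <- ft4_solution(p23, 203, 7.5)
  expect_true(is.finite(y))
  expect_equal(round(y, 1), 14.2)
})

test_that("invalid points raise a validity error naming the point", {
  p <- atd_params(a = 1, c = 0.01, ic50 = 50, c1 = -0.02)
  expect_error(ft4_solution(p, 0, 0), "validity.*t = 0, d = 0")
})

test_that("asymptote matches the large-time limit and decreases in dose", {
  p2 <- patient2_params()
  expect_equal(round(ft4_asymptote(p2, 0), 1), 17.3)
  expect_equal(ft4_asymptote(patient16_params(), 15), 11.611, tolerance = 1e-3)
  d <- seq(0, 60, by = 5)
  expect_true(all(diff(ft4_asymptote(p2, d)) < 0))
  gaps <- abs(ft4_solution(p2, c(10, 50, 200, 1000), 5) -
                ft4_asymptote(p2, 5))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-6)
})

test_that("derivative is negative, matches the ODE right-hand side and a
           finite-difference oracle", {
  p2 <- patient2_params()
  tt <- c(0, 1, 10, 35, 100)
  expect_true(all(ft4_derivative(p2, tt, 3) < 0))
  y <- ft4_solution(p2, 35, 3)
  rhs <- p2$a * inhibition_factor(3, p2$ic50) * y - p2$c * y^2
  expect_equal(ft4_derivative(p2, 35, 3), rhs, tolerance = 1e-10)
  h <- 1e-4
  fd <- (ft4_solution(p2, 35 + h, 3) - ft4_solution(p2, 35 - h, 3)) / (2 * h)
  expect_equal(ft4_derivative(p2, 35, 3), fd, tolerance = 1e-6)
  # near-zero c1: essentially flat tail
  pf <- atd_params(a = 0.05, c = 0.003, ic50 = 58, c1 = -1e-12,
                   strict_margin = 1e-13)
  expect_lt(abs(ft4_derivative(pf, 500, 0)), 1e-6)
})

test_that("validity report flags positive c1 and passes valid parameter
           grids", {
  p2 <- patient2_params()
  grid_t <- rep(c(0, 35, 203), each = 3)
  grid_d <- rep(c(0, 7.5, 60), times = 3)
  expect_true(check_validity(p2, grid_t, grid_d)$pass)
  bad <- check_validity(list(a = 1, c = 0.01, ic50 = 50, c1 = 0.01), 0, 0)
  expect_false(bad$pass)
  expect_false(bad$c1_ok)
  expect_match(bad$points$reason[1], "c1 must be negative")
})

test_that("Taylor shortcut is exact at t = 0, accurate for small ABt, and
           flags divergence beyond its radius", {
  p2 <- patient2_params()
  for (d in c(0, 13, 60))
    expect_equal(taylor_ft4(p2, 0, d)$value, ft4_solution(p2, 0, d))
  ty <- taylor_ft4(p2, 1, 0)
  expect_false(ty$diverged)
  expect_lt(abs(ty$value - ft4_solution(p2, 1, 0)) / ft4_solution(p2, 1, 0),
            1e-3)
  div <- taylor_ft4(p2, 56, 13.4)
  expect_true(div$diverged)
  expect_true(is.na(div$value))
})

test_that("reciprocal identity agrees with the direct exponential form", {
  draws <- draw_valid_params(10000, seed = 42)
  set.seed(43)
  d <- runif(nrow(draws), 0, 60)
  # keep exponents safely below double overflow for the direct oracle
  tmax <- 600 * (draws$ic50 + d) / (draws$a * draws$ic50)
  t <- runif(nrow(draws), 0, pmin(tmax, 400))
  for (i in seq_len(nrow(draws))) {
    p <- params_from_row(draws, i)
    expect_equal(ft4_solution(p, t[i], d[i]), ft4_direct_form(p, t[i], d[i]),
                 tolerance = 1e-10)
  }
})

test_that("closed form matches adaptive numerical integration of the ODE", {
  library(deSolve)
  draws <- draw_valid_params(20, seed = 7)
  set.seed(8)
  doses <- runif(20, 0, 60)
  times <- seq(0, 400, by = 25)
  for (i in 1:20) {
    p <- params_from_row(draws, i)
    d <- doses[i]
    b <- inhibition_factor(d, p$ic50)
    y0 <- p$a * b / (p$c + p$a * b * p$c1)
    sol <- deSolve::lsoda(
      y = c(y = y0), times = times,
      func = function(t, y, parms) list(p$a * b * y - p$c * y^2),
      rtol = 1e-10, atol = 1e-12)
    expect_equal(ft4_solution(p, times, d), unname(sol[, "y"]),
                 tolerance = 1e-6)
  }
})

test_that("FT4 decreases in time and is sandwiched between asymptote and
           start", {
  draws <- draw_valid_params(10000, seed = 99)
  set.seed(100)
  d <- runif(nrow(draws), 0, 60)
  # sample on the kinetic time scale u = A*B(d)*t, keeping u below ~25 so
  # the strict decline stays representable in double precision (beyond
  # that the solution saturates at the asymptote to machine accuracy)
  ab <- draws$a * draws$ic50 / (draws$ic50 + d)
  t1 <- runif(nrow(draws), 0, 20) / ab
  t2 <- t1 + runif(nrow(draws), 0.5, 5) / ab
  for (i in sample(nrow(draws), 200)) {  # elementwise spot-check
    p <- params_from_row(draws, i)
    expect_lt(ft4_solution(p, t2[i], d[i]), ft4_solution(p, t1[i], d[i]))
  }
  # vectorized full sweep
  y1 <- mapply(function(i) ft4_solution(params_from_row(draws, i), t1[i],
                                        d[i]), seq_len(nrow(draws)))
  y2 <- mapply(function(i) ft4_solution(params_from_row(draws, i), t2[i],
                                        d[i]), seq_len(nrow(draws)))
  y0 <- mapply(function(i) ft4_solution(params_from_row(draws, i), 0, d[i]),
               seq_len(nrow(draws)))
  ya <- mapply(function(i) ft4_asymptote(params_from_row(draws, i), d[i]),
               seq_len(nrow(draws)))
  expect_true(all(y2 < y1))
  expect_true(all(ya < y2 & y1 <= y0))
})

test_that("Taylor truncation error scales as the cube of ABt", {
  # K fitted once on this reference grid during development, then frozen
  K <- 1.3
  p2 <- patient2_params()
  for (d in c(0, 5, 13, 30, 60)) {
    ab <- p2$a * p2$ic50 / (p2$ic50 + d)
    tt <- seq(0.5, 0.3 / ab, length.out = 25)
    exact <- ft4_solution(p2, tt, d)
    approx <- taylor_ft4(p2, tt, d)$value
    expect_true(all(abs(approx - exact) / exact <= K * (ab * tt)^3))
  }
})

test_that("parameter constructor reconciles reported products and enforces
           invariants", {
  p2 <- patient2_params()
  expect_equal(p2$a * p2$ic50, 3.024, tolerance = 1e-12)
  expect_equal(p2$a * p2$ic50 * p2$c1, -0.154, tolerance = 1e-12)
  direct <- atd_params(a = p2$a, c = p2$c, ic50 = p2$ic50, c1 = p2$c1)
  expect_equal(direct[c("a", "c", "ic50", "c1")],
               p2[c("a", "c", "ic50", "c1")])
  expect_error(atd_params(a = -1, c = 0.1, ic50 = 50, c1 = -0.1), "positive")
  expect_error(atd_params(a = 1, c = 0.1, ic50 = 200, c1 = -0.1),
               "ic50")
  expect_error(atd_params(a = 1, c = 0.1, ic50 = 50, c1 = 0.1), "negative")
  expect_error(atd_params(a = 1, c = 0.1, ic50 = 50, c1 = -1e-12),
               "negative")  # strict margin
})

test_that("parameter JSON documents round-trip with provenance", {
  path <- withr::local_tempfile(fileext = ".json")
  write_params(patient2_params(), path,
               meta = list(patient_id = "2", objective = 1.43))
  doc <- read_params(path)
  expect_equal(doc$params$a, patient2_params()$a)
  expect_equal(doc$params$c1, patient2_params()$c1)
  expect_equal(doc$meta$patient_id, "2")
})
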