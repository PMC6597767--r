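# Fixtures built in code: the three published per-patient parameter sets
# (entered through their reported products), their follow-up series, and
# an independent random draw of valid parameter sets for property tests.

patient2_params <- function()
  atd_params(a_ic50 = 3.024, c = 0.003, a_ic50_c1 = -0.154, ic50 = 58.151)

patient16_params <- function()
  atd_params(a_ic50 = 378.648, c = 0.371, a_ic50_c1 = -0.379, ic50 = 72.901)

patient23_params <- function()
  atd_params(a_ic50 = 148.558, c = 0.246, a_ic50_c1 = -4.902, ic50 = 35.062)

patient16_series <- function()
  patient_series("16", dose_prev = c(0, 15, 17.5),
                 interval_days = c(0, 90, 78), ft4 = c(14, 13, 10))

patient23_series <- function()
  patient_series("23", dose_prev = c(0, 15, 15, 7.5),
                 interval_days = c(0, 35, 84, 84), ft4 = c(40, 16, 10, 13))

# independent draw of globally valid parameter sets (c1 pinned so that
# 1/y(t,d) >= 1/y1 > 0 for all t, d >= 0); returns a data frame
draw_valid_params <- function(n, seed) {
  set.seed(seed)
  a <- exp(runif(n, log(0.03), log(8)))
  ic50 <- runif(n, 20, 120)
  yinf <- runif(n, 9, 18)
  y1 <- runif(n, 20, 90)
  data.frame(a = a, c = a / yinf, ic50 = ic50, c1 = 1 / y1 - 1 / yinf,
             y1 = y1)
}

params_from_row <- function(df, i)
  atd_params(a = df$a[i], c = df$c[i], ic50 = df$ic50[i], c1 = df$c1[i])

# direct exponential form of the closed-form solution; independent oracle
# for the reciprocal identity (only safe below the overflow threshold)
ft4_direct_form <- function(p, t, d) {
  ab <- p$a * p$ic50 / (p$ic50 + d)
  ab * exp(ab * t) / (p$c * exp(ab * t) + ab * p$c1)
}
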