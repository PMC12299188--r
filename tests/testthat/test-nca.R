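# Non-compartmental analysis: trapezoidal AUC, terminal slope, peak picking.

test_that("trapezoidal AUC matches hand-computed areas", {
  expect_equal(auc_trapezoid(c(0, 1), conc = c(100, 100)), 100)
  expect_equal(auc_trapezoid(c(0, 1, 2), conc = c(0, 100, 0)), 100)
  # log-down segment: (100 - 50) / ln(100/50) = 50/ln 2
  expect_equal(
    auc_trapezoid(c(0, 1), conc = c(100, 50), method = "linear_log"),
    50 / log(2), tolerance = 1e-10)
  expect_error(auc_trapezoid(c(0), conc = c(100)), "at least 2")
})

test_that("AUC is additive over a partition and invariant to interpolant points", {
  t <- c(0, 0.5, 1, 2, 3, 5)
  c <- c(0, 80, 100, 60, 30, 5)
  full <- auc_trapezoid(t, conc = c)
  cut <- 3L
  expect_equal(auc_trapezoid(t[1:cut], conc = c[1:cut]) +
                 auc_trapezoid(t[cut:6], conc = c[cut:6]), full)
  # inserting a point on the linear interpolant leaves the linear AUC unchanged
  tin <- 1.5
  cin <- approx(t, c, xout = tin)$y
  expect_equal(auc_trapezoid(sort(c(t, tin)), conc = append(c, cin, after = 3)),
               full)
})

test_that("AUC extrapolation to infinity follows C_last/lambda_z", {
  expect_equal(extrapolate_auc_inf(100, 10, 0.5), 120)
  expect_equal(extrapolate_auc_inf(100, 0, 0.5), 100)
  expect_equal(extrapolate_auc_inf(100, 0, NA), 100)
  expect_error(extrapolate_auc_inf(100, 10, 0), "lambda_z")
})

test_that("lambda_z recovers exact exponential slopes", {
  p <- make_exp_profile(c0 = 100, k = 0.5)
  expect_equal(fit_lambda_z(p), 0.5, tolerance = 1e-10)
  p2 <- make_exp_profile(c0 = 100, k = 0.231)
  r <- run_nca(p2)
  expect_equal(r$half_life, log(2) / 0.231, tolerance = 1e-10)
  flat <- plasma_profile(c(0, 1, 2, 3), rep(50, 4), 1, 1, "iv_bolus")
  expect_warning(lz <- fit_lambda_z(flat), "not estimable")
  expect_true(is.na(lz))
})

test_that("cmax/tmax come from observed samples with earliest-time tie-break", {
  p <- plasma_profile(c(0, 0.75, 2), c(0, 94.2, 40), 10, 76, "oral")
  pk <- cmax_tmax(p)
  expect_equal(pk$cmax, 94.2)
  expect_equal(pk$tmax, 0.75)
  zero <- plasma_profile(c(0, 1, 2), c(0, 0, 0), 1, 1, "oral")
  expect_equal(cmax_tmax(zero)$tmax, 0)
  tie <- plasma_profile(c(0, 1, 2, 3), c(0, 70, 70, 10), 1, 1, "oral")
  expect_equal(cmax_tmax(tie)$tmax, 1)
})

test_that("NCA clearance equals the generating clearance for a mono-exponential", {
  # C0/V and k chosen so CL = k*V = 2 L/h for a 1 mg dose, BW 1 kg
  v <- 4; k <- 0.5; dose <- 1
  times <- seq(0.25, 16, by = 0.25)
  p <- plasma_profile(times, dose / v * 1000 * exp(-k * times),
                      dose_mg = dose, bw_kg = 1, route = "iv_bolus")
  r <- run_nca(p, auc_method = "linear_log")
  cl_l_h <- r$cl * 60 / 1000      # mL/min/kg at 1 kg -> L/h
  expect_equal(cl_l_h, k * v, tolerance = 1e-6)
})

test_that("profile constructor validates inputs and converts minutes", {
  expect_error(plasma_profile(c(0, 1), c(1, 2, 3), 1, 1), "equal length")
  expect_error(plasma_profile(c(1, 1), c(1, 2), 1, 1), "strictly increasing")
  expect_error(plasma_profile(c(0, 1), c(-1, 2), 1, 1), ">= 0")
  expect_error(plasma_profile(c(0, 1), c(1, 2), 0, 1), "dose")
  p <- plasma_profile(c(30, 60), c(5, 4), 1, 1, time_unit = "min")
  expect_equal(p$times, c(0.5, 1))
})
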