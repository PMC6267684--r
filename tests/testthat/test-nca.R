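test_that("linear trapezoid AUC: rectangle, hand example, boundary clipping", {
  flat <- data.frame(time = c(0, 6, 12, 24), conc = rep(10, 4))
  expect_equal(auc_trapezoid(flat, 0, 24), 240)
  tri <- data.frame(time = c(0, 1, 2), conc = c(100, 50, 25))
  expect_equal(auc_trapezoid(tri, 0, 2), 112.5)   # 75 + 37.5 by hand
  # boundary obtained by linear interpolation: C(0.5) = 75 on the 100->50 leg
  expect_equal(auc_trapezoid(tri, 0.5, 1), (75 + 50) / 2 * 0.5)
  expect_error(auc_trapezoid(tri, 0, 5), "beyond the sampled range")
  expect_error(auc_trapezoid(tri, 2, 1), "t_start")
})

test_that("AUC is additive over adjacent subintervals", {
  set.seed(42)
  for (i in 1:20) {
    tt <- sort(runif(8, 0, 24))
    d <- data.frame(time = tt, conc = runif(8, 1, 100))
    a <- min(tt); b <- max(tt)
    m <- runif(1, a, b)
    expect_equal(auc_trapezoid(d, a, m) + auc_trapezoid(d, m, b),
                 auc_trapezoid(d, a, b), tolerance = 1e-12)
  }
})

test_that("trapezoid error on monoexponential decay respects the h^2 bound", {
  c0 <- 100; lam <- 0.2
  for (h in c(0.5, 0.25, 0.1)) {
    tt <- seq(0, 24, by = h)
    d <- data.frame(time = tt, conc = monoexp(c0, lam, tt))
    truth <- c0 / lam * (1 - exp(-lam * 24))
    err <- abs(auc_trapezoid(d, 0, 24) - truth)
    expect_lt(err, h^2 / 12 * lam^2 * truth * 1.01)
  }
})

test_that("lambda-z is exact on monoexponential samples", {
  # monotone decay: the Cmax sample (t = 10) is excluded from the windows
  tt <- c(10, 15, 20, 24)
  d <- data.frame(time = tt, conc = monoexp(100, 0.1, tt))
  fit <- estimate_lambda_z(d)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)
  expect_equal(fit$points_used, 3)

  # with a distinct absorption peak, all terminal points are candidates and
  # the perfect-fit tie is broken toward the larger window
  tt2 <- c(2, 10, 15, 20, 24)
  d2 <- data.frame(time = tt2, conc = c(120, monoexp(100, 0.1, tt2[-1])))
  fit2 <- estimate_lambda_z(d2)
  expect_equal(fit2$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(fit2$points_used, 4)
})

test_that("best-fit window equals exhaustive suffix enumeration", {
  # perturbed monoexponential: last point doubled
  tt <- c(1, 4, 8, 10, 15, 20, 24)
  cc <- monoexp(100, 0.12, tt); cc[7] <- cc[7] * 2
  fit <- estimate_lambda_z(data.frame(time = tt, conc = cc))
  orc <- oracle_lambda_best_fit(tt, cc)
  expect_equal(fit$lambda_z, orc$lambda, tolerance = 1e-12)
  expect_equal(fit$points_used, orc$k)

  # randomized property: noisy decays, oracle identity in window and value
  set.seed(7)
  for (i in 1:50) {
    tt <- sort(c(runif(1, 0.1, 1), runif(6, 1, 30)))
    cc <- monoexp(runif(1, 50, 200), runif(1, 0.05, 0.4), tt) *
      exp(rnorm(7, 0, 0.15))
    fit <- estimate_lambda_z(data.frame(time = tt, conc = cc))
    orc <- oracle_lambda_best_fit(tt, cc)
    if (is.null(orc)) {
      expect_false(fit$estimable)
    } else {
      expect_equal(fit$lambda_z, orc$lambda, tolerance = 1e-10)
      expect_equal(fit$points_used, orc$k)
    }
  }
})

test_that("lambda-z preconditions: too few points, rising terminal phase", {
  d2 <- data.frame(time = c(2, 4, 6), conc = c(100, 50, 25))  # 2 post-Tmax
  expect_error(estimate_lambda_z(d2), "insufficient data")
  rising <- data.frame(time = c(1, 2, 4, 8, 12), conc = c(50, 10, 12, 15, 20))
  fit <- estimate_lambda_z(rising)
  expect_false(fit$estimable)
  expect_true(is.na(fit$lambda_z))
})

test_that("manual lambda window regresses over the requested times", {
  tt <- c(1, 2, 4, 8, 12, 24)
  cc <- monoexp(100, 0.15, tt)
  fit <- estimate_lambda_z(data.frame(time = tt, conc = cc),
                           selection = "manual", window = c(4, 24))
  expect_equal(fit$points_used, 4)
  expect_equal(fit$lambda_z, 0.15, tolerance = 1e-12)
  expect_error(estimate_lambda_z(data.frame(time = tt, conc = cc),
                                 selection = "manual", window = c(20, 24)),
               "insufficient")
})

test_that("half-life uses the 0.693 convention", {
  expect_equal(half_life(0.1), 6.93)
  expect_equal(half_life(0.693), 1.0)
  # printed t1/2 of 5 h implies lambda 0.1386/h, which round-trips
  expect_equal(half_life(0.693 / 5), 5)
  expect_error(half_life(0), "positive")
})

test_that("AUC extrapolation to infinity and its fraction", {
  ext <- auc_to_infinity(100, 10, 0.1)
  expect_equal(ext$auc_0_inf, 200)
  expect_equal(ext$extrapolated_fraction, 0.5)
  ext0 <- auc_to_infinity(100, 0, 0.1)
  expect_equal(ext0$auc_0_inf, 100)
  expect_equal(ext0$extrapolated_fraction, 0)
  # dense monoexponential: AUCinf approaches the closed form C0/lambda
  tt <- seq(0, 48, by = 0.05)
  d <- data.frame(time = tt, conc = monoexp(100, 0.1, tt))
  auc_t <- auc_trapezoid(d, 0, 48)
  ext <- auc_to_infinity(auc_t, monoexp(100, 0.1, 48), 0.1)
  expect_equal(ext$auc_0_inf, 1000, tolerance = 1e-4)
})

test_that("Cmax/Tmax with tie to the earliest time", {
  d <- data.frame(time = c(1, 2, 3, 4), conc = c(5, 9, 9, 2))
  expect_equal(cmax_tmax(d), list(c_max = 9, t_max = 2))
  expect_equal(cmax_tmax(data.frame(time = 2, conc = 7)),
               list(c_max = 7, t_max = 2))
  expect_error(cmax_tmax(data.frame(time = numeric(), conc = numeric())),
               "no quantifiable")
})

test_that("IV clearance from dose and AUC reproduces the reference value", {
  expect_equal(clearance_iv(3, 1040), 48.0769, tolerance = 1e-4)
  expect_equal(round(clearance_iv(3, 1040)), 48)
  expect_error(clearance_iv(3, 1040, route = "PO_gavage"), "IV")
  expect_error(clearance_iv(3, 0), "positive")
})

test_that("Vdss recovers volume for a monoexponential IV profile", {
  # 1-compartment: V = 2 L/kg, CL = 6 L/h/kg -> k = 3/h, MRT = 1/k
  tt <- seq(0, 6, by = 0.002)
  d <- data.frame(time = tt, conc = monoexp(1000 / 2, 3, tt))  # 1 mg/kg dose
  v <- vdss_iv(1, d, 3)
  expect_equal(v, 2, tolerance = 1e-3)
  expect_true(is.na(vdss_iv(1, d, NA)))
})

test_that("Vdss recovers the 2-compartment steady-state volume", {
  # known micro-constants; Vss = V1 + V2
  v1 <- 5; v2 <- 12; cl_h <- 2.88; q_h <- 1.5
  k10 <- cl_h / v1; k12 <- q_h / v1; k21 <- q_h / v2
  s <- k10 + k12 + k21; disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2; be <- (s - disc) / 2
  A <- (1000 / v1) * (al - k21) / (al - be)
  B <- (1000 / v1) * (k21 - be) / (al - be)
  tt <- sort(unique(c(seq(0, 2, 5e-4), seq(2, 120, 0.01))))
  d <- data.frame(time = tt, conc = A * exp(-al * tt) + B * exp(-be * tt))
  expect_equal(vdss_iv(1, d, be), v1 + v2, tolerance = 0.05)
})

test_that("bioavailability: dose normalization, identity, above-unity flag", {
  f <- bioavailability(871, 3, 1040, 3)
  expect_equal(f$f, 0.8375, tolerance = 1e-4)
  expect_false(f$above_unity)
  expect_equal(bioavailability(500, 5, 500, 5)$f, 1)
  f10 <- bioavailability(4790, 10, 1040, 3)
  expect_equal(f10$f, 1.3817, tolerance = 1e-4)
  expect_true(f10$above_unity)
  expect_error(bioavailability(1, 1, 0, 1), "positive")
})

test_that("exposure ratios reproduce the reference table roundings", {
  tp <- exposure_ratio(68600, 871, "tissue_plasma")
  expect_equal(tp$value, 78.76, tolerance = 1e-3)
  expect_equal(tp$display, "79")
  acc <- exposure_ratio(1150000, 232000, "accumulation")
  expect_equal(acc$value, 4.957, tolerance = 1e-3)
  expect_equal(acc$display, "5.0")
  expect_equal(exposure_ratio(5, 5)$value, 1)
  expect_error(exposure_ratio(1, 0), "positive")
  expect_error(exposure_ratio(NA, 3), "missing")
})

test_that("reporting precision: half-up rounding at each ratio kind", {
  expect_equal(format_ratio(36.51, "tissue_plasma"), "37")
  expect_equal(format_ratio(19.17, "tissue_plasma"), "19")
  expect_equal(format_ratio(4.96, "accumulation"), "5.0")
  expect_equal(format_ratio(1.84, "accumulation"), "1.8")
  expect_equal(format_ratio(2.5, "tissue_plasma"), "3")
})

test_that("dose-proportionality regression: exact line and reference fit", {
  fit <- dose_proportionality(c(1, 2, 3), c(10, 20, 30))
  expect_equal(fit$slope, 10)
  expect_equal(fit$r_squared, 1)
  ref <- dose_proportionality(c(3, 10, 25), c(871, 4790, 14400))
  expect_gt(ref$r_squared, 0.99)
  two <- dose_proportionality(c(1, 2), c(5, 11))
  expect_true(two$degenerate)
  expect_equal(two$r_squared, 1)
  expect_error(dose_proportionality(c(2, 2), c(1, 2)), "distinct")
})

test_that("run_nca composes: extravascular invariants and partial AUCs", {
  tt <- c(0.5, 1, 2, 4, 8, 12, 24, 48)
  ka <- 0.8; k <- 0.1
  cc <- 500 * ka / (ka - k) * (exp(-k * tt) - exp(-ka * tt))
  p <- make_profile(tt, cc, route = "PO_gavage", dose = 10)
  r <- run_nca(p)
  expect_gte(r$auc_0_inf, r$auc_0_24)
  expect_gte(r$auc_0_48, r$auc_0_24)
  expect_equal(r$c_mean, r$auc_0_24 / 24)
  expect_equal(r$t_half, 0.693 / r$lambda_z)
  expect_equal(r$lambda_z, k, tolerance = 1e-3)
  expect_true(r$extrapolated_fraction < 1 && r$extrapolated_fraction >= 0)
})

test_that("IV C(0) back-extrapolation enlarges AUC over zero-origin handling", {
  tt <- c(1/6, 1/3, 1, 2, 4, 7, 24)
  cc <- monoexp(600, 0.15, tt)
  p <- make_profile(tt, cc, route = "IV", dose = 3)
  r <- run_nca(p)
  expect_equal(r$c0, 600, tolerance = 1e-9)   # exact log-linear backcast
  no_c0 <- auc_trapezoid(data.frame(time = tt, conc = cc), min(tt), max(tt))
  expect_gt(r$auc_0_t, no_c0)
  expect_false(is.na(r$cl_p))
  expect_false(is.na(r$vd_ss))
})

test_that("scale equivariance of the full parameter set", {
  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  cc <- 300 * 0.8 / 0.7 * (exp(-0.1 * tt) - exp(-0.8 * tt))
  k_scale <- 3.7
  r1 <- run_nca(make_profile(tt, cc, route = "PO_gavage"))
  r2 <- run_nca(make_profile(tt, k_scale * cc, route = "PO_gavage"))
  for (m in c("auc_0_t", "auc_0_24", "auc_0_inf", "c_max", "c_mean")) {
    expect_equal(r2[[m]], k_scale * r1[[m]], tolerance = 1e-10)
  }
  for (m in c("lambda_z", "t_half", "t_max", "extrapolated_fraction")) {
    expect_equal(r2[[m]], r1[[m]], tolerance = 1e-10)
  }
  iv1 <- run_nca(make_profile(tt, monoexp(500, 0.12, tt), route = "IV"))
  iv2 <- run_nca(make_profile(tt, k_scale * monoexp(500, 0.12, tt),
                              route = "IV"))
  expect_equal(iv2$cl_p, iv1$cl_p / k_scale, tolerance = 1e-10)
  expect_equal(iv2$vd_ss, iv1$vd_ss / k_scale, tolerance = 1e-10)
})

test_that("chow profiles get a steady-state window, no terminal phase", {
  p <- make_profile(c(0, 3, 6, 9, 12, 15, 24), c(80, 95, 90, 85, 92, 88, 83),
                    route = "PO_chow", dose = 10)
  r <- run_nca(p)
  expect_false(is.na(r$auc_0_24))
  expect_true(is.na(r$lambda_z))
  expect_true(is.na(r$auc_0_inf))
  expect_equal(r$c_mean, r$auc_0_24 / 24)
})
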