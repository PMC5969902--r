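test_that("survival fractions follow the product-limit construction", {
  # no events: S stays at 1 over the whole window
  s0 <- survival_curve(numeric(0), censor_times = rep(100, 5))
  expect_true(all(s0$fraction == 1))
  expect_equal(s0$censored_count, 5)
  # pure counting: 4 events, no censoring
  s1 <- survival_curve(c(1, 2, 3, 4))
  expect_equal(s1$times, c(0, 1, 2, 3, 4))
  expect_equal(s1$fraction, c(1, 0.75, 0.5, 0.25, 0))
  # censoring removes filaments from the risk set without counting events:
  # events at 1 and 10, two censored at 5 -> risk set at 10 is a single
  # filament, so S drops 0.75 -> 0 there
  s2 <- survival_curve(c(1, 10), censor_times = c(5, 5))
  expect_equal(s2$fraction[s2$times == 1], 0.75)
  expect_equal(s2$n_risk[s2$times == 10], 1)
  expect_equal(s2$fraction[s2$times == 10], 0)
  expect_true(all(diff(s2$fraction) <= 0))
})

test_that("survival_curve validates its inputs", {
  expect_error(survival_curve(c(-1, 2)), ">= 0")
  expect_error(survival_curve(c(5, 30), censor_times = 10, horizon = 20),
               "exceeds")
  expect_error(survival_curve(c(1, 2), n0 = 5), "must equal")
})

test_that("exponential fits recover rates from clean and raw data", {
  # noiseless recovery from a densely sampled analytic curve
  t <- seq(0, 400, by = 2)
  curve <- survival_curve_points(t, exp(-0.01 * t), n0 = 50)
  est <- fit_exponential(curve)
  expect_equal(est$k, 0.01, tolerance = 1e-4)
  expect_equal(est$ci65_high - est$k, est$k / sqrt(50), tolerance = 1e-6)
  # MLE is the reciprocal mean lifetime
  mcurve <- survival_curve(c(50, 100, 150, 200))
  expect_equal(fit_exponential(mcurve, method = "mle")$k, 1 / 125)
  # too few events is an explicit estimation error
  expect_error(fit_exponential(survival_curve(c(3, 9))), "at least 3 events")
})

test_that("least-squares and MLE fits agree on exponential data", {
  set.seed(33)
  for (i in 1:5) {
    lt <- rexp(200, 0.02)
    curve <- survival_curve(lt)
    k_lsq <- fit_exponential(curve)$k
    k_mle <- fit_exponential(curve, method = "mle")$k
    expect_lt(abs(k_lsq - k_mle), 2 * k_mle / sqrt(200))
  }
})

test_that("CI calibration: k0/sqrt(N) is about a 65% interval", {
  for (n in c(20, 50)) {
    cal <- ci_calibration(n, k0 = 0.01, m = 800, seed = 100 + n)
    expect_gte(cal$coverage, 0.60)
    expect_lte(cal$coverage, 0.70)
  }
  # the central-65% spread of the estimates sits near k0/sqrt(n)
  cal <- ci_calibration(35, k0 = 0.02, m = 800, seed = 2)
  expect_equal(cal$half_width_65, 0.02 / sqrt(35), tolerance = 0.15)
  # coverage estimates are consistent across m within binomial error
  c1 <- ci_calibration(35, 0.01, m = 400, seed = 3)
  c2 <- ci_calibration(35, 0.01, m = 3000, seed = 4)
  expect_lt(abs(c1$coverage - c2$coverage),
            3 * sqrt(0.65 * 0.35 / 400) + 3 * sqrt(0.65 * 0.35 / 3000))
  expect_error(ci_calibration(3, 0.01, 500), "n must be")
  expect_error(ci_calibration(35, 0.01, 50), "m must be")
})

test_that("local hazard is flat on constant-rate survival", {
  t <- seq(0, 300, by = 3)
  curve <- survival_curve_points(t, exp(-0.02 * t), n0 = 100)
  hz <- local_hazard(curve, window = 10)
  expect_true(all(abs(hz$hazard - 0.02) < 1e-8))
})

test_that("local hazard tracks an exponentially accelerating rate", {
  # S(t) = exp(-(k0/a)(e^{at}-1)) has hazard k0 * e^{at}
  k0 <- 0.001; a <- 0.01
  t <- seq(0, 400, by = 1)
  S <- exp(-(k0 / a) * (exp(a * t) - 1))
  hz <- local_hazard(survival_curve_points(t, S, n0 = 100), window = 8)
  expect_equal(hz$hazard, k0 * exp(a * hz$t), tolerance = 0.02)
  expect_true(all(diff(hz$hazard) > 0))
})

test_that("local hazard on constant-rate noisy data shows no trend", {
  # adjacent sliding windows share events, so the trend test must use
  # non-overlapping windows (independent hazard estimates)
  slopes_sig <- vapply(1:5, function(s) {
    set.seed(400 + s)
    curve <- survival_curve(rexp(150, 0.01))
    hz <- local_hazard(curve, window = 15)
    ind <- hz[seq(1, nrow(hz), by = 15), ]
    fit <- summary(stats::lm(hazard ~ t, data = ind))
    fit$coefficients["t", "Pr(>|t|)"] < 0.05
  }, NA)
  expect_lte(sum(slopes_sig), 1)
})

test_that("local hazard rejects oversized windows", {
  curve <- survival_curve(c(1, 2, 3, 4, 5))
  expect_error(local_hazard(curve, window = 50), "exceeds")
})

test_that("time maps to force through the mean-length trajectory", {
  expect_equal(map_time_to_force(0, kappa = 0.051, L0 = 4.9), 0.2499)
  expect_equal(map_time_to_force(c(10, 100), kappa = 0, L0 = 3, v = 1),
               c(0, 0))
  expect_equal(map_time_to_force(100, kappa = 0.2, L0 = 3, v = 0.02), 1)
  expect_error(map_time_to_force(-1, 0.1, 1), ">= 0")
})

test_that("force binning averages points and omits empty bins", {
  one <- bin_by_force(c(0.5, 0.7), c(0.01, 0.03), bin_edges = c(0, 1))
  expect_equal(one$f, 0.6)
  expect_equal(one$k_obs, 0.02)
  expect_equal(one$n, 2)
  # equal-count default bins cover all points
  set.seed(5)
  f <- runif(200, 0, 4); k <- 0.003 * exp(f * 0.6) * exp(rnorm(200, 0, 0.05))
  bins <- bin_by_force(f, k, n_bins = 8)
  expect_equal(sum(bins$n), 200)
  # binned means of Bell-law points are monotone in force
  expect_true(all(diff(bins$k_obs) > 0))
  expect_error(bin_by_force(c(5, 6), c(1, 1), bin_edges = c(0, 1)),
               "no points")
})

test_that("detachment-rate correction brackets the dissociation rate", {
  b <- correct_detachment_rate(0.1, 0.74)
  expect_equal(b$k_off_low, 0.074)
  expect_equal(b$k_off_high, 0.1)
  d <- correct_detachment_rate(0.05, 1)
  expect_equal(d$k_off_low, d$k_off_high)
  z <- correct_detachment_rate(0, 0.74)
  expect_equal(unlist(z), c(k_off_low = 0, k_off_high = 0))
  expect_error(correct_detachment_rate(0.1, 0), "functional_fraction")
  expect_error(correct_detachment_rate(0.1, 1.2), "functional_fraction")
})

test_that("striped deconvolution inverts the composition formulas", {
  sc <- striped_schedule(100, 20, v2 = 12.5, k2 = 0.009)
  # homogeneous schedule: composites equal the references
  hom <- deconvolve_striped(12.5, 0.009, sc)
  expect_equal(hom$v1, 12.5)
  expect_equal(hom$k1, 0.009)
  # worked inversions with the 100 s / 20 s schedule
  expect_equal(deconvolve_striped(10, 0.009, sc)$v1, 9.5)
  expect_equal(deconvolve_striped(12.5, 0.005, sc)$k1, 0.0042)
  # noise can push a recovered rate negative: flagged, not clipped
  expect_warning(res <- deconvolve_striped(1, 0.0001, sc), "negative")
  expect_true(res$negative)
  expect_lt(res$v1, 0)
  expect_error(striped_schedule(0, 20, 1, 1), "durations")
})

test_that("compose/deconvolve round-trip is exact for random schedules", {
  set.seed(77)
  for (i in 1:50) {
    sc <- striped_schedule(runif(1, 5, 300), runif(1, 5, 300),
                           v2 = runif(1, 1, 60), k2 = runif(1, 1e-4, 0.05))
    v1 <- runif(1, 0, 40); k1 <- runif(1, 1e-5, 0.03)
    comp <- compose_striped(v1, k1, sc)
    back <- deconvolve_striped(comp$v, comp$k, sc)
    expect_equal(back$v1, v1, tolerance = 1e-12)
    expect_equal(back$k1, k1, tolerance = 1e-12)
  }
})
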