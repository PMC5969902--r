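test_that("bell_rate follows the slip-bond law and rejects bad input", {
  expect_equal(bell_rate(0.1, delta = 0, f = 5), 0.1)
  expect_equal(bell_rate(0.1, delta = 2.7, f = 0), 0.1)
  # f * delta / kBT = 1 exactly at these values
  expect_equal(bell_rate(0.1, delta = 2.7, f = 1.522, kBT = 4.11),
               0.1 * exp(1.522 * 2.7 / 4.11))
  expect_equal(bell_rate(0.1, 2.7, 1.522, 4.11), 0.2718, tolerance = 1e-3)
  f <- seq(0, 10, by = 0.5)
  expect_true(all(diff(bell_rate(0.05, 1.3, f)) >= 0))
  expect_error(bell_rate(0.1, 2.7, 5, kBT = 0), "kBT")
  expect_error(bell_rate(0.1, 2.7, NaN), "non-finite")
  expect_error(bell_rate(0.1, 2.7, -1), ">= 0")
  expect_error(bell_rate(1, 10, 1000, kBT = 4.11), "unphysical")
})

test_that("open-state occupancy is a force-tilted Boltzmann factor", {
  p <- formin_params(K_co = 1)
  expect_equal(p_open(0, p), 0.5)
  expect_equal(p_open(200, p), 1, tolerance = 1e-10)
  expect_equal(p_open(2.85, p, kBT = 4.11),
               1 / (1 + exp(-2.85 * 2.7 / 4.11)))
  expect_equal(p_open(2.85, p), 0.867, tolerance = 1e-3)
  f <- seq(0, 8, by = 0.25)
  for (kco in c(0.2, 1, 5)) {
    pk <- formin_params(K_co = kco)
    po <- p_open(f, pk)
    expect_true(all(po > 0 & po <= 1))
    expect_true(all(diff(po) >= 0))
  }
})

test_that("profilin occupancy: solution and FH1 routes saturate as expected", {
  p <- formin_params()
  occ0 <- profilin_occupancy(conditions(profilin = 0), p)
  expect_equal(occ0$pi_solution, 0)
  expect_equal(occ0$pi_fh1, 0)
  # FH1-less constructs have no ring-complex occupancy at any profilin
  pf <- formin_params(has_FH1 = FALSE)
  expect_equal(profilin_occupancy(conditions(profilin = 10), pf)$pi_fh1, 0)
  # half-saturation at the respective affinity scales
  expect_equal(
    profilin_occupancy(conditions(profilin = p$K_PB), p)$pi_solution, 0.5)
  expect_equal(
    profilin_occupancy(conditions(profilin = p$K_ring), p)$pi_fh1, 0.5)
})

test_that("elongation rate: linear in actin, biphasic in profilin", {
  p <- formin_params()
  expect_equal(elongation_rate(conditions(actin = 0), 0, p), 0)
  # without profilin, FH1 constructs elongate exactly like FH2-only
  pf <- formin_params(has_FH1 = FALSE)
  cn <- conditions(actin = 0.7)
  expect_equal(elongation_rate(cn, 0, p), elongation_rate(cn, 0, pf))
  # linear in actin at fixed profilin
  v <- vapply(c(0.5, 1, 2), function(a)
    elongation_rate(conditions(actin = a, profilin = 3), 1, p), 0)
  expect_equal(v[3] / v[2], 2)
  expect_equal(v[1] / v[2], 0.5)
  # biphasic in profilin: rises (FH1 delivery) then falls (barbed-end block)
  pb <- formin_params(k_on = 10, K_co = 1e-9, fh1_boost_max = 9,
                      K_boost = 1, K_PB = 50)
  prof <- seq(0, 40, by = 0.25)
  vv <- vapply(prof, function(pr)
    elongation_rate(conditions(actin = 1, profilin = pr), 0, pb), 0)
  imax <- which.max(vv)
  expect_gt(imax, 1)
  expect_lt(imax, length(prof))
  expect_gt(max(vv), vv[1])
})

test_that("dissociation rate splits into open and transition routes", {
  p <- formin_params()
  # no monomer: no additions, so only the open route remains
  pred0 <- dissociation_rate(conditions(actin = 0), 0, p)
  expect_equal(pred0$k_off_transition_route, 0)
  expect_equal(pred0$k_off, pred0$k_off_open_route)
  # route sum identity and non-negativity across a force sweep
  pred <- dissociation_rate(conditions(actin = 1, profilin = 2), 0:6, p)
  expect_equal(pred$k_off,
               pred$k_off_open_route + pred$k_off_transition_route)
  expect_true(all(pred$k_off >= 0))
  # transition route grows with actin (it rides on the elongation rate)
  k1 <- dissociation_rate(conditions(actin = 1), 0, p)
  k2 <- dissociation_rate(conditions(actin = 2), 0, p)
  expect_gt(k2$k_off_transition_route, k1$k_off_transition_route)
  expect_equal(k2$k_off_open_route, k1$k_off_open_route)
})

test_that("k_off at fixed force is affine-increasing in actin (no profilin)", {
  p <- formin_params()
  k <- vapply(c(0, 0.5, 1, 2), function(a)
    dissociation_rate(conditions(actin = a), 0, p)$k_off, 0)
  expect_true(all(diff(k) > 0))
  # affine: equal increments for equal actin increments
  expect_equal(k[4] - k[3], 2 * (k[3] - k[2]))
})

test_that("FH2-only dissociation collapses onto elongation rate alone", {
  pf <- formin_params(has_FH1 = FALSE)
  # same v reached with profilin (higher actin, barbed ends part-blocked)
  c_plain <- conditions(actin = 1)
  c_prof <- conditions(actin = 2, profilin = 30) # pi_solution = 0.5
  expect_equal(elongation_rate(c_plain, 0, pf),
               elongation_rate(c_prof, 0, pf))
  expect_equal(dissociation_rate(c_plain, 0, pf)$k_off,
               dissociation_rate(c_prof, 0, pf)$k_off)
})

test_that("with FH1, equal elongation rates do not imply equal k_off", {
  p <- formin_params()
  c_prof <- conditions(actin = 1, profilin = 1)
  v_target <- elongation_rate(c_prof, 0, p)
  # reach the same v without profilin by raising actin
  a_eq <- v_target / elongation_rate(conditions(actin = 1), 0, p)
  c_plain <- conditions(actin = a_eq)
  expect_equal(elongation_rate(c_plain, 0, p), v_target)
  expect_lt(dissociation_rate(c_prof, 0, p)$k_off,
            dissociation_rate(c_plain, 0, p)$k_off)
})

test_that("k_off decreases with profilin while FH1 speeds elongation", {
  p <- formin_params()
  prof <- seq(0, 5, by = 0.1)
  k <- vapply(prof, function(pr)
    dissociation_rate(conditions(actin = 1, profilin = pr), 0, p)$k_off, 0)
  expect_true(all(diff(k) < 0))
  v <- vapply(prof, function(pr)
    elongation_rate(conditions(actin = 1, profilin = pr), 0, p), 0)
  expect_gt(v[length(v)], v[1])
})

test_that("k_off(f) is non-decreasing in force for random parameter sets", {
  set.seed(11)
  f <- seq(0, 6, by = 0.3)
  for (i in 1:25) {
    p <- formin_params(k_on = runif(1, 1, 60), K_co = runif(1, 0.1, 5),
                       k_offO0 = runif(1, 0, 1e-2),
                       k_offT0 = runif(1, 0, 10),
                       k_decay = 10^runif(1, 3, 6),
                       delta_O = runif(1, 0, 4), delta_T = runif(1, 0, 4))
    cn <- conditions(actin = runif(1, 0.2, 3), profilin = runif(1, 0, 10))
    k <- dissociation_rate(cn, f, p)$k_off
    expect_true(all(diff(k) >= -1e-12))
  }
})

test_that("FH2-only with no profilin predicts identically to FH1 variant", {
  pT <- formin_params(has_FH1 = TRUE)
  pF <- formin_params(has_FH1 = FALSE)
  cn <- conditions(actin = 1.5, profilin = 0)
  for (f in c(0, 2.5)) {
    a <- dissociation_rate(cn, f, pT)
    b <- dissociation_rate(cn, f, pF)
    expect_equal(a$k_off, b$k_off)
    expect_equal(a$v_elong, b$v_elong)
  }
})

test_that("mean filament length converts v/k with 2.7 nm subunits", {
  # v = 1 subunit/s, k = 1 /s: length is one subunit, 0.0027 um
  p <- formin_params(k_on = 2, K_co = 1, k_offO0 = 1, delta_O = 0,
                     k_offT0 = 0)
  cn <- conditions(actin = 1)
  pred <- dissociation_rate(cn, 0, p)
  expect_equal(pred$v_elong, 1)
  expect_equal(mean_filament_length(cn, 0, p),
               pred$v_elong / pred$k_off * 0.0027)
  # identity L * k / v = 2.7 nm for arbitrary parameter sets
  set.seed(4)
  for (i in 1:10) {
    p <- formin_params(k_on = runif(1, 5, 50), k_offO0 = runif(1, 1e-5, 1e-2),
                       k_offT0 = runif(1, 0.1, 5), delta_T = runif(1, 0, 2))
    cn <- conditions(actin = runif(1, 0.3, 2), profilin = runif(1, 0, 8))
    L <- mean_filament_length(cn, 1, p)
    pr <- dissociation_rate(cn, 1, p)
    expect_equal(L * pr$k_off / pr$v_elong * 1000, 2.7)
  }
  # a formin that never dissociates grows without bound
  p0 <- formin_params(k_offO0 = 0, k_offT0 = 0)
  expect_identical(mean_filament_length(conditions(actin = 1), 0, p0), Inf)
})

test_that("doubling actin changes mean length less than two-fold", {
  p <- formin_params()
  L1 <- mean_filament_length(conditions(actin = 1), 0, p)
  L2 <- mean_filament_length(conditions(actin = 2), 0, p)
  expect_gt(L2 / L1, 1 / 2)
  expect_lt(L2 / L1, 2)
})

test_that("force-curve families classify converging vs separated regimes", {
  base <- formin_params()
  cn <- conditions(actin = 1)
  f_grid <- seq(0, 6, by = 0.25)
  pB <- formin_params(delta_O = base$delta_step, delta_T = 0)
  famB <- koff_force_family(c(0.3, 1, 2), f_grid, cn, pB)
  expect_identical(famB$regime, "converging")
  expect_lt(famB$ratio_high, famB$ratio_low)
  pC <- formin_params(delta_O = 0, delta_T = base$delta_step)
  famC <- koff_force_family(c(0.3, 1, 2), f_grid, cn, pC)
  expect_identical(famC$regime, "separated")
  # degenerate one-point grid: equal ratios tie-break to "separated"
  fam1 <- koff_force_family(c(0.3, 1), 2, cn, pB)
  expect_equal(fam1$ratio_low, fam1$ratio_high)
  expect_identical(fam1$regime, "separated")
  expect_error(koff_force_family(1, f_grid, cn, pB), "at least 2")
})

test_that("parameter and condition validation enforces invariants", {
  expect_error(formin_params(k_offO0 = -1), ">= 0")
  expect_error(formin_params(K_co = 0), "K_co")
  expect_error(formin_params(K_PB = 0), "affinity")
  expect_error(formin_params(k_on = Inf), "finite")
  # FH2-only constructs cannot carry a delivery boost
  pf <- formin_params(has_FH1 = FALSE, fh1_boost_max = 5)
  expect_equal(pf$fh1_boost_max, 0)
  expect_error(conditions(actin = -1), "non-negative")
  expect_error(conditions(labeling_fraction = 1.2), "labeling_fraction")
  expect_error(conditions(kBT = 0), "kBT")
})

test_that("prediction tables carry the documented tidy schema", {
  tab <- predict_table(formin_params(), construct = "mDia1",
                       actin = c(0.5, 1), profilin = c(0, 2),
                       force = c(0, 3))
  expect_equal(nrow(tab), 8)
  expect_named(tab, c("construct", "actin_uM", "profilin_uM", "kcl_mM",
                      "force_pN", "v_elong_sub_s", "koff_s", "route_open_s",
                      "route_transition_s"))
  expect_equal(tab$koff_s, tab$route_open_s + tab$route_transition_s)
  path <- withr::local_tempfile(fileext = ".csv")
  predict_table(formin_params(), path = path)
  expect_true(file.exists(path))
})
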