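test_that("membrane series vanishes at t = 0 and reaches the lag-line asymptote", {
  expect_identical(qrf_series(1, 0.1, 0), 0)
  t_big <- 200
  expect_equal(qrf_series(1, 0.1, t_big), 0.1 * t_big - 1 / 6,
               tolerance = 1e-12)
  tt <- seq(0, 60, by = 0.5)
  expect_true(all(diff(qrf_series(2, 0.05, tt)) >= -1e-12))
})

test_that("membrane series matches an independent finite-difference solution", {
  # same membrane expressed physically: Q(t) = qrf_series(C_d*K*L, D/L^2, t)
  d_cm2h <- 1.27e-7 * 3600
  l_cm <- 0.0767
  k <- 3; c_d <- 71
  m2 <- d_cm2h / l_cm^2
  m1 <- c_d * k * l_cm
  tt <- c(0.1, 0.5, 1, 2, 5, 10) / m2  # spans lag through linear phase
  oracle <- fd_membrane_oracle(d_cm2h, k, l_cm, c_d, tt, nx = 400)
  series <- qrf_series(m1, m2, oracle$time_h)
  nonzero <- series > 1e-3 * m1
  expect_true(all(abs(oracle$q_ug_cm2[nonzero] / series[nonzero] - 1) < 0.005))
})

test_that("isolated-dermis fit is self-consistent and recovers physical parameters", {
  tt <- c(1.5, 3, 5, 7, 9, 12, 14, 16, 20, 24)
  q <- qrf_series(1.5, 0.08, tt)
  f <- fit_isolated_dermis(tt, q, stack_vitro, c_d = 71)
  expect_equal(f$m1, 1.5, tolerance = 1e-6)
  expect_equal(f$m2, 0.08, tolerance = 1e-6)
  # physical round trip: d_de = m2 L^2, k = m1 / (C_d L)
  l_cm <- um_to_cm(stack_vitro$thickness_de)
  expect_equal(f$d_de, cm2h_to_cm2s(0.08 * l_cm^2), tolerance = 1e-6)
  expect_equal(f$k_de_veh, 1.5 / (71 * l_cm), tolerance = 1e-6)
})

test_that("degenerate permeation curves are rejected", {
  tt <- c(1.5, 3, 5, 7, 9, 12)
  expect_error(fit_isolated_dermis(tt, rep(0, 6), stack_vitro, 71),
               "estimation-failure")
  expect_error(fit_isolated_dermis(tt[1:4], 1:4, stack_vitro, 71),
               ">= 6 timepoints")
})

test_that("evaporation time follows the dry-down arithmetic", {
  expect_equal(evaporation_time(0.004, 1.0, 0.123), 0)
  expect_equal(evaporation_time(1.0, 0.5, 0.25), 2.0)
  expect_warning(et <- evaporation_time(1, 0.5, 0), "never ends")
  expect_identical(et, Inf)
})

test_that("evaporation fit recovers plateau and rate", {
  f <- fit_evaporation(0:4, c(4.0, 3.0, 2.2, 2.0, 2.0))
  expect_equal(f$residual_fraction, 0.5)

  fc <- fit_evaporation(0:4, rep(3, 5))
  expect_equal(fc$residual_fraction, 1)
  expect_equal(fc$evaporation_rate, 0)
  expect_equal(fc$evap_time, 0)

  expect_error(fit_evaporation(0:4, c(4, 3.5, 3, 2.5, 2)), "no-plateau")

  # exponential decay to plateau: initial slope encodes the stated rate
  g <- gen_evaporation_curve(initial_mass_mg = 4, residual_fraction = 0.1,
                             evaporation_rate = 0.008,
                             times = seq(0, 8, by = 0.02),
                             profile = "exponential", seed = 1)
  fe <- fit_evaporation(g$data$time_h, g$data$mass_mg)
  expect_equal(fe$evaporation_rate, 0.008, tolerance = 0.05)
  expect_equal(fe$residual_fraction, 0.1, tolerance = 0.02)
})

test_that("first-tier in silico dermal parameters follow the correlations", {
  # intercept: at logP = 0 the partition term is exactly 1
  small <- chemical_properties("s", mw = 18, logp = 0, sw = 1000, fup = 0.5,
                               rbp = 1)
  p0 <- l1_insilico_dermal(small, stack_vitro)
  expect_equal(p0$k_sc_w, 1)
  # strict monotonicity in logP at fixed MW
  ks <- vapply(seq(-1, 5, by = 0.5), function(lp) {
    ch <- chemical_properties("s", mw = 228.2, logp = lp, sw = 1, fup = 0.5,
                              rbp = 1)
    l1_insilico_dermal(ch, stack_vitro)$k_sc_w
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
  # the full first-tier set runs the Franz simulator end to end
  dp <- l1_insilico_dermal(oxy, stack_vitro, forms$F1)
  expect_length(validate_record(dp), 0)
  res <- simulate_franz(oxy, forms$F1, stack_vitro, dp,
                        grid_spec = franz_grid(8, 1e-6, 1e-8),
                        times = c(0, 4, 16, 24))
  expect_true(all(res$receptor_cumulative >= 0))
})

test_that("hepatic clearance is the non-restrictive well-stirred form", {
  expect_equal(hepatic_clearance(90, 0, 0.693), 0)
  expect_equal(hepatic_clearance(90, 90, 1), 45)
  cl <- seq(0, 2000, by = 50)
  vals <- vapply(cl, hepatic_clearance, numeric(1), q_liver = 90, rbp = 0.693)
  expect_true(all(diff(vals) > 0))               # increasing
  expect_true(all(diff(diff(vals)) < 1e-9))      # concave
  expect_true(all(vals <= 90 * 0.693 + 1e-9))    # flow limit
})

test_that("clearance scaling and renal filtration are linear unit conversions", {
  expect_equal(scale_clint(1, 1, 1000), 0.06)
  expect_equal(scale_clint(2, 3, 500), 2 * scale_clint(1, 3, 500))
  expect_equal(scale_clint(1, 3, 1000), 2 * scale_clint(1, 3, 500))
  expect_equal(renal_clearance(0, 7), 0)
  expect_equal(renal_clearance(0.5, 7), 3.5)
})

test_that("half-life converts to intrinsic clearance", {
  # V/P of 494 uL/mg reproduces the measured skin clearance pair
  expect_equal(halflife_to_clint(856, 494, 1), 0.40, tolerance = 0.001)
  expect_equal(halflife_to_clint(1e12, 494, 1), 0, tolerance = 1e-9)
  expect_equal(halflife_to_clint(856, 494, 2),
               halflife_to_clint(856, 494, 1) / 2)
})
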