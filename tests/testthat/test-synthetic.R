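test_that("sampling designs match the study protocol", {
  cc <- franz_cell_config()
  expect_length(cc$sampling_times, 15)
  expect_equal(cc$sampling_times,
               c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 12, 16, 20, 24))
  expect_equal(cc$wash_times, c(4, 16, 24))
  expect_equal(cc$receptor_volume, 3)
  expect_equal(cc$replacement_volume, 0.3)

  g <- gen_dermis_permeation(1, 0.1, noise_cv = 0, n = 1, seed = 1)
  expect_equal(g$data$time_h, c(1.5, 3, 5, 7, 9, 12, 14, 16, 20, 24))

  ev <- regimen_repeated()$events
  expect_equal(nrow(ev), 13)
  expect_equal(ev$time_h, c(0, 24, 26, 28, 30, 48, 50, 52, 54, 72, 74, 76, 78))
  expect_equal(ev$mass_mg[1] * formulation_fixtures()$F1$active_fraction, 1710)
  expect_equal(ev$mass_mg[1] * formulation_fixtures()$F2$active_fraction, 1140)
  expect_equal(ev$area_cm2[1], 14250)
})

test_that("generators are noise-free limits of the deterministic model", {
  g0 <- gen_dermis_permeation(1.5, 0.08, noise_cv = 0, n = 1, seed = 42)
  expect_equal(g0$data$q_rf_ug_per_cm2,
               qrf_series(1.5, 0.08, g0$data$time_h))

  fr <- gen_franz_dataset(oxy, forms$F1, truths$F1, noise_cv = 0,
                          n_replicates = 1, seed = 42, thickness_sd = 0)
  sim <- simulate_franz(oxy, forms$F1, stack_vitro, truths$F1,
                        grid_spec = franz_grid(10, 1e-6, 1e-8))
  la <- layer_amounts_at(sim, c(4, 16, 24))
  got <- fr$layer_data[fr$layer_data$compartment == "sc", "amount_ug"]
  expect_equal(got, unname(la[, "sc"]), tolerance = 1e-9)

  # linear dry-down at 8 mg/h reaches the 0.4 mg plateau before t = 1 h
  e0 <- gen_evaporation_curve(4, 0.1, 0.008, times = c(0, 0.25, 2, 6),
                              seed = 1)
  expect_equal(e0$data$mass_mg, c(4, 2, 0.4, 0.4))
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- gen_dermis_permeation(1.5, 0.08, noise_cv = 0.1, n = 3, seed = 7)
  b <- gen_dermis_permeation(1.5, 0.08, noise_cv = 0.1, n = 3, seed = 7)
  expect_identical(a$data, b$data)
  d <- gen_dermis_permeation(1.5, 0.08, noise_cv = 0.1, n = 3, seed = 8)
  expect_false(identical(a$data, d$data))

  fa <- gen_franz_dataset(oxy, forms$F2, truths$F2, noise_cv = 0.2,
                          n_replicates = 2, seed = 3)
  fb <- gen_franz_dataset(oxy, forms$F2, truths$F2, noise_cv = 0.2,
                          n_replicates = 2, seed = 3)
  expect_identical(fa$layer_data, fb$layer_data)
  expect_identical(fa$receptor_data, fb$receptor_data)
})

test_that("the injected noise reproduces the requested dispersion", {
  fr <- gen_franz_dataset(oxy, forms$F1, truths$F1, noise_cv = 0.2,
                          n_replicates = 24, seed = 12, thickness_sd = 0)
  cvs <- with(subset(fr$layer_data, time_h == 24),
              tapply(amount_ug, compartment, function(x) sd(x) / mean(x)))
  # log-normal with CV 0.2, n = 24 per compartment: allow sampling error
  expect_true(all(cvs > 0.1 & cvs < 0.32))
})

test_that("dermis-curve closure: fitting the generated data recovers truth", {
  g <- gen_dermis_permeation(16.3, 0.0777, noise_cv = 0.03, n = 6, seed = 21)
  ag <- aggregate(q_rf_ug_per_cm2 ~ time_h, data = g$data, FUN = mean)
  f <- fit_isolated_dermis(ag$time_h, ag$q_rf_ug_per_cm2, stack_vitro,
                           c_d = 71)
  expect_equal(f$m1, 16.3, tolerance = 0.1)
  expect_equal(f$m2, 0.0777, tolerance = 0.1)
})

test_that("clinical-profile generator produces the study shape", {
  # zero CV: all subjects identical
  g0 <- gen_clinical_profiles(oxy, truths$F1, forms$F1, stack_vivo,
                              regimen_single(), clinical_subjects()$F1,
                              inter_subject_cv = c(rbp = 0),
                              n_subjects = 2, seed = 5)
  expect_equal(g0$metrics$cmax[1], g0$metrics$cmax[2])

  # modest variability: mean Cmax within 3 SE of the truth-model Cmax
  g <- gen_clinical_profiles(oxy, truths$F1, forms$F1, stack_vivo,
                             regimen_single(), clinical_subjects()$F1,
                             inter_subject_cv = c(rbp = 0.15),
                             n_subjects = 8, seed = 6)
  truth_cmax <- g0$metrics$cmax[1]
  se <- sd(g$metrics$cmax) / sqrt(nrow(g$metrics))
  expect_lt(abs(mean(g$metrics$cmax) - truth_cmax), 3 * se + 0.05 * truth_cmax)
  expect_true(all(c("metric", "mean", "cv_pct") %in% names(g$summary)))
})
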