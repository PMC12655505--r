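toy_obs <- data.frame(compartment = c("sc", "ve", "rf"),
                      time_h = c(4, 4, 4),
                      amount_ug = c(10, 4, 2))

test_that("objective kinds weight residuals as specified", {
  spec <- objective_spec("inv_y_plus_yhat2")
  expect_equal(objective(toy_obs, toy_obs, spec), 0)

  obs1 <- data.frame(compartment = "sc", time_h = 1, amount_ug = 2)
  pred1 <- data.frame(compartment = "sc", time_h = 1, amount_ug = 1)
  expect_equal(objective(obs1, pred1, spec), 1 / 9)

  # three kinds against a hand-evaluated toy set
  pred <- toy_obs; pred$amount_ug <- c(12, 3, 2.5)
  hand <- function(w) sum((toy_obs$amount_ug - pred$amount_ug)^2 * w)
  expect_equal(objective(toy_obs, pred, objective_spec("inv_y2")),
               hand(1 / toy_obs$amount_ug^2))
  expect_equal(objective(toy_obs, pred, objective_spec("inv_yhat2")),
               hand(1 / pred$amount_ug^2))
  expect_equal(objective(toy_obs, pred, objective_spec("inv_y_plus_yhat2")),
               hand(1 / (toy_obs$amount_ug + pred$amount_ug)^2))

  # zero pairs contribute zero; observed zero breaks 1/Y^2 only
  obs0 <- data.frame(compartment = "sc", time_h = c(1, 2),
                     amount_ug = c(0, 5))
  pred0 <- data.frame(compartment = "sc", time_h = c(1, 2),
                      amount_ug = c(0, 5))
  expect_equal(objective(obs0, pred0, objective_spec("inv_y2")), 0)
  pred0$amount_ug <- c(1, 5)
  expect_error(objective(obs0, pred0, objective_spec("inv_y2")),
               "undefined-weight")

  # per-compartment weights enter linearly
  spec_w <- objective_spec("inv_y2", weights = c(sc = 2, ve = 0, de = 1, rf = 0))
  pred2 <- toy_obs; pred2$amount_ug <- c(11, 99, 99)
  expect_equal(objective(toy_obs, pred2, spec_w), 2 * (10 - 11)^2 / 100)
})

test_that("stage-1 at the generating values stays put on noiseless data", {
  ds <- closure_datasets(noise_cv = 0, n_replicates = 1, seed = 1)[c("F1", "F2")]
  s1 <- stage1_chemical_fit(ds, oxy, start = stage1_truth,
                            lower = stage1_truth / 30,
                            upper = stage1_truth * 30)
  expect_lt(s1$objective_value, 1e-6)
  expect_equal(unname(s1$fitted_params / stage1_truth), rep(1, 3),
               tolerance = 0.01)
  expect_true(all(s1$fitted_params >= s1$bounds["lower", ] &
                    s1$fitted_params <= s1$bounds["upper", ]))
})

test_that("a single-formulation stage-1 run is flagged", {
  ds <- closure_datasets(noise_cv = 0, n_replicates = 1, seed = 1)["F1"]
  expect_warning(
    s1 <- stage1_chemical_fit(ds, oxy, start = stage1_truth,
                              lower = stage1_truth / 2,
                              upper = stage1_truth * 2),
    "identifiab")
  expect_match(s1$convergence_report$flag, "identifiab")
})

test_that("stage-2 bounds pinned to a point return that point", {
  ds <- closure_datasets(noise_cv = 0, n_replicates = 1, seed = 1)$F1
  pin <- c(k_vh_w = 1500, d_sc = 1e-9, k_sc_w = 150, application_time = 0.4)
  s2 <- stage2_formulation_fit(ds, oxy, ds$dermal_params,
                               start = pin, lower = pin, upper = pin)
  expect_equal(s2$fitted_params, pin)
})

test_that("fitted application time tracks the generator's evaporation ordering", {
  # two synthetic studies differing only in exposure time; fit it alone
  dp_short <- truths$F1; dp_short$application_time <- 0.3
  dp_long <- truths$F1; dp_long$application_time <- 0.9
  mk <- function(dp, seed) {
    g <- gen_franz_dataset(oxy, forms$F1, dp, noise_cv = 0,
                           n_replicates = 1, seed = seed, thickness_sd = 0)
    g$dataset
  }
  fit_app <- function(ds) {
    s2 <- stage2_formulation_fit(
      ds, oxy, ds$dermal_params,
      start = c(application_time = 0.6),
      lower = c(application_time = 0.05),
      upper = c(application_time = 5))
    s2$fitted_params[["application_time"]]
  }
  t_short <- fit_app(mk(dp_short, 3))
  t_long <- fit_app(mk(dp_long, 4))
  expect_lt(t_short, t_long)
  expect_equal(t_short, 0.3, tolerance = 0.1)
  expect_equal(t_long, 0.9, tolerance = 0.1)
})

test_that("fits are bit-reproducible for identical settings", {
  ds <- closure_datasets(noise_cv = 0.05, n_replicates = 2, seed = 11)$F1
  run <- function() stage2_formulation_fit(
    ds, oxy, ds$dermal_params,
    start = c(k_vh_w = 900), lower = c(k_vh_w = 100),
    upper = c(k_vh_w = 10000), seed = 5)
  expect_identical(run()$fitted_params, run()$fitted_params)
})
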