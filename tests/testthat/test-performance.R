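test_that("classification is total with explicit boundary behaviour", {
  expect_equal(classify_sensitivity(c(0.6, 0.5, 0.3, 0.2, 0.15, 0.1, 0.05, 0)),
               c("high", "high", "medium", "medium", "low", "low",
                 "negligible", "negligible"))
  expect_equal(classify_sensitivity(-0.7), "high")   # magnitude counts
  expect_equal(classify_uncertainty(c(2.5, 2, 1, 0.3, 0.2, 0)),
               c("high", "high", "medium", "medium", "low", "low"))
  # totality: every finite value gets exactly one class
  x <- seq(-3, 3, by = 0.01)
  expect_true(all(classify_sensitivity(x) %in%
                    c("high", "medium", "low", "negligible")))
  u <- seq(0, 5, by = 0.01)
  expect_true(all(classify_uncertainty(u) %in% c("high", "medium", "low")))
})

test_that("normalized sensitivity is exact on analytic models", {
  s_lin <- sensitivity_scan(function(p) 7 * p[["x"]] + 2 * p[["z"]],
                            c(x = 3, z = 0.001))
  expect_equal(s_lin$s[s_lin$parameter == "x"], 7 * 3 / (21.002),
               tolerance = 1e-9)
  s1 <- sensitivity_scan(function(p) 4 * p[["x"]], c(x = 2))
  expect_equal(s1$s, 1, tolerance = 1e-12)
  expect_equal(s1$s_class, "high")

  # parameter with no pathway to the output
  s0 <- sensitivity_scan(function(p) 5 * p[["x"]], c(x = 1, dead = 10))
  expect_equal(s0$s[s0$parameter == "dead"], 0)
  expect_equal(s0$s_class[s0$parameter == "dead"], "negligible")

  # quadratic: central difference of x^2 gives exactly 2
  s2 <- sensitivity_scan(function(p) p[["x"]]^2, c(x = 3))
  expect_equal(s2$s, 2, tolerance = 1e-9)

  expect_error(sensitivity_scan(function(p) 0, c(x = 1)),
               "undefined-sensitivity")
})

test_that("uncertainty metric matches the analytic log-normal spread", {
  u0 <- uncertainty_eval(function(p) p[["x"]], c(x = 2), cv = c(x = 0),
                         n_subjects = 100, seed = 1)
  expect_equal(u0$metric, 0)
  expect_equal(u0$u_class, "low")

  # passthrough with sigma = 0.4497: metric -> 2 sinh(1.96 sigma) = 2.0
  sigma <- 0.4497
  cv <- sqrt(exp(sigma^2) - 1)
  u <- uncertainty_eval(function(p) p[["x"]], c(x = 1), cv = c(x = cv),
                        n_subjects = 20000, seed = 2)
  expect_equal(u$metric, 2 * sinh(1.96 * sigma), tolerance = 0.05)

  expect_equal(classify_uncertainty(2.5), "high")
  expect_equal(classify_uncertainty(0.2), "low")

  # determinism and failure accounting
  u_a <- uncertainty_eval(function(p) p[["x"]], c(x = 1), cv = c(x = 0.3),
                          n_subjects = 100, seed = 9)
  u_b <- uncertainty_eval(function(p) p[["x"]], c(x = 1), cv = c(x = 0.3),
                          n_subjects = 100, seed = 9)
  expect_identical(u_a$samples, u_b$samples)
  expect_error(
    uncertainty_eval(function(p) stop("boom"), c(x = 1), cv = c(x = 0.3),
                     n_subjects = 100, seed = 1),
    "failed")
})

test_that("reliability grades combine the two classifications", {
  sens <- data.frame(parameter = c("a", "b", "c", "d"),
                     s_class = c("high", "low", "high", "negligible"))
  unc <- data.frame(parameter = c("a", "b", "c", "d"),
                    u_class = c("high", "low", "medium", "low"))
  r <- reliability_matrix(sens, unc)
  expect_equal(r$reliability[r$parameter == "a"], "low")
  expect_equal(r$reliability[r$parameter == "b"], "high")
  expect_equal(r$reliability[r$parameter == "c"], "medium")
  expect_equal(r$reliability[r$parameter == "d"], "high")
  expect_warning(
    reliability_matrix(sens,
                       data.frame(parameter = c("a", "zzz"),
                                  u_class = c("high", "low"))),
    "unmatched")
})

test_that("population simulation summarizes correctly and degenerates cleanly", {
  # all CVs zero, fixed demographics: every subject identical
  p0 <- population_simulate(function(subj) c(cmax = subj$params[["a"]]),
                            params = c(a = 2), cv = c(a = 0), n = 10,
                            age_range = c(40, 40),
                            weight_range = c(70, 70), seed = 1)
  expect_equal(p0$summary$cv_pct, 0)
  expect_true(all(p0$metrics[, "cmax"] == 2))

  # passthrough log-normal: sample mean within 3 SE of the analytic mean
  cv <- 0.4
  pp <- population_simulate(function(subj) c(cmax = subj$params[["a"]]),
                            params = c(a = 1), cv = c(a = cv), n = 400,
                            seed = 7)
  sigma2 <- log(1 + cv^2)
  analytic_mean <- exp(sigma2 / 2)     # median 1, mean e^{sigma^2/2}
  se <- sd(pp$metrics[, "cmax"]) / sqrt(400)
  expect_lt(abs(pp$summary$mean - analytic_mean), 3 * se)

  # summary carries the population-table fields
  expect_true(all(c("mean", "geo_mean", "cv_pct", "min", "max",
                    "ci90_lo", "ci90_hi") %in% names(pp$summary)))
})
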