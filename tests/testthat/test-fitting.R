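# True generating coefficients used throughout: the pooled-stage models
# (DMI: 3.27 STAGE + 9.21 NEm + 0.133 SBW^0.75 - 14.38; NEMI: 0.224 NEm
# + 0.0346 STAGE - 0.142).

dmi_truth <- c("(Intercept)" = -14.38, mbw = 0.133, nem = 9.21, stage = 3.27)
nemi_truth <- c("(Intercept)" = -0.142, nem = 0.224, stage = 0.0346)

test_that("zero-noise data are recovered exactly by both fits", {
  # exact interpolation: the generating coefficients come back to
  # numerical precision, and any other retained term is numerically zero
  cfg <- generator_config(noise_sd = 0)
  sim <- simulate_cow_data(cfg, seed = 61)
  m <- suppressWarnings(fit_dmi_model(sim))
  expect_true(all(names(dmi_truth) %in% m$terms))
  expect_equal(m$coefficients[names(dmi_truth)], dmi_truth,
               tolerance = 1e-6)
  extra <- setdiff(m$terms, names(dmi_truth))
  if (length(extra) > 0L) {
    expect_lt(max(abs(m$coefficients[extra])), 1e-8)
  }
  expect_equal(m$syx, 0, tolerance = 1e-6)

  cfg2 <- generator_config(model = "NEMI", noise_sd = 0)
  sim2 <- simulate_cow_data(cfg2, seed = 62)
  m2 <- suppressWarnings(fit_nemi_model(sim2))
  expect_true(all(names(nemi_truth) %in% m2$terms))
  expect_equal(m2$coefficients[names(nemi_truth)], nemi_truth,
               tolerance = 1e-6)
  extra2 <- setdiff(m2$terms, names(nemi_truth))
  if (length(extra2) > 0L) {
    expect_lt(max(abs(m2$coefficients[extra2])), 1e-8)
  }
})

test_that("noisy data recover the truth within two standard errors", {
  cfg <- generator_config(n_nonlactating = 300, n_lactating = 200,
                          noise_sd = 1.31)
  sim <- simulate_cow_data(cfg, seed = 67)
  m <- fit_dmi_model(sim)
  for (t in names(dmi_truth)) {
    expect_lt(abs(m$coefficients[[t]] - dmi_truth[[t]]), 2 * m$ses[[t]])
  }
  # interactions and quadratic (true coefficient zero) were pruned
  expect_false(any(c("nem_stage", "mbw_stage") %in% m$terms))
  expect_gt(m$adj_r2, 0.5)

  # NEMI response: generate from the NEMI model, refit
  cfg2 <- generator_config(n_nonlactating = 300, n_lactating = 200,
                           model = "NEMI", noise_sd = 0.5)
  sim2 <- simulate_cow_data(cfg2, seed = 68)
  m2 <- fit_nemi_model(sim2)
  for (t in names(nemi_truth)) {
    expect_lt(abs(m2$coefficients[[t]] - nemi_truth[[t]]), 2 * m2$ses[[t]])
  }
})

test_that("a strong injected interaction is retained", {
  cfg <- generator_config(n_nonlactating = 250, n_lactating = 250,
                          noise_sd = 0)
  sim <- simulate_cow_data(cfg, seed = 71)
  d <- as.data.frame(sim)
  # add a NEm-by-stage interaction far larger than its standard error,
  # plus mild noise so the fit is not exact
  set.seed(72)
  d$dmi_obs <- d$dmi_obs + 3 * d$diet_nem * stage_code(d$stage) +
    rnorm(nrow(d), 0, 0.5)
  m <- fit_dmi_model(cow_data(d))
  expect_true("nem_stage" %in% m$terms)
  expect_equal(m$coefficients[["nem_stage"]], 3, tolerance = 0.5)
})

test_that("the fitted solution matches the normal-equations oracle", {
  sim <- simulate_cow_data(seed = 73)
  m <- fit_dmi_model(sim)
  X <- cbind(1, metabolic_weight(sim$sbw_kg), sim$diet_nem,
             stage_code(sim$stage))
  oracle <- ols_oracle(X, sim$dmi_obs)
  got <- m$coefficients[c("(Intercept)", "mbw", "nem", "stage")]
  expect_equal(unname(got), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(m$ses[c("(Intercept)", "mbw", "nem", "stage")]),
               unname(oracle$se), tolerance = 1e-8)
})

test_that("model fitting guards its preconditions", {
  sim <- simulate_cow_data(seed = 79)
  one_stage <- cow_data(as.data.frame(sim)[sim$stage == "nonlactating", ])
  expect_error(fit_dmi_model(one_stage), "both production stages")
  expect_error(fit_nemi_model(one_stage), "both production stages")
  no_dmi <- as.data.frame(sim); no_dmi$dmi_obs[3] <- NA
  expect_error(fit_dmi_model(cow_data(no_dmi)), "dmi_obs")
})

test_that("dmi_from_nemi converts published coefficients to intake", {
  m <- intake_model("NEMI", nemi_truth)
  lact <- cow("lactating", sbw_kg = 545, diet_nem = 1.3)
  expect_equal(dmi_from_nemi(m, lact), 15.948, tolerance = 1e-3)
  dry <- cow("nonlactating", sbw_kg = 545, diet_nem = 0.9)
  expect_equal(dmi_from_nemi(m, dry), 7.470, tolerance = 1e-3)
  # zero energy intake maps to zero feed intake
  m0 <- intake_model("NEMI", c("(Intercept)" = 0))
  expect_equal(dmi_from_nemi(m0, lact), 0)
  # response type is enforced
  mD <- intake_model("DMI", dmi_truth)
  expect_error(dmi_from_nemi(mD, lact), "NEMI")
})

test_that("milk response summary spreads the stage adjustment over milk", {
  s <- milk_response_summary(3.27, 6.56)
  expect_equal(round(s$intake_per_kg_milk, 2), 0.50)
  expect_equal(s$intake_per_kg_milk, 3.27 / 6.56)
  expect_equal(round(milk_response_summary(3.27, 7.3)$intake_per_kg_milk, 2),
               0.45)
  expect_equal(milk_response_summary(0, 5)$intake_per_kg_milk, 0)
  expect_equal(s$comparison_nasem, 0.2 * 6.56)
  expect_error(milk_response_summary(3.27, 0), "positive")
  expect_error(milk_response_summary(3.27, -2), "positive")
})

test_that("the lactation energy budget balances requirement and response", {
  b <- lactation_energy_budget(6.56, diet_nem = 1.3, stage_coefficient = 3.27)
  expect_equal(round(b$lactation_requirement, 1), 6.9)
  expect_equal(round(b$intake_response, 1), 4.3)
  expect_equal(round(b$intake_response, 1) - round(b$lactation_requirement, 1),
               -2.6)
  expect_lt(b$balance, 0)  # moderate-energy diet cannot cover lactation
  b0 <- lactation_energy_budget(0, maintenance_increment = 0,
                                diet_nem = 1.3, stage_coefficient = 3.27)
  expect_equal(b0$lactation_requirement, 0)
  expect_error(
    lactation_energy_budget(-1, diet_nem = 1.3, stage_coefficient = 3.27),
    "non-negative")
  expect_error(
    lactation_energy_budget(6.56, diet_nem = 0, stage_coefficient = 3.27),
    "positive")
})

test_that("an overparameterized concave intake curve is rejected", {
  # force a strong concave-in-NEm quadratic into the generating model so
  # the implied intake curve bends downward inside the data range
  set.seed(83)
  gen <- intake_model("DMI", c("(Intercept)" = -40, mbw = 0.133,
                               nem = 60, nem2 = -20, stage = 3.27))
  cfg <- generator_config(n_nonlactating = 200, n_lactating = 150,
                          model = gen, noise_sd = 0.3)
  sim <- simulate_cow_data(cfg, seed = 83)
  m <- fit_dmi_model(sim)
  expect_true(m$overparameterized)
  expect_false("nem2" %in% m$terms)
})
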