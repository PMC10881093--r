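# The 4-point worked instance below has closed-form OLS solutions:
# sum((P - Pbar)(O - Obar)) = 19, sum((P - Pbar)^2) = 20, so b = 0.95,
# a = 13.75 - 0.95 * 13 = 1.40, RSS = 0.70.
O4 <- c(11, 13, 14, 17)
P4 <- c(10, 12, 14, 16)

test_that("unity regression matches the closed-form 4-point solution", {
  r <- unity_regression(O4, P4)
  expect_equal(r$slope, 0.95)
  expect_equal(r$intercept, 1.40)
  expect_equal(r$r2, 0.96267, tolerance = 1e-5)
  expect_equal(r$syx_rmse, 0.5916, tolerance = 1e-4)
})

test_that("a perfect predictor yields the unity line with zero scatter", {
  o <- c(10, 12, 15, 18, 21)
  r <- suppressWarnings(unity_regression(o, o))
  expect_equal(r$intercept, 0)
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)
  expect_equal(r$syx_rmse, 0)
})

test_that("a doubled response is detected as slope 2", {
  set.seed(3)
  p <- runif(100, 8, 20)
  r <- unity_regression(2 * p + rnorm(100, 0, 0.1), p)
  expect_equal(r$slope, 2, tolerance = 0.02)
  expect_lt(r$p_slope_one, 1e-10)
})

test_that("unity regression agrees with the normal-equations oracle", {
  set.seed(17)
  for (k in 1:30) {
    p <- runif(5, 8, 20)
    o <- 1 + 0.9 * p + rnorm(5)
    r <- unity_regression(o, p)
    oracle <- ols_oracle(cbind(1, p), o)
    expect_equal(r$intercept, unname(oracle$beta[1]), tolerance = 1e-8)
    expect_equal(r$slope, unname(oracle$beta[2]), tolerance = 1e-8)
    expect_equal(unname(r$se_intercept), unname(oracle$se[1]),
                 tolerance = 1e-8)
    expect_equal(unname(r$se_slope), unname(oracle$se[2]), tolerance = 1e-8)
  }
})

test_that("unity regression rejects degenerate input", {
  expect_error(unity_regression(c(1, 2, 3), c(1, 1, 1)), "constant")
  expect_error(unity_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(unity_regression(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("rmsd is the root mean squared distance from the unity line", {
  expect_equal(rmsd(O4, P4), sqrt(3 / 4))
  expect_equal(rmsd(c(5, 7), c(5, 7)), 0)
  expect_equal(rmsd(10, 13), 3)
  expect_error(rmsd(c(1, 2), 1), "equal length")
})

test_that("Theil partition matches the hand-worked 4-point instance", {
  th <- theil_decomposition(O4, P4)
  expect_equal(th$sspe, 3)
  expect_equal(th$u_bias_pct, 75)
  expect_equal(th$u_slope_pct, 100 * 0.05 / 3, tolerance = 1e-10)
  expect_equal(th$u_error_pct, 100 * 0.70 / 3, tolerance = 1e-10)
})

test_that("pure-bias and pure-disturbance patterns land on one component", {
  p <- c(10, 12, 14, 16)
  th <- theil_decomposition(p + 2, p)
  expect_equal(th$u_bias_pct, 100)
  expect_equal(th$u_slope_pct, 0)
  expect_equal(th$u_error_pct, 0)
  # residuals orthogonal to the predictor with equal means: slope 1,
  # no mean shift, so everything is disturbance
  e <- c(1, -1, -1, 1)
  th2 <- theil_decomposition(p + e, p)
  expect_equal(th2$u_error_pct, 100)
})

test_that("the three Theil components sum to SSPE to machine precision", {
  set.seed(23)
  for (k in 1:50) {
    n <- sample(3:40, 1)
    p <- runif(n, 5, 25)
    o <- runif(1, -3, 3) + runif(1, 0.5, 1.8) * p + rnorm(n, 0, 2)
    th <- theil_decomposition(o, p)
    expect_equal(th$u_bias_pct + th$u_slope_pct + th$u_error_pct, 100,
                 tolerance = 1e-10)
    # reconstructed absolute components
    b <- cov(o, p) / var(p)
    bias <- n * (mean(o) - mean(p))^2
    slope <- (b - 1)^2 * sum((p - mean(p))^2)
    expect_equal(th$sspe, sum((o - p)^2))
    expect_equal(th$sspe * th$u_bias_pct / 100, bias, tolerance = 1e-9)
    expect_equal(th$sspe * th$u_slope_pct / 100, slope, tolerance = 1e-9)
  }
})

test_that("SSPE dominates the regression residual SS, equal only on unity", {
  set.seed(29)
  for (k in 1:30) {
    n <- sample(5:30, 1)
    p <- runif(n, 5, 25)
    o <- runif(1, -2, 2) + runif(1, 0.6, 1.6) * p + rnorm(n)
    r <- unity_regression(o, p)
    sspe <- sum((o - p)^2)
    expect_gte(sspe + 1e-12, r$rss)
  }
  # equality when the fit is exactly the unity line
  p <- c(10, 12, 14, 16)
  o <- p + c(1, -1, -1, 1)  # slope 1, intercept 0 by construction
  r <- unity_regression(o, p)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(sum((o - p)^2), r$rss, tolerance = 1e-12)
})

test_that("slope and non-bias components are shift-invariant", {
  set.seed(31)
  p <- runif(20, 8, 20)
  o <- 1.5 + 1.2 * p + rnorm(20)
  r1 <- unity_regression(o, p)
  th1 <- theil_decomposition(o, p)
  r2 <- unity_regression(o + 5, p + 5)
  th2 <- theil_decomposition(o + 5, p + 5)
  expect_equal(r1$slope, r2$slope)
  expect_equal(th1$sspe * th1$u_slope_pct, th2$sspe * th2$u_slope_pct,
               tolerance = 1e-8)
  expect_equal(th1$sspe * th1$u_error_pct, th2$sspe * th2$u_error_pct,
               tolerance = 1e-8)
})

test_that("evaluate_equation composes prediction and validation", {
  # self-consistency: data generated from the pooled DMI model evaluated
  # with the same model recovers the unity line
  cfg <- generator_config(n_nonlactating = 500, n_lactating = 0)
  sim <- simulate_cow_data(cfg, seed = 101)
  rep <- evaluate_equation("DMI", sim)
  expect_lt(abs(rep$slope - 1), 0.1)
  expect_lt(abs(rep$intercept), 1)
  expect_true(rep$theil_defined)
  expect_equal(rep$n, 500)

  # the classical nonlactating equation underpredicts at high intake:
  # observed-on-predicted slope well above 1
  repA <- evaluate_equation("A", sim)
  expect_gt(repA$slope, 1.1)

  # perfect prediction: report flags the undefined Theil partition
  perfect <- as.data.frame(sim[1:10, ])
  perfect$dmi_obs <- predict_dmi("DMI", cow_data(perfect))$dmi_pred
  repP <- suppressWarnings(evaluate_equation("DMI", cow_data(perfect)))
  expect_false(repP$theil_defined)
  expect_equal(repP$rmsd, 0)
  expect_equal(repP$slope, 1)

  # reports concatenate into a combined table
  tab <- rbind(as.data.frame(rep), as.data.frame(repA))
  expect_equal(tab$equation_id, c("DMI", "A"))
  expect_equal(ncol(tab), 16)
})
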