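# Observed-versus-predicted validation: regression of observed intake (y)
# on predicted intake (x), deviation from the unity line y = x, and the
# Theil partition of the squared sum of prediction error.

#' Regression of observed on predicted values with unity-line tests
#'
#' Fits ordinary least squares of observed values (y) on predicted values
#' (x) and tests the fitted line against the unity line y = x: marginal
#' t-tests of intercept = 0 and slope = 1, plus the joint 2-df F-test of
#' (intercept, slope) = (0, 1). `syx_rmse` is the residual standard error
#' about the fitted line (denominator n - 2); it equals the root mean
#' squared deviation about the unity line only when the fit is exactly
#' the unity line.
#'
#' @param observed Numeric vector of observed values (kg/d).
#' @param predicted Numeric vector of predicted values (kg/d), same
#'   length, not constant, n >= 3.
#' @return A `unity_regression` object: list with `n`, `intercept`,
#'   `se_intercept`, `slope`, `se_slope`, `p_intercept_zero`,
#'   `p_slope_one`, `p_joint`, `r2`, `syx_rmse` and the residual sum of
#'   squares `rss`.
#' @examples
#' unity_regression(c(11, 13, 14, 17), c(10, 12, 14, 16))
#' @export
unity_regression <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 3L)
  if (stats::sd(predicted) == 0) {
    stop("`predicted` is constant; regression design is degenerate",
         call. = FALSE)
  }
  n <- length(observed)
  fit <- stats::lm(observed ~ predicted)
  cf <- summary(fit)$coefficients
  a <- cf["(Intercept)", "Estimate"]
  b <- cf["predicted", "Estimate"]
  se_a <- cf["(Intercept)", "Std. Error"]
  se_b <- cf["predicted", "Std. Error"]
  rss <- sum(stats::residuals(fit)^2)
  df_res <- n - 2L
  p_a <- 2 * stats::pt(abs(a / se_a), df_res, lower.tail = FALSE)
  p_b <- 2 * stats::pt(abs((b - 1) / se_b), df_res, lower.tail = FALSE)
  # restricted model (a, b) = (0, 1) has residuals observed - predicted
  sspe <- sum((observed - predicted)^2)
  f_joint <- ((sspe - rss) / 2) / (rss / df_res)
  p_joint <- if (rss == 0) {
    if (sspe == 0) NA_real_ else 0
  } else {
    stats::pf(f_joint, 2, df_res, lower.tail = FALSE)
  }
  structure(list(
    n = n, intercept = a, se_intercept = se_a, slope = b, se_slope = se_b,
    p_intercept_zero = p_a, p_slope_one = p_b, p_joint = p_joint,
    r2 = stats::cor(observed, predicted)^2,
    syx_rmse = sqrt(rss / df_res), rss = rss
  ), class = "unity_regression")
}

#' @export
print.unity_regression <- function(x, ...) {
  cat("<unity_regression> n =", x$n, "\n")
  cat(sprintf("  intercept %.3f +/- %.3f (p[a=0] = %.3g)\n",
              x$intercept, x$se_intercept, x$p_intercept_zero))
  cat(sprintf("  slope     %.3f +/- %.3f (p[b=1] = %.3g)\n",
              x$slope, x$se_slope, x$p_slope_one))
  cat(sprintf("  r2 = %.3f, Sy.x (RMSE) = %.3f, p[joint a=0,b=1] = %.3g\n",
              x$r2, x$syx_rmse, x$p_joint))
  invisible(x)
}

#' Root mean squared deviation about the unity line
#'
#' The average distance of observed values from the line y = x:
#' `sqrt(mean((observed - predicted)^2))`. Unlike the residual standard
#' error of the fitted regression, this penalises bias and slope
#' departures, which is what matters when prediction is the goal.
#'
#' @inheritParams unity_regression
#' @return RMSD in the units of the inputs (kg/d).
#' @examples
#' rmsd(c(11, 13, 14, 17), c(10, 12, 14, 16)) # sqrt(3/4)
#' @export
rmsd <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 1L)
  sqrt(mean((observed - predicted)^2))
}

#' Theil decomposition of the squared sum of prediction error
#'
#' Partitions `SSPE = sum((observed - predicted)^2)` into three exactly
#' additive components: mean bias `n * (mean(O) - mean(P))^2`, slope
#' deviation `(b - 1)^2 * sum((P - mean(P))^2)` where `b` is the
#' observed-on-predicted regression slope, and the residual (random) sum
#' of squares of that regression. Each is reported as a percent of SSPE.
#' When SSPE is zero the prediction is perfect and the partition is
#' undefined: the percentages are `NA` and `perfect` is `TRUE`.
#'
#' @inheritParams unity_regression
#' @return A `theil_decomposition` object: list with `sspe`,
#'   `u_bias_pct`, `u_slope_pct`, `u_error_pct`, `perfect`.
#' @examples
#' theil_decomposition(c(11, 13, 14, 17), c(10, 12, 14, 16))
#' @export
theil_decomposition <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 3L)
  n <- length(observed)
  sspe <- sum((observed - predicted)^2)
  if (sspe == 0) {
    return(structure(list(
      sspe = 0, u_bias_pct = NA_real_, u_slope_pct = NA_real_,
      u_error_pct = NA_real_, perfect = TRUE
    ), class = "theil_decomposition"))
  }
  if (stats::sd(predicted) == 0) {
    stop("`predicted` is constant; slope component is undefined",
         call. = FALSE)
  }
  sxx <- sum((predicted - mean(predicted))^2)
  b <- sum((predicted - mean(predicted)) * (observed - mean(observed))) / sxx
  bias <- n * (mean(observed) - mean(predicted))^2
  slope <- (b - 1)^2 * sxx
  a <- mean(observed) - b * mean(predicted)
  err <- sum((observed - a - b * predicted)^2)
  structure(list(
    sspe = sspe,
    u_bias_pct = 100 * bias / sspe,
    u_slope_pct = 100 * slope / sspe,
    u_error_pct = 100 * err / sspe,
    perfect = FALSE
  ), class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, ...) {
  if (x$perfect) {
    cat("<theil_decomposition> SSPE = 0 (perfect prediction; partition undefined)\n")
  } else {
    cat(sprintf(
      "<theil_decomposition> SSPE = %.4g; U_bias = %.0f%%, U_slope = %.0f%%, U_error = %.0f%%\n",
      x$sspe, x$u_bias_pct, x$u_slope_pct, x$u_error_pct))
  }
  invisible(x)
}

#' Validate one prediction equation against observed intake
#'
#' Predicts intake for every row of `data` with [predict_dmi()], then
#' composes [unity_regression()], [rmsd()] and [theil_decomposition()]
#' into a single validation report. Reports for several equations can be
#' row-bound via `as.data.frame()` into a combined table of fit
#' statistics and error partitions.
#'
#' @inheritParams predict_dmi
#' @return An `evaluation_report` object; `as.data.frame()` yields one
#'   row with all statistics.
#' @export
evaluate_equation <- function(eq, data, nem_window = c(0.7, 2.1)) {
  eq <- intake_equation(eq)
  if (!inherits(data, "cow_data")) data <- cow_data(data)
  if (anyNA(data$dmi_obs)) {
    stop("all observations must carry dmi_obs for evaluation", call. = FALSE)
  }
  pred <- predict_dmi(eq, data, nem_window = nem_window)$dmi_pred
  obs <- data$dmi_obs
  reg <- unity_regression(obs, pred)
  theil <- theil_decomposition(obs, pred)
  structure(list(
    equation_id = eq$id, n = reg$n,
    intercept = reg$intercept, se_intercept = reg$se_intercept,
    slope = reg$slope, se_slope = reg$se_slope,
    p_intercept_zero = reg$p_intercept_zero, p_slope_one = reg$p_slope_one,
    p_joint = reg$p_joint, r2 = reg$r2, syx_rmse = reg$syx_rmse,
    rmsd = rmsd(obs, pred), sspe = theil$sspe,
    u_bias_pct = theil$u_bias_pct, u_slope_pct = theil$u_slope_pct,
    u_error_pct = theil$u_error_pct, theil_defined = !theil$perfect
  ), class = "evaluation_report")
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(x[c("equation_id", "n", "r2", "rmsd", "intercept", "se_intercept",
                 "slope", "se_slope", "p_intercept_zero", "p_slope_one",
                 "p_joint", "syx_rmse", "sspe", "u_bias_pct", "u_slope_pct",
                 "u_error_pct")],
             stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> equation ", x$equation_id, ", n = ", x$n, "\n",
      sep = "")
  cat(sprintf("  r2 = %.2f  RMSD = %.2f kg/d  Sy.x = %.2f kg/d\n",
              x$r2, x$rmsd, x$syx_rmse))
  cat(sprintf("  intercept %.2f +/- %.2f (p = %.3g), slope %.2f +/- %.2f (p vs 1 = %.3g)\n",
              x$intercept, x$se_intercept, x$p_intercept_zero,
              x$slope, x$se_slope, x$p_slope_one))
  if (x$theil_defined) {
    cat(sprintf("  SSPE = %.3g: U_bias %.0f%%, U_slope %.0f%%, U_error %.0f%%\n",
                x$sspe, x$u_bias_pct, x$u_slope_pct, x$u_error_pct))
  } else {
    cat("  SSPE = 0 (perfect prediction; Theil partition undefined)\n")
  }
  invisible(x)
}

# shared argument checks for paired observed/predicted vectors
check_pair <- function(observed, predicted, min_n) {
  if (!is.numeric(observed) || !is.numeric(predicted)) {
    stop("`observed` and `predicted` must be numeric", call. = FALSE)
  }
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  invisible(TRUE)
}
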