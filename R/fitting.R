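# Refitting the two pooled-stage intake models on any dataset:
# the NEMI model (metabolic-scaled daily NEm intake, Mcal/kg^0.75/d) and
# the direct DMI model (kg/d), each with backward pruning of
# non-significant interactions and quadratic, and a monotonicity guard
# against the overparameterized concave intake curve.

# canonical term vocabulary; interactions are encoded as product columns
.TERM_LABELS <- c(
  "(Intercept)" = "(Intercept)",
  nem = "NEm", nem2 = "NEm^2", stage = "STAGE", mbw = "SBW^0.75",
  nem_stage = "NEm:STAGE", mbw_stage = "SBW^0.75:STAGE"
)

.design_frame <- function(data) {
  stg <- stage_code(data$stage)
  mbw <- metabolic_weight(data$sbw_kg)
  data.frame(
    nem = data$diet_nem, nem2 = data$diet_nem^2, stage = stg,
    mbw = mbw, nem_stage = data$diet_nem * stg, mbw_stage = mbw * stg
  )
}

.design_matrix <- function(d, terms) {
  stopifnot("(Intercept)" %in% terms)
  X <- cbind(`(Intercept)` = rep(1, nrow(d)))
  for (t in setdiff(terms, "(Intercept)")) X <- cbind(X, d[[t]])
  colnames(X) <- terms
  X
}

#' Construct an intake model from known coefficients
#'
#' Builds a fitted-model object directly from a named coefficient vector,
#' e.g. to apply the published pooled-stage coefficients to new cows.
#' Valid term names: `"(Intercept)"`, `"nem"`, `"nem2"`, `"stage"`,
#' `"mbw"`, `"nem_stage"`, `"mbw_stage"` (`mbw` is `SBW^0.75`; the last
#' two are the stage interactions).
#'
#' @param response `"NEMI"` (Mcal/kg^0.75/d) or `"DMI"` (kg/d).
#' @param coefficients Named numeric vector of coefficients.
#' @return An `intake_model` object (without inference statistics).
#' @examples
#' m <- intake_model("NEMI",
#'   c("(Intercept)" = -0.142, nem = 0.224, stage = 0.0346))
#' @export
intake_model <- function(response = c("NEMI", "DMI"), coefficients) {
  response <- match.arg(response)
  if (is.null(names(coefficients)) ||
      !all(names(coefficients) %in% names(.TERM_LABELS))) {
    stop("coefficients must be named with terms among: ",
         paste(names(.TERM_LABELS), collapse = ", "), call. = FALSE)
  }
  structure(list(
    response = response, terms = names(coefficients),
    coefficients = coefficients,
    ses = rep(NA_real_, length(coefficients)),
    p_values = rep(NA_real_, length(coefficients)),
    adj_r2 = NA_real_, syx = NA_real_, n = NA_integer_,
    dropped = data.frame(term = character(0), p_value = numeric(0)),
    overparameterized = FALSE
  ), class = "intake_model")
}

#' @export
predict.intake_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "cow_data")) newdata <- cow_data(newdata)
  d <- .design_frame(newdata)
  X <- .design_matrix(d, object$terms)
  drop(X %*% object$coefficients[object$terms])
}

#' @export
print.intake_model <- function(x, ...) {
  cat("<intake_model> response: ", x$response,
      if (is.na(x$n)) " (fixed coefficients)" else paste0(", n = ", x$n),
      "\n", sep = "")
  tab <- data.frame(
    term = .TERM_LABELS[x$terms],
    estimate = signif(unname(x$coefficients), 4),
    se = signif(unname(x$ses), 3),
    p = signif(unname(x$p_values), 3)
  )
  print(tab, row.names = FALSE)
  if (!is.na(x$adj_r2)) {
    cat(sprintf("  adj R2 = %.3f, Sy.x = %.3f\n", x$adj_r2, x$syx))
  }
  if (nrow(x$dropped) > 0L) {
    cat("  dropped (p > 0.05): ",
        paste0(.TERM_LABELS[x$dropped$term], " (p = ",
               signif(x$dropped$p_value, 2), ")", collapse = ", "),
        "\n", sep = "")
  }
  if (x$overparameterized) {
    cat("  note: quadratic NEm term produced a non-monotone intake curve;",
        "linear model reported\n")
  }
  invisible(x)
}

# Backward elimination shared by both model fits. Droppable terms leave
# the model one at a time (interactions before the quadratic, highest p
# first); main effects are never dropped. Returns the final lm fit, the
# retained terms, and a log of drops.
.prune_fit <- function(y, d, start_terms, interactions, quadratic,
                       alpha = 0.05) {
  terms <- start_terms
  dropped <- data.frame(term = character(0), p_value = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    df_fit <- cbind(y = y, d[, setdiff(terms, "(Intercept)"), drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_fit)
    p <- summary(fit)$coefficients[, "Pr(>|t|)"]
    p[is.na(p)] <- 1  # inestimable or exactly-interpolated terms drop
    # consider interactions first; the quadratic only once they are gone
    cand <- intersect(interactions, terms)
    if (length(cand) == 0L) cand <- intersect(quadratic, terms)
    cand <- cand[cand %in% names(p)]
    if (length(cand) == 0L || all(p[cand] <= alpha)) {
      return(list(fit = fit, terms = terms, dropped = dropped))
    }
    worst <- cand[which.max(p[cand])]
    dropped <- rbind(dropped, data.frame(term = worst, p_value = p[[worst]],
                                         stringsAsFactors = FALSE))
    terms <- setdiff(terms, worst)
  }
}

# Predicted-DMI monotonicity over the observed NEm range; a quadratic
# that bends intake downward-then-upward (or up-then-down) within the
# data range signals overparameterization.
.dmi_curve_monotone <- function(coefs, terms, response, nem_range, mbw_ref,
                                stages) {
  grid <- seq(nem_range[1], nem_range[2], length.out = 101)
  for (s in stages) {
    d <- data.frame(nem = grid, nem2 = grid^2, stage = s, mbw = mbw_ref,
                    nem_stage = grid * s, mbw_stage = mbw_ref * s)
    X <- .design_matrix(d, terms)
    resp <- drop(X %*% coefs[terms])
    dmi <- if (response == "NEMI") resp * mbw_ref / grid else resp
    if (any(diff(dmi) < -1e-10)) return(FALSE)
  }
  TRUE
}

.finish_model <- function(pruned, y, d, response, quadratic_term,
                          nem_range, mbw_ref, stages, check_shape = TRUE) {
  fit <- pruned$fit
  terms <- pruned$terms
  dropped <- pruned$dropped
  over <- FALSE
  if (check_shape && quadratic_term %in% terms) {
    cf <- stats::coef(fit)
    names(cf)[1] <- "(Intercept)"
    if (!.dmi_curve_monotone(cf, terms, response, nem_range, mbw_ref,
                             stages)) {
      over <- TRUE
      terms <- setdiff(terms, quadratic_term)
      df_fit <- cbind(y = y, d[, setdiff(terms, "(Intercept)"), drop = FALSE])
      fit <- stats::lm(y ~ ., data = df_fit)
    }
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  rownames(cf)[1] <- "(Intercept)"
  structure(list(
    response = response, terms = terms,
    coefficients = stats::setNames(cf[terms, "Estimate"], terms),
    ses = stats::setNames(cf[terms, "Std. Error"], terms),
    p_values = stats::setNames(cf[terms, "Pr(>|t|)"], terms),
    adj_r2 = sm$adj.r.squared, syx = sm$sigma, n = length(y),
    dropped = dropped, overparameterized = over
  ), class = "intake_model")
}

.check_fit_data <- function(data) {
  if (!inherits(data, "cow_data")) data <- cow_data(data)
  if (anyNA(data$dmi_obs)) {
    stop("all observations must carry dmi_obs for fitting", call. = FALSE)
  }
  if (any(stage_counts(data) == 0L)) {
    stop("both production stages must be represented to estimate the ",
         "STAGE term", call. = FALSE)
  }
  data
}

#' Fit the metabolic-scaled energy intake (NEMI) model
#'
#' The response is daily NEm intake per unit metabolic weight,
#' `NEMI = DMI * NEm / SBW^0.75` (Mcal/kg^0.75/d). Candidate predictors
#' are diet NEm, its square, the 0/1 stage indicator, and the NEm-by-stage
#' interaction. The interaction is dropped when non-significant
#' (p > 0.05), then the quadratic; if a retained quadratic bends the
#' implied intake curve (`NEMI * SBW^0.75 / NEm`) non-monotonically over
#' the observed NEm range, the model is flagged overparameterized and the
#' linear form is reported.
#'
#' @param data A [cow_data] object with `dmi_obs` on every row and both
#'   stages represented.
#' @param alpha Significance threshold for retaining droppable terms.
#' @param prune If `FALSE`, keep the full candidate model: no backward
#'   elimination and no shape-based quadratic rejection. Useful for
#'   simulation studies of the unselected OLS estimator.
#' @return An `intake_model` with `response = "NEMI"`.
#' @seealso [dmi_from_nemi()] to convert predictions to kg/d intake.
#' @export
fit_nemi_model <- function(data, alpha = 0.05, prune = TRUE) {
  data <- .check_fit_data(data)
  d <- .design_frame(data)
  y <- data$dmi_obs * data$diet_nem / d$mbw
  pruned <- .prune_fit(
    y, d, start_terms = c("(Intercept)", "nem", "nem2", "stage", "nem_stage"),
    interactions = "nem_stage", quadratic = "nem2",
    alpha = if (prune) alpha else Inf
  )
  .finish_model(pruned, y, d, response = "NEMI", quadratic_term = "nem2",
                nem_range = range(d$nem), mbw_ref = mean(d$mbw),
                stages = unique(d$stage), check_shape = prune)
}

#' Fit the direct DMI model
#'
#' Ordinary least squares of observed intake (kg/d) on metabolic body
#' weight, diet NEm, its square, the 0/1 stage indicator, and the
#' NEm-by-stage and weight-by-stage interactions. Non-significant
#' (p > 0.05) interactions are dropped stepwise (highest p first), then a
#' non-significant quadratic; a retained quadratic that makes the
#' predicted intake curve non-monotone over the observed NEm range is
#' flagged overparameterized and removed. Main effects are never dropped.
#'
#' @inheritParams fit_nemi_model
#' @return An `intake_model` with `response = "DMI"`.
#' @export
fit_dmi_model <- function(data, alpha = 0.05, prune = TRUE) {
  data <- .check_fit_data(data)
  d <- .design_frame(data)
  y <- data$dmi_obs
  pruned <- .prune_fit(
    y, d,
    start_terms = c("(Intercept)", "mbw", "nem", "nem2", "stage",
                    "nem_stage", "mbw_stage"),
    interactions = c("nem_stage", "mbw_stage"), quadratic = "nem2",
    alpha = if (prune) alpha else Inf
  )
  .finish_model(pruned, y, d, response = "DMI", quadratic_term = "nem2",
                nem_range = range(d$nem), mbw_ref = mean(d$mbw),
                stages = unique(d$stage), check_shape = prune)
}

#' Convert NEMI-model predictions to daily intake
#'
#' Predicted daily energy intake per metabolic weight is divided by diet
#' energy concentration and rescaled:
#' `DMI = NEMI * SBW^0.75 / NEm` (kg/d).
#'
#' @param model An `intake_model` with `response = "NEMI"`.
#' @param data A [cow_data] object.
#' @return Numeric vector of predicted DMI, kg/d.
#' @examples
#' m <- intake_model("NEMI",
#'   c("(Intercept)" = -0.142, nem = 0.224, stage = 0.0346))
#' dmi_from_nemi(m, cow("lactating", sbw_kg = 545, diet_nem = 1.3))
#' @export
dmi_from_nemi <- function(model, data) {
  if (!inherits(model, "intake_model") || model$response != "NEMI") {
    stop("`model` must be an intake_model with response 'NEMI'",
         call. = FALSE)
  }
  if (!inherits(data, "cow_data")) data <- cow_data(data)
  nemi_hat <- predict(model, data)
  nemi_hat * metabolic_weight(data$sbw_kg) / data$diet_nem
}

#' Feed-intake response to milk yield implied by the stage adjustment
#'
#' Spreads the lactation intercept adjustment of the DMI model over the
#' mean milk yield of the lactating data: kg of additional feed intake
#' per kg of milk produced, alongside the conventional benchmark of
#' 0.2 kg feed per kg milk.
#'
#' @param stage_coefficient Lactation intercept adjustment, kg/d.
#' @param mean_milk Mean milk yield of the lactating observations, kg/d;
#'   must be positive.
#' @return A `milk_response_summary`: list with `stage_coefficient`,
#'   `mean_milk`, `intake_per_kg_milk` (exact ratio),
#'   `comparison_nasem` (`0.2 * mean_milk`, kg/d).
#' @examples
#' milk_response_summary(3.27, 6.56)
#' @export
milk_response_summary <- function(stage_coefficient, mean_milk) {
  if (!is.numeric(mean_milk) || length(mean_milk) != 1L ||
      !is.finite(mean_milk) || mean_milk <= 0) {
    stop("`mean_milk` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(stage_coefficient) || length(stage_coefficient) != 1L ||
      !is.finite(stage_coefficient)) {
    stop("`stage_coefficient` must be a finite number", call. = FALSE)
  }
  structure(list(
    stage_coefficient = stage_coefficient,
    mean_milk = mean_milk,
    intake_per_kg_milk = stage_coefficient / mean_milk,
    comparison_nasem = 0.2 * mean_milk
  ), class = "milk_response_summary")
}

#' @export
print.milk_response_summary <- function(x, ...) {
  cat(sprintf(
    "<milk_response_summary> %.2f kg DMI per kg milk (stage adj %.2f kg/d over %.2f kg/d milk)\n",
    round(x$intake_per_kg_milk, 2), x$stage_coefficient, x$mean_milk))
  cat(sprintf("  benchmark 0.2 kg/kg adjustment: %.2f kg/d\n",
              x$comparison_nasem))
  invisible(x)
}

#' Energy budget of the lactation intake response
#'
#' Compares the net energy required for lactation (milk energy output
#' plus the increment in maintenance requirement) with the extra energy
#' intake delivered by the lactation adjustment of the DMI model at a
#' given diet energy density.
#'
#' @param milk_kg_d Milk yield, kg/d (non-negative).
#' @param milk_energy Net energy concentration of milk, Mcal/kg;
#'   default 0.72.
#' @param maintenance_increment Extra maintenance requirement during
#'   lactation, Mcal NEm/d; default 2.2.
#' @param diet_nem Diet NEm, Mcal/kg DM (positive).
#' @param stage_coefficient Lactation intake adjustment, kg/d
#'   (non-negative).
#' @return A `lactation_energy_budget`: list with
#'   `lactation_requirement` (Mcal/d), `intake_response` (Mcal/d), and
#'   `balance` (response minus requirement, Mcal/d).
#' @examples
#' lactation_energy_budget(6.56, diet_nem = 1.3, stage_coefficient = 3.27)
#' @export
lactation_energy_budget <- function(milk_kg_d, milk_energy = 0.72,
                                    maintenance_increment = 2.2,
                                    diet_nem, stage_coefficient) {
  num1 <- function(v, nm, min_ok = 0, strict = FALSE) {
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (strict) v > min_ok else v >= min_ok)
    if (!ok) stop("`", nm, "` must be a ",
                  if (strict) "positive" else "non-negative",
                  " number", call. = FALSE)
  }
  num1(milk_kg_d, "milk_kg_d")
  num1(milk_energy, "milk_energy", strict = TRUE)
  num1(maintenance_increment, "maintenance_increment")
  num1(diet_nem, "diet_nem", strict = TRUE)
  num1(stage_coefficient, "stage_coefficient")
  requirement <- milk_kg_d * milk_energy + maintenance_increment
  response <- stage_coefficient * diet_nem
  structure(list(
    lactation_requirement = requirement,
    intake_response = response,
    balance = response - requirement
  ), class = "lactation_energy_budget")
}

#' @export
print.lactation_energy_budget <- function(x, ...) {
  cat(sprintf(
    "<lactation_energy_budget> requirement %.1f Mcal/d, intake response %.1f Mcal/d, balance %+.1f Mcal/d\n",
    x$lactation_requirement, x$intake_response, x$balance))
  invisible(x)
}
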