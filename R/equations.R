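# The eight closed-form intake equations. A-C predict intake of
# nonlactating cows, D-F their lactating counterparts (D and E add the
# conventional 0.2 kg DMI per kg milk), and NEMI/DMI are the pooled-stage
# models with a 0/1 stage indicator. C and F use full SBW, not SBW^0.75,
# exactly as published.

EQUATION_IDS <- c("A", "B", "C", "D", "E", "F", "NEMI", "DMI")

.equation_table <- list(
  A = list(
    applicable_stage = "nonlactating", requires_milk = FALSE,
    coefficients = c(mbw_base = 0.0194, mbw_nem = 0.0545),
    label = "DMI = SBW^0.75 * (0.0194 + 0.0545 * NEm)"
  ),
  B = list(
    applicable_stage = "nonlactating", requires_milk = FALSE,
    coefficients = c(nem2 = 0.04997, const = 0.04631),
    label = "DMI = SBW^0.75 * (0.04997 * NEm^2 + 0.04631) / NEm"
  ),
  C = list(
    applicable_stage = "nonlactating", requires_milk = FALSE,
    coefficients = c(nem2 = -0.0323, nem = 0.0944, const = -0.0418),
    label = "DMI = (-0.0323 * NEm^2 + 0.0944 * NEm - 0.0418) * SBW"
  ),
  D = list(
    applicable_stage = "lactating", requires_milk = TRUE,
    coefficients = c(mbw_base = 0.0194, mbw_nem = 0.0545, milk = 0.2),
    label = "DMI = SBW^0.75 * (0.0194 + 0.0545 * NEm) + 0.2 * milk"
  ),
  E = list(
    applicable_stage = "lactating", requires_milk = TRUE,
    coefficients = c(nem2 = 0.04997, const = 0.04631, milk = 0.2),
    label = "DMI = (SBW^0.75 * (0.04997 * NEm^2 + 0.04631) + 0.2 * milk) / NEm"
  ),
  F = list(
    applicable_stage = "lactating", requires_milk = FALSE,
    coefficients = c(nem2 = -0.0261, nem = 0.07777, const = -0.0277),
    label = "DMI = (-0.0261 * NEm^2 + 0.07777 * NEm - 0.0277) * SBW"
  ),
  NEMI = list(
    applicable_stage = "both", requires_milk = FALSE,
    coefficients = c(nem = 0.224, stage = 0.0346, intercept = -0.142),
    label = "NEMI = 0.224 * NEm + 0.0346 * STAGE - 0.142; DMI = NEMI * SBW^0.75 / NEm"
  ),
  DMI = list(
    applicable_stage = "both", requires_milk = FALSE,
    coefficients = c(stage = 3.27, nem = 9.21, mbw = 0.133, intercept = -14.38),
    label = "DMI = 3.27 * STAGE + 9.21 * NEm + 0.133 * SBW^0.75 - 14.38"
  )
)

#' Look up an intake prediction equation
#'
#' Returns the specification of one of the eight closed-form prediction
#' equations: `"A"`, `"B"`, `"C"` (nonlactating), `"D"`, `"E"`, `"F"`
#' (lactating; D and E require a milk yield), and the two pooled-stage
#' models `"NEMI"` (metabolic-scaled energy intake, converted to DMI by
#' dividing by diet NEm) and `"DMI"` (direct intake model).
#'
#' @param id Equation identifier, one of
#'   `"A","B","C","D","E","F","NEMI","DMI"`.
#' @return An `intake_equation` object: a list with `id`,
#'   `applicable_stage`, `requires_milk`, `coefficients` and `label`.
#' @examples
#' intake_equation("DMI")
#' @export
intake_equation <- function(id) {
  if (inherits(id, "intake_equation")) return(id)
  id <- toupper(as.character(id))
  if (length(id) != 1L || !(id %in% EQUATION_IDS)) {
    stop("unknown equation id; expected one of ",
         paste(EQUATION_IDS, collapse = ", "), call. = FALSE)
  }
  spec <- .equation_table[[id]]
  structure(c(list(id = id), spec), class = "intake_equation")
}

#' @export
print.intake_equation <- function(x, ...) {
  cat("<intake_equation ", x$id, "> stage: ", x$applicable_stage,
      if (x$requires_milk) ", requires milk yield" else "", "\n  ",
      x$label, "\n", sep = "")
  invisible(x)
}

#' Predict dry matter intake for cow treatment means
#'
#' Applies one of the eight prediction equations to every row of a cow
#' table. Rows must satisfy the equation's stage requirement (A-C
#' nonlactating; D-F lactating; NEMI and DMI accept both), and D/E need a
#' milk yield. Diet NEm outside the validity window produces a warning,
#' not an error: the published response curves themselves extrapolate
#' beyond the data range.
#'
#' @param eq Equation id or [intake_equation] object.
#' @param data A [cow_data] object (or anything [cow_data()] accepts).
#' @param nem_window Length-2 numeric validity window for diet NEm,
#'   Mcal/kg; values outside trigger a warning. Default `c(0.7, 2.1)`.
#' @return A data frame with columns `equation_id`, `dmi_pred` (kg/d) and
#'   `nemi_pred` (Mcal/kg^0.75/d; non-missing for the NEMI equation only).
#' @examples
#' cows <- cow("nonlactating", sbw_kg = 545, diet_nem = 1.3)
#' predict_dmi("DMI", cows)
#' @export
predict_dmi <- function(eq, data, nem_window = c(0.7, 2.1)) {
  eq <- intake_equation(eq)
  if (!inherits(data, "cow_data")) data <- cow_data(data)

  if (eq$applicable_stage != "both") {
    bad <- which(as.character(data$stage) != eq$applicable_stage)
    if (length(bad) > 0L) {
      stop("equation ", eq$id, " applies to ", eq$applicable_stage,
           " cows only; violated in row ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  milk <- data$milk_kg_d
  if (eq$requires_milk) {
    bad <- which(is.na(milk))
    if (length(bad) > 0L) {
      stop("equation ", eq$id, " requires milk_kg_d; missing in row ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  nem <- data$diet_nem
  outside <- nem < nem_window[1] | nem > nem_window[2]
  if (any(outside)) {
    warning("diet_nem outside validity window [", nem_window[1], ", ",
            nem_window[2], "] Mcal/kg in ", sum(outside),
            " row(s); extrapolating", call. = FALSE)
  }

  sbw <- data$sbw_kg
  mbw <- metabolic_weight(sbw)
  stg <- stage_code(data$stage)
  nemi <- rep(NA_real_, nrow(data))

  dmi <- switch(eq$id,
    A = mbw * (0.0194 + 0.0545 * nem),
    B = mbw * (0.04997 * nem^2 + 0.04631) / nem,
    C = (-0.0323 * nem^2 + 0.0944 * nem - 0.0418) * sbw,
    D = mbw * (0.0194 + 0.0545 * nem) + 0.2 * milk,
    E = (mbw * (0.04997 * nem^2 + 0.04631) + 0.2 * milk) / nem,
    F = (-0.0261 * nem^2 + 0.07777 * nem - 0.0277) * sbw,
    DMI = 3.27 * stg + 9.21 * nem + 0.133 * mbw - 14.38,
    NEMI = {
      nemi <- 0.224 * nem + 0.0346 * stg - 0.142
      nemi * mbw / nem
    }
  )

  data.frame(equation_id = eq$id, dmi_pred = dmi, nemi_pred = nemi,
             stringsAsFactors = FALSE)
}

#' Predicted-intake response curve over a diet energy grid
#'
#' Evaluates one equation for a fixed cow over an increasing grid of diet
#' NEm values — the computation behind the published intake-response
#' curves for a 545-kg cow (with 7 kg/d milk for the lactating family).
#'
#' @param eq Equation id or [intake_equation] object.
#' @param sbw_kg Shrunk body weight, kg.
#' @param nem_grid Strictly increasing grid of diet NEm values, Mcal/kg,
#'   all positive.
#' @param milk_kg_d Milk yield, kg/d; required by equations D and E.
#' @param stage Production stage for the pooled-stage equations; defaults
#'   to the equation's applicable stage, or to `"lactating"` when a milk
#'   yield is supplied and `"nonlactating"` otherwise.
#' @inheritParams predict_dmi
#' @return Data frame with columns `equation_id`, `diet_nem`, `dmi_pred`
#'   and `nemi_pred`.
#' @examples
#' response_curve("B", sbw_kg = 545, nem_grid = seq(0.9, 1.6, by = 0.1))
#' @export
response_curve <- function(eq, sbw_kg, nem_grid, milk_kg_d = NA_real_,
                           stage = NULL, nem_window = c(0.7, 2.1)) {
  eq <- intake_equation(eq)
  if (length(nem_grid) == 0L) stop("`nem_grid` must be non-empty", call. = FALSE)
  if (any(!is.finite(nem_grid)) || any(nem_grid <= 0)) {
    stop("`nem_grid` values must be positive and finite", call. = FALSE)
  }
  if (length(nem_grid) > 1L && any(diff(nem_grid) <= 0)) {
    stop("`nem_grid` must be strictly increasing", call. = FALSE)
  }
  if (is.null(stage)) {
    stage <- if (eq$applicable_stage != "both") {
      eq$applicable_stage
    } else if (!is.na(milk_kg_d)) "lactating" else "nonlactating"
  }
  cows <- cow_data(data.frame(
    stage = stage, sbw_kg = sbw_kg, diet_nem = nem_grid,
    milk_kg_d = milk_kg_d, stringsAsFactors = FALSE
  ))
  pred <- predict_dmi(eq, cows, nem_window = nem_window)
  data.frame(equation_id = eq$id, diet_nem = nem_grid,
             dmi_pred = pred$dmi_pred, nemi_pred = pred$nemi_pred,
             stringsAsFactors = FALSE)
}
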