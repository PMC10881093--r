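# Outlier screening of treatment means: studentized residuals from the
# covariate regression of observed intake on diet NEm, SBW^0.75 and
# production stage.

#' Flag outlying treatment means by studentized residual
#'
#' Fits OLS of observed DMI on diet NEm, metabolic body weight
#' (`SBW^0.75`) and the 0/1 stage indicator (main effects only), computes
#' studentized residuals, and flags observations whose absolute residual
#' exceeds `threshold` (default 3). Externally studentized (leave-one-out)
#' residuals are the default; internal studentization is available. A
#' single screening pass is performed — flagged rows are reported, never
#' iteratively re-screened.
#'
#' @param data A [cow_data] object in which every row carries `dmi_obs`.
#' @param threshold Absolute studentized-residual cutoff; default 3.
#' @param type `"external"` (leave-one-out, default) or `"internal"`.
#' @param by_stage If `TRUE`, fit and studentize separately within each
#'   production stage (the stage indicator drops out of the within-stage
#'   model); default `FALSE` (pooled model with the stage term).
#' @return An `outlier_report`: data frame with columns `row`, `stage`,
#'   `dmi_obs`, `studentized_residual`, `flag`; the threshold and type
#'   are carried as attributes.
#' @export
flag_outliers <- function(data, threshold = 3,
                          type = c("external", "internal"),
                          by_stage = FALSE) {
  type <- match.arg(type)
  if (!inherits(data, "cow_data")) data <- cow_data(data)
  if (anyNA(data$dmi_obs)) {
    stop("all observations must carry dmi_obs for screening", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a positive number", call. = FALSE)
  }

  resid_for <- function(idx, with_stage) {
    d <- data.frame(
      dmi = data$dmi_obs[idx],
      nem = data$diet_nem[idx],
      mbw = metabolic_weight(data$sbw_kg[idx]),
      stage = stage_code(data$stage[idx])
    )
    n_terms <- if (with_stage) 4L else 3L  # including intercept
    if (nrow(d) < n_terms + 2L) {
      stop("too few observations (", nrow(d), ") for the screening model",
           call. = FALSE)
    }
    fit <- if (with_stage) {
      stats::lm(dmi ~ nem + mbw + stage, data = d)
    } else {
      stats::lm(dmi ~ nem + mbw, data = d)
    }
    if (type == "external") stats::rstudent(fit) else stats::rstandard(fit)
  }

  res <- numeric(nrow(data))
  if (by_stage) {
    for (s in STAGE_LEVELS) {
      idx <- which(data$stage == s)
      if (length(idx) > 0L) res[idx] <- resid_for(idx, with_stage = FALSE)
    }
  } else {
    res <- resid_for(seq_len(nrow(data)), with_stage = TRUE)
  }

  out <- data.frame(
    row = seq_len(nrow(data)),
    stage = as.character(data$stage),
    dmi_obs = data$dmi_obs,
    studentized_residual = as.numeric(res),
    flag = abs(as.numeric(res)) > threshold,
    stringsAsFactors = FALSE
  )
  structure(out, threshold = threshold, type = type, by_stage = by_stage,
            class = c("outlier_report", "data.frame"))
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", nrow(x), " observations screened (",
      attr(x, "type"), " studentization, |r| > ", attr(x, "threshold"),
      if (isTRUE(attr(x, "by_stage"))) ", within stage" else "",
      ")\n", sep = "")
  flagged <- x[x$flag, , drop = FALSE]
  if (nrow(flagged) == 0L) {
    cat("  no outliers flagged\n")
  } else {
    cat("  flagged rows:\n")
    print(as.data.frame(flagged), row.names = FALSE)
  }
  invisible(x)
}
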