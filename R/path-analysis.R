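# Recursive path model: diet NEm and production stage are exogenous;
# metabolic body weight (SBW^0.75) and DMI are endogenous. The model is
# just-identified, so standardized coefficients from two sequential OLS
# fits coincide with the structural (path-analytic) solution.

#' Fit the recursive path model of intake determinants
#'
#' All variables are z-scored (the 0/1 stage indicator by its sample
#' standard deviation), then two regressions are fit:
#' `SBW^0.75 ~ NEm + STAGE` and `DMI ~ NEm + STAGE + SBW^0.75`.
#' The standardized slopes are the direct path coefficients; indirect
#' effects of the exogenous variables on DMI are the products of their
#' path into `SBW^0.75` and the `SBW^0.75 -> DMI` path, and total effects
#' are direct plus indirect.
#'
#' @param data A [cow_data] object with `dmi_obs` on every row, both
#'   stages represented, and at least 10 observations.
#' @return A `path_model` object whose `paths` element is a data frame
#'   with columns `from`, `to`, `type` (`direct`/`indirect`/`total`),
#'   `coefficient`, `t`, `p`, `signif` (stars at p < 0.001 and p < 0.05;
#'   tests are reported for direct paths only).
#' @export
fit_path_model <- function(data) {
  if (!inherits(data, "cow_data")) data <- cow_data(data)
  if (anyNA(data$dmi_obs)) {
    stop("all observations must carry dmi_obs for path analysis",
         call. = FALSE)
  }
  if (nrow(data) < 10L) {
    stop("need at least 10 observations", call. = FALSE)
  }
  if (any(stage_counts(data) == 0L)) {
    stop("both production stages must be represented", call. = FALSE)
  }

  z <- function(v) (v - mean(v)) / stats::sd(v)
  d <- data.frame(
    nem = z(data$diet_nem),
    stage = z(stage_code(data$stage)),
    mbw = z(metabolic_weight(data$sbw_kg)),
    dmi = z(data$dmi_obs)
  )
  if (qr(cbind(1, d$nem, d$stage, d$mbw))$rank < 4L) {
    stop("predictors are collinear; path coefficients are not estimable",
         call. = FALSE)
  }

  fit1 <- stats::lm(mbw ~ nem + stage, data = d)
  fit2 <- stats::lm(dmi ~ nem + stage + mbw, data = d)
  cf1 <- summary(fit1)$coefficients
  cf2 <- summary(fit2)$coefficients

  direct <- data.frame(
    from = c("NEm", "STAGE", "NEm", "STAGE", "SBW^0.75"),
    to = c("SBW^0.75", "SBW^0.75", "DMI", "DMI", "DMI"),
    type = "direct",
    coefficient = c(cf1["nem", 1], cf1["stage", 1],
                    cf2["nem", 1], cf2["stage", 1], cf2["mbw", 1]),
    t = c(cf1["nem", 3], cf1["stage", 3],
          cf2["nem", 3], cf2["stage", 3], cf2["mbw", 3]),
    p = c(cf1["nem", 4], cf1["stage", 4],
          cf2["nem", 4], cf2["stage", 4], cf2["mbw", 4]),
    stringsAsFactors = FALSE
  )
  path <- function(from, to) {
    direct$coefficient[direct$from == from & direct$to == to]
  }
  indirect <- data.frame(
    from = c("NEm", "STAGE"), to = "DMI", type = "indirect",
    coefficient = c(path("NEm", "SBW^0.75") * path("SBW^0.75", "DMI"),
                    path("STAGE", "SBW^0.75") * path("SBW^0.75", "DMI")),
    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  total <- data.frame(
    from = c("NEm", "STAGE"), to = "DMI", type = "total",
    coefficient = c(path("NEm", "DMI") + indirect$coefficient[1],
                    path("STAGE", "DMI") + indirect$coefficient[2]),
    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  paths <- rbind(direct, indirect, total)
  paths$signif <- ifelse(is.na(paths$p), "",
                         ifelse(paths$p < 0.001, "***",
                                ifelse(paths$p < 0.05, "*", "")))
  structure(list(paths = paths, n = nrow(d)), class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> n =", x$n, "\n")
  tab <- x$paths
  tab$coefficient <- signif(tab$coefficient, 3)
  tab$t <- signif(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
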