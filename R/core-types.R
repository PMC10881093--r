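# Domain types, unit conventions, and CSV plumbing shared by all stages.
# Units are fixed throughout: kg for weights, kg/d for intake and milk,
# Mcal/kg DM for diet energy.

STAGE_LEVELS <- c("nonlactating", "lactating")

#' Convert live body weight to shrunk body weight
#'
#' Shrunk body weight (SBW) is the standard 4% shrink applied to live
#' weight to remove gut-fill variation: `SBW = BW * 0.96`.
#'
#' @param bw_kg Live body weight, kg. Must be positive and finite.
#' @return Shrunk body weight, kg.
#' @examples
#' shrink_weight(600) # 576
#' @export
shrink_weight <- function(bw_kg) {
  if (!is.numeric(bw_kg) || length(bw_kg) == 0L ||
      any(!is.finite(bw_kg)) || any(bw_kg <= 0)) {
    stop("`bw_kg` must be positive and finite", call. = FALSE)
  }
  bw_kg * 0.96
}

#' Metabolic body weight
#'
#' Scales shrunk body weight to metabolic size, `SBW^0.75` — the
#' conventional scaling for maintenance energy and intake.
#'
#' @param sbw_kg Shrunk body weight, kg. Must be positive and finite.
#' @return Metabolic body weight, kg^0.75.
#' @examples
#' metabolic_weight(545)
#' @export
metabolic_weight <- function(sbw_kg) {
  if (!is.numeric(sbw_kg) || length(sbw_kg) == 0L ||
      any(!is.finite(sbw_kg)) || any(sbw_kg <= 0)) {
    stop("`sbw_kg` must be positive and finite", call. = FALSE)
  }
  sbw_kg^0.75
}

#' Numeric coding of production stage
#'
#' Maps the categorical production stage to the 0/1 indicator used in all
#' model formulas: 0 = nonlactating, 1 = lactating.
#'
#' @param stage Character or factor vector with values `"nonlactating"` or
#'   `"lactating"`.
#' @return Numeric vector of 0/1 codes.
#' @export
stage_code <- function(stage) {
  stage <- as_stage(stage)
  as.numeric(stage == "lactating")
}

# Coerce to the canonical stage factor, erroring on unknown levels.
as_stage <- function(stage) {
  s <- as.character(stage)
  bad <- !is.na(s) & !(s %in% STAGE_LEVELS)
  if (any(bad)) {
    stop("unknown stage value(s): ", paste(unique(s[bad]), collapse = ", "),
         " (expected 'nonlactating' or 'lactating')", call. = FALSE)
  }
  factor(s, levels = STAGE_LEVELS)
}

#' Construct a single-cow treatment mean
#'
#' Convenience constructor for a one-row [cow_data] table; handy for
#' worked examples and response curves.
#'
#' @param stage `"nonlactating"` or `"lactating"`.
#' @param sbw_kg Shrunk body weight, kg.
#' @param diet_nem Diet net energy for maintenance, Mcal/kg DM.
#' @param dmi_obs Observed dry matter intake, kg/d (optional).
#' @param milk_kg_d Daily milk yield, kg/d (optional; lactating only).
#' @param bcs Body condition score, 1-9 scale (optional).
#' @param source_id Free-text provenance label (optional).
#' @return A one-row [cow_data] object.
#' @examples
#' cow("lactating", sbw_kg = 545, diet_nem = 1.3, milk_kg_d = 6.56)
#' @export
cow <- function(stage, sbw_kg, diet_nem, dmi_obs = NA_real_,
                milk_kg_d = NA_real_, bcs = NA_real_,
                source_id = NA_character_) {
  cow_data(data.frame(
    stage = stage, sbw_kg = sbw_kg, diet_nem = diet_nem,
    dmi_obs = dmi_obs, milk_kg_d = milk_kg_d, bcs = bcs,
    source_id = source_id, stringsAsFactors = FALSE
  ))
}

#' Validated table of cow treatment means
#'
#' Validates and classes a data frame of treatment means. Required
#' columns: `stage` (`"nonlactating"`/`"lactating"`), `sbw_kg` (shrunk
#' body weight, kg), `diet_nem` (Mcal/kg DM). Optional columns:
#' `dmi_obs` (kg/d), `milk_kg_d` (kg/d), `bcs` (1-9), `source_id`.
#'
#' Row invariants enforced (violations are reported with row indices):
#' positive `sbw_kg` and `diet_nem`; positive `dmi_obs` where present;
#' non-negative `milk_kg_d` restricted to lactating rows (nonlactating
#' rows may carry 0 or missing milk); `bcs` in \[1, 9\] where present.
#'
#' @param x A data frame.
#' @param label Free-text label for the dataset.
#' @return A `cow_data` object (a data frame).
#' @seealso [read_cow_data()], [cow()]
#' @export
cow_data <- function(x, label = "") {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  required <- c("stage", "sbw_kg", "diet_nem")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0L) stop("dataset must contain at least one row", call. = FALSE)

  out <- data.frame(
    stage = as_stage(x$stage),
    sbw_kg = as_num_col(x$sbw_kg, "sbw_kg"),
    diet_nem = as_num_col(x$diet_nem, "diet_nem"),
    bcs = if ("bcs" %in% names(x)) as_num_col(x$bcs, "bcs") else NA_real_,
    dmi_obs = if ("dmi_obs" %in% names(x)) as_num_col(x$dmi_obs, "dmi_obs") else NA_real_,
    milk_kg_d = if ("milk_kg_d" %in% names(x)) as_num_col(x$milk_kg_d, "milk_kg_d") else NA_real_,
    source_id = if ("source_id" %in% names(x)) as.character(x$source_id) else NA_character_,
    stringsAsFactors = FALSE
  )

  problems <- character(0)
  flag <- function(bad, what) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad) > 0L) {
      problems <<- c(problems, paste0(
        "row ", paste(bad, collapse = ", "), ": ", what))
    }
  }
  flag(is.na(out$stage), "missing stage")
  flag(is.na(out$sbw_kg) | out$sbw_kg <= 0, "sbw_kg must be positive")
  flag(is.na(out$diet_nem) | out$diet_nem <= 0, "diet_nem must be positive")
  flag(!is.na(out$dmi_obs) & out$dmi_obs <= 0, "dmi_obs must be positive when present")
  flag(!is.na(out$milk_kg_d) & out$milk_kg_d < 0, "milk_kg_d must be non-negative")
  flag(out$stage == "nonlactating" & !is.na(out$milk_kg_d) & out$milk_kg_d > 0,
       "nonlactating rows must have milk_kg_d absent or 0")
  flag(!is.na(out$bcs) & (out$bcs < 1 | out$bcs > 9), "bcs must lie in [1, 9]")
  if (length(problems) > 0L) {
    stop("invalid cow data:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  structure(out, label = label, class = c("cow_data", "data.frame"))
}

# Strict numeric coercion: character cells that do not parse are an error,
# never a silent NA.
as_num_col <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  v_chr <- trimws(as.character(v))
  v_chr[v_chr == ""] <- NA_character_
  parsed <- suppressWarnings(as.numeric(v_chr))
  bad <- which(!is.na(v_chr) & is.na(parsed))
  if (length(bad) > 0L) {
    stop("column '", name, "': unparseable numeric value(s) in row ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  parsed
}

#' Per-stage observation counts
#'
#' @param data A [cow_data] object.
#' @return Named integer vector with counts for `nonlactating` and
#'   `lactating`.
#' @export
stage_counts <- function(data) {
  stopifnot(inherits(data, "cow_data"))
  counts <- table(data$stage)
  out <- as.integer(counts[STAGE_LEVELS])
  names(out) <- STAGE_LEVELS
  out[is.na(out)] <- 0L
  out
}

#' @export
print.cow_data <- function(x, ...) {
  counts <- stage_counts(x)
  label <- attr(x, "label")
  cat("<cow_data> ", nrow(x), " treatment means (",
      counts[["nonlactating"]], " nonlactating, ",
      counts[["lactating"]], " lactating)",
      if (nzchar(label)) paste0(" - ", label) else "", "\n", sep = "")
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10L) cat("... and ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' Read a cow treatment-mean table from CSV
#'
#' Reads a comma-separated, header-required, UTF-8 file with "." decimals.
#' Empty cells are treated as missing optional fields; sentinel codes are
#' rejected as unparseable. If the file carries a live body-weight column
#' (`bw_kg`) and no `sbw_kg`, shrunk body weight is derived via
#' [shrink_weight()] and the conversion is reported with a message.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping canonical
#'   names to file column names, e.g. `c(sbw_kg = "BW_shrunk")`.
#' @param label Dataset label; defaults to the file name.
#' @return A [cow_data] object.
#' @export
read_cow_data <- function(path, column_map = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop("`column_map` must be a named character vector", call. = FALSE)
    }
    for (canonical in names(column_map)) {
      file_col <- column_map[[canonical]]
      if (!file_col %in% names(raw)) {
        stop("`column_map` refers to absent column: ", file_col, call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canonical
    }
  }
  if (!"sbw_kg" %in% names(raw) && "bw_kg" %in% names(raw)) {
    bw <- as_num_col(raw$bw_kg, "bw_kg")
    raw$sbw_kg <- NA_real_
    ok <- !is.na(bw)
    if (any(ok)) raw$sbw_kg[ok] <- shrink_weight(bw[ok])
    message("derived sbw_kg from bw_kg (shrink factor 0.96) for ",
            sum(ok), " row(s)")
  }
  required <- c("stage", "sbw_kg", "diet_nem")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cow_data(raw, label = label)
}

#' Write a tabular report to CSV at full precision
#'
#' Serializes any data frame (a [cow_data] table, an evaluation report,
#' an outlier report, ...) as comma-separated text. Numeric columns are
#' written with 17 significant digits so that reading the file back
#' recovers each double exactly; missing values become empty cells.
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cow_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    } else if (is.factor(out[[j]])) {
      out[[j]] <- as.character(out[[j]])
    }
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE),
    error = function(e) stop("cannot write to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}
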