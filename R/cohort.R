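#' Variable schema for the ASCVD risk-factor cohort
#'
#' The cohort data model covers 13 variables: two demographic roots (age,
#' sex), five binary clinical states (smoking, diabetes, hypertension,
#' metabolic syndrome, ASCVD), and six measurements recorded on continuous
#' scales (BMI in kg/m2; FBS, TG, T-C, HDL-C and LDL-C in mg/dL) that are
#' discretized into clinical categories. Each schema entry carries the ordered
#' state labels, the discretization rule for continuous variables, the
#' reference state used in descriptive tables, and the "risk" state used when
#' instantiating evidence in conditional-probability reports.
#'
#' Clinical cut-offs: age under/over 45 years; BMI normal < 25, overweight
#' 25 to < 30, obesity >= 30 (values below 18.5 are mapped to normal with a
#' warning since the cohort uses three classes); FBS high >= 100 mg/dL;
#' TG high >= 150 mg/dL; T-C high >= 200 mg/dL; HDL-C low < 45, normal 45-55,
#' high > 55 mg/dL; LDL-C high >= \code{ldl_boundary} (default 130 mg/dL).
#' The guideline bands for LDL-C leave 130-159 mg/dL unnamed between
#' "normal < 130" and "high >= 160"; the default places the single boundary
#' at 130 so the two categories partition the range, while
#' \code{strict = TRUE} turns the unassigned band (and BMI < 18.5) into
#' errors instead.
#'
#' @param ldl_boundary numeric, mg/dL boundary between normal and high LDL-C.
#' @param strict logical; if TRUE, values in undefined bands raise errors
#'   instead of being mapped with a warning.
#' @return A named list of variable specifications, one per column of the
#'   standard cohort table, each with elements \code{name}, \code{kind},
#'   \code{states}, \code{reference}, \code{risk} and (for continuous
#'   variables) \code{unit}.
#' @export
cohort_schema <- function(ldl_boundary = 130, strict = FALSE) {
  spec <- function(name, states, kind = "categorical", reference = states[1],
                   risk = states[length(states)], unit = NULL) {
    list(name = name, kind = kind, states = states, reference = reference,
         risk = risk, unit = unit)
  }
  out <- list(
    age = spec("age", c("under45", "over45"), "continuous", unit = "years"),
    sex = spec("sex", c("female", "male")),
    smoking = spec("smoking", c("never", "past-or-current")),
    diabetes = spec("diabetes", c("no", "yes")),
    hypertension = spec("hypertension", c("no", "yes")),
    mets = spec("mets", c("no", "yes")),
    ascvd = spec("ascvd", c("no", "yes")),
    bmi = spec("bmi", c("normal", "overweight", "obesity"), "continuous",
               reference = "normal", risk = "obesity", unit = "kg/m2"),
    fbs = spec("fbs", c("normal", "high"), "continuous", unit = "mg/dL"),
    tg = spec("tg", c("normal", "high"), "continuous", unit = "mg/dL"),
    tc = spec("tc", c("normal", "high"), "continuous", unit = "mg/dL"),
    hdl = spec("hdl", c("low", "normal", "high"), "continuous",
               reference = "normal", risk = "low", unit = "mg/dL"),
    ldl = spec("ldl", c("normal", "high"), "continuous", unit = "mg/dL")
  )
  attr(out, "ldl_boundary") <- ldl_boundary
  attr(out, "strict") <- strict
  out
}

cohort_variables <- function() names(cohort_schema())

#' State spaces of the standard cohort variables
#'
#' @param schema a schema from [cohort_schema()].
#' @return Named list mapping each variable to its ordered state labels.
#' @export
cohort_levels <- function(schema = cohort_schema()) {
  lapply(schema, `[[`, "states")
}

#' Discretize one continuous measurement into its clinical category
#'
#' @param variable variable name (one of the 13 standard cohort columns).
#' @param x numeric vector of raw measurements.
#' @param schema schema from [cohort_schema()] (carries the LDL-C boundary
#'   and the strict/lenient boundary policy).
#' @return Character vector of category labels.
#' @export
discretize_value <- function(variable, x, schema = cohort_schema()) {
  if (!variable %in% names(schema))
    stop("unknown variable '", variable, "'", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("non-finite value for '", variable, "'", call. = FALSE)
  if (any(x <= 0))
    stop("non-positive measurement for '", variable, "'", call. = FALSE)
  strict <- isTRUE(attr(schema, "strict"))
  ldl_boundary <- attr(schema, "ldl_boundary") %||% 130
  switch(variable,
    age = ifelse(x < 45, "under45", "over45"),
    bmi = {
      if (any(x < 18.5)) {
        msg <- paste0("BMI below 18.5 kg/m2 (", paste(x[x < 18.5], collapse = ", "),
                      "): outside the three cohort classes")
        if (strict) stop(msg, call. = FALSE)
        warning(msg, "; mapped to 'normal'", call. = FALSE)
      }
      ifelse(x < 25, "normal", ifelse(x < 30, "overweight", "obesity"))
    },
    fbs = ifelse(x < 100, "normal", "high"),
    tg = ifelse(x < 150, "normal", "high"),
    tc = ifelse(x < 200, "normal", "high"),
    hdl = ifelse(x < 45, "low", ifelse(x <= 55, "normal", "high")),
    ldl = {
      if (strict && any(x >= 130 & x < 160))
        stop("LDL-C value in the unassigned guideline band [130, 160): ",
             paste(x[x >= 130 & x < 160], collapse = ", "), call. = FALSE)
      ifelse(x < ldl_boundary, "normal", "high")
    },
    stop("variable '", variable, "' is categorical, not continuous",
         call. = FALSE)
  )
}

#' Discretize a cohort data frame
#'
#' Continuous columns (age, bmi, fbs, tg, tc, hdl, ldl) are mapped to their
#' clinical categories; columns that already hold category labels pass
#' through unchanged (discretization is idempotent). The result is a
#' validated cohort table with one factor column per variable.
#'
#' @param data data frame containing the 13 standard cohort columns (extra
#'   columns are ignored). Cells may be raw numeric measurements or category
#'   labels.
#' @param schema schema from [cohort_schema()].
#' @return A `cohort_table`: a data frame of factors, levels per schema.
#' @export
discretize_cohort <- function(data, schema = cohort_schema()) {
  vars <- names(schema)
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (v in vars) {
    col <- data[[v]]
    if (anyNA(col)) {
      bad <- which(is.na(col))
      stop("missing values in '", v, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; the analysis uses completers only", call. = FALSE)
    }
    states <- schema[[v]]$states
    if (is.numeric(col) && schema[[v]]$kind == "continuous") {
      col <- discretize_value(v, col, schema)
    } else {
      col <- as.character(col)
      bad <- which(!col %in% states)
      if (length(bad))
        stop("invalid state for '", v, "' at row ", bad[1], ": '",
             col[bad[1]], "' (expected one of ",
             paste(states, collapse = ", "), ")", call. = FALSE)
    }
    out[[v]] <- factor(col, levels = states)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read a cohort CSV
#'
#' Expects a header row naming all 13 standard variables (extra columns are
#' ignored). Raw continuous measurements are discretized on load; already
#' categorical files are validated and passed through. Missing values are
#' rejected: the analysis is restricted to completers.
#'
#' @param path CSV file path.
#' @param schema schema from [cohort_schema()].
#' @param quiet suppress the row-count message.
#' @return A `cohort_table` data frame of factors.
#' @export
load_cohort <- function(path, schema = cohort_schema(), quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing))
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- discretize_cohort(raw, schema)
  if (!quiet)
    message("loaded cohort: ", nrow(tab), " records, ",
            length(names(schema)), " variables")
  tab
}

#' Write a cohort table to CSV
#'
#' @param data a `cohort_table` (or any cohort data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- as.data.frame(lapply(data, as.character),
                       stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
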