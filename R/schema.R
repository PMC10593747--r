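# Variable schemas.
#
# A schema is a data.frame with one row per original variable:
#   name             variable name
#   kind             "time_invariant" or "time_varying"
#   dtype            "continuous" or "categorical"
#   imputation_rule  "mean" or "median" (continuous only; categorical always
#                    uses the median of its ordinal codes)
#   normal_flag      TRUE when the training distribution looked approximately
#                    normal (|skewness| < 1), in which case the mean is used
#
# The model-facing feature width for a schema is
#   |time_invariant| + |time_varying| + |time_varying| + 2
# (originals, auxiliary imputation indicators, and the two elapsed-time
# channels: time on dialysis and interval since the previous session).

#' Time-varying variable names used by the synthetic generator
#' @keywords internal
hd_tv_names <- function() {
  c("sbp", "dbp", "heart_rate", "respiratory_rate", "body_temp",
    "blood_flow_rate", "ultrafiltration_rate", "spo2",
    "venous_pressure", "dialysate_temp")
}

hd_static_names <- function() {
  c("age", "sex", "diabetes", "hypertension", "dialysis_vintage_years",
    "dry_weight", "hemoglobin", "albumin", "calcium", "phosphate",
    "sodium", "potassium")
}

#' Build a variable schema
#'
#' @param full If `TRUE`, pad the time-invariant block with additional lab
#'   covariates so that the schema has 56 time-invariant plus 10 time-varying
#'   variables (66 in total), matching the width of a realistic hemodialysis
#'   EMR extract. If `FALSE` (default) only the 12 core time-invariant
#'   variables of the synthetic generator are used.
#' @return A `data.frame` schema (class `hd_schema`).
#' @export
default_schema <- function(full = FALSE) {
  tv <- hd_tv_names()
  st <- hd_static_names()
  if (full) {
    st <- c(st, sprintf("lab_extra_%02d", seq_len(56L - length(st))))
  }
  categorical <- c("sex", "diabetes", "hypertension")
  sch <- data.frame(
    name  = c(st, tv),
    kind  = c(rep("time_invariant", length(st)), rep("time_varying", length(tv))),
    dtype = ifelse(c(st, tv) %in% categorical, "categorical", "continuous"),
    imputation_rule = "median",
    normal_flag = FALSE,
    stringsAsFactors = FALSE
  )
  class(sch) <- c("hd_schema", "data.frame")
  sch
}

#' Feature-column count implied by a schema
#'
#' Originals plus one auxiliary imputation-indicator column per time-varying
#' variable plus the two elapsed-time channels.
#' @param schema an `hd_schema`
#' @return integer column count
#' @export
schema_feature_count <- function(schema) {
  n_tv <- sum(schema$kind == "time_varying")
  nrow(schema) + n_tv + 2L
}

hd_schema_check <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "kind", "dtype") %in% names(schema)))
  if (anyDuplicated(schema$name))
    hd_stop("duplicate variable names in schema", "hdtft_schema_error")
  invisible(schema)
}
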