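# Woman-level record schema: the flat, DHS-like table every microdata
# estimator consumes. One row per woman of reproductive age.

record_columns <- function() {
  c("age_group", "in_union", "births_in_window", "method",
    "amenorrhea_months", "wastage_in_window",
    "region", "wealth_quintile", "education", "residence", "weight")
}

#' Validate a woman-level record table
#'
#' Checks and normalises a data frame of survey-style woman records:
#' one row per woman with her five-year age group, union status, live
#' births and foetal-wastage events in the retrospective window, current
#' contraceptive method, months of postpartum amenorrhea after the most
#' recent birth (NA when no recent birth - structural missingness, never
#' imputed), four background covariates and an optional sampling weight.
#'
#' Schema rules enforced:
#' * `age_group` one of the seven labels from [age_group_labels()];
#' * `method` one of none/pill/IUD/sterilization/injection/other, and
#'   `method != "none"` implies `in_union` (prevalence is defined among
#'   in-union women);
#' * counts non-negative, weights strictly positive (default 1).
#'
#' @param df A data frame with the columns above; `weight` and the
#'   covariate columns may be omitted (weight defaults to 1, covariates
#'   to a single level "all").
#' @return The normalised data frame, classed `woman_records`.
#' @export
woman_records <- function(df) {
  df <- as.data.frame(df)
  required <- c("age_group", "in_union", "births_in_window", "method",
                "amenorrhea_months", "wastage_in_window")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("woman records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("woman records table is empty")
  for (v in strata_vars()) if (is.null(df[[v]])) df[[v]] <- "all"
  if (is.null(df[["weight"]])) df[["weight"]] <- 1

  df$age_group <- as.character(df$age_group)
  bad_age <- setdiff(unique(df$age_group), age_group_labels())
  if (length(bad_age)) {
    stop("unknown age_group level(s): ", paste(bad_age, collapse = ", "),
         " (expected ", paste(age_group_labels(), collapse = ", "), ")")
  }
  df$in_union <- as.logical(df$in_union)
  if (anyNA(df$in_union)) stop("in_union must be TRUE/FALSE with no missing values")
  df$method <- as.character(df$method)
  bad_m <- setdiff(unique(df$method), method_levels())
  if (length(bad_m)) {
    stop("unknown method level(s): ", paste(bad_m, collapse = ", "),
         " (expected ", paste(method_levels(), collapse = ", "), ")")
  }
  if (any(df$method != "none" & !df$in_union)) {
    stop("method != 'none' requires in_union (prevalence is defined among in-union women)")
  }
  for (v in c("births_in_window", "wastage_in_window")) {
    df[[v]] <- as.numeric(df[[v]])
    if (anyNA(df[[v]]) || any(df[[v]] < 0)) stop(v, " must be non-negative counts")
  }
  df$amenorrhea_months <- as.numeric(df$amenorrhea_months)
  if (any(!is.na(df$amenorrhea_months) & df$amenorrhea_months < 0)) {
    stop("amenorrhea_months must be non-negative where present")
  }
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight) || any(df$weight <= 0)) stop("weights must be positive")
  for (v in strata_vars()) df[[v]] <- as.character(df[[v]])

  df <- df[record_columns()]
  class(df) <- c("woman_records", "data.frame")
  df
}

#' Read woman records from CSV
#'
#' Header-validated reader for the [woman_records()] schema. Empty
#' strings and "NA" in `amenorrhea_months` are read as missing.
#'
#' @param path Path to a CSV file.
#' @return A validated `woman_records` data frame.
#' @export
read_woman_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  woman_records(df)
}

#' Write woman records to CSV
#'
#' @param records A `woman_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_woman_records <- function(records, path) {
  stopifnot(inherits(records, "woman_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
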