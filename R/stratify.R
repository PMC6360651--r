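# Stratified analysis, percent-inhibition reporting, projection tables,
# and table rendering. Rounding per the reporting contract happens only
# here: indices to 3 dp, TFR to 3 dp, percents to 1 dp, projections to
# 1 dp (configurable through pd_config()$rounding).

#' Stratified proximate-determinants analysis
#'
#' Splits a woman-level table by one background covariate and estimates a
#' full [proximate_indices()] bundle per level, each computed only from
#' that level's records. Levels whose records fail an estimator
#' precondition (e.g. an empty age group) are reported by name in the
#' result's `warnings` and excluded from the rows.
#'
#' @param records A [woman_records()] table.
#' @param stratum_var One of `"region"`, `"wealth_quintile"`,
#'   `"education"`, `"residence"`.
#' @param window_years Retrospective window in years; defaults to the
#'   config's value.
#' @param config A [pd_config()].
#' @param survey_label Free-text label carried into rendered tables.
#' @return An object of class `stratified_result` with fields
#'   `stratum_var`, `survey_label`, `rows` (one data-frame row per level:
#'   level, Cm, Cc, Ci, Cfw, TF, TFR, all unrounded), `indices` (the
#'   per-level `proximate_indices` objects) and `warnings`.
#' @export
stratified_analysis <- function(records, stratum_var, window_years = NULL,
                                config = pd_config(), survey_label = "") {
  config <- as_pd_config(config)
  if (!stratum_var %in% strata_vars()) {
    stop("stratum_var must be one of ", paste(strata_vars(), collapse = ", "))
  }
  records <- woman_records(records)
  levels_present <- sort(unique(records[[stratum_var]]))
  rows <- list()
  per_level <- list()
  warns <- character(0)
  for (lv in levels_present) {
    sub <- records[records[[stratum_var]] == lv, , drop = FALSE]
    res <- tryCatch(
      estimate_indices(sub, window_years = window_years, config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      warns <- c(warns, sprintf("level '%s' excluded: %s", lv,
                                conditionMessage(res)))
      next
    }
    per_level[[lv]] <- res
    rows[[lv]] <- data.frame(level = lv, Cm = res$Cm, Cc = res$Cc,
                             Ci = res$Ci, Cfw = res$Cfw, TF = res$TF,
                             TFR = res$tfr_model,
                             n = res$inputs$n)
  }
  if (!length(rows)) stop("no level of ", stratum_var, " could be estimated")
  structure(list(stratum_var = stratum_var,
                 survey_label = survey_label,
                 rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 indices = per_level,
                 warnings = warns),
            class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("Stratified analysis by %s%s\n", x$stratum_var,
              if (nzchar(x$survey_label)) paste0(" (", x$survey_label, ")") else ""))
  df <- x$rows
  num <- c("Cm", "Cc", "Ci", "Cfw", "TFR")
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  if (length(x$warnings)) cat(paste0("! ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Percent-inhibition decomposition report
#'
#' One row per index in the order Cm, Cc, Ci, Cfw with its value and the
#' percentage of fertility it inhibits, plus the composed TFR as an
#' attribute.
#'
#' @param indices A [proximate_indices()] object.
#' @param config A [pd_config()] (rounding contract).
#' @return A data frame with columns `index`, `value`,
#'   `inhibition_pct`; attributes `tfr_model` (unrounded) and
#'   `tfr_reported` (rounded per contract).
#' @export
#' @examples
#' decomposition_report(proximate_indices(0.622, 0.715, 0.653, 0.908))
decomposition_report <- function(indices, config = pd_config()) {
  stopifnot(inherits(indices, "proximate_indices"))
  config <- as_pd_config(config)
  vals <- c(Cm = indices$Cm, Cc = indices$Cc, Ci = indices$Ci,
            Cfw = indices$Cfw)
  out <- data.frame(
    index = names(vals),
    value = round(unname(vals), config$rounding$index),
    inhibition_pct = round(percent_inhibition(unname(vals)),
                           config$rounding$percent))
  attr(out, "tfr_model") <- indices$tfr_model
  attr(out, "tfr_reported") <- round(indices$tfr_model, config$rounding$tfr)
  out
}

#' Project fertility for one or more contraception scenarios
#'
#' Evaluates the contraception-only projection for each scenario row,
#' holding the other determinants fixed.
#'
#' @param scenarios A data frame (or single named list) with columns
#'   `tfr1`, `u1`, `u2`, `e1` and optionally `e2` (defaults to `e1`,
#'   i.e. constant use-effectiveness) and `label`.
#' @param config A [pd_config()].
#' @return A data frame with one row per scenario: the inputs, the
#'   unrounded `tfr2`, and `tfr2_reported` rounded per the projection
#'   contract (1 dp).
#' @export
#' @examples
#' run_projection(data.frame(tfr1 = 4.6, u1 = 0.36, u2 = 0.55, e1 = 0.933))
run_projection <- function(scenarios, config = pd_config()) {
  config <- as_pd_config(config)
  if (!is.data.frame(scenarios)) scenarios <- as.data.frame(scenarios)
  needed <- c("tfr1", "u1", "u2", "e1")
  missing_cols <- setdiff(needed, names(scenarios))
  if (length(missing_cols)) {
    stop("scenarios missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(scenarios)) stop("no projection scenarios supplied")
  if (is.null(scenarios$e2)) scenarios$e2 <- scenarios$e1
  if (is.null(scenarios$label)) {
    scenarios$label <- sprintf("scenario %d", seq_len(nrow(scenarios)))
  }
  scenarios$tfr2 <- vapply(seq_len(nrow(scenarios)), function(r) {
    project_tfr(scenarios$tfr1[r], scenarios$u1[r], scenarios$u2[r],
                scenarios$e1[r], scenarios$e2[r],
                sterility_adjustment = config$sterility_adjustment)
  }, numeric(1))
  scenarios$tfr2_reported <- round(scenarios$tfr2, config$rounding$projection)
  scenarios[c("label", "tfr1", "u1", "e1", "u2", "e2", "tfr2",
              "tfr2_reported")]
}

round_for_report <- function(df, config) {
  digits <- config$rounding
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    d <- switch(nm,
                Cm = , Cc = , Ci = , Cfw = , value = digits$index,
                TFR = , tfr_model = , tfr2 = digits$tfr,
                inhibition_pct = digits$percent,
                tfr2_reported = digits$projection,
                NULL)
    if (!is.null(d)) df[[nm]] <- round(df[[nm]], d)
  }
  df
}

renderable_df <- function(x, config) {
  if (inherits(x, "stratified_result")) {
    df <- x$rows
    df$n <- NULL
  } else if (inherits(x, "proximate_indices")) {
    df <- decomposition_report(x, config)
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    stop("cannot render objects of class ", paste(class(x), collapse = "/"))
  }
  if (!nrow(df)) stop("no rows to render")
  round_for_report(as.data.frame(df), config)
}

#' Render an analysis result as a CSV or aligned-text table
#'
#' Applies the reporting rounding contract (indices 3 dp, TFR 3 dp,
#' percents 1 dp, projections 1 dp) and writes the result. Output bytes
#' are deterministic for fixed input.
#'
#' @param x A `stratified_result`, `proximate_indices`, or plain data
#'   frame (e.g. the output of [run_projection()]).
#' @param format `"csv"` or `"text"`.
#' @param path Output file path.
#' @param config A [pd_config()].
#' @return `path`, invisibly.
#' @export
render_tables <- function(x, format = c("csv", "text"), path,
                          config = pd_config()) {
  config <- as_pd_config(config)
  if (length(format) == 1L && !format %in% c("csv", "text")) {
    stop("unknown format '", format, "'; supported formats: csv, text")
  }
  format <- match.arg(format)
  df <- renderable_df(x, config)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    cols <- vapply(names(df), function(nm) {
      formatted <- format(df[[nm]], trim = TRUE, scientific = FALSE)
      formatC(c(nm, formatted), width = max(nchar(c(nm, formatted))))
    }, character(nrow(df) + 1L))
    writeLines(apply(cols, 1L, paste, collapse = "  "), path)
  }
  invisible(path)
}
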