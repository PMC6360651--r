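# Microdata estimators: derive every model input from a woman-level
# table. All tallies are weighted; with unit weights they reduce to
# simple counts, and scaling all weights by a constant leaves every
# estimate unchanged.

wtd_mean <- function(x, w) sum(x * w) / sum(w)

#' Estimate the age schedule from woman records
#'
#' Per five-year group: m(a) is the weighted share of women currently in
#' union, and g(a) the weighted births per woman-year,
#' `births_in_window / window_years` averaged over all women in the group
#' (an all-women age-specific fertility rate).
#'
#' @param records A [woman_records()] table.
#' @param window_years Retrospective window length in years; default 3.
#' @return An [age_schedule()].
#' @export
estimate_age_schedule <- function(records, window_years = 3) {
  records <- woman_records(records)
  stopifnot(window_years > 0)
  groups <- age_group_labels()
  present <- unique(records$age_group)
  empty <- setdiff(groups, present)
  if (length(empty)) {
    stop("no records in age group(s): ", paste(empty, collapse = ", "))
  }
  f <- factor(records$age_group, levels = groups)
  wsum <- tapply(records$weight, f, sum)
  m <- tapply(records$weight * records$in_union, f, sum) / wsum
  g <- tapply(records$weight * records$births_in_window, f, sum) /
    (wsum * window_years)
  age_schedule(as.numeric(m), as.numeric(g))
}

#' Estimate the contraceptive method mix from woman records
#'
#' Among in-union women: u is the weighted share using any method and the
#' per-method shares partition u.
#'
#' @inheritParams estimate_age_schedule
#' @param effectiveness Effectiveness table for the resulting
#'   [method_mix()]; default [default_effectiveness()].
#' @return A [method_mix()].
#' @export
estimate_method_mix <- function(records, effectiveness = default_effectiveness()) {
  records <- woman_records(records)
  inu <- records[records$in_union, , drop = FALSE]
  if (!nrow(inu)) stop("method mix undefined: no in-union women in records")
  wtot <- sum(inu$weight)
  methods <- setdiff(method_levels(), "none")
  shares <- vapply(methods,
                   function(mm) sum(inu$weight[inu$method == mm]) / wtot,
                   numeric(1))
  method_mix(u = sum(shares), shares = shares, effectiveness = effectiveness)
}

#' Mean duration of postpartum amenorrhea
#'
#' Weighted mean of reported amenorrhea months among women with a live
#' birth in the window. Women without a recent birth have structurally
#' missing durations and are excluded, never imputed.
#'
#' @inheritParams estimate_age_schedule
#' @return i, mean months of postpartum amenorrhea.
#' @export
mean_amenorrhea <- function(records) {
  records <- woman_records(records)
  elig <- records$births_in_window > 0 & !is.na(records$amenorrhea_months)
  if (!any(elig)) {
    stop("mean amenorrhea undefined: no women with a birth in the window and a reported duration")
  }
  wtd_mean(records$amenorrhea_months[elig], records$weight[elig])
}

#' Total foetal wastage rate (TFW)
#'
#' Age-specific wastage rates computed exactly as the fertility rates
#' g(a) but counting foetal-wastage events (miscarriage + abortion +
#' stillbirth); TFW is five times their sum, mirroring the TFR identity.
#'
#' @inheritParams estimate_age_schedule
#' @return TFW, wastage events per woman over the reproductive span.
#' @export
total_fetal_wastage <- function(records, window_years = 3) {
  records <- woman_records(records)
  stopifnot(window_years > 0)
  groups <- age_group_labels()
  empty <- setdiff(groups, unique(records$age_group))
  if (length(empty)) {
    stop("no records in age group(s): ", paste(empty, collapse = ", "))
  }
  f <- factor(records$age_group, levels = groups)
  wsum <- tapply(records$weight, f, sum)
  rates <- tapply(records$weight * records$wastage_in_window, f, sum) /
    (wsum * window_years)
  5 * sum(rates)
}

#' Estimate all four proximate-determinant indices from microdata
#'
#' Runs every component estimator - age schedule for Cm and the observed
#' TFR, method mix for Cc (with Cc = 1 exactly at zero prevalence), mean
#' amenorrhea for Ci, and the wastage rate for Cfw - and assembles a
#' [proximate_indices()] bundle with the composed model TFR. Component
#' failures are re-raised with the estimator's identity attached.
#'
#' @inheritParams estimate_age_schedule
#' @param config A [pd_config()]; supplies TF, the sterility adjustment,
#'   the effectiveness table and (when `window_years` is NULL) the
#'   window length.
#' @param window_years Retrospective window in years; defaults to the
#'   config's value.
#' @return A `proximate_indices` object whose `inputs` field carries u,
#'   e, i, TFW, AFW and the observed TFR.
#' @export
#' @examples
#' spec <- population_spec_ethiopia("2016", n = 2000)
#' pop <- simulate_population(spec, seed = 1)
#' estimate_indices(pop)
estimate_indices <- function(records, window_years = NULL, config = pd_config()) {
  config <- as_pd_config(config)
  if (is.null(window_years)) window_years <- config$window_years
  records <- woman_records(records)

  with_context <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  schedule <- with_context("age_schedule",
                           estimate_age_schedule(records, window_years))
  cm <- with_context("index_marriage", index_marriage(schedule))
  tfr_obs <- tfr_from_schedule(schedule)

  mix <- with_context("method_mix",
                      estimate_method_mix(records, config$effectiveness))
  if (mix$u > 0) {
    e <- mean_use_effectiveness(mix)
    cc <- index_contraception(mix$u, e, config$sterility_adjustment)
  } else {
    e <- NA_real_
    cc <- 1
  }

  i <- with_context("mean_amenorrhea", mean_amenorrhea(records))
  ci <- index_postpartum(i)

  tfw <- with_context("total_fetal_wastage",
                      total_fetal_wastage(records, window_years))
  afw <- averted_fetal_wastage(mix$u, tfw)
  cfw <- with_context("index_fetal_wastage", index_fetal_wastage(tfr_obs, afw))

  proximate_indices(cm, cc, ci, cfw, tf = config$tf,
                    inputs = list(u = mix$u, e = e, i = i, tfw = tfw,
                                  afw = afw, tfr_obs = tfr_obs,
                                  n = nrow(records),
                                  window_years = window_years))
}
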