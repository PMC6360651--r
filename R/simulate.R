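# Synthetic survey-population generator. A population_spec states the
# world - union and fertility schedules, contraceptive prevalence and
# method mix, amenorrhea distribution, wastage rate, covariate level
# shares - and the implied Bongaarts indices follow in closed form, so
# estimator output can be checked against analytic ground truth.

sim_param_names <- function() {
  c("m_by_age", "g_by_age", "u_target", "method_shares",
    "i_mean", "i_shape", "tfw_target")
}

default_covariate_shares <- function() {
  list(
    region = c(Tigray = 0.07, Afar = 0.02, Amhara = 0.23, Oromia = 0.35,
               Somali = 0.04, Benishangul = 0.01, SNNPR = 0.20,
               Gambela = 0.01, Harari = 0.01, "Addis Ababa" = 0.04,
               "Dire Dawa" = 0.02),
    wealth_quintile = c(Lowest = 0.2, Second = 0.2, Middle = 0.2,
                        Fourth = 0.2, Highest = 0.2),
    education = c("No education" = 0.48, Primary = 0.36,
                  Secondary = 0.10, Higher = 0.06),
    residence = c(Urban = 0.2, Rural = 0.8)
  )
}

normalise_method_shares <- function(method_shares, u_target) {
  methods <- setdiff(method_levels(), "none")
  if (u_target == 0) {
    return(stats::setNames(numeric(length(methods)), methods))
  }
  if (is.null(names(method_shares))) stop("method_shares must be named by method")
  bad <- setdiff(names(method_shares), methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  full <- stats::setNames(numeric(length(methods)), methods)
  full[names(method_shares)] <- as.numeric(method_shares)
  if (any(full < 0)) stop("method_shares must be non-negative")
  s <- sum(full)
  if (abs(s - 1) <= 1e-9) return(full)           # conditional on use
  if (abs(s - u_target) <= 1e-9) return(full / u_target)  # absolute, summing to u
  if (s > u_target && s > 1) {
    stop("infeasible spec: method shares sum to ", format(s),
         ", exceeding u_target = ", format(u_target))
  }
  stop("method_shares must sum to 1 (conditional on use) or to u_target (absolute)")
}

#' Specify a synthetic survey population
#'
#' States the world from which [simulate_population()] draws and from
#' which [implied_indices()] computes analytic ground truth: target union
#' proportions and fertility rates per age group, contraceptive
#' prevalence and method mix, the amenorrhea distribution, the total
#' foetal wastage rate, covariate level shares, and optional per-stratum
#' parameter overrides for one covariate.
#'
#' @param n Number of women; default 15,000, mirroring the scale of a
#'   national demographic survey round.
#' @param m_by_age Length-7 vector of target union proportions per age
#'   group, each in \eqn{[0, 1]}.
#' @param g_by_age Length-7 vector of target age-specific fertility rates
#'   (births per woman per year), each \eqn{\ge 0}.
#' @param u_target Contraceptive prevalence among in-union women.
#' @param method_shares Named method shares, either conditional on use
#'   (summing to 1) or absolute (summing to `u_target`).
#' @param i_mean Mean postpartum amenorrhea, months.
#' @param i_shape Gamma shape for amenorrhea durations (right-skewed,
#'   positive; only the mean matters to Ci). Default 4.
#' @param tfw_target Total foetal wastage rate, events per woman.
#' @param covariates Named list of level-share vectors for region,
#'   wealth_quintile, education, residence; each must sum to 1 with all
#'   shares positive.
#' @param overrides Optional per-stratum overrides:
#'   `list(var = "<covariate>", specs = list(<level> = list(<param> = value, ...)))`.
#'   Levels without an entry keep the base parameters.
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' spec <- population_spec_ethiopia("2016", n = 1000)
#' implied_indices(spec)
population_spec <- function(n = 15000,
                            m_by_age,
                            g_by_age,
                            u_target,
                            method_shares = NULL,
                            i_mean,
                            i_shape = 4,
                            tfw_target,
                            covariates = default_covariate_shares(),
                            overrides = NULL) {
  stopifnot(length(n) == 1L, n >= 7)
  sched <- age_schedule(m_by_age, g_by_age)  # validates lengths and ranges
  if (is.na(u_target) || u_target < 0 || u_target > 1) {
    stop("u_target must lie in [0, 1]")
  }
  shares <- normalise_method_shares(method_shares, u_target)
  stopifnot(i_mean >= 0, i_shape > 0, tfw_target >= 0)

  covs_in <- covariates
  covariates <- list()
  for (v in strata_vars()) {
    sh <- covs_in[[v]]
    if (is.null(sh)) {
      covariates[[v]] <- c(all = 1)
      next
    }
    if (is.null(names(sh)) || any(!nzchar(names(sh)))) {
      stop("covariate shares for ", v, " must be named by level")
    }
    if (any(sh <= 0)) stop("every listed level of ", v, " needs a positive share")
    covariates[[v]] <- sh / sum(sh)
  }

  if (!is.null(overrides)) {
    if (!is.list(overrides) || !all(c("var", "specs") %in% names(overrides))) {
      stop("overrides must be list(var =, specs =)")
    }
    if (!overrides$var %in% strata_vars()) {
      stop("overrides$var must be one of ", paste(strata_vars(), collapse = ", "))
    }
    levels_var <- names(covariates[[overrides$var]])
    bad <- setdiff(names(overrides$specs), levels_var)
    if (length(bad)) {
      stop("override level(s) not present in ", overrides$var, ": ",
           paste(bad, collapse = ", "))
    }
    for (lv in names(overrides$specs)) {
      bad_p <- setdiff(names(overrides$specs[[lv]]), sim_param_names())
      if (length(bad_p)) {
        stop("unknown override parameter(s) for level ", lv, ": ",
             paste(bad_p, collapse = ", "))
      }
    }
  }

  structure(list(n = as.integer(n),
                 m_by_age = unname(sched$m),
                 g_by_age = unname(sched$g),
                 u_target = u_target,
                 method_shares = shares,
                 i_mean = i_mean,
                 i_shape = i_shape,
                 tfw_target = tfw_target,
                 covariates = covariates,
                 overrides = overrides),
            class = "population_spec")
}

#' Parameters in force for one stratum of a spec
#'
#' Merges a spec's base parameters with the overrides (if any) for one
#' level of the overridden covariate, returning a spec with no overrides.
#' This is the per-stratum ground truth used by stratified recovery
#' tests.
#'
#' @param spec A [population_spec()].
#' @param level A level of `spec$overrides$var` (ignored if the spec has
#'   no overrides).
#' @return A `population_spec` describing that stratum alone.
#' @export
stratum_spec <- function(spec, level) {
  stopifnot(inherits(spec, "population_spec"))
  params <- spec[sim_param_names()]
  if (!is.null(spec$overrides) && level %in% names(spec$overrides$specs)) {
    ov <- spec$overrides$specs[[level]]
    params[names(ov)] <- ov
    # re-normalise shares against the (possibly overridden) prevalence
    if (is.null(ov$method_shares)) params$method_shares <- spec$method_shares
  }
  population_spec(n = spec$n,
                  m_by_age = params$m_by_age,
                  g_by_age = params$g_by_age,
                  u_target = params$u_target,
                  method_shares = params$method_shares,
                  i_mean = params$i_mean,
                  i_shape = params$i_shape,
                  tfw_target = params$tfw_target,
                  covariates = spec$covariates)
}

# draw one chunk of women sharing a single parameter set
simulate_chunk <- function(params, age_idx, window_years) {
  k <- length(age_idx)
  m_a <- params$m_by_age[age_idx]
  g_a <- params$g_by_age[age_idx]
  in_union <- stats::runif(k) < m_a
  method <- rep("none", k)
  if (params$u_target > 0) {
    users <- in_union & stats::runif(k) < params$u_target
    if (any(users)) {
      method[users] <- sample(names(params$method_shares), sum(users),
                              replace = TRUE, prob = params$method_shares)
    }
  }
  births <- stats::rpois(k, g_a * window_years)
  amen <- rep(NA_real_, k)
  recent <- births > 0
  if (any(recent)) {
    amen[recent] <- stats::rgamma(sum(recent), shape = params$i_shape,
                                  rate = params$i_shape / max(params$i_mean, 1e-12))
  }
  wastage <- stats::rpois(k, params$tfw_target / 35 * window_years)
  data.frame(in_union = in_union, births_in_window = births, method = method,
             amenorrhea_months = amen, wastage_in_window = wastage)
}

#' Simulate a woman-level survey population
#'
#' Draws `spec$n` women: age group uniform over the seven groups; union
#' status Bernoulli with the group's m(a); contraceptive method assigned
#' to in-union women at prevalence `u_target` and multinomially over the
#' method shares; births in the window Poisson with mean
#' `g(a) * window_years`; postpartum amenorrhea Gamma (mean `i_mean`)
#' for women with a recent birth; wastage events Poisson with per-year
#' rate `tfw_target / 35`. Covariates are assigned independently by their
#' level shares; when the spec carries overrides, women in each level of
#' the overridden covariate are drawn under that level's parameters.
#' Output is reproducible: identical spec and seed give identical tables.
#'
#' @param spec A [population_spec()].
#' @param seed Integer RNG seed.
#' @param window_years Retrospective window in years; default 3.
#' @return A [woman_records()] data frame with `spec$n` rows.
#' @export
simulate_population <- function(spec, seed = 1, window_years = 3) {
  stopifnot(inherits(spec, "population_spec"), window_years > 0)
  set.seed(as.integer(seed))
  n <- spec$n
  age_idx <- sample.int(7L, n, replace = TRUE)
  covs <- lapply(spec$covariates, function(sh) {
    sample(names(sh), n, replace = TRUE, prob = sh)
  })

  out <- data.frame(age_group = age_group_labels()[age_idx],
                    in_union = logical(n), births_in_window = integer(n),
                    method = character(n), amenorrhea_months = NA_real_,
                    wastage_in_window = integer(n),
                    region = covs$region,
                    wealth_quintile = covs$wealth_quintile,
                    education = covs$education,
                    residence = covs$residence,
                    weight = 1)

  if (is.null(spec$overrides)) {
    chunk <- simulate_chunk(spec[sim_param_names()], age_idx, window_years)
    out[names(chunk)] <- chunk
  } else {
    var_levels <- covs[[spec$overrides$var]]
    for (lv in names(spec$covariates[[spec$overrides$var]])) {
      idx <- which(var_levels == lv)
      if (!length(idx)) next
      params <- stratum_spec(spec, lv)[sim_param_names()]
      chunk <- simulate_chunk(params, age_idx[idx], window_years)
      out[idx, names(chunk)] <- chunk
    }
  }
  woman_records(out)
}

#' Closed-form indices implied by a population spec
#'
#' Ground truth against which estimates from a simulated population can
#' be compared: Cm from the m/g vectors, Cc from prevalence and method
#' mix, Ci from the mean amenorrhea, Cfw from the implied observed TFR
#' (five times the sum of g) and the wastage rate. For a spec with
#' per-stratum overrides this describes the *base* parameters; use
#' [stratum_spec()] for a level's ground truth.
#'
#' @param spec A [population_spec()].
#' @param config A [pd_config()].
#' @return A [proximate_indices()] object.
#' @export
implied_indices <- function(spec, config = pd_config()) {
  stopifnot(inherits(spec, "population_spec"))
  config <- as_pd_config(config)
  cm <- sum(spec$m_by_age * spec$g_by_age) / sum(spec$g_by_age)
  u <- spec$u_target
  if (u > 0) {
    e <- sum(config$effectiveness * spec$method_shares)
    cc <- 1 - config$sterility_adjustment * u * e
  } else {
    e <- NA_real_
    cc <- 1
  }
  ci <- 20 / (18.5 + spec$i_mean)
  tfr_obs <- 5 * sum(spec$g_by_age)
  afw <- averted_fetal_wastage(u, spec$tfw_target)
  cfw <- if (afw == 0) 1 else tfr_obs / (tfr_obs + afw)
  proximate_indices(cm, cc, ci, cfw, tf = config$tf,
                    inputs = list(u = u, e = e, i = spec$i_mean,
                                  tfw = spec$tfw_target, afw = afw,
                                  tfr_obs = tfr_obs))
}

# solve generator parameters that imply the given index targets exactly
spec_from_targets <- function(cm, cc, ci, cfw, tfr, mix_cond, n = 15000,
                              config = pd_config(), ...) {
  asfr_shape <- c(80, 175, 190, 160, 120, 60, 25) / 1000
  g <- asfr_shape * (tfr / 5) / sum(asfr_shape)
  m_shape <- c(0.25, 0.55, 0.72, 0.78, 0.80, 0.78, 0.75)
  w <- g / sum(g)
  m <- m_shape * cm / sum(m_shape * w)
  if (any(m > 1)) stop("marriage target ", cm, " infeasible for the union age shape")
  e <- sum(config$effectiveness[names(mix_cond)] * mix_cond)
  u <- (1 - cc) / (config$sterility_adjustment * e)
  if (u < 0 || u > 1) stop("contraception target ", cc, " implies prevalence outside [0, 1]")
  i <- 20 / ci - 18.5
  if (i < 0) stop("postpartum target ", ci, " implies negative amenorrhea")
  tfw <- tfr * (1 / cfw - 1) / (0.4 * (1 + u))
  list(n = n, m_by_age = m, g_by_age = g, u_target = u,
       method_shares = mix_cond, i_mean = i, tfw_target = tfw, ...)
}

ethiopia_mix <- function(year) {
  # injectable-dominated mixes typical of the two survey rounds
  switch(year,
         "2011" = c(pill = 0.10, IUD = 0.04, sterilization = 0.02,
                    injection = 0.60, other = 0.24),
         "2016" = c(pill = 0.08, IUD = 0.05, sterilization = 0.02,
                    injection = 0.63, other = 0.22))
}

#' Population spec calibrated to the published Ethiopia index values
#'
#' Builds a [population_spec()] whose implied indices equal the national
#' values printed for the chosen survey round (see [ethiopia_tables()]),
#' solving prevalence, amenorrhea and wastage from the index targets in
#' closed form. With `stratify_by = "residence"` the urban/rural strata
#' are instead calibrated to the published residence rows of that round's
#' stratified table, as per-level overrides.
#'
#' @param year `"2011"` or `"2016"`.
#' @param n Number of women; default 15,000.
#' @param stratify_by `NULL` (national parameters throughout) or
#'   `"residence"`.
#' @param config A [pd_config()].
#' @return A `population_spec`.
#' @export
#' @examples
#' implied_indices(population_spec_ethiopia("2016"))
population_spec_ethiopia <- function(year = c("2016", "2011"), n = 15000,
                                     stratify_by = NULL,
                                     config = pd_config()) {
  year <- match.arg(year)
  tabs <- ethiopia_tables()
  col <- paste0("y", year)
  t1 <- tabs$table1
  val <- function(q) t1[t1$quantity == q, col]
  base <- spec_from_targets(val("Cm"), val("Cc"), val("Ci"), val("Cfw"),
                            val("TFR"), ethiopia_mix(year), n = n,
                            config = config)
  if (is.null(stratify_by)) {
    return(do.call(population_spec, base))
  }
  if (!identical(stratify_by, "residence")) {
    stop("stratify_by must be NULL or \"residence\"")
  }
  strat <- tabs[[paste0("stratified_", year)]]
  res <- strat[strat$variable == "Residence", ]
  specs <- lapply(seq_len(nrow(res)), function(r) {
    row <- res[r, ]
    spec_from_targets(row$Cm, row$Cc, row$Ci, row$Cfw, row$TFR,
                      ethiopia_mix(year), config = config)[sim_param_names()[
                        sim_param_names() != "i_shape"]]
  })
  names(specs) <- res$level
  base$overrides <- list(var = "residence", specs = specs)
  base$covariates <- utils::modifyList(default_covariate_shares(),
                                       list(residence = c(Urban = 0.2, Rural = 0.8)))
  do.call(population_spec, base)
}
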