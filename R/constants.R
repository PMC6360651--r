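#' Standard five-year reproductive age groups
#'
#' The seven five-year age groups 15-19 through 45-49 used throughout
#' DHS-style fertility analysis. All age schedules in this package are
#' indexed by these labels, in this order.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' age_group_labels()
age_group_labels <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

#' Default contraceptive use-effectiveness table
#'
#' Method-specific use-effectiveness weights e(m) used to form the mean
#' effectiveness entering the contraception index: pill 0.90, IUD 0.95,
#' sterilization 1.00, injection 0.99 and all other methods (condom, LAM,
#' traditional, ...) 0.70.
#'
#' @return Named numeric vector over the five method classes.
#' @export
#' @examples
#' default_effectiveness()
default_effectiveness <- function() {
  c(pill = 0.90, IUD = 0.95, sterilization = 1.00,
    injection = 0.99, other = 0.70)
}

# method levels for woman records; "none" first, then the effectiveness classes
method_levels <- function() c("none", names(default_effectiveness()))

# recognised stratification covariates
strata_vars <- function() c("region", "wealth_quintile", "education", "residence")
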