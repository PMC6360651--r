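#' Age schedule of union and fertility
#'
#' Container for the per-age-group inputs of the marriage index: m(a), the
#' proportion of women currently in union in each five-year group, and
#' g(a), the age-specific fertility rate (births per woman per year).
#' Exactly seven groups, 15-19 through 45-49, in fixed order.
#'
#' @param m Numeric vector of length 7, proportions in union, each in
#'   \eqn{[0, 1]}.
#' @param g Numeric vector of length 7, age-specific fertility rates,
#'   each \eqn{\ge 0}.
#' @param age_groups Group labels; defaults to [age_group_labels()].
#' @return An object of class `age_schedule`.
#' @seealso [index_marriage()], [tfr_from_schedule()],
#'   [estimate_age_schedule()]
#' @export
#' @examples
#' sched <- age_schedule(m = rep(0.7, 7), g = c(0.08, 0.18, 0.19, 0.16, 0.12, 0.06, 0.02))
#' index_marriage(sched)
#' tfr_from_schedule(sched)
age_schedule <- function(m, g, age_groups = age_group_labels()) {
  if (length(age_groups) != 7L) stop("exactly 7 age groups are required")
  if (length(m) != 7L || length(g) != 7L) {
    stop("m and g must each have one value per age group (length 7)")
  }
  m <- as.numeric(m)
  g <- as.numeric(g)
  if (anyNA(m) || anyNA(g)) stop("m and g must not contain missing values")
  if (any(m < 0 | m > 1)) stop("all m(a) must lie in [0, 1]")
  if (any(g < 0)) stop("all g(a) must be non-negative")
  structure(list(age_groups = as.character(age_groups),
                 m = stats::setNames(m, age_groups),
                 g = stats::setNames(g, age_groups)),
            class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat("Age schedule (7 five-year groups)\n")
  print(data.frame(age_group = x$age_groups,
                   m = unname(x$m),
                   g = unname(x$g)),
        row.names = FALSE)
  invisible(x)
}

as_age_schedule <- function(x) {
  if (inherits(x, "age_schedule")) return(x)
  if (is.list(x) && all(c("m", "g") %in% names(x))) {
    return(age_schedule(x$m, x$g))
  }
  stop("expected an age_schedule (see age_schedule())")
}

#' Total fertility rate implied by an age schedule
#'
#' The standard demographic identity: five times the sum of the seven
#' annual age-specific rates.
#'
#' @param schedule An [age_schedule()].
#' @return TFR in births per woman.
#' @export
tfr_from_schedule <- function(schedule) {
  schedule <- as_age_schedule(schedule)
  5 * sum(schedule$g)
}
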