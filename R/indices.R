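# The four closed-form indices, their composition, percent-inhibition
# decomposition, and the contraception-only projection.
#
# Each index nominally lies in (0, 1]: 1 means no inhibition from that
# determinant, 0 complete inhibition. The formulas themselves do not
# enforce the range (e.g. Ci > 1 when mean amenorrhea is under 1.5
# months), so out-of-range values are returned as-is with a warning of
# class "pd_index_out_of_range" and an "out_of_range" attribute - never
# clamped silently.

flag_out_of_range <- function(value, name) {
  if (!is.finite(value) || value <= 0 || value > 1) {
    warning(warningCondition(
      sprintf("%s = %.6g lies outside the nominal (0, 1] index range",
              name, value),
      class = "pd_index_out_of_range"))
    attr(value, "out_of_range") <- TRUE
  }
  value
}

is_flagged <- function(x) isTRUE(attr(x, "out_of_range"))

#' Index of marriage (Cm)
#'
#' Fertility-weighted average of the age-specific proportions in union:
#' \eqn{C_m = \sum_a m(a) g(a) / \sum_a g(a)}. Equals 1 when all women of
#' reproductive age are in union; smaller values measure the inhibition
#' from delayed marriage and non-marriage. As a weighted average it always
#' lies within \eqn{[\min m(a), \max m(a)]}.
#'
#' @param schedule An [age_schedule()] with at least one positive g(a).
#' @return Cm, unitless.
#' @export
#' @examples
#' index_marriage(age_schedule(m = rep(0.5, 7),
#'                             g = c(0.08, 0.18, 0.19, 0.16, 0.12, 0.06, 0.02)))
index_marriage <- function(schedule) {
  schedule <- as_age_schedule(schedule)
  g <- schedule$g
  if (sum(g) <= 0) stop("marriage index undefined: no fertility in schedule")
  cm <- sum(schedule$m * g) / sum(g)
  flag_out_of_range(unname(cm), "Cm")
}

#' Index of contraception (Cc)
#'
#' \eqn{C_c = 1 - 1.08 \, u \, e}, where u is contraceptive prevalence
#' among in-union women, e the use-effectiveness-weighted mean over the
#' method mix, and 1.08 adjusts for non-use among women who know they are
#' sterile. Equals 1 at u = 0; can fall to or below 0 at very high
#' \eqn{u e}, in which case the value is flagged, not clamped.
#'
#' @param u Prevalence in \eqn{[0, 1]}.
#' @param e Mean use-effectiveness in \eqn{[0, 1]} (see
#'   [mean_use_effectiveness()]).
#' @param sterility_adjustment The sterility correction; default 1.08.
#' @return Cc, unitless.
#' @export
#' @examples
#' index_contraception(0.36, 0.933)
index_contraception <- function(u, e, sterility_adjustment = 1.08) {
  stopifnot(is.numeric(u), is.numeric(e), length(u) == 1L, length(e) == 1L)
  if (is.na(u) || u < 0 || u > 1) stop("u must lie in [0, 1]")
  if (is.na(e) || e < 0 || e > 1) stop("e must lie in [0, 1]")
  flag_out_of_range(1 - sterility_adjustment * u * e, "Cc")
}

#' Index of postpartum infecundability (Ci)
#'
#' \eqn{C_i = 20 / (18.5 + i)} with i the mean duration of postpartum
#' amenorrhea in months: the ratio of the average birth interval without
#' breastfeeding/abstinence (20 months = 1.5 months minimum anovulation +
#' 7.5 waiting to conception + 2 intrauterine mortality + 9 gestation) to
#' the interval with it (18.5 + i). Equals exactly 1 at i = 1.5 and is
#' strictly decreasing in i; i < 1.5 yields a flagged value above 1.
#'
#' @param i Mean postpartum amenorrhea, months, \eqn{\ge 0}.
#' @return Ci, unitless.
#' @export
#' @examples
#' index_postpartum(12.13)
index_postpartum <- function(i) {
  stopifnot(is.numeric(i), length(i) == 1L)
  if (is.na(i) || i < 0) stop("mean amenorrhea duration i must be non-negative")
  flag_out_of_range(20 / (18.5 + i), "Ci")
}

#' Births averted by foetal wastage (AFW)
#'
#' \eqn{AFW = 0.4 (1 + u) \, TFW}: the average number of births averted
#' per woman by the end of the reproductive years by all foetal wastage
#' (miscarriage + abortion + stillbirth), given the total foetal wastage
#' rate TFW and contraceptive prevalence u.
#'
#' @param u Contraceptive prevalence in \eqn{[0, 1]}.
#' @param tfw Total foetal wastage rate, events per woman, \eqn{\ge 0}.
#' @return AFW, births per woman.
#' @export
averted_fetal_wastage <- function(u, tfw) {
  stopifnot(is.numeric(u), is.numeric(tfw), length(u) == 1L, length(tfw) == 1L)
  if (is.na(u) || u < 0 || u > 1) stop("u must lie in [0, 1]")
  if (is.na(tfw) || tfw < 0) stop("TFW must be non-negative")
  0.4 * (1 + u) * tfw
}

#' Index of foetal wastage (Cfw)
#'
#' Ratio of the observed TFR to the TFR that would obtain had no foetal
#' wastage occurred: \eqn{C_{fw} = TFR / (TFR + AFW)}. Equals 1 iff
#' AFW = 0 and is strictly decreasing in AFW.
#'
#' @param tfr_obs Observed total fertility rate, births per woman, > 0.
#' @param afw Averted births per woman (see [averted_fetal_wastage()]),
#'   \eqn{\ge 0}.
#' @return Cfw, unitless.
#' @export
index_fetal_wastage <- function(tfr_obs, afw) {
  stopifnot(is.numeric(tfr_obs), is.numeric(afw),
            length(tfr_obs) == 1L, length(afw) == 1L)
  if (is.na(tfr_obs) || tfr_obs <= 0) stop("observed TFR must be positive")
  if (is.na(afw) || afw < 0) stop("AFW must be non-negative")
  flag_out_of_range(tfr_obs / (tfr_obs + afw), "Cfw")
}

#' Compose the total fertility rate from the four indices
#'
#' The multiplicative model \eqn{TFR = C_m C_c C_{fw} C_i \cdot TF}.
#'
#' @param cm,cc,ci,cfw The four indices.
#' @param tf Total fecundity, births per woman; default 15.3.
#' @return Model TFR, births per woman (unrounded).
#' @export
#' @examples
#' compose_tfr(0.656, 0.693, 0.655, 0.908)  # ~4.14
compose_tfr <- function(cm, cc, ci, cfw, tf = 15.3) {
  vals <- c(cm = cm, cc = cc, ci = ci, cfw = cfw, tf = tf)
  if (!all(is.finite(vals))) stop("all factors must be finite")
  if (tf <= 0) stop("total fecundity TF must be positive")
  unname(cm * cc * ci * cfw * tf)
}

#' Percent inhibition of an index
#'
#' \eqn{(1 - C) \times 100}: the percentage by which the determinant
#' reduces fertility below the level that would obtain without it.
#'
#' @param C An index in \eqn{(0, 1]}.
#' @return Percent, unrounded.
#' @export
#' @examples
#' percent_inhibition(0.622)  # 37.8
percent_inhibition <- function(C) {
  stopifnot(is.numeric(C))
  if (anyNA(C) || any(C <= 0) || any(C > 1)) {
    stop("percent inhibition requires indices in (0, 1]")
  }
  (1 - C) * 100
}

#' Bundle of proximate-determinant indices
#'
#' Holds the four indices, total fecundity, and the composed model TFR for
#' one population or stratum. The stored `tfr_model` always equals the
#' product of the stored factors.
#'
#' @param cm,cc,ci,cfw The four indices (finite; out-of-range values are
#'   carried but recorded in `flags`).
#' @param tf Total fecundity; default 15.3.
#' @param inputs Optional named list of underlying inputs (u, e, i, tfw,
#'   tfr_obs, ...) kept for reporting.
#' @return An object of class `proximate_indices` with fields `Cm`, `Cc`,
#'   `Ci`, `Cfw`, `TF`, `tfr_model`, `flags`, `inputs`.
#' @export
#' @examples
#' proximate_indices(0.622, 0.715, 0.653, 0.908)
proximate_indices <- function(cm, cc, ci, cfw, tf = 15.3, inputs = list()) {
  vals <- c(Cm = as.numeric(cm), Cc = as.numeric(cc),
            Ci = as.numeric(ci), Cfw = as.numeric(cfw))
  if (!all(is.finite(vals))) stop("all indices must be finite")
  flags <- names(vals)[vals <= 0 | vals > 1]
  structure(list(Cm = vals[["Cm"]], Cc = vals[["Cc"]],
                 Ci = vals[["Ci"]], Cfw = vals[["Cfw"]],
                 TF = tf,
                 tfr_model = compose_tfr(vals[["Cm"]], vals[["Cc"]],
                                         vals[["Ci"]], vals[["Cfw"]], tf),
                 flags = flags,
                 inputs = inputs),
            class = "proximate_indices")
}

#' @export
print.proximate_indices <- function(x, digits = 3, ...) {
  cat("Proximate determinants of fertility\n")
  df <- data.frame(
    index = c("Cm", "Cc", "Ci", "Cfw"),
    value = round(c(x$Cm, x$Cc, x$Ci, x$Cfw), digits),
    inhibition_pct = round((1 - c(x$Cm, x$Cc, x$Ci, x$Cfw)) * 100, 1))
  print(df, row.names = FALSE)
  cat(sprintf("TF = %.1f; composed TFR = %.3f births per woman\n",
              x$TF, x$tfr_model))
  if (length(x$flags)) {
    cat("flagged out of (0, 1]: ", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project future fertility under a contraceptive-prevalence change
#'
#' Holding marriage, postpartum infecundability and foetal wastage
#' constant, the TFR scales with the contraception index:
#' \deqn{TFR_2 = TFR_1 \frac{1 - 1.08\, u_2 e_2}{1 - 1.08\, u_1 e_1}.}
#'
#' @param tfr1 Baseline TFR, births per woman.
#' @param u1,u2 Baseline and target contraceptive prevalence, each in
#'   \eqn{[0, 1]}.
#' @param e1 Baseline mean use-effectiveness in \eqn{[0, 1]}.
#' @param e2 Target mean use-effectiveness; defaults to `e1` (constant
#'   use-effectiveness).
#' @param sterility_adjustment Default 1.08.
#' @return Projected TFR, births per woman (unrounded).
#' @export
#' @examples
#' project_tfr(4.6, u1 = 0.36, u2 = 0.55, e1 = 0.933)  # ~3.2
project_tfr <- function(tfr1, u1, u2, e1, e2 = e1,
                        sterility_adjustment = 1.08) {
  vals <- c(tfr1, u1, u2, e1, e2)
  if (!all(is.finite(vals))) stop("all projection inputs must be finite")
  if (tfr1 <= 0) stop("baseline TFR must be positive")
  if (any(c(u1, u2) < 0 | c(u1, u2) > 1)) stop("u1, u2 must lie in [0, 1]")
  if (any(c(e1, e2) < 0 | c(e1, e2) > 1)) stop("e1, e2 must lie in [0, 1]")
  cc1 <- 1 - sterility_adjustment * u1 * e1
  if (cc1 <= 0) stop("baseline contraception index is not positive")
  cc2 <- 1 - sterility_adjustment * u2 * e2
  tfr1 * cc2 / cc1
}
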