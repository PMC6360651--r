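#' Analysis configuration
#'
#' Bundles the tunable constants of the model: total fecundity TF, the
#' sterility adjustment in the contraception index, the method
#' effectiveness table, and the reporting rounding contract. Rounding is
#' applied only at the reporting layer (tables, CLI output), never inside
#' computation.
#'
#' @param tf Total fecundity, births per woman in the absence of all four
#'   inhibiting behaviours. Default 15.3.
#' @param sterility_adjustment Multiplier correcting for non-use of
#'   contraception by women who know they are sterile. Default 1.08.
#' @param effectiveness Named numeric vector of method use-effectiveness
#'   weights; must cover `pill`, `IUD`, `sterilization`, `injection`,
#'   `other`, each in \eqn{[0, 1]}.
#' @param rounding Named list of reporting digits: `index` (3), `tfr` (3),
#'   `tfr_headline` (2), `percent` (1), `projection` (1).
#' @param window_years Length of the retrospective exposure window used by
#'   the microdata estimators, in years. Default 3 (DHS convention).
#'
#' @return An object of class `pd_config`.
#' @export
#' @examples
#' cfg <- pd_config()
#' cfg$tf
pd_config <- function(tf = 15.3,
                      sterility_adjustment = 1.08,
                      effectiveness = default_effectiveness(),
                      rounding = list(index = 3L, tfr = 3L, tfr_headline = 2L,
                                      percent = 1L, projection = 1L),
                      window_years = 3) {
  stopifnot(is.numeric(tf), length(tf) == 1L, tf > 0,
            is.numeric(sterility_adjustment), sterility_adjustment > 0,
            is.numeric(window_years), window_years > 0)
  needed <- names(default_effectiveness())
  if (!all(needed %in% names(effectiveness))) {
    stop("effectiveness table must name all of: ", paste(needed, collapse = ", "))
  }
  effectiveness <- effectiveness[needed]
  if (any(effectiveness < 0 | effectiveness > 1)) {
    stop("effectiveness weights must lie in [0, 1]")
  }
  default_round <- list(index = 3L, tfr = 3L, tfr_headline = 2L,
                        percent = 1L, projection = 1L)
  rounding <- utils::modifyList(default_round, as.list(rounding))
  structure(list(tf = tf,
                 sterility_adjustment = sterility_adjustment,
                 effectiveness = effectiveness,
                 rounding = rounding,
                 window_years = window_years),
            class = "pd_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Fields absent from the file keep their [pd_config()] defaults.
#'
#' @param path Path to a JSON file with any subset of the `pd_config`
#'   fields (`tf`, `sterility_adjustment`, `effectiveness`, `rounding`,
#'   `window_years`).
#' @return A `pd_config` object.
#' @export
read_pd_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("tf", "sterility_adjustment", "effectiveness", "rounding",
               "window_years")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(raw$effectiveness)) raw$effectiveness <- unlist(raw$effectiveness)
  defaults <- pd_config()
  args <- utils::modifyList(
    list(tf = defaults$tf,
         sterility_adjustment = defaults$sterility_adjustment,
         effectiveness = defaults$effectiveness,
         rounding = defaults$rounding,
         window_years = defaults$window_years),
    raw)
  do.call(pd_config, args)
}

as_pd_config <- function(config) {
  if (is.null(config)) return(pd_config())
  if (inherits(config, "pd_config")) return(config)
  stop("config must be a pd_config object (see pd_config())")
}
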