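#' Contraceptive method mix
#'
#' Prevalence u of contraceptive use among in-union women 15-49 together
#' with its partition into per-method shares u(m) and the method
#' effectiveness table e(m). The shares are absolute proportions of
#' in-union women (not conditional on use) and must sum to u.
#'
#' @param u Contraceptive prevalence among in-union women, in \eqn{[0, 1]}.
#' @param shares Named numeric vector of per-method proportions over
#'   `pill`, `IUD`, `sterilization`, `injection`, `other`; must sum to `u`
#'   (tolerance 1e-9). Methods omitted are taken as 0.
#' @param effectiveness Method effectiveness table; defaults to
#'   [default_effectiveness()].
#' @return An object of class `method_mix`.
#' @seealso [mean_use_effectiveness()], [index_contraception()]
#' @export
#' @examples
#' mix <- method_mix(0.36, c(pill = 0.20, injection = 0.16))
#' mean_use_effectiveness(mix)
method_mix <- function(u, shares, effectiveness = default_effectiveness()) {
  stopifnot(is.numeric(u), length(u) == 1L)
  if (is.na(u) || u < 0 || u > 1) stop("u must lie in [0, 1]")
  methods <- names(default_effectiveness())
  full <- stats::setNames(numeric(length(methods)), methods)
  if (length(shares)) {
    if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
      stop("shares must be named by method")
    }
    bad <- setdiff(names(shares), methods)
    if (length(bad)) {
      stop("unknown method(s) in shares: ", paste(bad, collapse = ", "),
           " (expected ", paste(methods, collapse = ", "), ")")
    }
    full[names(shares)] <- as.numeric(shares)
  }
  if (any(full < 0)) stop("method shares must be non-negative")
  if (abs(sum(full) - u) > 1e-9) {
    stop("method shares must sum to u (got ", format(sum(full)),
         " vs u = ", format(u), ")")
  }
  if (!all(methods %in% names(effectiveness))) {
    stop("effectiveness must name all of: ", paste(methods, collapse = ", "))
  }
  structure(list(u = u, shares = full,
                 effectiveness = effectiveness[methods]),
            class = "method_mix")
}

#' @export
print.method_mix <- function(x, ...) {
  cat(sprintf("Method mix: u = %.4f among in-union women\n", x$u))
  print(data.frame(method = names(x$shares),
                   share = unname(x$shares),
                   effectiveness = unname(x$effectiveness)),
        row.names = FALSE)
  invisible(x)
}

#' Mean contraceptive use-effectiveness
#'
#' The effectiveness-weighted mean over the method mix,
#' \eqn{e = \sum_m e(m) u(m) / u}. Undefined at zero prevalence: callers
#' composing the contraception index must treat Cc = 1 directly when
#' u = 0.
#'
#' @param mix A [method_mix()].
#' @return Mean use-effectiveness e; lies in \eqn{[0.70, 1.00]} under the
#'   default effectiveness table.
#' @export
mean_use_effectiveness <- function(mix) {
  if (!inherits(mix, "method_mix")) stop("mix must be a method_mix object")
  if (mix$u <= 0) stop("effectiveness undefined when prevalence is zero")
  sum(mix$effectiveness * mix$shares) / mix$u
}
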