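#' Speciation-rate functions of a continuous trait
#'
#' Constructors for the four functional forms relating a continuously
#' evolving trait \eqn{x} to the speciation rate \eqn{\lambda(x)}:
#'
#' \describe{
#'   \item{constant}{\eqn{\lambda(x) = y_0}}
#'   \item{linear}{\eqn{\lambda(x) = \max(0, a + b x)} (clamped at zero)}
#'   \item{sigmoid}{\eqn{\lambda(x) = y_0 + (y_1 - y_0) / (1 + e^{-r (x - x_{mid})})}}
#'   \item{modal}{\eqn{\lambda(x) = y_0 + (y_1 - y_0)\,
#'     e^{-(x - x_{mid})^2 / (2 s^2)}} — a Gaussian hump with baseline
#'     \eqn{y_0}, peak \eqn{y_1}, optimum \eqn{x_{mid}} and width
#'     variance \eqn{s^2}}
#' }
#'
#' All forms evaluate to non-negative rates (events per lineage per Myr).
#'
#' @param y0 Baseline rate (constant value for `form = "constant"`).
#' @param intercept,slope Linear coefficients; negative evaluations are
#'   clamped to zero.
#' @param y1 Rate at the sigmoid's upper asymptote / the modal peak.
#' @param xmid Inflection point (sigmoid) or optimum (modal).
#' @param r Sigmoid steepness; must be finite.
#' @param s2 Modal width variance; must be strictly positive.
#' @return An object of class `speciation_fn`.
#' @examples
#' f <- modal_speciation(0.1, 0.4, xmid = 10.2, s2 = 4)
#' eval_speciation(f, c(5, 10.2, 15))
#' @name speciation_fn
NULL

new_speciation_fn <- function(form, params) {
  structure(list(form = form, params = params), class = "speciation_fn")
}

#' @rdname speciation_fn
#' @export
constant_speciation <- function(y0) {
  stopifnot(is.numeric(y0), length(y0) == 1L, y0 >= 0, is.finite(y0))
  new_speciation_fn("constant", list(y0 = y0))
}

#' @rdname speciation_fn
#' @export
linear_speciation <- function(intercept, slope) {
  stopifnot(is.finite(intercept), is.finite(slope))
  new_speciation_fn("linear", list(intercept = intercept, slope = slope))
}

#' @rdname speciation_fn
#' @export
sigmoid_speciation <- function(y0, y1, xmid, r) {
  stopifnot(y0 >= 0, y1 >= 0, is.finite(xmid), is.finite(r))
  new_speciation_fn("sigmoid", list(y0 = y0, y1 = y1, xmid = xmid, r = r))
}

#' @rdname speciation_fn
#' @export
modal_speciation <- function(y0, y1, xmid, s2) {
  if (!is.numeric(s2) || s2 <= 0)
    stop("modal width variance 's2' must be > 0, got ", s2)
  stopifnot(y0 >= 0, y1 >= 0, is.finite(xmid))
  new_speciation_fn("modal", list(y0 = y0, y1 = y1, xmid = xmid, s2 = s2))
}

#' Evaluate a speciation function
#'
#' @param fn A [speciation_fn] object.
#' @param x Numeric vector of trait values.
#' @return Numeric vector of rates, all `>= 0`.
#' @export
eval_speciation <- function(fn, x) {
  stopifnot(inherits(fn, "speciation_fn"))
  p <- fn$params
  switch(fn$form,
    constant = rep(p$y0, length(x)),
    linear   = pmax(0, p$intercept + p$slope * x),
    sigmoid  = p$y0 + (p$y1 - p$y0) / (1 + exp(-p$r * (x - p$xmid))),
    modal    = p$y0 + (p$y1 - p$y0) * exp(-(x - p$xmid)^2 / (2 * p$s2)),
    stop("unknown speciation form: ", fn$form)
  )
}

#' @export
print.speciation_fn <- function(x, ...) {
  cat("<speciation_fn:", x$form, "> ",
      paste(names(x$params), signif(unlist(x$params), 4),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
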