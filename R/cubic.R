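#' Cubic fast nullclines
#'
#' The model families use one of two cubic source terms for the fast
#' (voltage-like) variable: the *soft* cubic \eqn{f(u) = -u^3/3 + u}
#' (the classical FitzHugh choice, used throughout the ODE analysis) and
#' the *steep* cubic \eqn{f(u) = -u^3 + 3u} (used by the reaction-diffusion
#' parameter sets and the fold blow-up computation). Both have folds at
#' \eqn{u = \pm 1} where \eqn{f'(\pm 1) = 0}.
#'
#' @param variant `"soft"` or `"steep"`.
#' @return An object of class `fhn_cubic`.
#' @examples
#' cubic_eval(1, fhn_cubic("steep")) # f = 2, fprime = 0
#' @export
fhn_cubic <- function(variant = c("soft", "steep")) {
  variant <- match.arg(variant)
  structure(list(variant = variant), class = "fhn_cubic")
}

#' @export
print.fhn_cubic <- function(x, ...) {
  form <- if (x$variant == "soft") "f(u) = -u^3/3 + u" else "f(u) = -u^3 + 3u"
  cat("<fhn_cubic> ", x$variant, ": ", form, "\n", sep = "")
  invisible(x)
}

as_cubic <- function(cubic) {
  if (inherits(cubic, "fhn_cubic")) return(cubic)
  if (is.character(cubic)) return(fhn_cubic(cubic))
  abort("`cubic` must be an fhn_cubic object or \"soft\"/\"steep\"")
}

cubic_code <- function(cubic) if (as_cubic(cubic)$variant == "soft") 0L else 1L

cubic_f <- function(u, variant) {
  if (variant == "soft") -u^3 / 3 + u else -u^3 + 3 * u
}

cubic_fprime <- function(u, variant) {
  if (variant == "soft") 1 - u^2 else 3 - 3 * u^2
}

#' Evaluate a cubic nullcline and its derivative
#'
#' @param u Numeric vector of evaluation points.
#' @param cubic An [fhn_cubic()] object or `"soft"`/`"steep"`.
#' @return A tibble with columns `u`, `f` and `fprime`.
#' @examples
#' cubic_eval(c(0, 1, 2), "soft")
#' @export
cubic_eval <- function(u, cubic = fhn_cubic("soft")) {
  cubic <- as_cubic(cubic)
  tibble(u = u,
         f = cubic_f(u, cubic$variant),
         fprime = cubic_fprime(u, cubic$variant))
}
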