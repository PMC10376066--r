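#' Parameter records for the ODE model families
#'
#' Constructors for the dimensionless parameter sets of the three ordinary
#' differential equation families studied by the package:
#'
#' * `fhr_params()` -- the three-variable FitzHugh-Rinzel variant
#'   \deqn{\epsilon \dot u = f(u) - v + w + I, \quad \dot v = u - b v - c,
#'         \quad \dot w = \epsilon(-u - w),}
#'   the workhorse of the slow-fast analysis (defaults `b = 0.8`, `c = 0`,
#'   `eps = 0.1`, soft cubic).
#' * `fhr_original_params()` -- the original FitzHugh-Rinzel bursting model.
#'   Its printed form places \eqn{\epsilon} on the left of the voltage
#'   equation; `literal_eps_on_v = TRUE` implements that form exactly, while
#'   `FALSE` uses the classical convention without the \eqn{1/\epsilon}
#'   factor on the first equation.  The model's variables \eqn{(v, w, y)} are
#'   mapped onto the package-wide `(u, v, w)` state slots in that order.
#' * `fhn2d_params()` -- the planar FitzHugh-Nagumo system
#'   \deqn{\epsilon \dot u = f(u) - v + I + w_0, \quad \dot v = u - b v,}
#'   where the optional additive constant `drive_w` stands for the frozen
#'   super-slow variable of the three-dimensional system.
#'
#' All quantities are dimensionless; time is the model's own.
#'
#' @param I External drive (bifurcation parameter).
#' @param a,b,c,d,phi Model constants.
#' @param eps Small timescale-separation parameter; must be positive.
#' @param cubic Cubic variant, see [fhn_cubic()].
#' @param drive_w Additive constant standing for the frozen slow variable.
#' @param literal_eps_on_v Implement the printed form with \eqn{1/\epsilon}
#'   on the voltage equation (`TRUE`, default) or the classical convention
#'   (`FALSE`).
#' @return A parameter record (list with class `fhr_params`,
#'   `fhr_original_params` or `fhn2d_params`, all inheriting `fhn_params`).
#' @examples
#' fhr_params(I = 1.45)
#' fhr_original_params()
#' @export
fhr_params <- function(I, b = 0.8, c = 0, eps = 0.1, cubic = "soft") {
  stopifnot(is.numeric(I), length(I) == 1, is.finite(I))
  if (eps <= 0) abort("`eps` must be positive")
  if (b < 0) abort("`b` must be non-negative")
  structure(list(I = I, b = b, c = c, eps = eps, cubic = as_cubic(cubic)),
            class = c("fhr_params", "fhn_params"))
}

#' @rdname fhr_params
#' @export
fhr_original_params <- function(I = 0.3125, a = 0.7, b = 0.8, c = -0.775,
                                d = 1.0, phi = 0.08, eps = 1e-4,
                                literal_eps_on_v = TRUE) {
  if (eps <= 0) abort("`eps` must be positive")
  structure(list(I = I, a = a, b = b, c = c, d = d, phi = phi, eps = eps,
                 cubic = fhn_cubic("soft"),
                 literal_eps_on_v = isTRUE(literal_eps_on_v)),
            class = c("fhr_original_params", "fhn_params"))
}

#' @rdname fhr_params
#' @export
fhn2d_params <- function(I, b = 0.8, eps = 0.1, cubic = "soft", drive_w = 0) {
  stopifnot(is.numeric(I), length(I) == 1, is.finite(I))
  if (eps <= 0) abort("`eps` must be positive")
  structure(list(I = I, b = b, eps = eps, cubic = as_cubic(cubic),
                 drive_w = drive_w),
            class = c("fhn2d_params", "fhn_params"))
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- params_flatten(x)
  cat(paste0("  ", names(flat), " = ", unlist(flat), collapse = "\n"), "\n")
  invisible(x)
}

params_flatten <- function(p) {
  out <- lapply(unclass(p), function(v) {
    if (inherits(v, "fhn_cubic")) v$variant else v
  })
  out
}

#' Write or read a parameter record as a key-value config file
#'
#' Parameter records round-trip through a flat YAML mapping, with the class
#' recorded so that `read_params()` can rebuild the record.
#'
#' @param params A parameter record.
#' @param path File path.
#' @return `read_params()` returns the parameter record; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  flat <- params_flatten(params)
  flat$.class <- class(params)[1]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- yaml::read_yaml(path)
  cls <- flat$.class
  flat$.class <- NULL
  ctor <- switch(cls,
    fhr_params = fhr_params,
    fhr_original_params = fhr_original_params,
    fhn2d_params = fhn2d_params,
    nhfhn_params = nhfhn_params,
    abort(paste0("unknown parameter class: ", cls)))
  do.call(ctor, flat)
}

state_names <- function(params) {
  if (inherits(params, "fhn2d_params")) c("u", "v") else c("u", "v", "w")
}

# integer model code + flat parameter vector for the compiled integrator
model_code <- function(params) {
  if (inherits(params, "fhr_params")) {
    list(code = 1L, pars = c(params$I, params$b, params$c, params$eps,
                             cubic_code(params$cubic)))
  } else if (inherits(params, "fhr_original_params")) {
    list(code = 2L, pars = c(params$I, params$a, params$b, params$c, params$d,
                             params$phi, params$eps,
                             as.numeric(params$literal_eps_on_v)))
  } else if (inherits(params, "fhn2d_params")) {
    list(code = 3L, pars = c(params$I, params$b, params$eps,
                             cubic_code(params$cubic), params$drive_w))
  } else {
    abort("no compiled integrator for this parameter class")
  }
}

#' Default integration step for a model family
#'
#' The fixed-step RK4 integrator needs a step small enough for the stiff
#' voltage equation: the default is `eps/100` (i.e. `1e-3` at `eps = 0.1`),
#' floored at `1e-5`, which convergence tests show resolves the relaxation
#' jumps.  For the original bursting model in its classical convention the
#' voltage equation is not stiff and `0.01` is used.
#'
#' @param params A parameter record.
#' @return A positive scalar step size.
#' @export
default_dt <- function(params) {
  if (inherits(params, "fhr_original_params") && !params$literal_eps_on_v) {
    return(0.01)
  }
  max(params$eps / 100, 1e-5)
}
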