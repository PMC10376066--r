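#' Right-hand sides of the ODE model families
#'
#' Time derivatives of the three-variable FitzHugh-Rinzel variant
#' (`fhr_rhs()`), the original bursting model (`fhr_original_rhs()`) and the
#' planar FitzHugh-Nagumo system (`fhn2d_rhs()`). These are the exact vector
#' fields the integrators advance; they are exported so that analysis code
#' (and tests) can evaluate them pointwise.
#'
#' @param state Named or unnamed numeric state, `(u, v, w)` for the
#'   three-variable families and `(u, v)` for the planar one.  For the
#'   original model the published model's variables \eqn{(v, w, y)} occupy the
#'   `(u, v, w)` slots in that order.
#' @param params The matching parameter record, see [fhr_params()].
#' @return A named numeric vector of time derivatives.
#' @examples
#' fhr_rhs(c(0, 0, 0), fhr_params(I = 1.45))
#' @export
fhr_rhs <- function(state, params) {
  check_state(state, 3)
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  var <- params$cubic$variant
  c(u = (cubic_f(u, var) - v + w + params$I) / params$eps,
    v = u - params$b * v - params$c,
    w = params$eps * (-u - w))
}

#' @rdname fhr_rhs
#' @export
fhr_original_rhs <- function(state, params) {
  check_state(state, 3)
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  du <- cubic_f(u, "soft") - v + w + params$I
  if (params$literal_eps_on_v) du <- du / params$eps
  c(u = du,
    v = params$phi * (params$a + u - params$b * v),
    w = params$eps * (params$c - u - params$d * w))
}

#' @rdname fhr_rhs
#' @export
fhn2d_rhs <- function(state, params) {
  check_state(state, 2)
  u <- state[[1]]; v <- state[[2]]
  var <- params$cubic$variant
  c(u = (cubic_f(u, var) - v + params$I + params$drive_w) / params$eps,
    v = u - params$b * v)
}

check_state <- function(state, n) {
  if (length(state) != n || !all(is.finite(state))) {
    abort(paste0("state must be ", n, " finite values (numerical blow-up?)"))
  }
  invisible(state)
}

# closure f(t, y) for the generic RK4 integrator
rhs_fun <- function(params) {
  if (inherits(params, "fhr_params")) {
    function(t, y) fhr_rhs(y, params)
  } else if (inherits(params, "fhr_original_params")) {
    function(t, y) fhr_original_rhs(y, params)
  } else if (inherits(params, "fhn2d_params")) {
    function(t, y) fhn2d_rhs(y, params)
  } else {
    abort("no right-hand side for this parameter class")
  }
}
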