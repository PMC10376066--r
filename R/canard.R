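#' Slow-fast singular subsystems
#'
#' The three singular limits of the three-variable system obtained by
#' rescaling time before letting \eqn{\epsilon \to 0}:
#'
#' * `"reduced"` -- the slow flow on the critical manifold
#'   \eqn{v = f(u) + w + I}: \eqn{\dot v = u - bv}, \eqn{\dot w = 0}, with
#'   \eqn{\dot u = \dot v / f'(u)} by differentiating the constraint.  At a
#'   fold (\eqn{f'(u) = 0}) the slow flow is undefined (the derivative
#'   explodes in finite time) and an error is raised.
#' * `"layer"` -- the fast fibres: \eqn{\dot u = f(u) - v + w + I},
#'   \eqn{\dot v = \dot w = 0}.  Every point of the critical manifold is an
#'   equilibrium; generic initial conditions converge to an attracting
#'   branch (\eqn{f'(u) < 0}).
#' * `"superslow"` -- the flow on the one-dimensional slow manifold
#'   \eqn{v = f(u) + w + I}, \eqn{u = bv}: \eqn{\dot w = -(w + u)}, with the
#'   induced \eqn{\dot u, \dot v} from the constraints.
#'
#' @param regime `"reduced"`, `"layer"` or `"superslow"`.
#' @param state Numeric `(u, v, w)`.
#' @param params An [fhr_params()] record.
#' @return A list with `derivatives` (named vector), `constraint_residual`
#'   (how far the state is off the relevant manifold(s)) and `at_fold`.
#' @export
subsystem_rhs <- function(regime = c("reduced", "layer", "superslow"),
                          state, params) {
  regime <- match.arg(regime)
  check_state(state, 3)
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  var <- params$cubic$variant
  fu <- cubic_f(u, var)
  fp <- cubic_fprime(u, var)
  manifold <- fu - v + w + params$I
  at_fold <- abs(fp) < 1e-10
  if (regime == "layer") {
    return(list(derivatives = c(u = manifold, v = 0, w = 0),
                constraint_residual = 0, at_fold = at_fold))
  }
  if (regime == "reduced") {
    if (at_fold) {
      abort("reduced system undefined at a fold point (f'(u) = 0)")
    }
    dv <- u - params$b * v
    return(list(derivatives = c(u = dv / fp, v = dv, w = 0),
                constraint_residual = abs(manifold), at_fold = at_fold))
  }
  # superslow: both constraints active
  dw <- -(w + u)
  denom <- params$b * fp - 1
  dv <- if (abs(denom) > 1e-14) -dw / denom else NA_real_
  list(derivatives = c(u = params$b * dv, v = dv, w = dw),
       constraint_residual = max(abs(manifold), abs(u - params$b * v)),
       at_fold = at_fold)
}

#' Fold frame of the steep-cubic system
#'
#' Change of variables moving the origin to the right fold of the critical
#' manifold of the steep-cubic three-variable system: shifts
#' \eqn{\tilde v = 1/b} (from \eqn{1 - b\tilde v = 0}) and \eqn{\tilde w}
#' solving \eqn{f(1) - \tilde v + \tilde w + I = 0}, and the unfolding
#' parameter \eqn{\mu = 1 + \tilde w = -1 + 1/b - I}.  In the shifted
#' coordinates the fast equation's quadratic term is \eqn{-3u^2} (the steep
#' cubic's expansion about \eqn{u = 1}).
#'
#' @param params An [fhr_params()] record with the steep cubic and `b > 0`.
#' @return A one-row tibble with `v_tilde`, `w_tilde`, `mu`.
#' @examples
#' fold_frame(fhr_params(I = 0, b = 1, cubic = "steep"))
#' @export
fold_frame <- function(params) {
  if (params$b <= 0) abort("fold frame requires b > 0")
  if (params$cubic$variant != "steep") {
    abort("the fold expansion is about u = 1 of the steep cubic")
  }
  v_tilde <- 1 / params$b
  w_tilde <- v_tilde - cubic_f(1, "steep") - params$I
  tibble(v_tilde = v_tilde, w_tilde = w_tilde, mu = 1 + w_tilde)
}

#' First integral of the fold blow-up system
#'
#' The blow-up of the fold yields the integrable planar system
#' \eqn{\dot u = -3u^2 - v + w}, \eqn{\dot v = u} (with \eqn{w} constant),
#' which conserves
#' \deqn{G(u, v; w) = \big(-3u^2 - (v - w) + 1/6\big)\, e^{6(v - w)}.}
#' Its zero level set (the parabola \eqn{v - w = 1/6 - 3u^2}) separates the
#' periodic orbits around the center \eqn{(0, w)} from the escape orbits
#' with \eqn{u, v \to -\infty}.
#'
#' @param u,v Coordinates (vectorized).
#' @param w Constant slow value (the general case reduces to `w = 0` by
#'   shifting `v`).
#' @return Numeric vector of `G` values.
#' @examples
#' first_integral_G(0, 0) # 1/6
#' @export
first_integral_G <- function(u, v, w = 0) {
  s <- v - w
  (-3 * u^2 - s + 1 / 6) * exp(6 * s)
}

#' Right-hand side of the fold blow-up system
#'
#' @param state Numeric `(u, v, w)`; `w` is constant along the flow.
#' @return Named derivative vector.
#' @export
blowup_rhs <- function(state) {
  check_state(state, 3)
  c(u = -3 * state[[1]]^2 - state[[2]] + state[[3]],
    v = state[[1]],
    w = 0)
}

#' Classify an orbit of the fold blow-up system
#'
#' Launch point \eqn{(u, v) = (0, c)} at slow value `w`.  The analytic rule
#' uses the first integral: the center \eqn{c = w} is a fixed point;
#' orbits with \eqn{0 < G(0, c; w) < G(0, w; w) = 1/6} are periodic; orbits
#' with \eqn{G \le 0} (i.e. \eqn{c \ge w + 1/6}) escape with
#' \eqn{u, v \to -\infty}.  The integration method instead advances the
#' system and reports `"escape"` when the blow-up detector trips within
#' `t_max`, `"periodic"` otherwise.
#'
#' @param c_launch Launch ordinate `c`.
#' @param w Constant slow value.
#' @param method `"analytic"` (first integral) or `"integrate"`.
#' @param dt,t_max Integration controls for `method = "integrate"`.
#' @return `"fixed_point"`, `"periodic"` or `"escape"`.
#' @examples
#' classify_orbit(0.1)  # periodic: 0 < 0.1 < 1/6
#' classify_orbit(0.2)  # escape
#' @export
classify_orbit <- function(c_launch, w = 0,
                           method = c("analytic", "integrate"),
                           dt = 1e-3, t_max = 500) {
  method <- match.arg(method)
  if (c_launch == w) return("fixed_point")
  if (method == "analytic") {
    G <- first_integral_G(0, c_launch, w)
    if (G <= 0) return("escape")
    return("periodic")
  }
  tr <- integrate_model("blowup", y0 = c(0, c_launch, w), t1 = t_max, dt = dt,
                        stride = 1e9)
  if (blown_up(tr)) "escape" else "periodic"
}

#' Escape threshold of the fold blow-up system
#'
#' Bisects between a periodic and an escaping launch ordinate using the
#' integration-based classifier of [classify_orbit()]; the analytic value
#' from the first integral is \eqn{c^* = w + 1/6}.
#'
#' @param w Constant slow value.
#' @param tol Bisection tolerance on `c`.
#' @param c_bracket Bracket around the threshold; defaults to
#'   `w + c(0.05, 0.30)`.
#' @param dt,t_max Integration controls.
#' @return A list with `c_star`, `analytic` (`w + 1/6`), `tol` and the
#'   bracket.
#' @export
escape_threshold <- function(w = 0, tol = 1e-5, c_bracket = NULL,
                             dt = 1e-3, t_max = 500) {
  if (is.null(c_bracket)) c_bracket <- w + c(0.05, 0.30)
  lo <- c_bracket[1]; hi <- c_bracket[2]
  cls <- function(c) classify_orbit(c, w, method = "integrate", dt = dt,
                                    t_max = t_max)
  if (cls(lo) != "periodic" || cls(hi) != "escape") {
    abort("c_bracket must enclose the periodic/escape transition")
  }
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (cls(mid) == "periodic") lo <- mid else hi <- mid
  }
  list(c_star = 0.5 * (lo + hi), analytic = w + 1 / 6, tol = tol,
       bracket = c_bracket)
}
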