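#' First-return map on the section \{u = 0, v < 0\}
#'
#' Integrates the three-variable system from the section point
#' `(0, v, w)` and returns the first re-crossing of `u = 0` with `v < 0` in
#' the same crossing direction as the departure (rising `u`: the jump off
#' the left branch of the critical manifold).  The crossing is located by
#' bisection on the sub-step, so its accuracy is that of the RK4 step
#' itself.  For `|w|` not too large the orbit executes a relaxation loop
#' and the map is well defined; if no qualifying crossing occurs within
#' `t_budget` the result is flagged `converged = FALSE`.
#'
#' @param v,w Section coordinates (`v < 0`).
#' @param params An [fhr_params()] record (the finder is intended for small
#'   `I` and small `eps`).
#' @param dt Step size; defaults to [default_dt()].
#' @param t_budget Maximal integration time; defaults to `50 / eps` (one
#'   relaxation loop is O(1) in the slow time).
#' @return A one-row tibble: `v`, `w` (the image), `return_time`,
#'   `converged`.
#' @examples
#' p <- fhr_params(I = 0, eps = 0.01)
#' return_map(-2 / 3, 0.01, p)
#' @export
return_map <- function(v, w, params, dt = NULL, t_budget = NULL) {
  stopifnot(v < 0)
  if (is.null(dt)) dt <- default_dt(params)
  if (is.null(t_budget)) t_budget <- 50 / params$eps
  mc <- model_code(params)
  res <- integrate_until_section_cpp(mc$code, mc$pars, c(0, v, w), 0,
                                     t_budget, dt, 0L, 0, 1L,
                                     min_time = 2 * dt, require_vneg = TRUE,
                                     blowup = 1e8)
  tibble(v = res$state[2], w = res$state[3], return_time = res$time,
         converged = isTRUE(res$found))
}

# inner fixed point phi(w): v with F2(0, v, w) = v, by damped fixed-point
# iteration (the return v-coordinate is nearly independent of v, so the
# iteration contracts strongly); returns NA if the map fails to return.
poincare_phi <- function(w, params, dt, v0 = NULL, tol = 1e-12,
                         max_iter = 60) {
  if (is.null(v0)) v0 <- cubic_f(-1, params$cubic$variant)
  v <- v0
  for (k in seq_len(max_iter)) {
    r <- return_map(v, w, params, dt = dt)
    if (!r$converged) return(list(v = NA_real_, iter = k))
    if (abs(r$v - v) < tol) return(list(v = r$v, iter = k))
    v <- r$v
  }
  list(v = v, iter = max_iter)
}

#' Periodic orbit via the Poincaré map
#'
#' Two-stage search for a fixed point of the first-return map on
#' \{u = 0, v < 0\}: an inner solve for \eqn{\varphi(w)}, the
#' `v`-coordinate fixed at frozen `w`, then an outer scalar root of
#' \eqn{F_3(0, \varphi(w), w) - w} in `w`.  The outer map changes sign
#' across the periodic orbit (positive for small `w < 0`, negative for
#' small `w > 0`), which guarantees the bracket.
#'
#' @param params An [fhr_params()] record, typically `I = 0`, `eps = 0.01`.
#' @param w_bracket Bracket for the outer root.
#' @param dt Step size; defaults to [default_dt()].
#' @param tol Outer root tolerance on `w`.
#' @return An object of class `periodic_orbit`: `v_star`, `w_star`,
#'   `period`, `residual` (phase-space distance between the section point
#'   and its image) and the one-period `orbit` trajectory.
#' @examples
#' \donttest{
#' orb <- find_periodic_orbit(fhr_params(I = 0, eps = 0.01))
#' orb$period
#' }
#' @export
find_periodic_orbit <- function(params, w_bracket = c(-0.05, 0.05),
                                dt = NULL, tol = 1e-10) {
  if (is.null(dt)) dt <- default_dt(params)
  h <- function(w) {
    phi <- poincare_phi(w, params, dt)
    if (is.na(phi$v)) {
      abort(sprintf("return map not defined at w = %g (no return)", w))
    }
    r <- return_map(phi$v, w, params, dt = dt)
    list(h = r$w - w, v = phi$v, period = r$return_time, image = r)
  }
  hlo <- h(w_bracket[1])
  hhi <- h(w_bracket[2])
  if (sign(hlo$h) == sign(hhi$h)) {
    sweep <- purrr::map_dbl(seq(w_bracket[1], w_bracket[2], length.out = 9),
                            function(w) h(w)$h)
    abort(paste0("no sign change of F3(w) - w on the bracket; sweep: ",
                 paste(format(sweep, digits = 3), collapse = ", ")))
  }
  root <- uniroot(function(w) h(w)$h, w_bracket, tol = tol)
  w_star <- root$root
  sol <- h(w_star)
  residual <- sqrt((sol$image$v - sol$v)^2 + (sol$image$w - w_star)^2)
  orbit <- integrate_model(params, y0 = c(0, sol$v, w_star), t0 = 0,
                           t1 = sol$period, dt = dt,
                           stride = max(1L, floor(sol$period / dt / 2000)))
  out <- list(v_star = sol$v, w_star = w_star, period = sol$period,
              residual = residual, orbit = orbit, params = params, dt = dt)
  class(out) <- "periodic_orbit"
  out
}

#' @export
print.periodic_orbit <- function(x, ...) {
  cat(sprintf(paste0("<periodic_orbit> section point (u, v, w) = ",
                     "(0, %.8f, %.8f)\n  period %.6f, residual %.2e\n"),
              x$v_star, x$w_star, x$period, x$residual))
  invisible(x)
}

#' @export
glance.periodic_orbit <- function(x, ...) {
  tibble(v_star = x$v_star, w_star = x$w_star, period = x$period,
         residual = x$residual)
}
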