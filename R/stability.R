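#' Fixed points of the model families
#'
#' For the three-variable system the unique fixed point satisfies
#' \eqn{v^* = u^*/b}, \eqn{w^* = -u^*} with \eqn{u^*} the unique real root of
#' \eqn{f(u) - (1 + 1/b)u + I = 0}; for the soft cubic with \eqn{b > 0} the
#' defining map is strictly decreasing (\eqn{f' \le 1 < 1 + 1/b}), so the
#' root is unique.  For the planar system the fixed point satisfies
#' \eqn{v^* = u^*/b} with \eqn{u^*} the unique root of
#' \eqn{f(u) - u/b + I = 0} (requires \eqn{0 < b < 1}); \eqn{u^*} is
#' strictly increasing in \eqn{I}.
#'
#' @param params An [fhr_params()] (3d) or [fhn2d_params()] (2d) record.
#' @return A one-row tibble with the fixed-point coordinates and the
#'   residual of the defining equation (polished below `1e-12`).
#' @examples
#' fixed_point_3d(fhr_params(I = 1.45))
#' @export
fixed_point_3d <- function(params) {
  if (!inherits(params, "fhr_params")) abort("expected fhr_params")
  if (params$b <= 0) abort("fixed point formula requires b > 0")
  var <- params$cubic$variant
  slope <- 1 + 1 / params$b
  g <- function(u) cubic_f(u, var) - slope * u + params$I
  u <- root_scalar(g, dg = function(u) cubic_fprime(u, var) - slope)
  tibble(u_star = u, v_star = u / params$b, w_star = -u,
         residual = abs(g(u)))
}

#' @rdname fixed_point_3d
#' @export
fixed_point_2d <- function(params) {
  if (!inherits(params, "fhn2d_params")) abort("expected fhn2d_params")
  if (params$b <= 0 || params$b >= 1) {
    abort("planar fixed point statement requires 0 < b < 1")
  }
  var <- params$cubic$variant
  g <- function(u) {
    cubic_f(u, var) - u / params$b + params$I + params$drive_w
  }
  u <- root_scalar(g, dg = function(u) cubic_fprime(u, var) - 1 / params$b)
  tibble(u_star = u, v_star = u / params$b, residual = abs(g(u)))
}

# decreasing scalar root with expanding bracket + Newton polish
root_scalar <- function(g, dg, lo = -3, hi = 3) {
  for (k in 1:60) {
    if (g(lo) > 0) break
    lo <- lo - 2
  }
  for (k in 1:60) {
    if (g(hi) < 0) break
    hi <- hi + 2
  }
  u <- uniroot(g, c(lo, hi), tol = 1e-13)$root
  for (k in 1:3) u <- u - g(u) / dg(u)
  u
}

#' Jacobian of the three-variable system at a point
#'
#' \deqn{J(u) = \begin{pmatrix} f'(u)/\epsilon & -1/\epsilon & 1/\epsilon \\
#'   1 & -b & 0 \\ -\epsilon & 0 & -\epsilon \end{pmatrix}}
#'
#' @param u_star Evaluation point (usually the fixed point's `u` value).
#' @param params An [fhr_params()] record.
#' @return A 3x3 numeric matrix.
#' @export
jacobian3 <- function(u_star, params) {
  eps <- params$eps
  fp <- cubic_fprime(u_star, params$cubic$variant)
  matrix(c(fp / eps, -1 / eps, 1 / eps,
           1, -params$b, 0,
           -eps, 0, -eps),
         nrow = 3, byrow = TRUE)
}

#' Characteristic coefficients of the three-variable Jacobian
#'
#' The characteristic polynomial, normalized monic so that the
#' Routh-Hurwitz criterion applies in its standard statement, is
#' \eqn{\lambda^3 + a_2\lambda^2 + a_1\lambda + a_0} with
#' \deqn{a_2 = \epsilon + b - f'(u)/\epsilon,\quad
#'   a_1 = -\big(f'(u) + b f'(u)/\epsilon - b\epsilon - 1/\epsilon - 1\big),
#'   \quad a_0 = b u^2 + 1 > 0.}
#'
#' @inheritParams jacobian3
#' @return Named numeric vector `c(a2, a1, a0)`.
#' @export
char_coeffs <- function(u_star, params) {
  eps <- params$eps
  b <- params$b
  fp <- cubic_fprime(u_star, params$cubic$variant)
  c(a2 = eps + b - fp / eps,
    a1 = -(fp + b * fp / eps - b * eps - 1 / eps - 1),
    a0 = b * u_star^2 + 1)
}

#' Discriminant of a monic cubic (Cardan criterion)
#'
#' Discriminant of \eqn{\lambda^3 + a_2\lambda^2 + a_1\lambda + a_0}.
#' Negative values indicate one real root plus a complex-conjugate pair;
#' positive values indicate three distinct real roots.
#'
#' @param a2,a1,a0 Monic cubic coefficients.
#' @return The discriminant (sign convention: negative means complex pair).
#' @examples
#' cardan_delta(0, -1, 0) > 0  # lambda^3 - lambda: three real roots
#' cardan_delta(0,  1, 0) < 0  # lambda^3 + lambda: complex pair
#' @export
cardan_delta <- function(a2, a1, a0) {
  18 * a2 * a1 * a0 - 4 * a2^3 * a0 + a2^2 * a1^2 - 4 * a1^3 - 27 * a0^2
}

#' Spectral summary of the three-variable system at its fixed point
#'
#' Computes the fixed point, the Jacobian, the monic characteristic
#' coefficients, the Cardan discriminant, the eigenvalues and their
#' stability counts (real parts compared to zero with tolerance `tol`), and
#' the Routh-Hurwitz margin \eqn{a_2 a_1 - a_0}.  The Hurwitz verdict
#' requires \eqn{a_2 > 0}, \eqn{a_0 > 0} and \eqn{a_2 a_1 - a_0 > 0}.
#' `eig_signature()` is an alias.
#'
#' @param params An [fhr_params()] record.
#' @param tol Real-part tolerance for counting eigenvalues on the axis.
#' @return An object of class `spectral_summary` with fields
#'   `fixed_point`, `jacobian`, `a2`, `a1`, `a0`, `cardan_delta`,
#'   `eigenvalues`, `n_unstable`, `n_stable`, `n_center`,
#'   `has_complex_pair`, `hurwitz_margin`, `stable`.
#' @examples
#' s <- spectral_summary(fhr_params(I = 1.45))
#' s$n_unstable  # 2: an unstable complex pair
#' @export
spectral_summary <- function(params, tol = 1e-9) {
  fp <- fixed_point_3d(params)
  J <- jacobian3(fp$u_star, params)
  co <- char_coeffs(fp$u_star, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  re <- Re(ev)
  out <- list(
    params = params,
    fixed_point = fp,
    jacobian = J,
    a2 = unname(co["a2"]), a1 = unname(co["a1"]), a0 = unname(co["a0"]),
    cardan_delta = unname(cardan_delta(co["a2"], co["a1"], co["a0"])),
    eigenvalues = ev,
    n_unstable = sum(re > tol),
    n_stable = sum(re < -tol),
    n_center = sum(abs(re) <= tol),
    has_complex_pair = any(abs(Im(ev)) > tol),
    hurwitz_margin = unname(co["a2"] * co["a1"] - co["a0"]),
    stable = unname(co["a2"] > 0 && co["a0"] > 0 &&
                      co["a2"] * co["a1"] - co["a0"] > 0)
  )
  class(out) <- "spectral_summary"
  out
}

#' @rdname spectral_summary
#' @export
eig_signature <- spectral_summary

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary>\n")
  cat(sprintf("  fixed point u* = %.6f (residual %.2e)\n",
              x$fixed_point$u_star, x$fixed_point$residual))
  cat(sprintf("  eigenvalues: %s\n",
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  cat(sprintf("  unstable/stable/center: %d/%d/%d, complex pair: %s\n",
              x$n_unstable, x$n_stable, x$n_center, x$has_complex_pair))
  cat(sprintf("  Hurwitz margin a2*a1 - a0 = %.6g (stable: %s)\n",
              x$hurwitz_margin, x$stable))
  invisible(x)
}

#' @export
tidy.spectral_summary <- function(x, ...) {
  tibble(eigenvalue = seq_along(x$eigenvalues),
         real = Re(x$eigenvalues),
         imag = Im(x$eigenvalues),
         modulus = Mod(x$eigenvalues))
}

#' @export
glance.spectral_summary <- function(x, ...) {
  tibble(u_star = x$fixed_point$u_star, a2 = x$a2, a1 = x$a1, a0 = x$a0,
         cardan_delta = x$cardan_delta, hurwitz_margin = x$hurwitz_margin,
         n_unstable = x$n_unstable, n_stable = x$n_stable,
         has_complex_pair = x$has_complex_pair, stable = x$stable)
}

# max real part of the complex-conjugate eigenvalue pair; where the pair
# does not exist (real spectrum: node regimes at the bracket ends) the
# overall spectral abscissa is used, which has the same sign
complex_pair_re <- function(params, tol = 1e-9) {
  s <- spectral_summary(params, tol = tol)
  cp <- s$eigenvalues[abs(Im(s$eigenvalues)) > tol]
  if (length(cp) == 0) return(max(Re(s$eigenvalues)))
  max(Re(cp))
}

#' Locate the Hopf bifurcation of the three-variable system
#'
#' Bisects on the sign of the real part of the complex-conjugate eigenvalue
#' pair at the fixed point (equivalently, on the Routh-Hurwitz condition
#' becoming true) over a bracket in the drive `I`.  Below the located
#' \eqn{I^*} the fixed point is unstable, above it stable.
#'
#' @param params An [fhr_params()] record; its `I` is ignored.
#' @param I_bracket Bracket in `I` with a sign change of the pair's real
#'   part.
#' @param tol Bisection tolerance on `I`.
#' @return An object of class `hopf_fit` with fields `I_star`, `bracket`,
#'   `re_lo`, `re_hi` and `tol`.
#' @examples
#' hopf_locate(fhr_params(I = 1))$I_star
#' @export
hopf_locate <- function(params, I_bracket = c(0.5, 2.5), tol = 1e-10) {
  at <- function(I) {
    p <- params
    p$I <- I
    complex_pair_re(p)
  }
  lo <- I_bracket[1]; hi <- I_bracket[2]
  glo <- at(lo); ghi <- at(hi)
  if (glo * ghi >= 0) {
    abort("the complex pair's real part does not change sign on I_bracket")
  }
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    gm <- at(mid)
    if (gm * glo > 0) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid; ghi <- gm
    }
  }
  out <- list(I_star = 0.5 * (lo + hi), bracket = I_bracket,
              re_lo = glo, re_hi = ghi, tol = tol, params = params)
  class(out) <- "hopf_fit"
  out
}

#' @export
print.hopf_fit <- function(x, ...) {
  cat(sprintf("<hopf_fit> I* = %.10f (bracket [%g, %g], tol %g)\n",
              x$I_star, x$bracket[1], x$bracket[2], x$tol))
  invisible(x)
}

#' @export
glance.hopf_fit <- function(x, ...) {
  tibble(I_star = x$I_star, bracket_lo = x$bracket[1],
         bracket_hi = x$bracket[2], tol = x$tol)
}

#' Hopf point of the planar system
#'
#' For the planar system with the soft cubic the Hopf bifurcation occurs at
#' \eqn{f'(u^*) = b\epsilon}, i.e. \eqn{u^* = \sqrt{1 - b\epsilon}}.
#'
#' @param b,eps Planar model parameters.
#' @return The critical `u_star`.
#' @export
fhn2d_hopf_ustar <- function(b = 0.8, eps = 0.1) {
  stopifnot(b * eps < 1)
  sqrt(1 - b * eps)
}

#' Stability sweep over the drive parameter
#'
#' Evaluates the spectral summary on a grid of `I` values, one row per `I`:
#' the fixed point, the leading eigenvalue real/imaginary parts, the
#' characteristic coefficients, Cardan discriminant, Hurwitz margin and the
#' stability verdicts.
#'
#' @param params An [fhr_params()] record (its `I` is ignored).
#' @param I_values Numeric grid of drive values.
#' @return A tibble with one row per `I`.
#' @export
stability_sweep <- function(params, I_values) {
  purrr::map_dfr(I_values, function(I) {
    p <- params
    p$I <- I
    s <- spectral_summary(p)
    dplyr::bind_cols(tibble(I = I), glance(s),
                     tibble(re_pair = {
                       cp <- s$eigenvalues[abs(Im(s$eigenvalues)) > 1e-9]
                       if (length(cp)) max(Re(cp)) else NA_real_
                     },
                     re_max = max(Re(s$eigenvalues))))
  })
}
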