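#' Fixed point of the frozen-w planar subsystem
#'
#' Solves \eqn{0 = f(u) - v + w + I}, \eqn{0 = u - bv} for the "stationary"
#' point \eqn{(u^*(w), v^*(w))} of the first two equations of the
#' three-variable system with the super-slow variable frozen; the root is
#' continued from `guess` by safeguarded Newton.
#'
#' @param w Frozen slow-variable value (vectorized).
#' @param params An [fhr_params()] record.
#' @param guess Starting value for the Newton continuation.
#' @return Numeric vector `u_star(w)`.
#' @export
u_star_planar <- function(w, params, guess = 0) {
  var <- params$cubic$variant
  b <- params$b
  vapply(w, function(wi) {
    g <- function(u) cubic_f(u, var) - u / b + wi + params$I
    u <- root_scalar(g, dg = function(u) cubic_fprime(u, var) - 1 / b,
                     lo = guess - 1, hi = guess + 1)
    guess <<- u
    u
  }, numeric(1))
}

#' Symbolic classification of oscillation events
#'
#' Turns an alternating extrema sequence into ordered oscillation events:
#' one event per adjacent (min, max) pair, with peak-to-trough amplitude
#' `max - min`, labelled `"S"` (small), `"M"` (medium) or `"L"` (large) by
#' comparing the amplitude to the largest event: at least
#' `theta_ml * max(amplitude)` is large, at least `theta_sm * max(amplitude)`
#' medium, below that small.  The labels are invariant under uniform
#' rescaling of the signal.  The default cutoffs (0.3, 0.7) reflect the
#' three clearly separated amplitude bands the mixed-mode regimes produce;
#' they are not model constants and can be tuned.
#'
#' @param extrema Tibble from [find_extrema()] (alternating kinds).
#' @param theta_sm,theta_ml Amplitude cutoffs as fractions of the largest
#'   event, `0 < theta_sm < theta_ml < 1`.
#' @return A `symbol_sequence`: tibble with columns `time`, `amplitude`,
#'   `label`, carrying the thresholds as attributes.
#' @examples
#' tt <- seq(0, 30, by = 0.01)
#' x <- sin(tt) * rep(c(1, 1, 0.1), each = length(tt) / 3)
#' classify_oscillations(find_extrema(tt, x))
#' @export
classify_oscillations <- function(extrema, theta_sm = 0.3, theta_ml = 0.7) {
  stopifnot(theta_sm > 0, theta_sm < theta_ml, theta_ml < 1)
  empty <- structure(
    tibble(time = numeric(), amplitude = numeric(), label = character()),
    class = c("symbol_sequence", class(tibble())),
    thresholds = c(theta_sm = theta_sm, theta_ml = theta_ml))
  if (nrow(extrema) < 2) return(empty)
  k <- extrema$kind
  i <- which(k[-length(k)] == "min" & k[-1] == "max")
  if (length(i) == 0) return(empty)
  amp <- extrema$value[i + 1] - extrema$value[i]
  amax <- max(amp)
  label <- ifelse(amp >= theta_ml * amax, "L",
                  ifelse(amp >= theta_sm * amax, "M", "S"))
  out <- tibble(time = extrema$time[i + 1], amplitude = amp, label = label)
  class(out) <- c("symbol_sequence", class(out))
  attr(out, "thresholds") <- c(theta_sm = theta_sm, theta_ml = theta_ml)
  out
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat("<symbol_sequence> ", motif_compress(x), "\n", sep = "")
  NextMethod()
}

#' Motif string and run-length compression of a symbol sequence
#'
#' `motif_string()` concatenates the labels; `motif_compress()` greedily
#' compresses the string into repeated units, choosing at each position the
#' unit with the most consecutive repeats (longest unit on ties), e.g.
#' `"LLSLLSLLSLLSLM"` becomes `"LLS×4 LM"`.
#'
#' @param seq A `symbol_sequence`, or a plain label string.
#' @return A character scalar.
#' @examples
#' motif_compress("LLSLLSLLSLLSLM")
#' @export
motif_compress <- function(seq) {
  s <- motif_string(seq)
  n <- nchar(s)
  if (n == 0) return("")
  chars <- strsplit(s, "")[[1]]
  pieces <- character()
  i <- 1L
  while (i <= n) {
    rem <- n - i + 1L
    best_k <- 1L
    best_r <- 1L
    for (k in seq_len(rem)) {
      unit <- chars[i:(i + k - 1L)]
      r <- 1L
      while (i + (r + 1L) * k - 1L <= n &&
             identical(chars[(i + r * k):(i + (r + 1L) * k - 1L)], unit)) {
        r <- r + 1L
      }
      if (r > best_r || (r == best_r && k > best_k && r > 1L) ||
          (r == 1L && best_r == 1L && k > best_k)) {
        best_k <- k
        best_r <- r
      }
    }
    unit <- paste(chars[i:(i + best_k - 1L)], collapse = "")
    pieces <- c(pieces, list(c(unit = unit, r = best_r)))
    i <- i + best_k * best_r
  }
  if (length(pieces) == 1) {
    p <- pieces[[1]]
    return(paste0(p["unit"], "×", p["r"]))
  }
  paste(vapply(pieces, function(p) {
    r <- as.integer(p["r"])
    if (r > 1) paste0(p["unit"], "×", r) else p["unit"]
  }, character(1)), collapse = " ")
}

#' @rdname motif_compress
#' @export
motif_string <- function(seq) {
  if (is.character(seq) && length(seq) == 1) return(seq)
  paste(seq$label, collapse = "")
}

#' Focus-frame vector fields
#'
#' After moving the origin to the frozen-w planar fixed point
#' \eqn{(u^*(w), v^*(w))} (see [u_star_planar()]), the three-variable system
#' becomes the exact focus-frame system (`transformed_rhs()`):
#' \deqn{\epsilon \dot u = g(u^*, u) - v -
#'   \epsilon^2 k (u^* + u + w), \quad
#'   \dot v = u - bv - \tfrac{\epsilon k}{b}(u^* + u + w), \quad
#'   \dot w = -\epsilon(w + u^* + u)}
#' with \eqn{g(u^*, u) = f(u^* + u) - f(u^*)} and
#' \eqn{k = 1/(f'(u^*) - 1/b)}; the \eqn{O(\epsilon)} correction terms are
#' the chain-rule contributions of the moving frame
#' (\eqn{du^*/dw = -k}, \eqn{dv^*/dw = -k/b}), and with them the
#' focus-frame trajectories map back onto the original system exactly.
#' Dropping the nonlinear and \eqn{O(\epsilon)} correction terms in the
#' first two equations yields the moving-focus approximation
#' (`moving_focus_rhs()`):
#' \deqn{\epsilon \dot u = f'(u^*) u - v, \quad \dot v = u - bv, \quad
#'   \dot w = -\epsilon(w + u^* + u).}
#'
#' @param state Numeric `(u, v, w)` in focus coordinates.
#' @param params An [fhr_params()] record.
#' @return Named derivative vector.
#' @export
transformed_rhs <- function(state, params) {
  check_state(state, 3)
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  var <- params$cubic$variant
  us <- u_star_planar(w, params)
  fp <- cubic_fprime(us, var)
  if (abs(fp - 1 / params$b) < 1e-12) {
    abort("singular focus frame: f'(u*(w)) = 1/b")
  }
  k <- 1 / (fp - 1 / params$b)
  s <- us + u + w
  eps <- params$eps
  g <- cubic_f(us + u, var) - cubic_f(us, var)
  c(u = (g - v) / eps - eps * k * s,
    v = u - params$b * v - eps * k * s / params$b,
    w = -eps * (w + us + u))
}

#' @rdname transformed_rhs
#' @export
moving_focus_rhs <- function(state, params) {
  check_state(state, 3)
  u <- state[[1]]; v <- state[[2]]; w <- state[[3]]
  us <- u_star_planar(w, params)
  fp <- cubic_fprime(us, params$cubic$variant)
  eps <- params$eps
  c(u = (fp * u - v) / eps,
    v = u - params$b * v,
    w = -eps * (w + us + u))
}

#' Linearized focus matrix and its rotation rate
#'
#' The moving-focus approximation linearizes the planar block around
#' \eqn{u^*}: \eqn{A = \begin{pmatrix} f'(u^*)/\epsilon & -1/\epsilon \\
#' 1 & -b \end{pmatrix}}.  Where the eigenvalues are complex
#' (\eqn{(\mathrm{Tr}A)^2 < 4\det A}) they are
#' \eqn{\alpha \pm i\beta} with \eqn{\alpha = \mathrm{Tr}A/2} and
#' \eqn{\beta = \tfrac12\sqrt{4\det A - (\mathrm{Tr}A)^2}};
#' elsewhere `beta` is reported as 0 (no rotation).
#'
#' @param u_star Planar fixed-point value(s), vectorized.
#' @param params An [fhr_params()] record.
#' @return `focus_matrix()`: a 2x2 matrix (scalar `u_star` only);
#'   `focus_alpha_beta()`: a tibble with columns `u_star`, `alpha`, `beta`,
#'   `complex`.
#' @export
focus_matrix <- function(u_star, params) {
  stopifnot(length(u_star) == 1)
  eps <- params$eps
  fp <- cubic_fprime(u_star, params$cubic$variant)
  matrix(c(fp / eps, -1 / eps, 1, -params$b), nrow = 2, byrow = TRUE)
}

#' @rdname focus_matrix
#' @export
focus_alpha_beta <- function(u_star, params) {
  eps <- params$eps
  fp <- cubic_fprime(u_star, params$cubic$variant)
  tr <- fp / eps - params$b
  det <- -fp * params$b / eps + 1 / eps
  disc <- 4 * det - tr^2
  cplx <- disc > 0
  tibble(u_star = u_star,
         alpha = tr / 2,
         beta = ifelse(cplx, 0.5 * sqrt(pmax(disc, 0)), 0),
         complex = cplx)
}

# resolve a path argument (function of t, trajectory with a w column, or
# data frame time/value) into times + u_star samples
resolve_ustar_path <- function(path, T = NULL, params, n = 4097,
                               path_is = c("u_star", "w")) {
  path_is <- match.arg(path_is)
  if (is.function(path)) {
    stopifnot(!is.null(T), T >= 0)
    tt <- seq(0, T, length.out = n)
    val <- vapply(tt, path, numeric(1))
  } else if (is.data.frame(path)) {
    if (all(c("time", "w") %in% names(path))) {
      tt <- path$time
      val <- path$w
      path_is <- "w"
    } else {
      tt <- path$time
      val <- path$value
    }
  } else {
    abort("`path` must be a function of t or a data frame")
  }
  us <- if (path_is == "w") u_star_planar(val, params) else val
  list(time = tt, u_star = us)
}

#' Predicted number of small oscillations along a focus passage
#'
#' Integrates the local rotation rate of the moving focus:
#' \deqn{n_o = \frac{1}{2\pi}\int_0^T \beta(t)\,dt,}
#' by composite trapezoid quadrature, with \eqn{\beta} set to 0 wherever the
#' linearization's eigenvalues are real (no rotation).
#'
#' @param path Either a function of `t` returning the path value, a data
#'   frame with columns `time` and `value`, or an `fhn_trajectory` of the
#'   moving-focus system (its `w` column is used, with `path_is = "w"`).
#' @param T Duration (needed when `path` is a function).
#' @param params An [fhr_params()] record.
#' @param n Number of quadrature nodes when `path` is a function.
#' @param path_is Whether the path carries `u_star` directly or the slow
#'   variable `w` (converted through [u_star_planar()]).
#' @return The estimated count (a real number).
#' @export
count_small_oscillations <- function(path, T = NULL, params, n = 4097,
                                     path_is = c("u_star", "w")) {
  p <- resolve_ustar_path(path, T, params, n, match.arg(path_is))
  if (length(p$time) < 2) return(0)
  ab <- focus_alpha_beta(p$u_star, params)
  trapz(p$time, ab$beta) / (2 * pi)
}

#' Sign profile of the focus growth rate along a passage
#'
#' Partitions the time interval by the sign of \eqn{\alpha(t)}
#' (= \eqn{\mathrm{Tr}A/2}): negative means shrinking oscillation
#' amplitudes, positive growing ones; the sign change is the dynamic Hopf
#' passage.
#'
#' @inheritParams count_small_oscillations
#' @return A tibble with columns `start`, `end`, `sign` (-1, 0 or +1).
#' @export
alpha_sign_profile <- function(path, T = NULL, params, n = 4097,
                               path_is = c("u_star", "w")) {
  p <- resolve_ustar_path(path, T, params, n, match.arg(path_is))
  ab <- focus_alpha_beta(p$u_star, params)
  sgn <- sign(ab$alpha)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  tibble(start = p$time[starts], end = p$time[ends], sign = r$values)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
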