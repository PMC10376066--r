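#' Uniform cell-centered grid for the reaction-diffusion solver
#'
#' A 1D interval \eqn{(-L, L)} or a 2D square of side \eqn{2L}, discretized
#' into `n` cells per axis with cell-centered coordinates (an odd `n` puts a
#' cell exactly at the center).
#'
#' @param n Points per axis (at least 3).
#' @param half_width Half the domain extent `L`.
#' @param dim 1 or 2.
#' @return An `fhn_grid` with fields `dim`, `nx`, `ny`, `dx`, `x`, `y`,
#'   `half_width`.
#' @examples
#' g <- fhn_grid(401, half_width = 50)
#' g$dx
#' @export
fhn_grid <- function(n = 401, half_width = 50, dim = 1) {
  stopifnot(n >= 3, half_width > 0, dim %in% c(1, 2))
  dx <- 2 * half_width / n
  x <- -half_width + (seq_len(n) - 0.5) * dx
  structure(list(dim = dim, nx = as.integer(n),
                 ny = if (dim == 2) as.integer(n) else 1L,
                 dx = dx, x = x, y = if (dim == 2) x else 0,
                 half_width = half_width),
            class = "fhn_grid")
}

#' @export
print.fhn_grid <- function(x, ...) {
  cat(sprintf("<fhn_grid> %dD, %d%s cells, dx = %.4g on (-%g, %g)\n",
              x$dim, x$nx, if (x$dim == 2) paste0(" x ", x$ny) else "",
              x$dx, x$half_width, x$half_width))
  invisible(x)
}

grid_npts <- function(grid) grid$nx * grid$ny

# resolve a scalar or field against the grid, as a plain vector (2D fields
# are stored column-major: index i + nx * (j - 1))
resolve_field <- function(field, grid, what = "field") {
  n <- grid_npts(grid)
  if (is.null(field)) field <- 0
  if (length(field) == 1) return(rep(as.numeric(field), n))
  v <- as.numeric(field)
  if (length(v) != n) {
    abort(sprintf("%s must be a scalar or have %d values", what, n))
  }
  v
}

field_matrix <- function(v, grid) {
  if (grid$dim == 1) v else matrix(v, grid$nx, grid$ny)
}

#' Discrete Laplacian with Neumann (no-flux) boundaries
#'
#' Standard second-order central stencil; boundary cells use ghost-point
#' reflection (zero normal derivative), which conserves the discrete spatial
#' mean of the pure-diffusion sub-operator to round-off.
#'
#' @param field Numeric vector (1D) or matrix (2D) on the grid.
#' @param grid An [fhn_grid()].
#' @return Laplacian values, same shape as `field`.
#' @export
laplacian_neumann <- function(field, grid) {
  v <- resolve_field(field, grid, "field")
  out <- laplacian_neumann_cpp(v, grid$nx, grid$ny, grid$dx)
  if (is.matrix(field)) matrix(out, grid$nx, grid$ny) else out
}

#' Excitability profiles
#'
#' `c_profile_ball()` builds the 2D profile of the oscillatory-core
#' scenario: `c_inside` (default 0, oscillatory) within Euclidean distance
#' `radius` of the domain center and `c_outside` (default -1.21, excitable)
#' elsewhere.  `c_profile_quartic()` builds the 1D quartic well
#' \eqn{c(x) = p (x/\beta)^4 - 2p (x/\beta)^2}: zero at the center
#' (oscillatory) and \eqn{-p} at the borders \eqn{x = \pm\beta}, monotone in
#' `|x|` for `p > 0`.
#'
#' @param grid An [fhn_grid()] (2D for the ball, 1D for the quartic).
#' @param radius Ball radius (must be below the half-extent).
#' @param c_inside,c_outside Values inside/outside the ball.
#' @param p Well depth parameter (the border value is `-p`).
#' @param beta Half-width scaling the quartic; defaults to the grid
#'   half-width.
#' @return A matrix (ball) or vector (quartic) on the grid.
#' @export
c_profile_ball <- function(grid, radius = 5 * grid$dx, c_inside = 0,
                           c_outside = -1.21) {
  stopifnot(grid$dim == 2, radius < grid$half_width)
  r2 <- outer(grid$x^2, grid$y^2, `+`)
  ifelse(r2 <= radius^2, c_inside, c_outside)
}

#' @rdname c_profile_ball
#' @export
c_profile_quartic <- function(grid, p, beta = grid$half_width) {
  stopifnot(grid$dim == 1)
  s <- grid$x / beta
  p * s^4 - 2 * p * s^2
}

#' Parameters of the non-homogeneous reaction-diffusion system
#'
#' The oscillatory-excitable medium
#' \deqn{\epsilon u_t = f(u) - v + I(x) + d_u \Delta u, \quad
#'       v_t = u - b v - c(x) + d_v \Delta v}
#' with no-flux boundaries.  The space-dependent `c(x)` (and optionally
#' `I(x)`) encodes where the diffusion-less dynamics are oscillatory versus
#' excitable.  Profiles may be scalars or full fields and are resolved
#' against the grid at simulation time.
#'
#' @param eps Timescale separation (positive).
#' @param b Recovery coupling (`>= 0`).
#' @param d_u,d_v Diffusivities (`>= 0`).
#' @param cubic Cubic variant; the reaction-diffusion parameter sets use
#'   `"steep"`.
#' @param I_profile,c_profile Scalar or per-cell fields.
#' @return An `nhfhn_params` record.
#' @export
nhfhn_params <- function(eps = 0.1, b = 0, d_u = 1, d_v = 0,
                         cubic = "steep", I_profile = 0, c_profile = 0) {
  if (eps <= 0) abort("`eps` must be positive")
  if (d_u < 0 || d_v < 0) abort("diffusivities must be non-negative")
  if (b < 0) abort("`b` must be non-negative")
  structure(list(eps = eps, b = b, d_u = d_u, d_v = d_v,
                 cubic = as_cubic(cubic), I_profile = I_profile,
                 c_profile = c_profile),
            class = c("nhfhn_params", "fhn_params"))
}

#' Explicit time-step bound for the reaction-diffusion solver
#'
#' The stiffest term is the diffusion in the fast equation, giving
#' \eqn{dt \le \epsilon\, dx^2 / (4 n_{dim} d_u)} (the \eqn{1/\epsilon}
#' sharpens the usual explicit-diffusion constraint); the `v`-diffusion
#' contributes \eqn{dx^2/(4 n_{dim} d_v)}.
#'
#' @param params An [nhfhn_params()] record.
#' @param grid An [fhn_grid()].
#' @return The maximal admissible step.
#' @export
nhfhn_dt_max <- function(params, grid) {
  bounds <- Inf
  if (params$d_u > 0) {
    bounds <- min(bounds, params$eps * grid$dx^2 / (4 * grid$dim * params$d_u))
  }
  if (params$d_v > 0) {
    bounds <- min(bounds, grid$dx^2 / (4 * grid$dim * params$d_v))
  }
  bounds
}

# conservative default dt: half the diffusion bound, further capped by the
# local reaction stiffness |f'(u)|/eps over the excitability range
nhfhn_dt_default <- function(params, grid) {
  cvals <- resolve_field(params$c_profile, grid, "c_profile")
  umax <- max(2, abs(cvals))
  fpmax <- max(abs(cubic_fprime(c(0, umax), params$cubic$variant)))
  react <- 2 * params$eps / fpmax
  0.5 * min(nhfhn_dt_max(params, grid), react)
}

#' Simulate the non-homogeneous reaction-diffusion system
#'
#' Method of lines: spatial Laplacians from [laplacian_neumann()], classical
#' fixed-step RK4 in time (compiled core).  The default initial condition is
#' the `b = 0` stationary formula with the diffusion term dropped:
#' `u = c(x)`, `v = f(c) + I` -- deterministic and already close to
#' equilibrium in the excitable region.
#'
#' @param params An [nhfhn_params()] record.
#' @param grid An [fhn_grid()].
#' @param t_end Final time.
#' @param ic Optional list with fields `u`, `v` (vectors/matrices on the
#'   grid).
#' @param dt Time step; must satisfy [nhfhn_dt_max()] (an error proposes a
#'   compliant value).  Default: half the stability bound, further reduced
#'   if the reaction term is stiffer.
#' @param stride Record the full fields every `stride` steps; default keeps
#'   roughly 25 frames per time unit.
#' @param probes Optional locations recorded at every `probe_stride` steps
#'   with their `u`, `v` and Laplacian-of-`u` series: a vector of `x`
#'   positions (1D) or a 2-column matrix of `(x, y)` (2D).
#' @param probe_stride Step stride for the probe series.
#' @param blowup Blow-up truncation threshold.
#' @return An `nhfhn_solution`: list with `grid`, `params`, `times`,
#'   fields `u`, `v` (rows = recorded times, columns = cells), `probes`
#'   (long tibble) and a blow-up flag.
#' @export
simulate_nhfhn <- function(params, grid, t_end, ic = NULL, dt = NULL,
                           stride = NULL, probes = NULL, probe_stride = 1L,
                           blowup = 1e8) {
  Ip <- resolve_field(params$I_profile, grid, "I_profile")
  cp <- resolve_field(params$c_profile, grid, "c_profile")
  dtmax <- nhfhn_dt_max(params, grid)
  if (is.null(dt)) {
    dt <- nhfhn_dt_default(params, grid)
  } else if (dt > dtmax) {
    abort(sprintf(
      "dt = %g violates the explicit-diffusion bound %g; use dt <= %g",
      dt, dtmax, dtmax))
  }
  if (is.null(ic)) {
    u0 <- cp
    v0 <- cubic_f(cp, params$cubic$variant) + Ip
  } else {
    u0 <- resolve_field(ic$u, grid, "ic$u")
    v0 <- resolve_field(ic$v, grid, "ic$v")
  }
  if (is.null(stride)) {
    stride <- max(1L, floor(0.04 / dt))
  }
  pidx <- integer(0)
  ptab <- NULL
  if (!is.null(probes)) {
    ptab <- probe_index(probes, grid)
    pidx <- ptab$index - 1L
  }
  res <- nhfhn_cpp(u0, v0, grid$nx, grid$ny, grid$dx, params$eps, params$b,
                   params$d_u, params$d_v, cubic_code(params$cubic),
                   Ip, cp, 0, t_end, dt, as.integer(stride), pidx,
                   as.integer(probe_stride), blowup)
  probes_tbl <- NULL
  if (!is.null(ptab)) {
    probes_tbl <- purrr::map_dfr(seq_len(nrow(ptab)), function(q) {
      tibble(probe = q, x = ptab$x[q], y = ptab$y[q],
             time = res$probes$times,
             u = res$probes$u[, q], v = res$probes$v[, q],
             lap_u = res$probes$lap_u[, q])
    })
  }
  structure(list(grid = grid, params = params, times = res$times,
                 u = res$u, v = res$v, I_profile = Ip, c_profile = cp,
                 dt = dt, blown_up = res$blown_up, probes = probes_tbl),
            class = "nhfhn_solution")
}

probe_index <- function(probes, grid) {
  if (grid$dim == 1) {
    x <- as.numeric(probes)
    idx <- vapply(x, function(xx) which.min(abs(grid$x - xx)), integer(1))
    tibble(index = idx, x = grid$x[idx], y = 0)
  } else {
    m <- matrix(as.numeric(probes), ncol = 2)
    i <- vapply(m[, 1], function(xx) which.min(abs(grid$x - xx)), integer(1))
    j <- vapply(m[, 2], function(yy) which.min(abs(grid$y - yy)), integer(1))
    tibble(index = i + grid$nx * (j - 1L), x = grid$x[i], y = grid$y[j])
  }
}

#' @export
print.nhfhn_solution <- function(x, ...) {
  cat(sprintf(paste0("<nhfhn_solution> %dD, %d cells, %d frames on ",
                     "[0, %.4g], dt = %.3g%s\n"),
              x$grid$dim, grid_npts(x$grid), length(x$times),
              max(x$times), x$dt,
              if (x$blown_up) " [BLOWN UP]" else ""))
  invisible(x)
}

#' @export
as_tibble.nhfhn_solution <- function(x, ...) {
  grid <- x$grid
  nt <- length(x$times)
  xs <- if (grid$dim == 1) grid$x else rep(grid$x, grid$ny)
  ys <- if (grid$dim == 1) rep(0, grid$nx) else rep(grid$y, each = grid$nx)
  uu <- as.vector(t(x$u))
  vv <- as.vector(t(x$v))
  tibble(time = rep(x$times, each = length(xs)),
         x = rep(xs, nt), y = rep(ys, nt), u = uu, v = vv)
}

#' Stationary solution of the reaction-diffusion system
#'
#' Solves the stationary problem for `d_u > 0`, `d_v = 0`.  For `b = 0` the
#' solution is explicit: `u = c(x)` exactly and
#' `v = f(c) + I + d_u * Lap(u)` with the discrete Laplacian.  For `b > 0`
#' the elliptic system reduces to
#' \eqn{0 = f(u) - u/b + c(x)/b + I(x) + d_u \Delta u} with
#' \eqn{v = (u - c)/b}, solved by damped Newton on the finite-difference
#' discretization (sparse Jacobian) to residual sup-norm below `tol`.
#'
#' @param params An [nhfhn_params()] record with `d_u > 0`, `d_v = 0`.
#' @param grid An [fhn_grid()].
#' @param u_init Optional starting field for the Newton solve.
#' @param tol Residual sup-norm target.
#' @param max_iter Newton iteration budget.
#' @return An `nhfhn_stationary`: list with fields `u`, `v` (grid-shaped),
#'   `residual`, `iterations`.
#' @export
stationary_solve <- function(params, grid, u_init = NULL, tol = 1e-10,
                             max_iter = 60) {
  if (params$d_v != 0) abort("stationary solver requires d_v = 0")
  if (params$d_u <= 0) abort("stationary solver requires d_u > 0")
  Ip <- resolve_field(params$I_profile, grid, "I_profile")
  cp <- resolve_field(params$c_profile, grid, "c_profile")
  var <- params$cubic$variant
  if (params$b == 0) {
    u <- cp
    v <- cubic_f(cp, var) + Ip +
      params$d_u * laplacian_neumann_cpp(u, grid$nx, grid$ny, grid$dx)
    return(structure(list(u = field_matrix(u, grid),
                          v = field_matrix(v, grid),
                          residual = 0, iterations = 0L, grid = grid,
                          params = params),
                     class = "nhfhn_stationary"))
  }
  b <- params$b
  L <- neumann_laplacian_matrix(grid)
  Fres <- function(u) {
    cubic_f(u, var) - u / b + cp / b + Ip +
      params$d_u * laplacian_neumann_cpp(u, grid$nx, grid$ny, grid$dx)
  }
  starts <- list(u_init, cp, rep(0, grid_npts(grid)))
  starts <- starts[!vapply(starts, is.null, logical(1))]
  for (u0 in starts) {
    u <- resolve_field(u0, grid, "u_init")
    res <- Fres(u)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      if (max(abs(res)) < tol) {
        ok <- TRUE
        break
      }
      J <- Matrix::Diagonal(x = cubic_fprime(u, var) - 1 / b) +
        params$d_u * L
      step <- as.numeric(Matrix::solve(J, -res))
      lambda <- 1
      nrm <- sum(res^2)
      repeat {
        u_new <- u + lambda * step
        res_new <- Fres(u_new)
        if (sum(res_new^2) < (1 - 1e-4 * lambda) * nrm || lambda < 1e-8) {
          break
        }
        lambda <- lambda / 2
      }
      u <- u_new
      res <- res_new
    }
    if (ok || max(abs(res)) < tol) {
      v <- (u - cp) / b
      return(structure(list(u = field_matrix(u, grid),
                            v = field_matrix(v, grid),
                            residual = max(abs(res)), iterations = it,
                            grid = grid, params = params),
                       class = "nhfhn_stationary"))
    }
  }
  abort("stationary Newton solve did not converge from any initial guess")
}

#' @export
print.nhfhn_stationary <- function(x, ...) {
  cat(sprintf("<nhfhn_stationary> residual %.2e after %d Newton iterations\n",
              x$residual, x$iterations))
  invisible(x)
}

#' @export
glance.nhfhn_stationary <- function(x, ...) {
  tibble(residual = x$residual, iterations = x$iterations,
         u_min = min(x$u), u_max = max(x$u))
}

# sparse Neumann Laplacian (ghost reflection), matching laplacian_neumann
neumann_laplacian_matrix <- function(grid) {
  n <- grid$nx
  e <- rep(1, n - 1)
  L1 <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                           diagonals = list(e, c(-1, rep(-2, n - 2), -1), e))
  L1 <- L1 / grid$dx^2
  if (grid$dim == 1) return(L1)
  Id <- Matrix::Diagonal(n)
  Matrix::kronecker(Id, L1) + Matrix::kronecker(L1, Id)
}

#' Local dynamics at a grid location
#'
#' Extracts the time series of `u`, `v` and the discrete Laplacian of `u`
#' at one location -- the local picture of wave propagation, to be read
#' against the local "critical" manifold `v = f(u) + d_u * Lap(u)`.
#' If the location matches a recorded probe its (typically finer) series is
#' used; otherwise the series is assembled from the stored frames.
#'
#' @param sol An `nhfhn_solution`.
#' @param location An `x` position (1D) or `c(x, y)` (2D).
#' @return A tibble with columns `time`, `u`, `v`, `lap_u`.
#' @export
local_dynamics_extract <- function(sol, location) {
  grid <- sol$grid
  pt <- probe_index(if (grid$dim == 1) location[1] else rbind(location), grid)
  if (!is.null(sol$probes)) {
    hit <- dplyr::filter(sol$probes, .data$x == pt$x[1], .data$y == pt$y[1])
    if (nrow(hit) > 0) {
      return(dplyr::select(hit, "time", "u", "v", "lap_u"))
    }
  }
  idx <- pt$index[1]
  lap <- vapply(seq_along(sol$times), function(k) {
    laplacian_neumann_cpp(sol$u[k, ], grid$nx, grid$ny, grid$dx)[idx]
  }, numeric(1))
  tibble(time = sol$times, u = sol$u[, idx], v = sol$v[, idx], lap_u = lap)
}

#' Wave-propagation diagnostics
#'
#' Counts oscillation events per location over a time window and derives
#' the propagation picture: per-location large-oscillation counts and
#' frequency estimates, the *death spot* (smallest `|x|` whose
#' large-oscillation count falls below half the center count; `NA` when
#' propagation is full), and the *filtering ratio* (total oscillation count
#' at the center over the count at the border -- above 1 when the center's
#' small oscillations fail to propagate).  In 2D the diagnostics are taken
#' along the horizontal line through the domain center.
#'
#' @param sol An `nhfhn_solution`.
#' @param amplitude_threshold Peak-to-trough amplitude above which an
#'   oscillation counts as large; default 1 (half the relaxation amplitude
#'   of the steep cubic is about 2).
#' @param t_window Time window `c(from, to)`; defaults to the second half of
#'   the run (discarding the transient).
#' @return A `propagation_diagnostics` list: `by_location` (tibble with
#'   `x`, `n_large`, `n_events`, `frequency`), `center_count`,
#'   `border_count`, `death_spot`, `filtering_ratio`, `window`.
#' @export
propagation_diagnostics <- function(sol, amplitude_threshold = 1,
                                    t_window = NULL) {
  grid <- sol$grid
  tmax <- max(sol$times)
  if (is.null(t_window)) t_window <- c(tmax / 2, tmax)
  sel <- sol$times >= t_window[1] & sol$times <= t_window[2]
  tt <- sol$times[sel]
  if (grid$dim == 1) {
    cols <- seq_len(grid$nx)
    xs <- grid$x
  } else {
    jc <- which.min(abs(grid$y))
    cols <- seq_len(grid$nx) + grid$nx * (jc - 1L)
    xs <- grid$x
  }
  span <- diff(t_window)
  by_loc <- purrr::map_dfr(seq_along(cols), function(q) {
    s <- sol$u[sel, cols[q]]
    if (diff(range(s)) < 1e-12) {
      return(tibble(x = xs[q], n_large = 0L, n_events = 0L, frequency = 0))
    }
    ex <- find_extrema(tt, s, min_prominence = 0.02)
    ev <- classify_pairs(ex)
    tibble(x = xs[q],
           n_large = sum(ev >= amplitude_threshold),
           n_events = length(ev),
           frequency = sum(ev >= amplitude_threshold) / span)
  })
  ic <- which.min(abs(xs))
  ib <- which.max(abs(xs))
  center_count <- by_loc$n_large[ic]
  border_count <- by_loc$n_large[ib]
  fail <- by_loc$n_large < center_count / 2
  death_spot <- if (center_count > 0 && any(fail)) {
    min(abs(by_loc$x[fail]))
  } else if (center_count == 0) {
    # nothing oscillates: propagation dies at the first off-center cell
    abs(xs[order(abs(xs))][2])
  } else {
    NA_real_
  }
  filtering_ratio <- by_loc$n_events[ic] /
    max(by_loc$n_events[ib], 1L)
  structure(list(by_location = by_loc, center_count = center_count,
                 border_count = border_count, death_spot = death_spot,
                 filtering_ratio = filtering_ratio, window = t_window,
                 amplitude_threshold = amplitude_threshold),
            class = "propagation_diagnostics")
}

# peak-to-trough amplitudes of adjacent (min, max) extrema pairs
classify_pairs <- function(extrema) {
  if (nrow(extrema) < 2) return(numeric(0))
  k <- extrema$kind
  i <- which(k[-length(k)] == "min" & k[-1] == "max")
  extrema$value[i + 1] - extrema$value[i]
}

#' @export
print.propagation_diagnostics <- function(x, ...) {
  cat("<propagation_diagnostics>\n")
  cat(sprintf("  window [%.3g, %.3g], amplitude threshold %.3g\n",
              x$window[1], x$window[2], x$amplitude_threshold))
  cat(sprintf("  large-oscillation count: center %d, border %d\n",
              x$center_count, x$border_count))
  cat(sprintf("  death spot: %s, filtering ratio: %.3g\n",
              if (is.na(x$death_spot)) "none" else
                sprintf("|x| = %.4g", x$death_spot),
              x$filtering_ratio))
  invisible(x)
}

#' Write a reaction-diffusion solution to delimited text
#'
#' Writes `times.tsv`, `grid.tsv` and the `u`/`v` fields (one row per
#' recorded frame) as plain tab-separated files into a directory.
#'
#' @param sol An `nhfhn_solution`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_solution <- function(sol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble(time = sol$times), file.path(dir, "times.tsv"))
  g <- sol$grid
  readr::write_tsv(tibble(x = rep(g$x, g$ny),
                          y = rep(if (g$dim == 2) g$y else 0,
                                  each = g$nx)),
                   file.path(dir, "grid.tsv"))
  utils::write.table(sol$u, file.path(dir, "u.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sol$v, file.path(dir, "v.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
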