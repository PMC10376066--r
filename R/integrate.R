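new_trajectory <- function(times, states, names, blown_up = FALSE,
                           params = NULL) {
  states <- as.matrix(states)
  colnames(states) <- names
  out <- tibble(time = as.numeric(times))
  for (nm in names) out[[nm]] <- states[, nm]
  class(out) <- c("fhn_trajectory", class(out))
  attr(out, "blown_up") <- blown_up
  attr(out, "params") <- params
  out
}

#' Has an integration blown up?
#'
#' Fixed-step integrations are truncated when the state leaves the ball
#' `|state| <= blowup` (default `1e8`, far above any bounded orbit of these
#' systems but well below overflow); the returned trajectory then carries a
#' blow-up flag and ends at the last finite sample.
#'
#' @param traj An `fhn_trajectory`.
#' @return Logical scalar.
#' @export
blown_up <- function(traj) isTRUE(attr(traj, "blown_up"))

#' Fixed-step classical Runge-Kutta (RK4) integration
#'
#' Integrates `dy/dt = f(t, y)` with the classical fourth-order Runge-Kutta
#' scheme at a fixed step `dt`; the final step is shortened to land exactly
#' on `t1`.  This is the time discretization used throughout the package
#' (the compiled model integrators in [integrate_model()] take the identical
#' steps).  If the state becomes non-finite or exceeds `blowup` in magnitude
#' the trajectory is truncated and flagged (see [blown_up()]); escape orbits
#' of the fold blow-up system diverge in finite time and rely on this.
#'
#' @param f Function `f(t, y)` returning the derivative vector.
#' @param y0 Initial state (optionally named; names become columns).
#' @param t0,t1 Time interval, `t1 > t0`.
#' @param dt Positive step size.
#' @param blowup Magnitude threshold for blow-up truncation.
#' @param stride Record every `stride`-th step (the endpoint is always kept).
#' @return An `fhn_trajectory`: a tibble with a `time` column and one column
#'   per state component.
#' @examples
#' tr <- rk4_solve(function(t, y) -y, y0 = c(x = 1), t0 = 0, t1 = 1, dt = 1e-3)
#' abs(tr$x[nrow(tr)] - exp(-1)) < 1e-8
#' @export
rk4_solve <- function(f, y0, t0 = 0, t1, dt, blowup = 1e8, stride = 1L) {
  stopifnot(dt > 0, t1 > t0)
  d <- length(y0)
  nms <- names(y0)
  if (is.null(nms)) nms <- paste0("y", seq_len(d))
  y <- unname(as.numeric(y0))
  nsteps <- ceiling((t1 - t0) / dt - 1e-12)
  keep <- seq(0, nsteps, by = stride)
  if (keep[length(keep)] != nsteps) keep <- c(keep, nsteps)
  states <- matrix(NA_real_, length(keep), d)
  times <- numeric(length(keep))
  states[1, ] <- y
  times[1] <- t0
  rec <- 1L
  t <- t0
  blown <- FALSE
  for (s in seq_len(nsteps)) {
    h <- min(dt, t1 - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- if (s == nsteps) t1 else t + h
    if (any(!is.finite(y)) || any(abs(y) > blowup)) {
      blown <- TRUE
      break
    }
    if (s == keep[rec + 1L]) {
      rec <- rec + 1L
      states[rec, ] <- y
      times[rec] <- t
    }
  }
  new_trajectory(times[seq_len(rec)], states[seq_len(rec), , drop = FALSE],
                 nms, blown_up = blown)
}

#' Integrate a model family with the compiled RK4 core
#'
#' Advances one of the built-in vector fields (FitzHugh-Rinzel variant,
#' original bursting model, planar FitzHugh-Nagumo, the fold blow-up system,
#' and the focus-frame systems of the mixed-mode analysis) with the same
#' fixed-step RK4 scheme as [rk4_solve()], in compiled code.
#'
#' @param params A parameter record ([fhr_params()], [fhr_original_params()],
#'   [fhn2d_params()]), or one of the strings `"blowup"` (fold blow-up
#'   system, state `(u, v, w)` with `w` constant), `"moving_focus"` or
#'   `"transformed"` (focus-frame systems; pass the underlying
#'   [fhr_params()] record via `focus_of`).
#' @param y0 Initial state.
#' @param t0,t1 Time interval.
#' @param dt Step size; defaults to [default_dt()] of the parameter record.
#' @param stride Record every `stride`-th step.
#' @param blowup Blow-up truncation threshold.
#' @param focus_of For the focus-frame systems, the [fhr_params()] record
#'   whose planar fixed-point path defines the moving focus.
#' @return An `fhn_trajectory`.
#' @examples
#' p <- fhr_params(I = 1.45)
#' tr <- integrate_model(p, y0 = c(0, 0, 0), t1 = 10)
#' @export
integrate_model <- function(params, y0, t0 = 0, t1, dt = NULL, stride = 1L,
                            blowup = 1e8, focus_of = NULL) {
  if (is.character(params)) {
    kind <- match.arg(params, c("blowup", "moving_focus", "transformed"))
    if (kind == "blowup") {
      mc <- list(code = 4L, pars = 0)
      if (is.null(dt)) dt <- 1e-3
      nms <- c("u", "v", "w")
    } else {
      if (is.null(focus_of) || !inherits(focus_of, "fhr_params")) {
        abort("focus-frame systems need `focus_of = fhr_params(...)`")
      }
      mc <- list(code = if (kind == "moving_focus") 5L else 6L,
                 pars = c(focus_of$I, focus_of$b, focus_of$eps,
                          cubic_code(focus_of$cubic)))
      if (is.null(dt)) dt <- default_dt(focus_of)
      nms <- c("u", "v", "w")
    }
  } else {
    mc <- model_code(params)
    if (is.null(dt)) dt <- default_dt(params)
    nms <- state_names(params)
  }
  if (length(y0) != length(nms)) {
    abort(paste0("y0 must have length ", length(nms)))
  }
  res <- rk4_model_cpp(mc$code, mc$pars, as.numeric(y0), t0, t1, dt,
                       as.integer(stride), blowup)
  new_trajectory(res$times, res$states, nms, blown_up = res$blown_up,
                 params = if (is.character(params)) focus_of else params)
}

#' Local extrema of a sampled series
#'
#' Finds interior strict local extrema, removes low-persistence wiggles, and
#' refines each extremum's time and value with a three-point parabola.
#' Pairs of adjacent extrema whose value difference is below
#' `min_prominence` are discarded (smallest first), which keeps the
#' surviving sequence strictly alternating between maxima and minima.
#'
#' @param t Time vector, or an `fhn_trajectory`.
#' @param x Value vector, or (if `t` is a trajectory) the name of the column
#'   to analyse.
#' @param min_prominence Minimal value swing for an extremum to count;
#'   default `1e-3` times the series range (the mixed-mode small
#'   oscillations are far larger than this floor).
#' @param series Label stored in the `series` column.
#' @return A tibble with columns `time`, `value`, `kind` (`"max"`/`"min"`)
#'   and `series`.
#' @examples
#' tt <- seq(0, 2 * pi, length.out = 2000)
#' find_extrema(tt, sin(tt))
#' @export
find_extrema <- function(t, x = "u", min_prominence = NULL, series = NULL) {
  if (inherits(t, "fhn_trajectory") || is.data.frame(t)) {
    stopifnot(is.character(x), x %in% names(t))
    if (is.null(series)) series <- x
    xx <- t[[x]]
    tt <- t$time
  } else {
    tt <- t
    xx <- x
    if (is.null(series)) series <- "x"
  }
  stopifnot(length(tt) == length(xx), length(tt) >= 3)
  rng <- diff(range(xx))
  if (is.null(min_prominence)) min_prominence <- 1e-3 * rng
  empty <- tibble(time = numeric(), value = numeric(), kind = character(),
                  series = character())
  if (rng == 0) return(empty)

  n <- length(xx)
  i <- 2:(n - 1)
  is_max <- xx[i] > xx[i - 1] & xx[i] > xx[i + 1]
  is_min <- xx[i] < xx[i - 1] & xx[i] < xx[i + 1]
  idx <- i[is_max | is_min]
  if (length(idx) == 0) return(empty)
  kind <- ifelse(is_max[match(idx, i)], "max", "min")

  # enforce alternation: keep the most extreme of any same-kind run
  keep <- rep(TRUE, length(idx))
  j <- 1L
  while (j < length(idx)) {
    k <- j + 1L
    while (k <= length(idx) && (!keep[k] || kind[k] == kind[j])) {
      if (keep[k] && kind[k] == kind[j]) {
        better_k <- if (kind[j] == "max") xx[idx[k]] > xx[idx[j]]
                    else xx[idx[k]] < xx[idx[j]]
        if (better_k) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
      }
      k <- k + 1L
    }
    j <- k
  }
  idx <- idx[keep]; kind <- kind[keep]

  # persistence pruning: drop the smallest adjacent swing below threshold
  val <- xx[idx]
  while (length(idx) >= 2) {
    amp <- abs(diff(val))
    m <- which.min(amp)
    if (amp[m] >= min_prominence) break
    drop <- c(m, m + 1L)
    idx <- idx[-drop]; val <- val[-drop]; kind <- kind[-drop]
  }
  if (length(idx) == 0) return(empty)

  # three-point parabolic refinement on the original samples
  ref <- vapply(seq_along(idx), function(q) {
    i0 <- idx[q]
    y0 <- xx[i0 - 1]; y1 <- xx[i0]; y2 <- xx[i0 + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom == 0) return(c(tt[i0], y1))
    delta <- 0.5 * (y0 - y2) / denom
    delta <- max(min(delta, 1), -1)
    h1 <- tt[i0] - tt[i0 - 1]
    tv <- tt[i0] + delta * h1
    vv <- y1 - 0.25 * (y0 - y2) * delta
    c(tv, vv)
  }, numeric(2))
  tibble(time = ref[1, ], value = ref[2, ], kind = kind, series = series)
}

#' Interpolated crossings of a coordinate level
#'
#' Scans a trajectory for crossings of `component = level` and returns the
#' linearly interpolated crossing times and states, optionally filtered by
#' crossing direction.  Times are sorted and strictly inside the integration
#' window.
#'
#' @param traj An `fhn_trajectory` (or data frame with a `time` column).
#' @param component Column name or index (among the state columns).
#' @param level Crossing level.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return A tibble with `time` plus the interpolated state columns.
#' @export
section_crossings <- function(traj, component = "u", level = 0,
                              direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  cols <- setdiff(names(traj), "time")
  if (is.numeric(component)) component <- cols[component]
  g <- traj[[component]] - level
  n <- length(g)
  i <- which(g[-n] * g[-1] <= 0 & g[-n] != g[-1])
  i <- i[g[i] != 0]                   # avoid double-counting exact hits
  if (direction == "up") i <- i[g[i + 1] > g[i]]
  if (direction == "down") i <- i[g[i + 1] < g[i]]
  if (length(i) == 0) {
    out <- tibble(time = numeric())
    for (nm in cols) out[[nm]] <- numeric()
    return(out)
  }
  frac <- g[i] / (g[i] - g[i + 1])
  out <- tibble(time = traj$time[i] + frac * (traj$time[i + 1] - traj$time[i]))
  for (nm in cols) {
    out[[nm]] <- traj[[nm]][i] + frac * (traj[[nm]][i + 1] - traj[[nm]][i])
  }
  out[[component]] <- level
  dplyr::arrange(out, .data$time)
}

#' Write a trajectory to delimited text
#'
#' @param traj An `fhn_trajectory`.
#' @param path Output file (tab-separated, columns `time` then the states).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(as_tibble(traj), path)
  invisible(path)
}
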