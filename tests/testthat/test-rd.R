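test_that("Neumann Laplacian has the stencil and no-flux properties", {
  g <- fhn_grid(21, 10, dim = 1)
  expect_equal(laplacian_neumann(rep(3, 21), g), rep(0, 21))
  lp <- laplacian_neumann(g$x^2, g)
  expect_equal(lp[3:19], rep(2, 17), tolerance = 1e-10)
  # reflection at the boundary: one-sided difference of x^2
  expect_equal(lp[1], (g$x[2]^2 - g$x[1]^2) / g$dx^2)
  # 2D separable field
  g2 <- fhn_grid(15, 5, dim = 2)
  f2 <- outer(g2$x^2, g2$y^2, `+`)
  lp2 <- laplacian_neumann(f2, g2)
  expect_equal(lp2[3:13, 3:13], matrix(4, 11, 11), tolerance = 1e-10)
  # the pure-diffusion sub-operator conserves the discrete mean
  withr::with_seed(14, {
    f <- stats::runif(21)
    expect_lt(abs(sum(laplacian_neumann(f, g))), 1e-10)
    f2 <- matrix(stats::runif(225), 15, 15)
    expect_lt(abs(sum(laplacian_neumann(f2, g2))), 1e-9)
  })
  # the sparse matrix used by the stationary solver matches the stencil
  L <- fhnflow:::neumann_laplacian_matrix(g2)
  expect_equal(as.numeric(L %*% as.vector(f2)),
               as.vector(laplacian_neumann(f2, g2)), tolerance = 1e-12)
})

test_that("excitability profiles take the printed values", {
  g2 <- fhn_grid(64, 50, dim = 2)
  cp <- c_profile_ball(g2, radius = 8)
  ic <- which.min(abs(g2$x))
  expect_equal(cp[ic, ic], 0)          # center: oscillatory
  expect_equal(cp[1, 1], -1.21)        # corner: excitable
  # covered area matches the ball area to within one cell ring
  frac <- mean(cp == 0)
  area_frac <- pi * 8^2 / 100^2
  ring <- 2 * pi * 8 * g2$dx / 100^2
  expect_lt(abs(frac - area_frac), ring + 1e-3)

  g1 <- fhn_grid(101, 50, dim = 1)
  cq <- c_profile_quartic(g1, p = 1.5)
  expect_equal(cq[51], 0)                       # center of an odd grid
  s <- g1$x / 50
  expect_equal(cq, 1.5 * s^4 - 3 * s^2)
  # borders approach -p; monotone decreasing in |x|
  right <- cq[g1$x >= 0]
  expect_true(all(diff(right) < 0))
  expect_equal(1.5 * 1^4 - 2 * 1.5 * 1^2, -1.5)  # value at x = beta
})

test_that("homogeneous medium reduces to the pointwise ODE", {
  g <- fhn_grid(21, 10, dim = 1)
  pars <- nhfhn_params(eps = 0.1, b = 0.8, d_u = 1, d_v = 0.5,
                       cubic = "soft", I_profile = 0.5, c_profile = 0.2)
  sol <- simulate_nhfhn(pars, g, t_end = 5, ic = list(u = 0.3, v = 0.1),
                        dt = 1e-3, stride = 500L)
  ode <- rk4_solve(function(t, y) {
    c((cubic_eval(y[1], "soft")$f - y[2] + 0.5) / 0.1,
      y[1] - 0.8 * y[2] - 0.2)
  }, c(u = 0.3, v = 0.1), 0, 5, 1e-3, stride = 500L)
  for (k in seq_along(sol$times)) {
    expect_lt(max(abs(sol$u[k, ] - ode$u[k])), 1e-6)
    expect_lt(max(abs(sol$v[k, ] - ode$v[k])), 1e-6)
  }
})

test_that("spatial refinement converges at second order", {
  # smooth sub-threshold bump relaxing in an excitable medium, identical
  # time step on all grids so the spatial error dominates
  run_at <- function(n) {
    g <- fhn_grid(n, 10, dim = 1)
    pars <- nhfhn_params(eps = 0.1, b = 0, d_u = 1, d_v = 0,
                         cubic = "steep", c_profile = -1.21)
    ic <- list(u = -1.21 + 0.3 * exp(-g$x^2 / 4),
               v = cubic_eval(-1.21, "steep")$f)
    sol <- simulate_nhfhn(pars, g, t_end = 1, ic = ic, dt = 1e-4,
                          stride = 10000L)
    list(x = g$x, u = sol$u[nrow(sol$u), ])
  }
  a <- run_at(51)
  b <- run_at(101)
  c_ <- run_at(201)
  e1 <- max(abs(stats::approx(b$x, b$u, a$x, rule = 2)$y - a$u))
  e2 <- max(abs(stats::approx(c_$x, c_$u, b$x, rule = 2)$y - b$u))
  expect_lt(e2, e1 / 2.5)  # halving dx cuts the change by about 4
})

test_that("time step bound is enforced with a proposal", {
  g <- fhn_grid(51, 10, dim = 1)
  pars <- nhfhn_params(eps = 0.1, b = 0, d_u = 1, d_v = 0, c_profile = -1.5)
  expect_error(simulate_nhfhn(pars, g, t_end = 1, dt = 0.01),
               "use dt <=")
})

test_that("b = 0 stationary formula is exact and dynamically invariant", {
  g <- fhn_grid(81, 5, dim = 1)
  cp <- c_profile_quartic(g, p = 40)
  pars <- nhfhn_params(eps = 0.1, b = 0, d_u = 1, d_v = 0, cubic = "steep",
                       c_profile = cp)
  st <- stationary_solve(pars, g)
  expect_identical(as.numeric(st$u), as.numeric(cp))   # u = c bit-for-bit
  expect_equal(as.numeric(st$v),
               cubic_eval(cp, "steep")$f + 1 * laplacian_neumann(cp, g))
  # injected as an initial condition, the stationary state stays put
  sol <- simulate_nhfhn(pars, g, t_end = 2, ic = list(u = st$u, v = st$v))
  expect_lt(max(abs(sol$u[nrow(sol$u), ] - st$u)), 1e-6)
  expect_lt(max(abs(sol$v[nrow(sol$v), ] - st$v)), 1e-6)
})

test_that("b > 0 stationary Newton solve is grid-consistent and unique", {
  g <- fhn_grid(101, 50, dim = 1)
  pars <- nhfhn_params(eps = 0.1, b = 0.3, d_u = 1, d_v = 0,
                       cubic = "steep", c_profile = c_profile_quartic(g, 1.5))
  s1 <- stationary_solve(pars, g, u_init = rep(2, 101))
  s2 <- stationary_solve(pars, g, u_init = rep(-2, 101))
  expect_lt(s1$residual, 1e-10)
  expect_lt(max(abs(s1$u - s2$u)), 1e-8)
  expect_equal(as.numeric(s1$v),
               (as.numeric(s1$u) - c_profile_quartic(g, 1.5)) / 0.3)
  # homogeneous profile: the constant planar fixed point
  ph <- nhfhn_params(eps = 0.1, b = 0.8, d_u = 1, d_v = 0, cubic = "soft",
                     I_profile = 0.7, c_profile = 0)
  sh <- stationary_solve(ph, g)
  fp <- fixed_point_2d(fhn2d_params(I = 0.7, b = 0.8, eps = 0.1))
  expect_equal(as.numeric(sh$u), rep(fp$u_star, 101), tolerance = 1e-9)
})

test_that("local dynamics extraction exposes the diffusive jump signature", {
  g <- fhn_grid(81, 5, dim = 1)
  pars <- nhfhn_params(eps = 0.1, b = 0, d_u = 1, d_v = 0, cubic = "steep",
                       c_profile = c_profile_quartic(g, 1.2))
  sol <- simulate_nhfhn(pars, g, t_end = 60, probes = c(0, 2.5),
                        probe_stride = 10L)
  loc <- local_dynamics_extract(sol, 2.5)
  expect_named(loc, c("time", "u", "v", "lap_u"))
  keep <- loc$time > 30
  # near the border the Laplacian is quiet except around jump events
  lap <- loc$lap_u[keep]
  expect_gt(max(lap), 1)      # positive pull before the up-jump
  expect_lt(min(lap), -1)     # negative push after it
  expect_gt(mean(abs(lap) < 0.3), 0.5)  # mostly near zero in between
  # homogeneous run: identically zero Laplacian
  ph <- nhfhn_params(eps = 0.1, b = 0.8, d_u = 1, d_v = 0, cubic = "soft",
                     I_profile = 0.5, c_profile = 0)
  gh <- fhn_grid(21, 10, dim = 1)
  sh <- simulate_nhfhn(ph, gh, t_end = 3, ic = list(u = 0.3, v = 0.1))
  lh <- local_dynamics_extract(sh, 0)
  expect_equal(lh$lap_u, rep(0, length(lh$lap_u)))
})

test_that("propagation diagnostics separate the three wave regimes", {
  g <- fhn_grid(81, 5, dim = 1)
  run_p <- function(p) {
    pars <- nhfhn_params(eps = 0.1, b = 0, d_u = 1, d_v = 0,
                         cubic = "steep", c_profile = c_profile_quartic(g, p))
    propagation_diagnostics(simulate_nhfhn(pars, g, t_end = 120))
  }
  full <- run_p(1.0)
  expect_true(is.na(full$death_spot))
  expect_equal(full$center_count, full$border_count)
  expect_gt(full$center_count, 5)

  spot <- run_p(5.0)
  expect_false(is.na(spot$death_spot))
  expect_gt(spot$center_count, 5)
  expect_equal(spot$border_count, 0)

  dead <- run_p(40)
  expect_equal(dead$center_count, 0)
  expect_equal(sum(dead$by_location$n_large), 0)
  # death spot at the first off-center cell when nothing oscillates
  expect_equal(dead$death_spot, sort(abs(g$x))[2])
})
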