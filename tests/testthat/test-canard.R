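test_that("singular subsystems have the stated structure", {
  p <- fhr_params(I = 0.3, b = 0.8, c = 0, eps = 0.1)
  # layer system: every point of the critical manifold is an equilibrium
  u <- 0.4
  v_on <- cubic_eval(u, "soft")$f + 0.2 + p$I
  lay <- subsystem_rhs("layer", c(u, v_on, 0.2), p)
  expect_equal(unname(lay$derivatives), c(0, 0, 0))
  # off the manifold, the fast flow heads toward an attracting branch
  y <- c(2.5, v_on, 0.2)
  f <- function(t, s) {
    c(subsystem_rhs("layer", s, p)$derivatives[1], 0, 0)
  }
  tr <- rk4_solve(f, c(u = 2.5, v = v_on, w = 0.2), 0, 30, 1e-3,
                  stride = 1000L)
  u_end <- tr$u[nrow(tr)]
  expect_lt(cubic_eval(u_end, "soft")$fprime, 0)  # attracting branch
  expect_lt(abs(cubic_eval(u_end, "soft")$f + 0.2 + p$I - v_on), 1e-6)
  # superslow flow drives w by -(w + u)
  ss <- subsystem_rhs("superslow", c(0.4, 0.5, 0.2), p)
  expect_equal(unname(ss$derivatives["w"]), -(0.2 + 0.4))
  # the reduced system is singular at folds
  v_fold <- cubic_eval(1, "soft")$f + 0.2 + p$I
  expect_error(subsystem_rhs("reduced", c(1, v_fold, 0.2), p), "fold")
})

test_that("fold frame shifts and unfolding parameter are exact", {
  ff <- fold_frame(fhr_params(I = 0, b = 1, cubic = "steep"))
  expect_equal(ff$v_tilde, 1)
  expect_equal(ff$w_tilde, -1)
  expect_equal(ff$mu, 0)
  withr::with_seed(3, {
    for (k in 1:20) {
      b <- stats::runif(1, 0.2, 2)
      I <- stats::runif(1, -1, 2)
      ff <- fold_frame(fhr_params(I = I, b = b, cubic = "steep"))
      expect_equal(ff$mu, -1 + 1 / b - I, tolerance = 1e-12)
      expect_equal(ff$mu, 1 + ff$w_tilde, tolerance = 1e-12)
    }
  })
  # expansion about the fold: f(1 + u) - f(1) = -3u^2 - u^3 (steep cubic)
  u <- seq(-0.5, 0.5, by = 0.05)
  expect_equal(cubic_eval(1 + u, "steep")$f - 2, -3 * u^2 - u^3,
               tolerance = 1e-12)
  expect_error(fold_frame(fhr_params(I = 0, b = 1, cubic = "soft")), "steep")
})

test_that("the fold rescaling limits onto the blow-up system", {
  # consistent fold blow-up: u = sqrt(eps) ub, v = eps vb, w = eps wb,
  # tau = t / sqrt(eps).  In these variables the shifted system's vector
  # field converges to the blow-up field with an O(sqrt(eps)) correction.
  shifted_rhs <- function(s, eps, b, mu) {
    c((-3 * s[1]^2 - s[1]^3 - s[2] + s[3]) / eps,
      s[1] - b * s[2],
      -eps * (mu + s[1] + s[3]))
  }
  withr::with_seed(9, {
    pts <- matrix(stats::runif(30, -1, 1), ncol = 3)
    errs <- vapply(c(1e-2, 1e-4), function(eps) {
      max(apply(pts, 1, function(yb) {
        x <- c(sqrt(eps) * yb[1], eps * yb[2], eps * yb[3])
        dx <- shifted_rhs(x, eps, b = 0.8, mu = 0.1)
        d_scaled <- c(dx[1], dx[2] / sqrt(eps), dx[3] / sqrt(eps))
        max(abs(d_scaled - unname(blowup_rhs(yb))))
      }))
    }, numeric(1))
    # discrepancy shrinks like sqrt(eps): factor ~10 from 1e-2 to 1e-4
    expect_lt(errs[2], errs[1] / 5)
    expect_lt(errs[2], 0.05)
  })
})

test_that("G is a first integral with the stated special values", {
  expect_equal(first_integral_G(0, 0, 0), 1 / 6)
  # zero on the parabola v = 1/6 - 3u^2
  u <- seq(-2, 2, by = 0.1)
  expect_equal(first_integral_G(u, 1 / 6 - 3 * u^2), rep(0, length(u)))
  # shift property in w
  expect_equal(first_integral_G(0.3, 0.7, 0.5),
               first_integral_G(0.3, 0.2, 0))
  # conservation along the flow at dt = 1e-4 over one period
  tr <- integrate_model("blowup", y0 = c(0, 0.12, 0), t1 = 7, dt = 1e-4,
                        stride = 10L)
  G <- first_integral_G(tr$u, tr$v, tr$w)
  expect_lt(max(abs(G - G[1])) / abs(G[1]), 1e-6)
})

test_that("orbit classification separates center, periodic and escape", {
  expect_equal(classify_orbit(0, 0), "fixed_point")
  expect_equal(classify_orbit(0.1, 0), "periodic")
  expect_equal(classify_orbit(0.2, 0), "escape")
  expect_equal(classify_orbit(0.1, 0, method = "integrate"), "periodic")
  expect_equal(classify_orbit(0.2, 0, method = "integrate"), "escape")
  # escape orbits leave through the third quadrant
  tr <- integrate_model("blowup", y0 = c(0, 0.2, 0), t1 = 100, dt = 1e-3)
  expect_true(blown_up(tr))
  expect_lt(tr$u[nrow(tr)], 0)
  expect_lt(tr$v[nrow(tr)], 0)
})

test_that("analytic and integration classifiers agree off the threshold", {
  withr::with_seed(31, {
    w <- stats::runif(50, -0.5, 0.5)
    s <- stats::runif(50, 0.02, 0.30)
    s <- ifelse(abs(s - 1 / 6) < 1e-3, s + 5e-3, s)  # stay off the border
    for (k in 1:50) {
      cc <- w[k] + s[k]
      expect_equal(classify_orbit(cc, w[k], method = "analytic"),
                   classify_orbit(cc, w[k], method = "integrate",
                                  dt = 1e-3, t_max = 300))
    }
  })
})

test_that("escape threshold bisection recovers w + 1/6", {
  th <- escape_threshold(w = 0, tol = 1e-5)
  expect_lt(abs(th$c_star - 1 / 6), 1e-4)
  th <- escape_threshold(w = 0.5, tol = 1e-5)
  expect_lt(abs(th$c_star - (0.5 + 1 / 6)), 1e-4)
})

test_that("periodic orbit diameter grows toward the separatrix", {
  cs <- seq(0.05, 0.16, by = 0.01)
  diam <- vapply(cs, function(cc) {
    tr <- integrate_model("blowup", y0 = c(0, cc, 0), t1 = 60, dt = 1e-3,
                          stride = 10L)
    diff(range(tr$v))
  }, numeric(1))
  expect_true(all(diff(diam) > 0))
})
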