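test_that("three-variable fixed point solves the scalar reduction", {
  expect_equal(fixed_point_3d(fhr_params(I = 0))$u_star, 0, tolerance = 1e-12)
  fp <- fixed_point_3d(p_mmo(1.45))
  # unique root of u^3/3 + 1.25 u - 1.45 = 0 (independent polynomial oracle)
  oracle <- Re(polyroot(c(-1.45, 1.25, 0, 1 / 3)))
  oracle <- oracle[abs(Im(polyroot(c(-1.45, 1.25, 0, 1 / 3)))) < 1e-9]
  expect_equal(fp$u_star, oracle, tolerance = 1e-10)
  expect_equal(fp$u_star, 0.939127, tolerance = 1e-6)
  expect_equal(fp$v_star, fp$u_star / 0.8)
  expect_equal(fp$w_star, -fp$u_star)
  expect_lt(fp$residual, 1e-12)
  # monotone in the drive
  expect_gt(fixed_point_3d(p_mmo(1.5))$u_star,
            fixed_point_3d(p_mmo(1.3))$u_star)
  expect_error(fixed_point_3d(fhr_params(I = 1, b = 0)), "b > 0")
})

test_that("planar fixed point is increasing in I with the Hopf identity", {
  us <- vapply(seq(0.1, 2, by = 0.1),
               function(I) fixed_point_2d(fhn2d_params(I = I))$u_star,
               numeric(1))
  expect_true(all(diff(us) > 0))
  expect_equal(fixed_point_2d(fhn2d_params(I = 0))$u_star, 0,
               tolerance = 1e-12)
  # at u* = sqrt(1 - b eps), f'(u*) = b eps exactly
  ustar <- fhn2d_hopf_ustar(b = 0.8, eps = 0.1)
  expect_equal(cubic_eval(ustar, "soft")$fprime, 0.8 * 0.1)
})

test_that("Jacobian has the stated structure", {
  p <- p_mmo()
  J <- jacobian3(0, p)
  expect_equal(J, matrix(c(10, -10, 10, 1, -0.8, 0, -0.1, 0, -0.1),
                         nrow = 3, byrow = TRUE))
  withr::with_seed(11, {
    for (k in 1:10) {
      u <- stats::runif(1, -2, 2)
      J <- jacobian3(u, p)
      expect_equal(sum(diag(J)), (1 - u^2) / 0.1 - 0.8 - 0.1)
      # determinant consistent with the constant coefficient a0
      expect_equal(det(J), -(0.8 * u^2 + 1), tolerance = 1e-10)
    }
  })
})

test_that("characteristic coefficients match the numeric polynomial", {
  withr::with_seed(23, {
    for (k in 1:100) {
      p <- fhr_params(I = stats::runif(1, -1, 3),
                      b = stats::runif(1, 0.2, 1.5),
                      c = 0, eps = stats::runif(1, 0.02, 0.5))
      u <- stats::runif(1, -2, 2)
      co <- char_coeffs(u, p)
      ev <- eigen(jacobian3(u, p), only.values = TRUE)$values
      # coefficients from the eigenvalues (numeric poly oracle)
      expect_equal(unname(co["a2"]), -Re(sum(ev)), tolerance = 1e-8)
      expect_equal(unname(co["a1"]),
                   Re(ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]),
                   tolerance = 1e-8)
      expect_equal(unname(co["a0"]), -Re(prod(ev)), tolerance = 1e-8)
      # eigenvalues satisfy the monic cubic
      resid <- ev^3 + co["a2"] * ev^2 + co["a1"] * ev + co["a0"]
      expect_lt(max(Mod(resid)), 1e-8)
    }
  })
  expect_equal(unname(char_coeffs(0, p_mmo())["a0"]), 1)
  # a2 vanishes exactly when f'(u) = eps (eps + b)
  p <- p_mmo()
  u0 <- sqrt(1 - p$eps * (p$eps + p$b))
  expect_equal(unname(char_coeffs(u0, p)["a2"]), 0, tolerance = 1e-12)
})

test_that("cubic discriminant separates real triples from complex pairs", {
  expect_gt(cardan_delta(0, -1, 0), 0)  # roots -1, 0, 1
  expect_lt(cardan_delta(0, 1, 0), 0)   # roots 0, +/- i
  # along the analysis interval the spectrum keeps its complex pair
  for (I in seq(1, 2, by = 0.05)) {
    s <- spectral_summary(p_mmo(I))
    expect_lt(s$cardan_delta, 0)
    expect_true(s$has_complex_pair)
  }
})

test_that("eigenvalue signatures match the unstable-pair regime", {
  for (I in c(1.45, 1.3)) {
    s <- eig_signature(p_mmo(I))
    expect_equal(s$n_unstable, 2)
    expect_equal(s$n_stable, 1)
    expect_true(s$has_complex_pair)
    # the stable eigenvalue is the real one
    real_ev <- s$eigenvalues[abs(Im(s$eigenvalues)) < 1e-9]
    expect_length(real_ev, 1)
    expect_lt(Re(real_ev), 0)
  }
  expect_equal(eig_signature(p_mmo(2.5))$n_unstable, 0)
})

test_that("Routh-Hurwitz verdict agrees with the eigenvalue verdict", {
  for (I in seq(0.6, 2.4, by = 0.1)) {
    s <- spectral_summary(p_mmo(I))
    eig_stable <- all(Re(s$eigenvalues) < -1e-9)
    expect_equal(s$stable, eig_stable)
  }
})

test_that("Hopf bisection lands inside the proposition's bounds", {
  fit <- hopf_locate(p_mmo(1))
  expect_gte(fit$I_star, 1)
  expect_lte(fit$I_star, 2)
  # frozen value from an independent dense-grid eigenvalue scan
  expect_equal(fit$I_star, 1.5006917, tolerance = 1e-6)
  expect_error(hopf_locate(p_mmo(1), I_bracket = c(2.2, 2.5)), "sign")
})

test_that("linearized verdicts match simulated behavior near the Hopf", {
  fit <- hopf_locate(p_mmo(1))
  dist0 <- function(I, t1 = 30) {
    p <- p_mmo(I)
    fp <- fixed_point_3d(p)
    y0 <- c(fp$u_star + 1e-3, fp$v_star, fp$w_star)
    tr <- integrate_model(p, y0 = y0, t1 = t1, dt = 1e-3, stride = 100L)
    tail_states <- tr[tr$time > t1 / 2, ]
    max(sqrt((tail_states$u - fp$u_star)^2 + (tail_states$v - fp$v_star)^2 +
               (tail_states$w - fp$w_star)^2))
  }
  expect_lt(dist0(fit$I_star + 0.05), 1e-3)  # above I*: decays
  expect_gt(dist0(fit$I_star - 0.05), 1e-2)  # below I*: departs
})

test_that("stability sweep tabulates the transition", {
  sw <- stability_sweep(p_mmo(1), c(1.2, 1.8))
  expect_equal(nrow(sw), 2)
  expect_lt(sw$hurwitz_margin[1], 0)
  expect_gt(sw$hurwitz_margin[2], 0)
  expect_equal(sw$stable, c(FALSE, TRUE))
})
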