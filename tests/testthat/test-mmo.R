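make_extrema <- function(amps) {
  # alternating min/max events realizing the requested pair amplitudes
  n <- length(amps)
  tibble::tibble(time = seq_len(2 * n),
                 value = as.vector(rbind(-amps / 2, amps / 2)),
                 kind = rep(c("min", "max"), n),
                 series = "x")
}

test_that("oscillation labels follow the amplitude bands", {
  sq <- classify_oscillations(make_extrema(c(1, 1, 0.1)),
                              theta_sm = 0.3, theta_ml = 0.7)
  expect_equal(paste(sq$label, collapse = ""), "LLS")
  expect_equal(sq$amplitude, c(1, 1, 0.1))
  # all equal amplitudes are all large
  sq <- classify_oscillations(make_extrema(rep(2, 4)))
  expect_equal(unique(sq$label), "L")
  # scale invariance
  a <- classify_oscillations(make_extrema(c(1, 0.5, 0.05)))
  b <- classify_oscillations(make_extrema(c(1, 0.5, 0.05) * 137))
  expect_equal(a$label, b$label)
  # degenerate input
  expect_equal(nrow(classify_oscillations(make_extrema(numeric(0)))), 0)
})

test_that("motif compression finds repeated units", {
  expect_equal(motif_compress("LLSLLSLLSLLSLM"), "LLS×4 LM")
  expect_equal(motif_compress("LLLL"), "L×4")
  expect_equal(motif_compress("SML"), "SML×1")
  expect_equal(motif_compress(""), "")
})

test_that("the canard regime produces LLS motifs with medium events", {
  p <- p_mmo(1.3)
  tr <- integrate_model(p, y0 = c(0.5, 0.5, -0.5), t1 = 400, dt = 1e-3,
                        stride = 20L)
  keep <- tr$time >= 150
  sq <- classify_oscillations(find_extrema(tr$time[keep], tr$u[keep]))
  labels <- motif_string(sq)
  expect_true(grepl("LLS", labels))
  expect_true(grepl("M", labels))
  expect_true(grepl("S", labels))
})

test_that("focus MMO regime alternates many small with one large", {
  tr <- integrate_model(p_mmo(1.45), y0 = c(0.5, 0.5, -0.5), t1 = 400,
                        dt = 1e-3, stride = 20L)
  keep <- tr$time >= 150
  sq <- classify_oscillations(find_extrema(tr$time[keep], tr$u[keep]))
  expect_gt(sum(sq$label == "S"), 3 * sum(sq$label == "L"))
  expect_gt(sum(sq$label == "L"), 3)
})

test_that("the focus frame reproduces the original flow exactly", {
  p <- p_mmo(1.45)
  # at the focus the planar components reduce to the moving-frame
  # corrections (the focus itself drifts with w)
  us <- u_star_planar(-0.8, p)
  k <- 1 / (cubic_eval(us, "soft")$fprime - 1 / p$b)
  s <- us - 0.8
  d0 <- transformed_rhs(c(0, 0, -0.8), p)
  expect_equal(unname(d0[1]), -p$eps * k * s, tolerance = 1e-10)
  expect_equal(unname(d0[2]), -p$eps * k * s / p$b, tolerance = 1e-10)
  y0 <- c(1.2, 1.2, -0.8)
  us0 <- u_star_planar(y0[3], p)
  full <- integrate_model(p, y0 = y0, t1 = 5, dt = 1e-4, stride = 10L)
  tf <- integrate_model("transformed",
                        y0 = c(y0[1] - us0, y0[2] - us0 / p$b, y0[3]),
                        t1 = 5, dt = 1e-4, stride = 10L, focus_of = p)
  us <- u_star_planar(tf$w, p)
  err <- max(abs(tf$u + us - full$u), abs(tf$v + us / p$b - full$v),
             abs(tf$w - full$w))
  expect_lt(err, 1e-10)
})

test_that("moving-focus approximation tracks the full system initially", {
  p <- p_mmo(1.45)
  w0 <- -0.80
  a0 <- 0.25
  us0 <- u_star_planar(w0, p)
  approx <- integrate_model("moving_focus", y0 = c(a0, 0, w0), t1 = 40,
                            dt = 1e-3, stride = 10L, focus_of = p)
  full <- integrate_model(p, y0 = c(us0 + a0, us0 / p$b, w0), t1 = 40,
                          dt = 1e-3, stride = 10L)
  # compare the voltage traces (approximation mapped back to absolute
  # coordinates), relative to the voltage scale
  u_back <- approx$u + u_star_planar(approx$w, p)
  dev <- abs(u_back - full$u) / max(abs(full$u))
  arc <- approx$time <= 2
  expect_lt(max(dev[arc]), 0.10)   # very close at the beginning ...
  expect_gt(max(dev), 3 * max(dev[arc]))  # ... then the two separate
})

test_that("focus linearization matches a generic eigenvalue routine", {
  p <- p_mmo(1.45)
  withr::with_seed(5, {
    us <- stats::runif(50, -1.5, 1.5)
    ab <- focus_alpha_beta(us, p)
    for (k in seq_along(us)) {
      ev <- eigen(focus_matrix(us[k], p), only.values = TRUE)$values
      if (ab$complex[k]) {
        expect_equal(ab$alpha[k], Re(ev[1]), tolerance = 1e-10)
        expect_equal(ab$beta[k], abs(Im(ev[1])), tolerance = 1e-10)
      } else {
        expect_equal(ab$beta[k], 0)
        expect_true(all(abs(Im(ev)) < 1e-9))
      }
    }
  })
  # trace vanishes exactly where f'(u*) = eps b
  u0 <- sqrt(1 - p$eps * p$b)
  A <- focus_matrix(u0, p)
  expect_equal(sum(diag(A)), 0, tolerance = 1e-12)
})

test_that("rotation-count quadrature has closed form and converges", {
  p <- p_mmo(1.45)
  # constant u_star in the complex regime: n_o = beta0 T / (2 pi)
  us0 <- 0.9
  beta0 <- focus_alpha_beta(us0, p)$beta
  expect_gt(beta0, 0)
  n <- count_small_oscillations(function(t) us0, T = 10, params = p)
  expect_equal(n, beta0 * 10 / (2 * pi), tolerance = 1e-10)
  expect_equal(count_small_oscillations(function(t) us0, T = 0, params = p),
               0)
  # doubling the quadrature resolution barely moves the estimate
  path <- function(t) 0.9 + 0.01 * t
  n1 <- count_small_oscillations(path, T = 10, params = p, n = 4097)
  n2 <- count_small_oscillations(path, T = 10, params = p, n = 8193)
  expect_lt(abs(n1 - n2), 1e-6)
})

test_that("rotation count matches direct extrema count on a passage", {
  p <- p_mmo(1.45)
  tr <- integrate_model("moving_focus", y0 = c(0.05, 0, -0.80), t1 = 60,
                        dt = 1e-3, stride = 10L, focus_of = p)
  iend <- which(abs(tr$u) > 0.5)[1]
  passage <- tr[seq_len(iend), ]
  n_formula <- count_small_oscillations(passage, params = p, path_is = "w")
  n_direct <- sum(find_extrema(passage$time, passage$u,
                               min_prominence = 1e-6)$kind == "max")
  expect_lte(abs(n_formula - n_direct), 1)
})

test_that("growth-rate sign partitions the passage as shrink-then-grow", {
  p <- p_mmo(1.45)
  # constant paths on either side of the dynamic Hopf point
  us_stable <- sqrt(1 - p$eps * p$b) + 0.05   # 1 - u*^2 < eps b
  us_unstable <- sqrt(1 - p$eps * p$b) - 0.05
  prof <- alpha_sign_profile(function(t) us_stable, T = 1, params = p)
  expect_equal(prof$sign, -1)
  prof <- alpha_sign_profile(function(t) us_unstable, T = 1, params = p)
  expect_equal(prof$sign, 1)
  # along a focus passage the amplitudes shrink, then grow
  tr <- integrate_model("moving_focus", y0 = c(0.05, 0, -0.80), t1 = 50,
                        dt = 1e-3, stride = 10L, focus_of = p)
  iend <- which(abs(tr$u) > 0.5)[1]
  passage <- tr[seq_len(iend), ]
  prof <- alpha_sign_profile(passage, params = p, path_is = "w")
  expect_equal(prof$sign, c(-1, 1))
  ex <- find_extrema(passage$time, passage$u, min_prominence = 1e-6)
  peaks <- ex[ex$kind == "max", ]
  tswitch <- prof$end[1]
  early <- peaks$value[peaks$time < tswitch]
  late <- peaks$value[peaks$time > tswitch]
  expect_true(all(diff(early) < 0))    # decreasing before the switch
  expect_gt(max(late), min(early))     # growing after it
})
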