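# VAR fitting, Geweke spectral GC, band integration, reversal control.

test_that("multi-trial VAR estimation recovers known coefficients", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4; A[1, 2, 2] <- -0.2
  sim <- simulate_var(A, diag(2), 256, 200, seed = 5)
  m <- fit_var_pair(sim$x, sim$y, order = 2)
  expect_lt(sqrt(mean((m$A - A)^2)), 0.05)
  expect_lt(m$spectral_radius, 1)

  # independent white noise: cross-coefficients are null at 3 SE
  set.seed(6)
  x <- matrix(rnorm(50 * 256), 50); y <- matrix(rnorm(50 * 256), 50)
  m0 <- fit_var_pair(x, y, order = 10)
  se <- 1 / sqrt(m0$n_obs_effective)
  cross <- c(m0$A[1, 2, ], m0$A[2, 1, ])
  expect_gte(mean(abs(cross) < 3 * se), 0.95)

  # constant input is singular
  suppressWarnings(
    expect_error(fit_var_pair(matrix(1, 5, 100), matrix(rnorm(500), 5)),
                 "zero-variance"))
})

test_that("Geweke spectra match the analytic oracle and vanish when decoupled", {
  # decoupled VAR: GC identically zero both ways, even with correlated noise
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.4; A[2, 2, 1] <- 0.6
  spec0 <- geweke_spectral_gc(list(A = A, sigma = matrix(c(1, .3, .3, 1), 2),
                                   fs_hz = 1000))
  expect_equal(max(abs(spec0$fwd)), 0)
  expect_equal(max(abs(spec0$bwd)), 0)

  # known unidirectional VAR: estimate tracks the oracle, reverse stays null
  A1 <- array(0, c(2, 2, 1))
  A1[1, 1, 1] <- 0.5; A1[2, 2, 1] <- 0.5; A1[2, 1, 1] <- 0.4
  oracle <- geweke_spectral_gc(list(A = A1, sigma = diag(2), fs_hz = 1000))
  expect_true(all(oracle$fwd > 0))
  expect_equal(max(oracle$bwd), 0)

  # independent hand implementation of the open-loop identity at one frequency:
  # for x -> y with y = 0.5 y(t-1) + 0.4 x(t-1), H_yx/H_yy = 0.4 e^-iw/(1-0.5e^-iw)
  idx <- which.min(abs(oracle$freq_hz - 40))
  w <- 2 * pi * oracle$freq_hz[idx] / 1000
  Hratio <- abs(0.4 * exp(-1i * w) / (1 - 0.5 * exp(-1i * w)))^2
  expect_equal(oracle$fwd[idx], log1p(Hratio), tolerance = 1e-10)

  sim <- simulate_var(A1, diag(2), 256, 300, seed = 8)
  est <- geweke_spectral_gc(fit_var_pair(sim$x, sim$y, order = 50))
  sel <- est$freq_hz >= 4 & est$freq_hz <= 55
  expect_lt(mean(abs(est$fwd[sel] - oracle$fwd[sel])) / mean(oracle$fwd[sel]),
            0.10)

  # doubling the driving coefficient increases GC at every frequency
  A2 <- A1; A2[2, 1, 1] <- 0.8
  oracle2 <- geweke_spectral_gc(list(A = A2, sigma = diag(2), fs_hz = 1000))
  expect_true(all(oracle2$fwd > oracle$fwd))
})

test_that("band integration is a mean with exact antisymmetry of net GC", {
  A1 <- gamma_var_coefs(0.5)
  sim <- simulate_var(A1, diag(2), 256, 60, seed = 9)
  m_xy <- fit_var_pair(sim$x, sim$y)
  m_yx <- fit_var_pair(sim$y, sim$x)
  g_xy <- band_net_gc(geweke_spectral_gc(m_xy), c(35, 55))
  g_yx <- band_net_gc(geweke_spectral_gc(m_yx), c(35, 55))
  expect_equal(g_xy$net, -g_yx$net, tolerance = 1e-9)
  expect_gt(g_xy$net, 0)                 # gamma coupling detected forward

  expect_error(band_net_gc(geweke_spectral_gc(m_xy), c(200, 300)), "empty")

  # symmetric bidirectional coupling of equal strength: no dominant
  # direction (net is a few percent of either one-way index)
  As <- array(0, c(2, 2, 2))
  r <- exp(-pi * 20 / 1000); w <- 2 * pi * 45 / 1000
  As[1, 1, 1] <- As[2, 2, 1] <- 2 * r * cos(w)
  As[1, 1, 2] <- As[2, 2, 2] <- -r^2
  As[1, 2, 1] <- As[2, 1, 1] <- 0.05
  sims <- simulate_var(As, diag(2), 256, 100, seed = 10)
  gs <- band_net_gc(geweke_spectral_gc(fit_var_pair(sims$x, sims$y)), c(35, 55))
  expect_gt(gs$gci_fwd, 0.5)
  expect_gt(gs$gci_bwd, 0.5)
  expect_lt(abs(gs$net), 0.1 * max(gs$gci_fwd, gs$gci_bwd))
})

test_that("model order 50 and the true order give comparable band GC", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5; A[2, 1, 1] <- 0.4; A[2, 2, 2] <- -0.2
  sim <- simulate_var(A, diag(2), 256, 300, seed = 11)
  g50 <- band_net_gc(geweke_spectral_gc(fit_var_pair(sim$x, sim$y, 50)), c(4, 55))
  g2 <- band_net_gc(geweke_spectral_gc(fit_var_pair(sim$x, sim$y, 2)), c(4, 55))
  expect_lt(abs(g50$gci_fwd - g2$gci_fwd) / g2$gci_fwd, 0.15)
})

test_that("time reversal flips genuine coupling but not mixed common noise", {
  # reversal leaves lag-zero covariance untouched
  set.seed(12)
  x <- matrix(rnorm(10 * 100), 10); y <- 0.8 * x + 0.2 * matrix(rnorm(1000), 10)
  xr <- x[, 100:1]; yr <- y[, 100:1]
  expect_equal(cov(as.vector(x), as.vector(y)),
               cov(as.vector(xr), as.vector(yr)), tolerance = 1e-12)

  sim <- simulate_var(gamma_var_coefs(0.5), diag(2), 256, 20, seed = 13)
  rgt <- reverse_granger_test(sim$x, sim$y, c(35, 55), seed = 13)
  expect_true(rgt$pass)
  expect_gt(rgt$net, 0)
  expect_lt(rgt$net_reversed, 0)

  mix <- common_noise_pair(seed = 14)
  rgt_mix <- reverse_granger_test(mix$x, mix$y, c(35, 55), seed = 14)
  expect_false(rgt_mix$pass)

  # independent channels sit below the magnitude floor
  set.seed(15)
  rgt0 <- reverse_granger_test(matrix(rnorm(20 * 256), 20),
                               matrix(rnorm(20 * 256), 20), c(35, 55), seed = 15)
  expect_false(rgt0$pass)
})

test_that("the GC graph enumerates ordered pairs with consistent symmetry", {
  set.seed(16)
  ep <- make_epoched(function(tr, ch, t) rnorm(length(t)),
                     n_trials = 8, n_channels = 4,
                     condition = rep(1, 8))
  g <- build_gc_graph(ep, bands = list(gamma = c(35, 55)), order = 10,
                      n_null = 0)
  expect_equal(nrow(g), 12)           # 4 channels -> 12 ordered pairs x 1 band
  swapped <- dplyr::inner_join(
    g, g, by = c(source = "target", target = "source", band = "band"))
  expect_equal(swapped$net.x, -swapped$net.y, tolerance = 1e-12)
  expect_true(all(swapped$rgt_pass.x == swapped$rgt_pass.y))
})
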