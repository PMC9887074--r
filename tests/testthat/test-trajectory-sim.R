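test_that("simulation is deterministic given the seed", {
  e1 <- simulate_bm(50, 1e-3, 0.05, D = 2e-9, zeta = 20, seed = 11)
  e2 <- simulate_bm(50, 1e-3, 0.05, D = 2e-9, zeta = 20, seed = 11)
  expect_identical(e1$positions, e2$positions)
  f1 <- simulate_fbm(20, 1e-3, 0.05, K = 4e-9, H = 0.25, seed = 3)
  f2 <- simulate_fbm(20, 1e-3, 0.05, K = 4e-9, H = 0.25, seed = 3)
  expect_identical(f1$positions, f2$positions)
  c1 <- simulate_ctrw(10, beta = 0.5, gamma_t = 1e-4, D_alpha = 2e-9,
                      T = 0.01, dt_sample = 1e-4, seed = 5)
  c2 <- simulate_ctrw(10, beta = 0.5, gamma_t = 1e-4, D_alpha = 2e-9,
                      T = 0.01, dt_sample = 1e-4, seed = 5)
  expect_identical(c1$positions, c2$positions)
})

test_that("Brownian ensemble matches the Ornstein-Uhlenbeck MSD and velocity correlation", {
  D <- 2e-9; zeta <- 20
  e <- simulate_bm(30000, 1e-3, 0.25, D = D, zeta = zeta, seed = 42)
  m <- msd(e)
  t <- m$t[-1]
  th <- 2 * D * t - (2 * D / zeta) * (1 - exp(-zeta * t))
  # pointwise within 4 standard errors (the errors are correlated across t,
  # so a small number of 3-sigma excursions among 250 points is expected)
  expect_lt(max(abs(m$msd[-1] - th) / m$se[-1]), 4)
  # empirical velocity autocorrelation decays like kBT e^{-zeta s}
  va <- velocity_autocorrelation(e, 10)
  kBT <- D * zeta
  expect_equal(va$vacf[1] / kBT, 1, tolerance = 0.05)
  decay <- va$vacf[6] / va$vacf[1]
  expect_equal(decay, exp(-zeta * va$lag[6]), tolerance = 0.05)
  # D = 0 gives identically zero paths
  e0 <- simulate_bm(10, 1e-3, 0.02, D = 0, zeta = 20, seed = 1)
  expect_true(all(e0$positions == 0))
})

test_that("fractional Brownian ensemble has the exact fGn covariance and MSD law", {
  K <- 4e-9; H <- 0.25
  e <- simulate_fbm(20000, 1e-3, 0.5, K = K, H = H, seed = 7)
  m <- msd(e, fit_window = c(0.01, 0.5))
  expect_equal(unname(m$fit["exponent"]), 2 * H, tolerance = 0.02)
  th <- K * m$t[-1]^(2 * H)
  expect_lt(max(abs(m$msd[-1] - th) / m$se[-1]), 4)
  # increment autocovariance at small lags vs the exact fGn covariance
  incr <- t(diff(t(e$positions)))
  n <- ncol(incr)
  for (k in 0:3) {
    emp <- mean(incr[, seq_len(n - k)] * incr[, seq_len(n - k) + k])
    ex <- fgn_cov_exact(k, H, K, 1e-3)
    se <- stats::sd(incr[, seq_len(n - k)] * incr[, seq_len(n - k) + k]) /
      sqrt(length(incr[, seq_len(n - k)]))
    expect_lt(abs(emp - ex) / se, 4)
  }
  # H = 0.5 reduces to Brownian scaling MSD = K t
  e5 <- simulate_fbm(4000, 1e-3, 0.3, K = 4e-9, H = 0.5, seed = 8)
  m5 <- msd(e5)
  expect_equal(unname(m5$fit["exponent"]), 1, tolerance = 0.03)
  expect_lt(max(abs(m5$msd[-1] - 4e-9 * m5$t[-1]) / m5$se[-1]), 4)
})

test_that("diffusivity sampling has the right moments and support", {
  dg <- diffusivity_dist("gamma", k = 1.5, theta = 2e-9)
  x <- sample_diffusivity(dg, 2e5, seed = 10)
  expect_equal(mean(x), 1.5 * 2e-9,
               tolerance = 3 * stats::sd(x) / sqrt(length(x)) / (1.5 * 2e-9))
  dn <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-10)
  y <- sample_diffusivity(dn, 2e5, seed = 11)
  expect_true(all(y >= 0))
  expect_equal(mean(y), 2e-9, tolerance = 1e-3)
  # heavily truncated case goes through the inverse-transform branch and
  # still matches the truncated-density mean
  dh <- diffusivity_dist("truncated_gaussian", D_star = 1e-10, sigma_D = 1e-9)
  z <- sample_diffusivity(dh, 2e5, seed = 12)
  expect_true(all(z >= 0))
  expect_equal(mean(z), dh$mean, tolerance = 0.02)
  expect_length(sample_diffusivity(dg, 0), 0)
})

test_that("superstatistical ensemble: mean-diffusivity MSD and leptokurtic displacements", {
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  e <- simulate_ss(30000, 1e-3, 0.2, dg, seed = 9)
  m <- msd(e)
  th <- 2 * dg$mean * m$t[-1]
  expect_lt(max(abs(m$msd[-1] - th) / m$se[-1]), 4)
  # excess kurtosis of x(t) for a Gamma(k) scale mixture of Gaussians is 3/k
  # (kurtosis 3(1+1/k)); k = 0.5 gives kurtosis 9. Kurtosis estimates have
  # heavy-tailed sampling error, so the band is wide but excludes Gaussian.
  xT <- e$positions[, ncol(e$positions)]
  kurt <- mean(xT^4) / mean(xT^2)^2
  expect_gt(kurt, 6)
  expect_lt(kurt, 13)
  # point-mass limit: statistically plain Brownian, Gaussian displacements
  dn0 <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 2e-14)
  e0 <- simulate_ss(20000, 1e-3, 0.1, dn0, seed = 13)
  x0 <- e0$positions[, ncol(e0$positions)]
  expect_equal(mean(x0^4) / mean(x0^2)^2, 3, tolerance = 0.1)
  expect_lt(max(abs(msd(e0)$msd[-1] - 2 * 2e-9 * msd(e0)$t[-1]) /
                  msd(e0)$se[-1]), 4)
})

test_that("Mittag-Leffler waiting times: exponential limit and heavy tail", {
  set.seed(21)
  w1 <- rmittag_leffler(2e5, 0.999, 1e-4)
  expect_equal(mean(w1), 1e-4, tolerance = 0.02)
  # survival close to exponential at a few scales
  expect_equal(mean(w1 > 2e-4), exp(-2), tolerance = 0.02)
  set.seed(22)
  w2 <- rmittag_leffler(2e5, 0.5, 1e-4)
  # beta = 0.5: heavy tail P(tau > t) ~ t^(-1/2), so far more mass at 100x
  # the scale than any exponential could put there
  expect_gt(mean(w2 > 1e-2), 20 * exp(-100))
  expect_gt(mean(w2 > 1e-2), 0.002)
})

test_that("CTRW ensemble subdiffuses with the constructed exponent and scales", {
  e <- simulate_ctrw(1500, beta = 0.5, gamma_t = 1e-4, D_alpha = 2e-9,
                     T = 0.3, dt_sample = 1e-4, seed = 10)
  m <- msd(e, fit_window = c(0.01, 0.3))
  expect_equal(unname(m$fit["exponent"]), 0.5, tolerance = 0.06)
  # MSD prefactor convention: ensemble MSD tracks 2 D_alpha t^beta
  th <- 2 * 2e-9 * m$t[-1]^0.5
  idx <- which(m$t[-1] >= 0.01)
  expect_lt(max(abs(m$msd[-1][idx] - th[idx]) / m$se[-1][idx]), 4)
  # scale relations are mutually inverse
  gx <- ctrw_gamma_x(2e-9, 0.5, 1e-4)
  expect_equal(ctrw_D_alpha(gx, 0.5, 1e-4), 2e-9, tolerance = 1e-12)
  # zero elapsed time: position 0
  expect_true(all(e$positions[, 1] == 0))
  expect_error(simulate_ctrw(5, beta = 1.2, gamma_t = 1e-4, D_alpha = 2e-9,
                             T = 0.01, seed = 1))
})

test_that("near-exponential-limit CTRW diffuses almost linearly", {
  e <- simulate_ctrw(1200, beta = 0.95, gamma_t = 1e-4, D_alpha = 2e-9,
                     T = 0.2, dt_sample = 1e-4, seed = 14)
  m <- msd(e, fit_window = c(0.01, 0.2))
  expect_equal(unname(m$fit["exponent"]), 0.95, tolerance = 0.08)
})
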