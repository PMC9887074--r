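test_that("b-value follows the defining arithmetic and its invariants", {
  p <- pfg_params(g = 0.01, delta = 0.01, Delta = 0.1, gamma = proton)
  # direct arithmetic oracle, frozen from an independent evaluation
  expect_equal(b_value(p), 69182516.746926427, tolerance = 1e-14)
  expect_equal(b_value(pfg_params(g = 0, delta = 0.01, Delta = 0.1)), 0)
  expect_gt(b_value(pfg_params(g = 1e-3, delta = 1e-3, Delta = 1e-3)), 0)
  expect_equal(q_value(p), proton * 0.01 * 0.01 / (2 * pi))
  # invalid conditions rejected at construction (Delta = delta/3 is not
  # representable because Delta >= delta is enforced)
  expect_error(pfg_params(g = 0.01, delta = 0.01, Delta = 0.01 / 3))
  expect_error(pfg_params(g = 0.01, delta = -1, Delta = 0.1))
  expect_error(pfg_params(g = -0.01, delta = 0.01, Delta = 0.1))
})

test_that("Brownian closed form: Stejskal-Tanner limit, quadrature oracle, monotonicity", {
  p1 <- pfg_params(g = 0.01, delta = 0.01, Delta = 0.1)
  # zeta*delta -> infinity recovers -bD
  expect_equal(lnS_bm(p1, 2e-9, 1e6 / 0.01), lnS_stejskal_tanner(p1, 2e-9),
               tolerance = 1e-9)
  # D -> 0 limit of Stejskal-Tanner
  expect_equal(lnS_stejskal_tanner(p1, 0), 0)
  # from-first-principles 2-D trapezoid of the second-cumulant integral
  p2 <- pfg_params(g = 0.01, delta = 0.01, Delta = 0.1, gamma = proton)
  C <- vacf_exponential(2e-9, 20)
  expect_equal(lnS_cumulant_trapz2d(C, p2, n = 2000L), lnS_bm(p2, 2e-9, 20),
               tolerance = 1e-6)
  # monotone decreasing in Delta, always <= 0
  pg <- pfg_params(g = 0.01, delta = 0.01, Delta = seq(0.02, 1, by = 0.02))
  v <- lnS_bm(pg, 2e-9, 20)
  expect_true(all(v <= 0))
  expect_true(all(diff(v) < 0))
  # no overflow at very large delta*zeta
  pbig <- pfg_params(g = 0.01, delta = 0.05, Delta = 0.5)
  expect_true(is.finite(lnS_bm(pbig, 2e-9, 5e4)))
})

test_that("anomalous closed forms: alpha = 1 reduction and mutual agreement", {
  p <- pfg_params(g = 0.01, delta = 0.01, Delta = c(0.05, 0.1, 0.5, 1))
  st <- lnS_stejskal_tanner(p, 2e-9)
  # algebraic identity (Delta+d)^3 + (Delta-d)^3 - 2Delta^3 - 2d^3 = 6 Delta d^2 - 2 d^3
  expect_equal(lnS_anomalous_full(p, 1, 2e-9), st, tolerance = 1e-12)
  expect_equal(lnS_anomalous(p, 1, 2e-9), st, tolerance = 1e-12)
  # compact formula agrees with the full one within 1% on Delta >= 2*delta
  for (al in c(0.5, 0.7, 1.2)) {
    full <- lnS_anomalous_full(p, al, 2e-9)
    compact <- lnS_anomalous(p, al, 2e-9)
    expect_lt(max(abs(compact / full - 1)), 0.01)
  }
  # exact g^2 scaling
  p2g <- pfg_params(g = 0.02, delta = 0.01, Delta = c(0.05, 0.1, 0.5, 1))
  expect_equal(lnS_anomalous(p2g, 0.5, 2e-9), 4 * lnS_anomalous(p, 0.5, 2e-9))
  # narrow-pulse limit: -> -(gamma g delta)^2 D_alpha Delta^alpha; the
  # finite-pulse correction decays like (delta/Delta)^alpha
  pn <- pfg_params(g = 0.01, delta = 1e-4, Delta = 0.5)
  npg <- -(pn$gamma * pn$g * pn$delta)^2 * 2e-9 * 0.5^0.7
  corr <- 2 * (1e-4 / 0.5)^0.7 / (1.7 * 2.7)
  expect_equal(lnS_anomalous_full(pn, 0.7, 2e-9) / npg, 1, tolerance = 3 * corr)
  # warning (not error) below the validity bound
  pshort <- pfg_params(g = 0.01, delta = 0.01, Delta = 0.015)
  expect_warning(lnS_anomalous(pshort, 0.5, 2e-9), "2\\*delta")
})

test_that("general velocity/position quadrature reproduces the closed forms", {
  p <- pfg_params(g = 0.01, delta = 0.005, Delta = c(0.02, 0.1, 0.2, 0.5))
  # exponential kernel -> Brownian formula
  v <- lnS_general_velocity(vacf_exponential(2e-9, 20), p)
  expect_equal(v, lnS_bm(p, 2e-9, 20), tolerance = 1e-9)
  # power-law kernel -> full anomalous formula, incl. the singular alpha < 1 case
  for (al in c(0.5, 1.2)) {
    w <- lnS_general_velocity(vacf_power_law(al, 2e-9), p)
    expect_equal(w, lnS_anomalous_full(p, al, 2e-9), tolerance = 1e-5)
  }
  # position-correlation route reproduces the same result; the additive
  # constant X0 must cancel identically
  x1 <- lnS_general_position(pacf_anomalous(0.5, 2e-9, X0 = 0), p)
  x2 <- lnS_general_position(pacf_anomalous(0.5, 2e-9, X0 = 3e-7), p)
  expect_equal(x1, lnS_anomalous_full(p, 0.5, 2e-9), tolerance = 1e-4)
  expect_equal(x1, x2, tolerance = 1e-7)
  # static spins: C = 0 and X = 0 give no attenuation
  zero <- function(s) 0 * s
  expect_equal(lnS_general_velocity(zero, p), rep(0, 4))
  expect_equal(lnS_general_position(zero, p), rep(0, 4))
  # linearity of the position form
  Xf <- pacf_anomalous(0.5, 2e-9)
  Xs <- function(s) 3 * Xf(s)
  expect_equal(lnS_general_position(Xs, p), 3 * x1, tolerance = 1e-7)
})

test_that("MSD from the velocity autocorrelation matches the closed forms", {
  t <- c(0, 0.01, 0.1, 1)
  m_ou <- msd_from_vacf(vacf_exponential(2e-9, 20), t)
  expect_equal(m_ou, 2 * 2e-9 * t - (2 * 2e-9 / 20) * (1 - exp(-20 * t)),
               tolerance = 1e-12)
  m_an <- msd_from_vacf(vacf_power_law(0.5, 2e-9), t)
  expect_equal(m_an, 2 * 2e-9 * t^0.5, tolerance = 1e-12)
  expect_equal(msd_from_vacf(vacf_exponential(1e-9, 5), 0), 0)
})

test_that("superstatistical closed forms match the mixture quadrature and depend on b only", {
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  dn <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-10)
  p <- pfg_params(g = 0.01, delta = 0.01, Delta = grid48(0.01))
  expect_equal(lnS_ss_numeric(p, dg), lnS_ss_gamma(p, dg), tolerance = 1e-8)
  expect_equal(lnS_ss_numeric(p, dn), lnS_ss_gaussian(p, dn), tolerance = 1e-8)
  # b = 0 gives no attenuation
  p0 <- pfg_params(g = 0, delta = 0.01, Delta = 0.1)
  expect_equal(lnS_ss_gamma(p0, dg), 0)
  expect_equal(lnS_ss_gaussian(p0, dn), 0)
  # small b*theta: tangent is -<D> b
  psm <- pfg_params(g = 1e-4, delta = 0.01, Delta = 0.1)
  expect_equal(lnS_ss_gamma(psm, dg) / (-dg$mean * b_value(psm)), 1,
               tolerance = 1e-4)
  # a -> 0: delta-distributed diffusivity reduces to Stejskal-Tanner
  dn0 <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 2e-14)
  expect_equal(lnS_ss_gaussian(p, dn0), lnS_stejskal_tanner(p, 2e-9),
               tolerance = 1e-6)
  # plain-density path of the numeric route: exponential P(D) is the k = 1
  # Gamma case
  pdf_exp <- function(D) ifelse(D < 0, 0, exp(-D / 2e-9) / 2e-9)
  d1 <- diffusivity_dist("gamma", k = 1, theta = 2e-9)
  expect_equal(lnS_ss_numeric(p, pdf_exp, D_scale = 2e-9),
               lnS_ss_gamma(p, d1), tolerance = 1e-8)
  # functions of b alone: different (g, delta, Delta) with equal b agree
  pA <- pfg_params(g = 0.02, delta = 0.005, Delta = 0.3)
  DeltaB <- b_value(pA) / (proton * 0.01 * 0.01)^2 + 0.01 / 3
  pB <- pfg_params(g = 0.01, delta = 0.01, Delta = DeltaB, gamma = proton)
  expect_equal(b_value(pA), b_value(pB))
  expect_equal(lnS_ss_gamma(pA, dg), lnS_ss_gamma(pB, dg))
  expect_equal(lnS_ss_gaussian(pA, dn), lnS_ss_gaussian(pB, dn))
})

test_that("truncated-Gaussian form is numerically stable far into the tail", {
  dn <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-10)
  # b grid reaching a*D*b >> 1, where naive erfc underflows to 0
  p <- pfg_params(g = 0.5, delta = 0.02, Delta = c(0.1, 0.3, 0.6, 1.0))
  v <- lnS_ss_gaussian(p, dn)
  expect_true(all(is.finite(v)))
  expect_true(all(diff(v) < 0))
  expect_true(all(v < 0))
  # against the boundary-dominated Laplace asymptotics of the mixture
  # integral: lnS -> ln p(0) - ln b for b sigma_D >> 1
  b <- b_value(p)
  asym <- log(ddiffusivity(dn, 0)) - log(b)
  expect_equal(v[4] / asym[4], 1, tolerance = 1e-3)
})

test_that("g^2 proportionality holds for Gaussian-stationary forms and fails for superstatistical ones", {
  d1 <- pfg_params(g = 0.01, delta = 0.01, Delta = c(0.05, 0.2, 0.8))
  d2 <- pfg_params(g = 0.02, delta = 0.01, Delta = c(0.05, 0.2, 0.8))
  expect_equal(lnS_bm(d2, 2e-9, 20), 4 * lnS_bm(d1, 2e-9, 20))
  expect_equal(lnS_anomalous_full(d2, 0.5, 2e-9),
               4 * lnS_anomalous_full(d1, 0.5, 2e-9))
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  dn <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-9)
  # the superstatistical forms are strictly *less* attenuated than g^2 scaling
  # predicts (log of a convex mixture), by a non-trivial margin here
  expect_true(all(lnS_ss_gamma(d2, dg) > 4 * lnS_ss_gamma(d1, dg)))
  expect_gt(max(abs(lnS_ss_gamma(d2, dg) / (4 * lnS_ss_gamma(d1, dg)) - 1)), 0.05)
  expect_true(all(lnS_ss_gaussian(d2, dn) > 4 * lnS_ss_gaussian(d1, dn)))
})

test_that("pulse-duration difference function is Delta-independent on the anomalous form", {
  # f(d1, d2) evaluated analytically on the compact anomalous formula equals
  # 2 D_alpha (d1^a - d2^a) / ((a+1)(a+2)) at every Delta
  al <- 0.5; Da <- 2e-9; g <- 0.01
  d1 <- 0.005; d2 <- 0.02
  Delta <- seq(0.04, 1, length.out = 30)
  p1 <- pfg_params(g = g, delta = d1, Delta = Delta)
  p2 <- pfg_params(g = g, delta = d2, Delta = Delta)
  f <- (lnS_anomalous(p1, al, Da) / d1^2 - lnS_anomalous(p2, al, Da) / d2^2) /
    (p1$gamma * g)^2
  expect_equal(f, rep(2 * Da * (d1^al - d2^al) / ((al + 1) * (al + 2)),
                      length(Delta)), tolerance = 1e-10)
})
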