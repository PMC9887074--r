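# Analytic curve sets across the model families, used to pin the truth table
# of the collapse checks.
two_g_curves <- function(model, params, delta = 0.01, gs = c(0.01, 0.02),
                         lo = NULL) {
  lapply(gs, function(g) attenuation_analytic(model, params, g = g,
                                              delta = delta,
                                              Delta = grid48(delta, lo = lo)))
}

test_that("g2 collapse: exact pass for Gaussian-stationary forms, fail for superstatistical", {
  ca <- two_g_curves("anomalous", list(alpha = 0.5, D_alpha = 2e-9), lo = 0.02)
  chk <- g2_collapse_check(ca)
  expect_equal(chk$statistic, 0, tolerance = 1e-12)
  expect_true(chk$verdict)

  cb <- two_g_curves("bm", list(D = 2e-9, zeta = 20))
  expect_true(g2_collapse_check(cb)$verdict)

  cst <- two_g_curves("stejskal_tanner", list(D = 2e-9))
  expect_true(g2_collapse_check(cst)$verdict)

  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  cg <- two_g_curves("ss_gamma", list(dist = dg))
  chk_ss <- g2_collapse_check(cg)
  expect_false(chk_ss$verdict)
  expect_gt(chk_ss$statistic, 0.05)

  dn <- diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-9)
  cn <- two_g_curves("ss_gaussian", list(dist = dn))
  expect_false(g2_collapse_check(cn)$verdict)

  # preconditions
  expect_error(g2_collapse_check(ca[1]), ">= 2")
  expect_error(g2_collapse_check(list(ca[[1]], cb[[1]])), "distinct 'g'")
  mixed <- list(ca[[1]], attenuation_analytic("bm", list(D = 2e-9, zeta = 20),
                                              g = 0.02, delta = 0.02,
                                              Delta = grid48(0.02)))
  expect_error(g2_collapse_check(mixed), "equal 'delta'")
})

test_that("statistics are symmetric under curve order", {
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  cg <- two_g_curves("ss_gamma", list(dist = dg))
  s12 <- g2_collapse_check(cg)$statistic
  s21 <- g2_collapse_check(rev(cg))$statistic
  expect_equal(s12, s21, tolerance = 1e-6)
})

test_that("delta_f constancy: anomalous value matches the closed form; superstatistical drifts", {
  al <- 0.5; Da <- 2e-9
  d1 <- 0.005; d2 <- 0.02
  mk <- function(model, params, delta)
    attenuation_analytic(model, params, g = 0.01, delta = delta,
                         Delta = seq(0.04, 1, length.out = 48))
  pair <- list(mk("anomalous", list(alpha = al, D_alpha = Da), d1),
               mk("anomalous", list(alpha = al, D_alpha = Da), d2))
  chk <- delta_f_check(pair)
  expect_true(chk$verdict)
  expect_lt(chk$statistic, 1e-8)
  f_expected <- 2 * Da * (d1^al - d2^al) / ((al + 1) * (al + 2))
  expect_equal(chk$details$f, rep(f_expected, nrow(chk$details)),
               tolerance = 1e-9)

  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  pair_ss <- list(mk("ss_gamma", list(dist = dg), d1),
                  mk("ss_gamma", list(dist = dg), d2))
  expect_false(delta_f_check(pair_ss)$verdict)

  # degenerate equal-delta pair: f identically 0, degenerate pass
  same <- list(mk("anomalous", list(alpha = al, D_alpha = Da), d1),
               mk("anomalous", list(alpha = al, D_alpha = Da), d1))
  dchk <- delta_f_check(same)
  expect_true(dchk$verdict)
  expect_match(dchk$note, "degenerate")
  expect_equal(dchk$details$f, rep(0, nrow(dchk$details)))
})

test_that("b collapse: exact for superstatistical forms, fails for anomalous across delta", {
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  c1 <- attenuation_analytic("ss_gamma", list(dist = dg), g = 0.01,
                             delta = 0.01, Delta = grid48(0.01))
  c2 <- attenuation_analytic("ss_gamma", list(dist = dg), g = 0.02,
                             delta = 0.005, Delta = grid48(0.005))
  chk <- b_collapse_check(list(c1, c2))
  expect_true(chk$verdict)
  expect_lt(chk$statistic, 1e-3)   # only interpolation error

  # Stejskal-Tanner depends on b alone as well
  s1 <- attenuation_analytic("stejskal_tanner", list(D = 2e-9), g = 0.01,
                             delta = 0.01, Delta = grid48(0.01))
  s2 <- attenuation_analytic("stejskal_tanner", list(D = 2e-9), g = 0.02,
                             delta = 0.005, Delta = grid48(0.005))
  expect_true(b_collapse_check(list(s1, s2))$verdict)

  # anomalous (alpha != 1) curves at different delta do not collapse in b
  a1 <- attenuation_analytic("anomalous", list(alpha = 0.5, D_alpha = 2e-9),
                             g = 0.01, delta = 0.01, Delta = grid48(0.01, lo = 0.02))
  a2 <- attenuation_analytic("anomalous", list(alpha = 0.5, D_alpha = 2e-9),
                             g = 0.02, delta = 0.003, Delta = grid48(0.003))
  expect_false(b_collapse_check(list(a1, a2))$verdict)

  expect_error(b_collapse_check(list(c1, c1)), "distinct")
})

test_that("flowchart classifier reproduces the analytic truth table", {
  # Brownian -> gaussian_stationary_normal, full Brownian formula
  cb <- two_g_curves("bm", list(D = 2e-9, zeta = 20))
  rb <- pfg_classify(cb)
  expect_equal(rb$classification, "gaussian_stationary_normal")
  expect_equal(rb$recommended_formula, "bm")

  # anomalous sub/super -> anomalous formula
  ca <- two_g_curves("anomalous", list(alpha = 0.5, D_alpha = 2e-9), lo = 0.02)
  ra <- pfg_classify(ca)
  expect_equal(ra$classification, "gaussian_stationary_subdiffusive")
  expect_equal(ra$recommended_formula, "anomalous")
  cs <- two_g_curves("anomalous", list(alpha = 1.2, D_alpha = 1.5e-9),
                     delta = 0.02)
  expect_equal(pfg_classify(cs)$classification,
               "gaussian_stationary_superdiffusive")

  # superstatistical -> brownian_non_gaussian
  dg <- diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
  cg <- two_g_curves("ss_gamma", list(dist = dg))
  rg <- pfg_classify(cg)
  expect_equal(rg$classification, "brownian_non_gaussian")
  expect_equal(rg$recommended_formula, "ss_gamma/ss_gaussian")

  # one condition only: explicit failure naming the missing requirement
  expect_error(pfg_classify(cb[1]), "two acquisition conditions")
})

test_that("noise shrinks the Delta range over which the g2 collapse holds", {
  # Rician noise breaks the collapse from the attenuated (large-Delta) end:
  # the passable window shrinks monotonically as SNR drops
  mk <- function(g) attenuation_analytic("anomalous",
                                         list(alpha = 0.5, D_alpha = 2e-9),
                                         g = g, delta = 0.01,
                                         Delta = grid48(0.01, lo = 0.02))
  clean <- list(mk(0.01), mk(0.02))
  delta_star <- function(snr, seed) {
    cur <- if (is.finite(snr)) {
      list(add_rician_noise(clean[[1]], snr, seed = seed),
           add_rician_noise(clean[[2]], snr, seed = seed + 1))
    } else clean
    cand <- clean[[1]]$Delta[-(1:9)]   # need >= 10 points in the window
    passing <- vapply(cand, function(dmax) {
      trunc2 <- lapply(cur, function(c) {
        k <- c$Delta <= dmax
        attenuation_curve(Delta = c$Delta[k], lnS = c$lnS[k], g = c$g,
                          delta = c$delta, gamma = c$gamma, t1 = c$t1)
      })
      g2_collapse_check(trunc2, threshold = 0.1)$verdict
    }, logical(1))
    if (!any(passing)) return(min(cand))
    max(cand[passing])
  }
  ds <- vapply(c(Inf, 50, 20, 10), delta_star, numeric(1), seed = 91)
  expect_true(all(diff(ds) <= 0))
  expect_lt(ds[4], ds[1])
})
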