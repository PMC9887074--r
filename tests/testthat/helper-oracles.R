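# Independent oracles used across the test files. These deliberately avoid
# the package's own integration code paths.

# Brute-force double-trapezoid evaluation of the second-cumulant attenuation
#   lnS = -(gamma^2/2) int int C(|t1-t2|) F(t1) F(t2) dt1 dt2
# on [0, TE]^2, with F the five-branch pulse integral. Only suitable for
# smooth C at modest accuracy; used as the from-first-principles cross-check
# of the closed-form Brownian formula.
lnS_cumulant_trapz2d <- function(C, p, n = 1500L) {
  stopifnot(length(p$Delta) == 1L)
  TE <- p$t1 + p$Delta + p$delta
  t <- seq(0, TE, length.out = n)
  h <- t[2] - t[1]
  Fv <- gradient_waveform(p)$F(t)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  M <- outer(t, t, function(a, b) C(abs(a - b))) *
    outer(Fv, Fv) * outer(w, w)
  -(p$gamma^2 / 2) * sum(M) * h^2
}

# Exact covariance of binned fractional Gaussian noise increments at lag k,
# from the double integral of the continuous kernel H(2H-1)K|t-t'|^{2H-2}
# over two bins of width dt (closed form via second differences of t^{2H}).
fgn_cov_exact <- function(k, H, K, dt) {
  (K * dt^(2 * H) / 2) *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Small default Delta grid for fast analytic-curve tests.
grid48 <- function(delta, lo = NULL, hi = 1) {
  if (is.null(lo)) lo <- max(2 * delta, 0.01)
  seq(lo, hi, length.out = 48)
}

proton <- 2.6752218744e8
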