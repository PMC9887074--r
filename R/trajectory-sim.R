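# Seeded Monte-Carlo generators of 1-D position trajectories for the four
# diffusion models, plus ensemble statistics. Public simulate_* functions
# return an in-memory trajectory_ensemble; the signal engine (pfg-engine.R)
# reuses the internal block generators so that large ensembles are streamed
# and never held as a full position matrix.

.new_ensemble <- function(positions, dt, model, params, seed) {
  structure(list(
    dt = dt,
    n_steps = ncol(positions) - 1L,
    n_traj = nrow(positions),
    times = (seq_len(ncol(positions)) - 1L) * dt,
    positions = positions,
    model = model,
    params = params,
    seed = seed
  ), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: model '%s', %d paths, %d steps of dt = %g s (T = %g s), seed %s\n",
              x$model, x$n_traj, x$n_steps, x$dt, x$n_steps * x$dt,
              format(x$seed)))
  invisible(x)
}

# ---- Brownian motion (Ornstein-Uhlenbeck velocity) --------------------------

# One block of BM paths; columns are trajectories, rows are the n_steps+1 grid
# times. The joint (velocity, position) update of the integrated
# Ornstein-Uhlenbeck process is exact (Gillespie's formulas): the sampled
# positions have the exact continuous-time covariance at the grid times, so
# no dt bias enters the zeta-sensitive part of the attenuation.
.gen_bm_block <- function(ncol, n_steps, dt, D, zeta) {
  kBT <- D * zeta
  e1 <- exp(-zeta * dt)
  var_v <- kBT * (1 - e1^2)
  var_x <- (kBT / zeta^2) * (2 * zeta * dt - 3 + 4 * e1 - e1^2)
  cov_xv <- (kBT / zeta) * (1 - e1)^2
  # conditional decomposition: xi_v drives xi_x through the regression slope
  slope <- if (var_v > 0) cov_xv / var_v else 0
  sd_res <- sqrt(max(var_x - slope^2 * var_v, 0))
  v <- stats::rnorm(ncol, sd = sqrt(kBT))   # stationary initial velocity
  X <- matrix(0, n_steps + 1L, ncol)
  x <- numeric(ncol)
  drift <- (1 - e1) / zeta
  for (j in seq_len(n_steps)) {
    xi_v <- stats::rnorm(ncol, sd = sqrt(var_v))
    xi_x <- slope * xi_v + stats::rnorm(ncol, sd = sd_res)
    x <- x + v * drift + xi_x
    X[j + 1L, ] <- x
    v <- v * e1 + xi_v
  }
  X
}

#' Simulate Brownian-motion trajectories (Langevin dynamics)
#'
#' Velocity follows an Ornstein-Uhlenbeck process with drag rate `zeta` and
#' thermal variance \eqn{k_BT = D\zeta} (unit particle mass), advanced with the
#' exact discretization \eqn{v(t+dt) = v e^{-\zeta dt} + } noise of variance
#' \eqn{k_BT(1 - e^{-2\zeta dt})}, and initialized from its stationary
#' distribution. Positions are the cumulative (trapezoid) integral of the
#' velocity, starting at 0.
#'
#' @param n_traj number of trajectories.
#' @param dt sampling step, s.
#' @param T total duration, s.
#' @param D diffusion coefficient, m^2/s (>= 0; 0 yields identically zero paths).
#' @param zeta viscous drag rate, 1/s.
#' @param seed integer RNG seed.
#' @return A `"trajectory_ensemble"` (positions: n_traj x (n_steps+1)).
#' @export
simulate_bm <- function(n_traj, dt, T, D, zeta, seed) {
  stopifnot(n_traj >= 1, dt > 0, T > 0, D >= 0, zeta > 0)
  if (dt * zeta >= 1)
    warning("dt * zeta >= 1: the velocity process is under-resolved")
  n_steps <- ceiling(T / dt)
  set.seed(seed)
  X <- .gen_bm_block(n_traj, n_steps, dt, D, zeta)
  .new_ensemble(t(X), dt, "bm", list(D = D, zeta = zeta), seed)
}

# ---- fractional Brownian motion (Davies-Harte) ------------------------------

# Exact covariance of fractional Gaussian noise binned at step dt so that the
# ensemble MSD is K * t^{2H} at the grid times.
.fgn_autocov <- function(lags, H, K, dt) {
  (K * dt^(2 * H) / 2) *
    (abs(lags + 1)^(2 * H) - 2 * abs(lags)^(2 * H) + abs(lags - 1)^(2 * H))
}

# Circulant eigenvalues for Davies-Harte embedding of n fGn steps; retries
# with doubled padding if (numerically) negative eigenvalues appear.
.dh_eigenvalues <- function(n, H, K, dt) {
  npad <- 2^ceiling(log2(max(n, 2)))
  for (trial in 1:4) {
    M <- 2L * npad
    gamma_k <- .fgn_autocov(0:npad, H, K, dt)
    cvec <- c(gamma_k, rev(gamma_k[2:npad]))
    lam <- Re(stats::fft(cvec))
    if (min(lam) >= -1e-9 * max(lam)) {
      lam[lam < 0] <- 0
      return(list(lam = lam, M = M))
    }
    npad <- npad * 2L
  }
  stop("Davies-Harte circulant embedding failed: negative eigenvalues persist")
}

# One block of fGn paths via the two-samples-per-FFT circulant method:
# with lambda the (symmetric, nonnegative) circulant eigenvalues and zeta a
# vector of iid complex standard normals, Re and Im of fft(sqrt(lambda)*zeta)
# / sqrt(M) are two independent fGn samples.
.gen_fbm_block <- function(ncol, n_steps, dt, K, H, eig) {
  M <- eig$M
  ncplx <- ceiling(ncol / 2)
  A <- matrix(stats::rnorm(M * ncplx), M, ncplx)
  B <- matrix(stats::rnorm(M * ncplx), M, ncplx)
  Z <- (A + 1i * B) * sqrt(eig$lam)
  W <- stats::mvfft(Z) / sqrt(M)
  incr <- cbind(Re(W[seq_len(n_steps), , drop = FALSE]),
                Im(W[seq_len(n_steps), , drop = FALSE]))[, seq_len(ncol), drop = FALSE]
  X <- rbind(0, apply(incr, 2, cumsum))
  dim(X) <- c(n_steps + 1L, ncol)
  X
}

#' Simulate fractional Brownian motion trajectories (Davies-Harte)
#'
#' Generates exact fractional Gaussian noise increments by circulant
#' embedding (Davies-Harte), scaled so that the ensemble MSD equals
#' \eqn{K t^{2H}} at the grid times (i.e. \eqn{2 D_\alpha t^\alpha} with
#' \eqn{\alpha = 2H}, \eqn{D_\alpha = K/2}); positions are cumulative sums of
#' the increments. `H = 0.5` reduces to ordinary Brownian motion with
#' \eqn{K = 2D}.
#'
#' @inheritParams simulate_bm
#' @param K MSD prefactor, m^2/s^(2H) (> 0).
#' @param H Hurst exponent in (0, 1).
#' @return A `"trajectory_ensemble"`.
#' @export
simulate_fbm <- function(n_traj, dt, T, K, H, seed) {
  stopifnot(n_traj >= 1, dt > 0, T > 0, K > 0, H > 0, H < 1)
  n_steps <- ceiling(T / dt)
  eig <- .dh_eigenvalues(n_steps, H, K, dt)
  set.seed(seed)
  X <- .gen_fbm_block(n_traj, n_steps, dt, K, H, eig)
  .new_ensemble(t(X), dt, "fbm", list(K = K, H = H), seed)
}

# ---- superstatistical Brownian motion ---------------------------------------

#' Draw per-trajectory diffusivities from a diffusivity distribution
#'
#' Gamma kind: standard Gamma(k, theta) draws. Truncated-Gaussian kind: draws
#' from N(D_star, sigma_D^2) conditioned on D >= 0, by rejection when the
#' acceptance probability is at least 1/2 (the usual case, since the spread is
#' typically far from the origin) and by inverse-transform sampling of the
#' truncated CDF otherwise.
#'
#' @param dist a [diffusivity_dist].
#' @param n number of draws (0 allowed).
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return Numeric vector of `n` nonnegative diffusivities, m^2/s.
#' @export
sample_diffusivity <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "diffusivity_dist"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  if (dist$kind == "gamma")
    return(stats::rgamma(n, shape = dist$k, scale = dist$theta))
  p0 <- stats::pnorm(-dist$D_star / dist$sigma_D)   # mass below 0
  if (1 - p0 >= 0.5) {
    out <- numeric(0)
    while (length(out) < n) {
      d <- stats::rnorm(n, mean = dist$D_star, sd = dist$sigma_D)
      out <- c(out, d[d >= 0])
    }
    out[seq_len(n)]
  } else {
    u <- stats::runif(n, min = p0, max = 1)
    dist$D_star + dist$sigma_D * stats::qnorm(u)
  }
}

.gen_ss_block <- function(ncol, n_steps, dt, dist) {
  D <- sample_diffusivity(dist, ncol)
  incr <- matrix(stats::rnorm(n_steps * ncol), n_steps, ncol) *
    rep(sqrt(2 * D * dt), each = n_steps)
  X <- rbind(0, apply(incr, 2, cumsum))
  dim(X) <- c(n_steps + 1L, ncol)
  X
}

#' Simulate superstatistical (Brownian yet non-Gaussian) trajectories
#'
#' Each trajectory is overdamped Brownian motion (Gaussian increments of
#' variance \eqn{2 D dt}) with its own diffusion coefficient drawn once from
#' the diffusivity distribution `dist` (see [sample_diffusivity]). The
#' ensemble MSD is \eqn{2\langle D\rangle t}, but the displacement
#' distribution at fixed time is a scale mixture of Gaussians and hence
#' non-Gaussian (leptokurtic) whenever `dist` has positive spread.
#'
#' @inheritParams simulate_bm
#' @param dist a [diffusivity_dist].
#' @return A `"trajectory_ensemble"`.
#' @export
simulate_ss <- function(n_traj, dt, T, dist, seed) {
  stopifnot(n_traj >= 1, dt > 0, T > 0, inherits(dist, "diffusivity_dist"))
  n_steps <- ceiling(T / dt)
  set.seed(seed)
  X <- .gen_ss_block(n_traj, n_steps, dt, dist)
  .new_ensemble(t(X), dt, "ss", list(dist = dist), seed)
}

# ---- continuous-time random walk --------------------------------------------

#' Mittag-Leffler waiting times (Kozubowski-Rachev transform)
#'
#' Draws waiting times whose survival function is the Mittag-Leffler function
#' \eqn{E_\beta(-(t/\gamma_t)^\beta)}, via
#' \deqn{\tau = -\gamma_t \ln u \left[\frac{\sin(\beta\pi)}{\tan(\beta\pi v)}
#'  - \cos(\beta\pi)\right]^{1/\beta}}
#' with u, v independent uniforms on (0, 1). As \eqn{\beta \to 1} the
#' distribution tends to an exponential of scale `gamma_t`; for
#' \eqn{\beta < 1} it is heavy tailed with infinite mean.
#'
#' @param n number of draws.
#' @param beta Mittag-Leffler exponent in (0, 1].
#' @param gamma_t time scale, s.
#' @return Vector of waiting times, s.
#' @export
rmittag_leffler <- function(n, beta, gamma_t) {
  stopifnot(n >= 0, beta > 0, beta <= 1, gamma_t > 0)
  u <- stats::runif(n)
  v <- stats::runif(n)
  if (beta == 1) return(-gamma_t * log(u))
  -gamma_t * log(u) *
    (sin(beta * pi) / tan(beta * pi * v) - cos(beta * pi))^(1 / beta)
}

#' CTRW jump-scale relations
#'
#' The jump length scale `gamma_x` and the generalized diffusion coefficient
#' are linked by \eqn{D_\alpha = \gamma_x^2 / [\gamma_t^\beta \Gamma(1+\beta)]}.
#' `ctrw_gamma_x()` inverts the relation.
#'
#' @param gamma_x jump length scale, m.
#' @param D_alpha generalized diffusion coefficient, m^2/s^beta.
#' @param beta Mittag-Leffler exponent in (0, 1).
#' @param gamma_t waiting-time scale, s.
#' @return The converted scale.
#' @name ctrw_scales
#' @export
ctrw_D_alpha <- function(gamma_x, beta, gamma_t) {
  gamma_x^2 / (gamma_t^beta * gamma(1 + beta))
}

#' @rdname ctrw_scales
#' @export
ctrw_gamma_x <- function(D_alpha, beta, gamma_t) {
  sqrt(D_alpha * gamma_t^beta * gamma(1 + beta))
}

# Event-level CTRW sample for one trajectory: renewal times (cumsum of
# Mittag-Leffler waiting times) up to horizon T and the position after each
# event. Jumps are Gaussian with sd sqrt(2) * gamma_x, which makes the
# ensemble MSD follow 2 * D_alpha * t^beta (the same convention as the
# anomalous MSD law used throughout).
.gen_ctrw_events <- function(beta, gamma_t, gamma_x, T, chunk = 256L) {
  times <- numeric(0)
  total <- 0
  repeat {
    w <- rmittag_leffler(chunk, beta, gamma_t)
    cw <- total + cumsum(w)
    times <- c(times, cw)
    total <- cw[length(cw)]
    if (total > T) break
  }
  keep <- times <= T
  n_ev <- sum(keep)
  list(times = times[keep],
       pos = cumsum(stats::rnorm(n_ev, sd = sqrt(2) * gamma_x)))
}

#' Simulate subdiffusive CTRW trajectories
#'
#' Event-driven continuous-time random walk: waiting times are
#' Mittag-Leffler with exponent `beta` and scale `gamma_t` (see
#' [rmittag_leffler]); jumps are Gaussian with length scale `gamma_x`
#' (obtained from `D_alpha` through [ctrw_gamma_x] when not given directly).
#' The Gaussian jump standard deviation is \eqn{\sqrt{2}\,\gamma_x}, chosen so
#' that the ensemble MSD follows \eqn{2 D_\alpha t^\beta}, the same
#' generalized-diffusion convention as [simulate_fbm]. The piecewise-constant
#' path is resampled onto the uniform `dt_sample` grid (position held between
#' events).
#'
#' Note the memory cost of the resampled grid: for signal synthesis at scale
#' use [pfg_signal], which integrates the event-level step function exactly
#' without materializing the grid.
#'
#' @inheritParams simulate_bm
#' @param beta Mittag-Leffler exponent in (0, 1).
#' @param gamma_t waiting-time scale, s.
#' @param D_alpha generalized diffusion coefficient, m^2/s^beta (give this or
#'   `gamma_x`).
#' @param gamma_x jump length scale, m.
#' @param dt_sample resampling step, s.
#' @return A `"trajectory_ensemble"`.
#' @export
simulate_ctrw <- function(n_traj, beta, gamma_t, D_alpha = NULL,
                          gamma_x = NULL, T, dt_sample = 1e-5, seed) {
  stopifnot(n_traj >= 1, beta > 0, beta < 1, gamma_t > 0, T > 0, dt_sample > 0)
  if (is.null(gamma_x)) {
    if (is.null(D_alpha)) stop("give either 'D_alpha' or 'gamma_x'")
    gamma_x <- ctrw_gamma_x(D_alpha, beta, gamma_t)
  } else {
    D_alpha <- ctrw_D_alpha(gamma_x, beta, gamma_t)
  }
  if (dt_sample > gamma_t)
    warning("dt_sample > gamma_t: early-time dynamics will be under-resolved")
  n_steps <- ceiling(T / dt_sample)
  tgrid <- (0:n_steps) * dt_sample
  set.seed(seed)
  X <- matrix(0, n_traj, n_steps + 1L)
  for (i in seq_len(n_traj)) {
    ev <- .gen_ctrw_events(beta, gamma_t, gamma_x, T)
    idx <- findInterval(tgrid, ev$times)
    X[i, ] <- c(0, ev$pos)[idx + 1L]
  }
  .new_ensemble(X, dt_sample, "ctrw",
                list(beta = beta, gamma_t = gamma_t, gamma_x = gamma_x,
                     D_alpha = D_alpha), seed)
}

# ---- ensemble statistics ----------------------------------------------------

#' Ensemble mean squared displacement
#'
#' \eqn{\langle [x(t) - x(0)]^2 \rangle} averaged over the trajectories of an
#' ensemble, with an optional log-log power-law fit
#' \eqn{\mathrm{MSD} = A t^p} over a time window.
#'
#' @param e a `"trajectory_ensemble"`.
#' @param fit_window numeric length-2 window (s) over which to fit the
#'   power law, or `NULL` to fit over all t > 0.
#' @return A list with `t`, `msd`, `se` (standard error of the ensemble mean
#'   at each time) and `fit` (named vector: `exponent`, `prefactor`).
#' @export
msd <- function(e, fit_window = NULL) {
  stopifnot(inherits(e, "trajectory_ensemble"), e$n_traj >= 1)
  disp2 <- (e$positions - e$positions[, 1])^2
  m <- colMeans(disp2)
  se <- apply(disp2, 2, stats::sd) / sqrt(e$n_traj)
  t <- e$times
  sel <- t > 0 & m > 0
  if (!is.null(fit_window)) sel <- sel & t >= fit_window[1] & t <= fit_window[2]
  fit <- c(exponent = NA_real_, prefactor = NA_real_)
  if (sum(sel) >= 2) {
    co <- stats::coef(stats::lm(log(m[sel]) ~ log(t[sel])))
    fit <- c(exponent = unname(co[2]), prefactor = exp(unname(co[1])))
  }
  list(t = t, msd = m, se = se, fit = fit)
}

#' Empirical velocity autocorrelation of an ensemble
#'
#' Finite-difference velocity \eqn{v_j = (x_{j+1} - x_j)/dt} autocorrelation
#' \eqn{\langle v(t) v(t+s) \rangle} averaged over time origins and
#' trajectories, at lags \eqn{s = k\,dt}.
#'
#' @param e a `"trajectory_ensemble"`.
#' @param max_lag maximum lag in steps.
#' @return A list with `lag` (s) and `vacf` (m^2/s^2).
#' @export
velocity_autocorrelation <- function(e, max_lag = 50L) {
  stopifnot(inherits(e, "trajectory_ensemble"))
  V <- t(diff(t(e$positions))) / e$dt     # n_traj x n_steps increments
  n <- ncol(V)
  max_lag <- min(max_lag, n - 1L)
  vacf <- vapply(0:max_lag, function(k) {
    mean(V[, seq_len(n - k)] * V[, seq_len(n - k) + k])
  }, numeric(1))
  list(lag = (0:max_lag) * e$dt, vacf = vacf)
}
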