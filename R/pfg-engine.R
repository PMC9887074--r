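# Spin-phase engine: gradient waveform, phase accumulation along sampled
# trajectories, ensemble FID average, Rician noise. The heavy path
# (pfg_signal) streams trajectory blocks from the generators in
# trajectory-sim.R so the full position matrix is never materialized.

#' Attenuation curve container
#'
#' Holds \eqn{\ln S(\Delta)/S(0)} on a strictly increasing `Delta` grid,
#' tagged with the acquisition condition that produced it. Normally created
#' by [pfg_signal], [synthesize_signal], [attenuation_analytic] or
#' [read_attenuation]; the constructor is exported for building curves from
#' external data.
#'
#' @param Delta strictly increasing pulse interspacings, s (all >= delta).
#' @param lnS log attenuation values (NA allowed for flagged points).
#' @param g,delta,gamma,t1 acquisition condition (see [pfg_params]).
#' @param n_traj ensemble size for simulated curves, or NA.
#' @param se_lnS optional Monte-Carlo standard error of `lnS` per point.
#' @param imag optional imaginary FID component diagnostic per point.
#' @param noise_sigma optional Rician noise level as a fraction of S(0).
#' @param provenance one of "simulated", "analytic", "file".
#' @param model optional tag of the generating model.
#' @param params optional list of generating parameters.
#' @param seed optional integer seed of the generating simulation.
#' @return An object of class `"attenuation_curve"`.
#' @export
attenuation_curve <- function(Delta, lnS, g, delta, gamma = GAMMA_PROTON,
                              t1 = 0.005, n_traj = NA_integer_, se_lnS = NULL,
                              imag = NULL, noise_sigma = NULL,
                              provenance = "file", model = NA_character_,
                              params = NULL, seed = NA_integer_) {
  stopifnot(length(Delta) == length(lnS), delta > 0, g >= 0, gamma > 0)
  if (is.unsorted(Delta, strictly = TRUE))
    stop("'Delta' grid must be strictly increasing")
  if (any(Delta < delta)) stop("all Delta must be >= delta")
  structure(list(Delta = Delta, lnS = lnS, g = g, delta = delta, gamma = gamma,
                 t1 = t1,
                 n_traj = if (is.na(n_traj)) NA_integer_ else as.integer(n_traj),
                 se_lnS = se_lnS, imag = imag,
                 noise_sigma = noise_sigma, provenance = provenance,
                 model = model, params = params,
                 seed = if (is.na(seed)) NA_integer_ else as.integer(seed)),
            class = "attenuation_curve")
}

#' @export
print.attenuation_curve <- function(x, ...) {
  cat(sprintf("PFG attenuation curve (%s%s): %d Delta points in [%g, %g] s\n",
              x$provenance,
              if (!is.na(x$model)) paste0(", model '", x$model, "'") else "",
              length(x$Delta), min(x$Delta), max(x$Delta)))
  cat(sprintf("  g = %g T/m, delta = %g s, gamma = %g, t1 = %g s\n",
              x$g, x$delta, x$gamma, x$t1))
  if (!is.na(x$n_traj)) cat(sprintf("  n_traj = %d\n", x$n_traj))
  if (!is.null(x$noise_sigma)) cat(sprintf("  Rician noise sigma = %g\n", x$noise_sigma))
  if (anyNA(x$lnS)) cat(sprintf("  %d point(s) flagged (S <= 0)\n", sum(is.na(x$lnS))))
  cat(sprintf("  lnS range: [%g, %g]\n", min(x$lnS, na.rm = TRUE), max(x$lnS, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.attenuation_curve <- function(x, ...) {
  df <- data.frame(Delta_s = x$Delta, lnS = x$lnS, S_over_S0 = exp(x$lnS))
  if (!is.null(x$se_lnS)) df$se_lnS <- x$se_lnS
  if (!is.null(x$imag)) df$imag <- x$imag
  df
}

#' @export
plot.attenuation_curve <- function(x, add = FALSE, ...) {
  if (add) graphics::points(x$Delta, x$lnS, ...)
  else graphics::plot(x$Delta, x$lnS, xlab = expression(Delta ~ "(s)"),
                      ylab = expression(ln ~ S(Delta) / S(0)), ...)
  invisible(x)
}

#' Analytic attenuation curve from a closed-form model
#'
#' Evaluates one of the closed-form attenuation models on a `Delta` grid and
#' wraps the result as an [attenuation_curve] (provenance `"analytic"`).
#'
#' @param model one of `"stejskal_tanner"`, `"bm"`, `"anomalous"`,
#'   `"anomalous_full"`, `"ss_gamma"`, `"ss_gaussian"`.
#' @param params named list of model parameters: `D` (stejskal_tanner);
#'   `D`, `zeta` (bm); `alpha`, `D_alpha` (anomalous, anomalous_full);
#'   `dist` (a [diffusivity_dist]; ss_gamma, ss_gaussian).
#' @param g,delta,Delta,gamma,t1 acquisition condition.
#' @return An `"attenuation_curve"`.
#' @export
attenuation_analytic <- function(model, params, g, delta, Delta,
                                 gamma = GAMMA_PROTON, t1 = 0.005) {
  p <- pfg_params(g = g, delta = delta, Delta = Delta, gamma = gamma, t1 = t1)
  lnS <- switch(model,
    stejskal_tanner = lnS_stejskal_tanner(p, params$D),
    bm = lnS_bm(p, params$D, params$zeta),
    anomalous = lnS_anomalous(p, params$alpha, params$D_alpha),
    anomalous_full = lnS_anomalous_full(p, params$alpha, params$D_alpha),
    ss_gamma = lnS_ss_gamma(p, params$dist),
    ss_gaussian = lnS_ss_gaussian(p, params$dist),
    stop("unknown model '", model, "'"))
  attenuation_curve(Delta = p$Delta, lnS = lnS, g = g, delta = delta,
                    gamma = gamma, t1 = t1, provenance = "analytic",
                    model = model, params = params)
}

# ---- gradient waveform ------------------------------------------------------

#' Bipolar PFG gradient waveform and its integral
#'
#' Returns the gradient \eqn{G(t)} (+g on the first pulse, -g on the second,
#' 0 elsewhere) and its running integral \eqn{F(t) = \int_0^t G}, the
#' five-branch trapezoid-free form: 0 before the first pulse, ramp
#' \eqn{g(t-t_1)} during it, plateau \eqn{g\delta} between pulses, ramp down
#' during the second pulse, and exactly 0 after refocusing
#' (\eqn{F(t_1+\Delta+\delta) = 0}).
#'
#' @param p a [pfg_params] with scalar `Delta`.
#' @return A list of two vectorized functions, `G(t)` and `F(t)`.
#' @export
gradient_waveform <- function(p) {
  stopifnot(inherits(p, "pfg_params"), length(p$Delta) == 1L)
  g <- p$g; delta <- p$delta; Delta <- p$Delta; t1 <- p$t1
  G <- function(t) {
    g * ((t >= t1 & t < t1 + delta) - (t >= t1 + Delta & t < t1 + Delta + delta))
  }
  F <- function(t) {
    ifelse(t <= t1, 0,
    ifelse(t <= t1 + delta, g * (t - t1),
    ifelse(t <= t1 + Delta, g * delta,
    ifelse(t <= t1 + Delta + delta, g * (t1 + Delta + delta - t), 0))))
  }
  list(G = G, F = F)
}

# Map a time onto the sampling grid. strict = TRUE (operations on an already
# sampled path) rejects any misalignment beyond rounding error — no silent
# interpolation; strict = FALSE (config load in pfg_signal) snaps to the
# nearest multiple of dt with a warning.
.snap_to_grid <- function(x, dt, what, strict = TRUE) {
  i <- round(x / dt)
  snapped <- i * dt
  misaligned <- abs(snapped - x) > 1e-9 * max(dt, abs(x))
  if (misaligned && strict)
    stop(what, " = ", x, " is not aligned with the sampling grid (dt = ", dt,
         "); resample or snap the window explicitly")
  if (abs(snapped - x) > dt / 2 * (1 + 1e-9))
    stop("cannot snap ", what, " = ", x, " onto the dt grid")
  if (misaligned)
    warning(sprintf("%s = %g snapped to %g (sampling grid dt = %g)",
                    what, x, snapped, dt))
  as.integer(i)
}

# ---- phase accumulation -----------------------------------------------------

#' Spin phase accumulated by one trajectory under a bipolar PFG pair
#'
#' \eqn{\phi = \gamma g [\int_{t_1}^{t_1+\delta} x\,dt -
#' \int_{t_1+\Delta}^{t_1+\Delta+\delta} x\,dt]} by trapezoid integration on
#' the sampled path. The pulse windows must align with the sampling grid
#' (integer multiples of `dt`); misaligned windows are an error, never a
#' silent interpolation. With `method = "cumulative"` all `Delta` values are
#' obtained in one pass from the cumulative path integral; `"direct"`
#' re-integrates each window and is the slow reference path.
#'
#' @param path numeric vector: sampled positions at times 0, dt, ..., n*dt.
#' @param p a [pfg_params] (vectorized over `Delta`).
#' @param dt sampling step of `path`, s.
#' @param method `"cumulative"` or `"direct"`.
#' @return Phase in radians, one value per `Delta`.
#' @export
accumulate_phase <- function(path, p, dt, method = c("cumulative", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(p, "pfg_params"), is.numeric(path), dt > 0)
  i_t1 <- .snap_to_grid(p$t1, dt, "t1")
  i_del <- .snap_to_grid(p$delta, dt, "delta")
  if (i_del < 1L) stop("delta shorter than one sampling step")
  i_Del <- vapply(p$Delta, .snap_to_grid, integer(1), dt = dt, what = "Delta")
  need <- i_t1 + max(i_Del) + i_del + 1L
  if (need > length(path))
    stop("PFG sequence (t1 + Delta + delta) exceeds the trajectory duration")
  if (method == "cumulative") {
    cs <- cumsum(path)
    P <- dt * (cs - path / 2 - path[1] / 2)   # trapezoid running integral
    win1 <- P[i_t1 + i_del + 1L] - P[i_t1 + 1L]
    win2 <- P[i_t1 + i_Del + i_del + 1L] - P[i_t1 + i_Del + 1L]
    p$gamma * p$g * (win1 - win2)
  } else {
    trapz <- function(a, b) {   # indices are 0-based grid positions
      idx <- (a:b) + 1L
      dt * (sum(path[idx]) - path[idx[1]] / 2 - path[idx[length(idx)]] / 2)
    }
    win1 <- trapz(i_t1, i_t1 + i_del)
    vapply(i_Del, function(iD) {
      p$gamma * p$g * (win1 - trapz(i_t1 + iD, i_t1 + iD + i_del))
    }, numeric(1))
  }
}

# ---- FID synthesis ----------------------------------------------------------

# Core accumulator: given a positions block (rows = grid times 0..n_steps,
# cols = trajectories), add each trajectory's e^{i phi} to the running sums.
# Window indices are 0-based grid positions.
.accumulate_block <- function(X, dt, gamma_g, i_t1, i_del, i_Del, acc) {
  CS <- apply(X, 2, cumsum)
  dim(CS) <- dim(X)
  P <- dt * (CS - X / 2)                    # x(0) = 0 for all paths
  win1 <- P[i_t1 + i_del + 1L, ] - P[i_t1 + 1L, ]
  for (k in seq_along(i_Del)) {
    iD <- i_Del[k]
    phi <- gamma_g * (win1 - (P[i_t1 + iD + i_del + 1L, ] - P[i_t1 + iD + 1L, ]))
    acc$sum_cos[k] <- acc$sum_cos[k] + sum(cos(phi))
    acc$sum_cos2[k] <- acc$sum_cos2[k] + sum(cos(phi)^2)
    acc$sum_sin[k] <- acc$sum_sin[k] + sum(sin(phi))
  }
  acc$n <- acc$n + ncol(X)
  acc
}

.acc_to_curve <- function(acc, Delta, g, delta, gamma, t1, n_traj, model,
                          params, seed) {
  # acc$n may be a scalar or a per-Delta vector (sub-ensemble acquisition)
  S <- acc$sum_cos / acc$n
  se_S <- sqrt(pmax(acc$sum_cos2 / acc$n - S^2, 0) / acc$n)
  imag <- acc$sum_sin / acc$n
  lnS <- ifelse(S > 0, log(pmin(S, 1)), NA_real_)
  if (anyNA(lnS))
    warning(sum(is.na(lnS)), " Delta point(s) flagged: S/S0 <= 0 (attenuation ",
            "below the Monte-Carlo noise floor)")
  se_lnS <- ifelse(S > 0, se_S / S, NA_real_)
  attenuation_curve(Delta = Delta, lnS = lnS, g = g, delta = delta,
                    gamma = gamma, t1 = t1, n_traj = n_traj, se_lnS = se_lnS,
                    imag = imag, provenance = "simulated", model = model,
                    params = params, seed = seed)
}

#' Synthetic attenuation curve from an in-memory trajectory ensemble
#'
#' For each `Delta` on the grid, computes the spin phase of every trajectory
#' ([accumulate_phase], cumulative fast path), averages the complex FID
#' \eqn{S/S_0 = \mathrm{Re}\,E\{e^{i\phi}\}} over the ensemble, and records
#' the log attenuation together with its Monte-Carlo standard error and the
#' imaginary-component diagnostic (which must be statistically indistinguishable
#' from zero for symmetric zero-mean dynamics). Points where the ensemble
#' average falls at or below zero are flagged as `NA`, never passed to `log`.
#'
#' @param e a `"trajectory_ensemble"`.
#' @param g gradient strength, T/m.
#' @param delta pulse duration, s.
#' @param Delta_grid strictly increasing interspacings, s.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @param t1 sequence start offset, s.
#' @return An `"attenuation_curve"`.
#' @export
synthesize_signal <- function(e, g, delta, Delta_grid, gamma = GAMMA_PROTON,
                              t1 = 0.005) {
  stopifnot(inherits(e, "trajectory_ensemble"), e$n_traj >= 2)
  p <- pfg_params(g = g, delta = delta, Delta = Delta_grid, gamma = gamma, t1 = t1)
  dt <- e$dt
  i_t1 <- .snap_to_grid(t1, dt, "t1")
  i_del <- .snap_to_grid(delta, dt, "delta")
  i_Del <- vapply(Delta_grid, .snap_to_grid, integer(1), dt = dt, what = "Delta")
  if (i_t1 + max(i_Del) + i_del > e$n_steps)
    stop("PFG sequence (t1 + Delta + delta) exceeds the trajectory duration")
  acc <- list(sum_cos = numeric(length(i_Del)),
              sum_cos2 = numeric(length(i_Del)),
              sum_sin = numeric(length(i_Del)), n = 0L)
  acc <- .accumulate_block(t(e$positions), dt, gamma * g, i_t1, i_del, i_Del, acc)
  .acc_to_curve(acc, Delta_grid, g, delta, gamma, t1, e$n_traj, e$model,
                e$params, e$seed)
}

#' Default pulse-interspacing grid
#'
#' 48 linearly spaced `Delta` values spanning `[max(2*delta, 0.01), 1]` s
#' (mirroring a 48-point acquisition over 10-1000 ms), snapped onto the
#' sampling grid `dt`.
#'
#' @param delta pulse duration, s.
#' @param dt sampling step the grid must align with, s.
#' @param n number of points.
#' @param Delta_max largest interspacing, s.
#' @return Strictly increasing numeric vector of interspacings.
#' @export
default_Delta_grid <- function(delta, dt = 1e-3, n = 48L, Delta_max = 1.0) {
  lo <- max(2 * delta, 0.01)
  raw <- seq(lo, Delta_max, length.out = n)
  snapped <- unique(round(raw / dt) * dt)
  snapped[snapped >= delta]
}

#' Noise-floor-aware pulse-interspacing grid
#'
#' Designs a `Delta` grid for a planned acquisition the way an
#' experimentalist would: 48 points from `max(2*delta, 0.01)` s up to the
#' interspacing at which the *nominal* attenuation reaches the Monte-Carlo
#' (or experimental) noise floor, so that the measured signal stays
#' informative over the whole grid. The floor is taken at
#' \eqn{|\ln S| = \ln(\sqrt{n_{traj}}/10)}, the point where \eqn{S} falls to
#' ten times the standard error of an FID average over `n_traj` trajectories
#' (so the log-signal error stays near 0.1 and its quadratic log-bias is
#' negligible under uniform fitting weights); the upper end is capped at
#' `Delta_max` and kept at least twice the lower end. When strong
#' attenuation leaves too little room above the `2*delta` validity bound of
#' the compact anomalous formula, the window is instead extended down to the
#' pulse duration itself and out to the deeper 3-standard-error floor, and
#' the returned grid carries attribute `narrow = TRUE` — the signal for such
#' an acquisition should be synthesized with
#' `pfg_signal(independent_Delta = TRUE)` so the per-point errors are
#' independent, and fitted without the short-`Delta` exclusion.
#'
#' @param lnS_nominal function of `Delta` returning the expected log
#'   attenuation under the nominal model parameters.
#' @param delta pulse duration, s.
#' @param n_traj planned ensemble size.
#' @param dt sampling step the grid must align with, s.
#' @param n number of grid points.
#' @param Delta_max hard upper cap, s.
#' @return Strictly increasing vector of interspacings.
#' @export
design_Delta_grid <- function(lnS_nominal, delta, n_traj = 1e5, dt = 1e-3,
                              n = 48L, Delta_max = 1.0) {
  solve_hi <- function(lo, floor_lnS) {
    if (lnS_nominal(lo) <= floor_lnS) return(lo)
    if (lnS_nominal(Delta_max) >= floor_lnS) return(Delta_max)
    stats::uniroot(function(D) lnS_nominal(D) - floor_lnS,
                   lower = lo, upper = Delta_max, tol = dt / 4)$root
  }
  lo <- max(2 * delta, 0.01)
  hi <- solve_hi(lo, -log(sqrt(n_traj) / 10))
  narrow <- hi < 6 * lo
  if (hi < 3 * lo) {
    # strong attenuation: too little leverage above the 2*delta validity
    # bound of the compact anomalous formula. Extend the window down to the
    # pulse duration itself (the formula degrades gracefully there; the
    # approximation error of a few percent beats an unidentifiable fit) and
    # accept points down to the deeper 3-standard-error floor — tolerable
    # once each Delta is measured on its own ensemble, so the errors are
    # independent across the grid.
    lo <- max(delta, 0.01)
    hi <- min(max(solve_hi(lo, -log(sqrt(n_traj) / 3)), 2 * lo), Delta_max)
  }
  hi <- min(max(hi, 2 * lo), Delta_max)
  raw <- seq(lo, hi, length.out = n)
  snapped <- unique(round(raw / dt) * dt)
  out <- snapped[snapped >= delta]
  attr(out, "narrow") <- narrow
  out
}

#' Plan a synthetic PFG acquisition: grid plus ensemble-sharing mode
#'
#' Combines [design_Delta_grid] with the choice of ensemble sharing for
#' [pfg_signal]: grids whose informative window is wide get the cost-neutral
#' 4-way sub-ensemble interleaving (the grid designed for the per-point
#' ensemble size `n_traj/4`), while narrow-window acquisitions get one full
#' ensemble per `Delta` point. CTRW acquisitions always use one shared
#' ensemble (the event-level synthesis has no gridded generator).
#'
#' @param model,params,g,delta,gamma as in [pfg_signal].
#' @param n_traj planned total ensemble size per acquisition.
#' @param dt sampling step, s.
#' @return A list with `Delta_grid`, `independent_Delta` (to pass to
#'   [pfg_signal]) and `exclude_short` (to pass to [pfg_fit] for the
#'   anomalous model).
#' @export
design_acquisition <- function(model, params, g, delta, n_traj = 1e5,
                               dt = 1e-3, gamma = GAMMA_PROTON) {
  nominal <- .nominal_lnS(model, params, g, delta, gamma)
  grid_dt <- if (model == "ctrw") 1e-3 else dt
  grid <- design_Delta_grid(nominal, delta = delta, n_traj = n_traj / 4,
                            dt = grid_dt)
  mode <- 4L
  if (isTRUE(attr(grid, "narrow"))) {
    grid <- design_Delta_grid(nominal, delta = delta, n_traj = n_traj,
                              dt = grid_dt)
    mode <- TRUE
  }
  if (model == "ctrw") mode <- FALSE
  list(Delta_grid = grid, independent_Delta = mode,
       exclude_short = min(grid) >= 2 * delta)
}

# Nominal log-attenuation function of Delta for a planned simulation, used
# by the grid designer. For CTRW the anomalous closed form with alpha = beta
# is the natural a-priori expectation.
.nominal_lnS <- function(model, params, g, delta, gamma = GAMMA_PROTON) {
  mk <- function(D) pfg_params(g = g, delta = delta, Delta = D, gamma = gamma)
  switch(model,
    bm = function(D) lnS_bm(mk(D), params$D, params$zeta),
    fbm = {
      alpha <- if (!is.null(params$alpha)) params$alpha else 2 * params$H
      D_alpha <- if (!is.null(params$D_alpha)) params$D_alpha else params$K / 2
      function(D) lnS_anomalous_full(mk(D), alpha, D_alpha)
    },
    ss = if (params$dist$kind == "gamma")
      function(D) lnS_ss_gamma(mk(D), params$dist)
    else
      function(D) lnS_ss_gaussian(mk(D), params$dist),
    ctrw = function(D) suppressWarnings(
      lnS_anomalous(mk(D), params$beta, params$D_alpha)),
    stop("unknown model '", model, "'"))
}

#' Simulate a synthetic PFG attenuation curve end to end
#'
#' Generates trajectories for the requested diffusion model and accumulates
#' the PFG spin-phase FID in streamed blocks, so ensembles of 1e5 paths never
#' require the full position matrix in memory. For the grid-sampled models
#' (`"bm"`, `"fbm"`, `"ss"`) the trajectory duration is `t1 + max(Delta) +
#' delta` at step `dt`; for `"ctrw"` the event-level step function is
#' integrated exactly over the pulse windows (no resampling grid).
#'
#' @param model `"bm"`, `"fbm"`, `"ss"` or `"ctrw"`.
#' @param params named list: `D`, `zeta` (bm); `K`, `H` or `alpha`, `D_alpha`
#'   (fbm); `dist` (ss); `beta`, `gamma_t` and `D_alpha` or `gamma_x` (ctrw).
#' @param g gradient strength, T/m.
#' @param delta pulse duration, s.
#' @param Delta_grid interspacings, s; `NULL` for [default_Delta_grid].
#' @param gamma gyromagnetic ratio.
#' @param t1 sequence start offset, s.
#' @param n_traj ensemble size.
#' @param dt sampling step for bm/fbm/ss, s.
#' @param seed integer RNG seed.
#' @param block_size trajectories per streamed block.
#' @param independent_Delta controls how `Delta` points share trajectories.
#'   `FALSE` (default): one ensemble of `n_traj` serves the whole grid —
#'   cheapest, but the Monte-Carlo errors are strongly correlated across
#'   `Delta`, which inflates the scatter of parameters fitted to the curve
#'   well beyond what pointwise error bars suggest. `TRUE`: every `Delta` is
#'   measured on its own fresh ensemble of `n_traj` (a separate acquisition
#'   per interspacing, as in a real experiment) — fully independent errors
#'   at a cost growing with the number of grid points; worth it on narrow
#'   windows. An integer `K`: the ensemble is split into `K` independent
#'   sub-ensembles of `n_traj/K` and grid points are assigned round-robin —
#'   total cost stays that of one shared ensemble while errors at nearby
#'   `Delta` become independent (pointwise error bars grow by `sqrt(K)`).
#' @return An `"attenuation_curve"`.
#' @examples
#' \donttest{
#' curve <- pfg_signal("bm", list(D = 2e-9, zeta = 20), g = 0.01,
#'                     delta = 0.005, n_traj = 2000, seed = 1)
#' plot(curve)
#' }
#' @export
pfg_signal <- function(model = c("bm", "fbm", "ss", "ctrw"), params,
                       g, delta, Delta_grid = NULL, gamma = GAMMA_PROTON,
                       t1 = 0.005, n_traj = 1e5, dt = 1e-3, seed = 1,
                       block_size = 1000L, independent_Delta = FALSE) {
  model <- match.arg(model)
  if (model == "fbm" && !is.null(params$alpha)) {
    params$H <- params$alpha / 2
    params$K <- 2 * params$D_alpha
  }
  if (is.null(Delta_grid))
    Delta_grid <- default_Delta_grid(delta, dt = if (model == "ctrw") 1e-3 else dt)
  stopifnot(n_traj >= 2)
  set.seed(seed)
  if (model == "ctrw") {
    return(.pfg_signal_ctrw(params, g, delta, Delta_grid, gamma, t1, n_traj,
                            seed))
  }
  i_t1 <- .snap_to_grid(t1, dt, "t1", strict = FALSE)
  i_del <- .snap_to_grid(delta, dt, "delta", strict = FALSE)
  i_Del <- vapply(Delta_grid, .snap_to_grid, integer(1), dt = dt,
                  what = "Delta", strict = FALSE)
  make_gen <- function(n_steps) switch(model,
    bm = function(nc) .gen_bm_block(nc, n_steps, dt, params$D, params$zeta),
    ss = function(nc) .gen_ss_block(nc, n_steps, dt, params$dist),
    fbm = {
      eig <- .dh_eigenvalues(n_steps, params$H, params$K, dt)
      function(nc) .gen_fbm_block(nc, n_steps, dt, params$K, params$H, eig)
    })
  run_one <- function(i_Del_sub, n_sub) {
    n_steps <- i_t1 + max(i_Del_sub) + i_del
    gen <- make_gen(n_steps)
    acc <- list(sum_cos = numeric(length(i_Del_sub)),
                sum_cos2 = numeric(length(i_Del_sub)),
                sum_sin = numeric(length(i_Del_sub)), n = 0L)
    left <- n_sub
    while (left > 0) {
      nc <- min(block_size, left)
      X <- gen(nc)
      acc <- .accumulate_block(X, dt, gamma * g, i_t1, i_del, i_Del_sub, acc)
      left <- left - nc
    }
    acc
  }
  if (isTRUE(independent_Delta)) {
    accs <- lapply(i_Del, function(iD) run_one(iD, n_traj))
    acc <- list(sum_cos = vapply(accs, function(a) a$sum_cos, numeric(1)),
                sum_cos2 = vapply(accs, function(a) a$sum_cos2, numeric(1)),
                sum_sin = vapply(accs, function(a) a$sum_sin, numeric(1)),
                n = n_traj)
  } else if (is.numeric(independent_Delta) && independent_Delta > 1) {
    K <- as.integer(min(independent_Delta, length(i_Del)))
    groups <- split(seq_along(i_Del), rep_len(seq_len(K), length(i_Del)))
    n_sub <- floor(n_traj / K)
    acc <- list(sum_cos = numeric(length(i_Del)),
                sum_cos2 = numeric(length(i_Del)),
                sum_sin = numeric(length(i_Del)),
                n = rep(n_sub, length(i_Del)))
    for (idx in groups) {
      a <- run_one(i_Del[idx], n_sub)
      acc$sum_cos[idx] <- a$sum_cos
      acc$sum_cos2[idx] <- a$sum_cos2
      acc$sum_sin[idx] <- a$sum_sin
    }
  } else {
    acc <- run_one(i_Del, n_traj)
  }
  .acc_to_curve(acc, i_Del * dt, g, i_del * dt, gamma, i_t1 * dt,
                as.integer(n_traj), model, params, seed)
}

# CTRW signal path: the position is a step function of the event times, so
# the window integrals int x dt are computed exactly from the event-level
# sample, per trajectory, for all Delta at once.
.pfg_signal_ctrw <- function(params, g, delta, Delta_grid, gamma, t1, n_traj,
                             seed) {
  beta <- params$beta; gamma_t <- params$gamma_t
  gamma_x <- if (!is.null(params$gamma_x)) params$gamma_x
             else ctrw_gamma_x(params$D_alpha, beta, gamma_t)
  Tmax <- t1 + max(Delta_grid) + delta
  nD <- length(Delta_grid)
  # integral bounds: first-pulse window then each second-pulse window
  lo <- c(t1, t1 + Delta_grid)
  hi <- c(t1 + delta, t1 + Delta_grid + delta)
  sum_cos <- numeric(nD); sum_cos2 <- numeric(nD); sum_sin <- numeric(nD)
  for (i in seq_len(n_traj)) {
    ev <- .gen_ctrw_events(beta, gamma_t, gamma_x, Tmax)
    tt <- c(0, ev$times)                 # segment start times
    xx <- c(0, ev$pos)                   # position on [tt_k, tt_{k+1})
    # running exact integral of the step function at segment starts
    Q <- c(0, cumsum(xx[-length(xx)] * diff(tt)))
    intx <- function(b) {                # int_0^b x dt, vectorized over b
      k <- findInterval(b, tt)
      Q[k] + xx[k] * (b - tt[k])
    }
    wins <- intx(hi) - intx(lo)
    phi <- gamma * g * (wins[1] - wins[-1])
    sum_cos <- sum_cos + cos(phi)
    sum_cos2 <- sum_cos2 + cos(phi)^2
    sum_sin <- sum_sin + sin(phi)
  }
  acc <- list(sum_cos = sum_cos, sum_cos2 = sum_cos2, sum_sin = sum_sin,
              n = n_traj)
  .acc_to_curve(acc, Delta_grid, g, delta, gamma, t1, as.integer(n_traj),
                "ctrw", c(params, list(gamma_x = gamma_x)), seed)
}

# ---- Rician noise -----------------------------------------------------------

#' Add Rician noise to an attenuation curve
#'
#' Magnitude-signal noise model: \eqn{S_{noisy} = \sqrt{(S+\epsilon_1)^2 +
#' \epsilon_2^2}} with independent zero-mean Gaussians of standard deviation
#' \eqn{S(0)/\mathrm{snr}}. The log attenuation is recomputed from the noisy
#' magnitude (which is strictly positive) and the noise level is recorded in
#' `noise_sigma`.
#'
#' @param c an `"attenuation_curve"`.
#' @param snr signal-to-noise ratio (> 0); `Inf` returns the curve unchanged.
#' @param seed optional integer seed.
#' @return A new `"attenuation_curve"` with noisy `lnS`.
#' @export
add_rician_noise <- function(c, snr, seed = NULL) {
  stopifnot(inherits(c, "attenuation_curve"), snr > 0)
  if (!is.finite(snr)) return(c)
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  S <- exp(c$lnS)
  Sn <- sqrt((S + stats::rnorm(length(S), sd = sigma))^2 +
             stats::rnorm(length(S), sd = sigma)^2)
  out <- c
  out$lnS <- log(Sn)
  out$noise_sigma <- sigma
  out
}
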