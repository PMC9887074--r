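# Gyromagnetic ratio of the proton, rad s^-1 T^-1 (CODATA). Used only as the
# default of the `gamma` field; formulas always take gamma from the object.
GAMMA_PROTON <- 2.6752218744e8

#' PFG acquisition parameters
#'
#' Bundles one pulsed-field-gradient acquisition condition: a pair of bipolar
#' rectangular gradient pulses of strength `g` and duration `delta`, separated
#' by the interspacing `Delta`, the first pulse starting at `t1` after the
#' excitation. The diffusion weighting of the condition is its b-value,
#' \eqn{b = \gamma^2 g^2 \delta^2 (\Delta - \delta/3)}.
#'
#' @param g gradient strength, T/m (>= 0).
#' @param delta gradient pulse duration, s (> 0).
#' @param Delta gradient pulse interspacing, s (>= delta).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1; defaults to the proton value
#'   2.6752218744e8.
#' @param t1 sequence start offset of the first pulse, s (>= 0).
#' @return An object of class `"pfg_params"`.
#' @examples
#' p <- pfg_params(g = 0.01, delta = 0.01, Delta = 0.1)
#' b_value(p)
#' @export
pfg_params <- function(g, delta, Delta, gamma = GAMMA_PROTON, t1 = 0.005) {
  stopifnot(is.numeric(g), is.numeric(delta), is.numeric(Delta),
            is.numeric(gamma), is.numeric(t1))
  if (delta <= 0) stop("'delta' must be > 0")
  if (any(Delta < delta)) stop("'Delta' must be >= 'delta'")
  if (g < 0) stop("'g' must be >= 0")
  if (gamma <= 0) stop("'gamma' must be > 0")
  if (t1 < 0) stop("'t1' must be >= 0")
  structure(list(g = g, delta = delta, Delta = Delta, gamma = gamma, t1 = t1),
            class = "pfg_params")
}

#' @export
print.pfg_params <- function(x, ...) {
  cat("PFG acquisition condition\n")
  cat(sprintf("  g     = %g T/m\n  delta = %g s\n", x$g, x$delta))
  if (length(x$Delta) == 1L) {
    cat(sprintf("  Delta = %g s\n", x$Delta))
  } else {
    cat(sprintf("  Delta = %d values in [%g, %g] s\n",
                length(x$Delta), min(x$Delta), max(x$Delta)))
  }
  cat(sprintf("  gamma = %g rad/s/T, t1 = %g s\n", x$gamma, x$t1))
  cat(sprintf("  b     = %s s/m^2\n",
              paste(format(b_value(x), digits = 4), collapse = ", ")))
  invisible(x)
}

#' Diffusion weighting (b-value) of a PFG condition
#'
#' \eqn{b = \gamma^2 g^2 \delta^2 (\Delta - \delta/3)}, in s/m^2. Vectorized
#' over the `Delta` field.
#'
#' @param p a [pfg_params] object.
#' @return Numeric vector of b-values, one per `Delta`.
#' @export
b_value <- function(p) {
  stopifnot(inherits(p, "pfg_params"))
  p$gamma^2 * p$g^2 * p$delta^2 * (p$Delta - p$delta / 3)
}

#' Wavevector q of a PFG condition
#'
#' \eqn{q = \gamma g \delta / (2\pi)}, in 1/m.
#'
#' @param p a [pfg_params] object.
#' @return Scalar wavevector.
#' @export
q_value <- function(p) {
  stopifnot(inherits(p, "pfg_params"))
  p$gamma * p$g * p$delta / (2 * pi)
}

#' Per-trajectory diffusivity distribution for superstatistical diffusion
#'
#' Describes the distribution P(D) of the diffusion coefficient across
#' trajectories in the superstatistical (Brownian yet non-Gaussian) model.
#' Two families are supported: a Gamma distribution with shape `k` and scale
#' `theta` (mean k*theta), and a Gaussian of mean `D_star` and standard
#' deviation `sigma_D` truncated to D >= 0 (renormalized by the erfc factor).
#'
#' @param kind `"gamma"` or `"truncated_gaussian"`.
#' @param k,theta shape (dimensionless) and scale (m^2/s) of the Gamma kind.
#' @param D_star,sigma_D mean and spread (m^2/s) of the truncated-Gaussian kind.
#' @return An object of class `"diffusivity_dist"` with a `mean` field holding
#'   the distribution mean (for the truncated Gaussian, the mean of the
#'   truncated density, not `D_star`).
#' @examples
#' diffusivity_dist("gamma", k = 0.5, theta = 2e-9)
#' diffusivity_dist("truncated_gaussian", D_star = 2e-9, sigma_D = 1e-10)
#' @export
diffusivity_dist <- function(kind = c("gamma", "truncated_gaussian"),
                             k = NULL, theta = NULL,
                             D_star = NULL, sigma_D = NULL) {
  kind <- match.arg(kind)
  if (kind == "gamma") {
    if (is.null(k) || is.null(theta) || k <= 0 || theta <= 0)
      stop("gamma kind needs k > 0 and theta > 0")
    out <- list(kind = kind, k = k, theta = theta, mean = k * theta)
  } else {
    if (is.null(D_star) || is.null(sigma_D) || D_star <= 0 || sigma_D <= 0)
      stop("truncated_gaussian kind needs D_star > 0 and sigma_D > 0")
    a <- sigma_D / D_star
    # mean of N(D_star, sigma_D^2) truncated to [0, Inf)
    z <- -D_star / sigma_D
    mean_trunc <- D_star + sigma_D * stats::dnorm(z) / (1 - stats::pnorm(z))
    out <- list(kind = kind, D_star = D_star, sigma_D = sigma_D, a = a,
                mean = mean_trunc)
  }
  structure(out, class = "diffusivity_dist")
}

#' @export
print.diffusivity_dist <- function(x, ...) {
  if (x$kind == "gamma") {
    cat(sprintf("Gamma diffusivity distribution: k = %g, theta = %g m^2/s (mean %g)\n",
                x$k, x$theta, x$mean))
  } else {
    cat(sprintf("Truncated-Gaussian diffusivity distribution: D* = %g, sigma_D = %g m^2/s (a = %g)\n",
                x$D_star, x$sigma_D, x$a))
  }
  invisible(x)
}

#' Density of a diffusivity distribution
#'
#' Normalized density of P(D) on \eqn{[0, \infty)}; the truncated-Gaussian
#' kind carries the erfc renormalization factor.
#'
#' @param dist a [diffusivity_dist] object.
#' @param D vector of diffusivities, m^2/s.
#' @return Density values.
#' @export
ddiffusivity <- function(dist, D) {
  stopifnot(inherits(dist, "diffusivity_dist"))
  if (dist$kind == "gamma") {
    stats::dgamma(D, shape = dist$k, scale = dist$theta)
  } else {
    norm <- 1 - stats::pnorm(-dist$D_star / dist$sigma_D)
    ifelse(D < 0, 0,
           stats::dnorm(D, mean = dist$D_star, sd = dist$sigma_D) / norm)
  }
}
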