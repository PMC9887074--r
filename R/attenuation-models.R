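# Analytic attenuation models ln S(Delta)/S(0) for a bipolar rectangular PFG
# pair, plus the general quadrature forms driven by a velocity or position
# autocorrelation function. All functions return the *log* attenuation; use
# signal_from_lnS()/lnS_from_signal() to convert.

#' @rdname lnS_conversions
#' @export
signal_from_lnS <- function(lnS) exp(lnS)

#' Conversions between log-attenuation and normalized signal
#'
#' The package works on \eqn{\ln S(\Delta)/S(0)} throughout; these helpers
#' convert to and from the normalized signal \eqn{S/S(0)}.
#'
#' @param lnS log attenuation values (<= 0 for noiseless data).
#' @param S normalized signal values (> 0).
#' @return The converted vector.
#' @name lnS_conversions
#' @export
lnS_from_signal <- function(S) {
  if (any(S <= 0)) stop("signal values must be > 0 to take the log")
  log(S)
}

#' Stejskal-Tanner log attenuation
#'
#' The classical free-diffusion result \eqn{\ln S/S(0) = -bD}, the
#' short-correlation-time (\eqn{\zeta\delta \gg 1}) limit of [lnS_bm] and the
#' \eqn{\alpha = 1} case of [lnS_anomalous].
#'
#' @param p a [pfg_params] object (vectorized over its `Delta`).
#' @param D diffusion coefficient, m^2/s.
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_stejskal_tanner <- function(p, D) {
  stopifnot(D >= 0)
  -b_value(p) * D
}

#' Brownian-motion log attenuation with finite velocity-correlation time
#'
#' Full PFG attenuation for a particle whose velocity is an
#' Ornstein-Uhlenbeck process with drag rate `zeta` (velocity autocorrelation
#' \eqn{k_BT e^{-\zeta s}}, \eqn{D = k_BT/\zeta}):
#' \deqn{\ln\frac{S}{S_0} = -\gamma^2 g^2 \delta^2 D (\Delta - \delta/3)
#'  + 2\gamma^2 g^2 D\left\{\frac{\delta}{\zeta^2}
#'  - \frac{1 - e^{-\delta\zeta} + e^{-\Delta\zeta}[\cosh(\delta\zeta)-1]}
#'         {\zeta^3}\right\}.}
#' It generalizes the Stejskal-Tanner formula to pulse durations comparable to
#' the velocity correlation time \eqn{1/\zeta}; the correction term vanishes
#' as \eqn{\zeta\delta \to \infty}. The \eqn{e^{-\Delta\zeta}\cosh(\delta\zeta)}
#' product is evaluated in combined-exponent form to avoid overflow at large
#' \eqn{\delta\zeta}.
#'
#' @param p a [pfg_params] object.
#' @param D diffusion coefficient, m^2/s (> 0).
#' @param zeta viscous drag rate, 1/s (> 0).
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_bm <- function(p, D, zeta) {
  stopifnot(D > 0, zeta > 0)
  g <- p$g; delta <- p$delta; Delta <- p$Delta; gamma <- p$gamma
  # e^{-Delta z} (cosh(delta z) - 1) without forming cosh explicitly
  ez <- 0.5 * (exp(-(Delta - delta) * zeta) + exp(-(Delta + delta) * zeta)) -
    exp(-Delta * zeta)
  st <- -gamma^2 * g^2 * delta^2 * D * (Delta - delta / 3)
  corr <- 2 * gamma^2 * g^2 * D *
    (delta / zeta^2 - (1 - exp(-delta * zeta) + ez) / zeta^3)
  st + corr
}

#' Anomalous-diffusion log attenuation (full four-term form)
#'
#' Attenuation for a Gaussian stationary-increment process with power-law
#' velocity autocorrelation \eqn{C(s) = \alpha(\alpha-1) D_\alpha s^{\alpha-2}}
#' (MSD \eqn{2 D_\alpha t^\alpha}):
#' \deqn{\ln\frac{S}{S_0} = -\frac{\gamma^2 g^2 D_\alpha}{(\alpha+1)(\alpha+2)}
#'  \left[(\Delta+\delta)^{\alpha+2} + (\Delta-\delta)^{\alpha+2}
#'        - 2\Delta^{\alpha+2} - 2\delta^{\alpha+2}\right].}
#'
#' @param p a [pfg_params] object.
#' @param alpha anomalous exponent in (0, 2).
#' @param D_alpha generalized diffusion coefficient, m^2/s^alpha (> 0).
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_anomalous_full <- function(p, alpha, D_alpha) {
  stopifnot(alpha > 0, alpha < 2, D_alpha > 0)
  g <- p$g; delta <- p$delta; Delta <- p$Delta; gamma <- p$gamma
  a2 <- alpha + 2
  brack <- (Delta + delta)^a2 + (Delta - delta)^a2 - 2 * Delta^a2 - 2 * delta^a2
  -gamma^2 * g^2 * D_alpha / ((alpha + 1) * (alpha + 2)) * brack
}

#' Anomalous-diffusion log attenuation (Stejskal-Tanner extension)
#'
#' The compact generalization of the Stejskal-Tanner expression to anomalous
#' diffusion,
#' \deqn{\ln\frac{S}{S_0} = -\gamma^2 g^2 \delta^2 D_\alpha
#'  \left[\Delta^\alpha - \frac{2\delta^\alpha}{(\alpha+1)(\alpha+2)}\right],}
#' valid for pulse interspacings \eqn{\Delta \gtrsim 2\delta}. For
#' \eqn{\Delta < 2\delta} a warning is emitted and the value is still
#' computed. At \eqn{\alpha = 1} it reduces exactly to \eqn{-bD}.
#'
#' @inheritParams lnS_anomalous_full
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_anomalous <- function(p, alpha, D_alpha) {
  stopifnot(alpha > 0, alpha < 2, D_alpha > 0)
  if (any(p$Delta < 2 * p$delta))
    warning("some Delta < 2*delta: outside the stated validity domain of the ",
            "compact anomalous formula; computing anyway")
  g <- p$g; delta <- p$delta; Delta <- p$Delta; gamma <- p$gamma
  -gamma^2 * g^2 * delta^2 * D_alpha *
    (Delta^alpha - 2 * delta^alpha / ((alpha + 1) * (alpha + 2)))
}

# ---- autocorrelation kernels -------------------------------------------------

#' Velocity autocorrelation kernels
#'
#' Constructors for the two analytic velocity-autocorrelation functions used
#' by the quadrature attenuation form [lnS_general_velocity] and by
#' [msd_from_vacf]. Each returns a function `C(s)` carrying an
#' `"antiderivative"` attribute \eqn{I(s) = \int_0^s C(u)\,du}; for the
#' power-law kernel with \eqn{\alpha < 1} the antiderivative is the finite
#' part \eqn{\alpha D_\alpha s^{\alpha-1}} (the ordinary integral diverges at
#' the origin and the kernels are to be understood in that regularized sense).
#'
#' @param D,zeta diffusion coefficient (m^2/s) and drag rate (1/s) of the
#'   exponential (Ornstein-Uhlenbeck) kernel \eqn{C(s) = D\zeta e^{-\zeta s}}.
#' @param alpha,D_alpha exponent and generalized diffusion coefficient of the
#'   power-law kernel \eqn{C(s) = \alpha(\alpha-1)D_\alpha s^{\alpha-2}}.
#' @return A function of `s` with attribute `"antiderivative"`.
#' @name vacf_kernels
#' @export
vacf_exponential <- function(D, zeta) {
  stopifnot(D > 0, zeta > 0)
  kBT <- D * zeta
  C <- function(s) kBT * exp(-zeta * s)
  attr(C, "antiderivative") <- function(s) D * (1 - exp(-zeta * s))
  attr(C, "antiderivative2") <- function(s) D * s - D * (1 - exp(-zeta * s)) / zeta
  C
}

#' @rdname vacf_kernels
#' @export
vacf_power_law <- function(alpha, D_alpha) {
  stopifnot(alpha > 0, alpha < 2, D_alpha > 0)
  C <- function(s) alpha * (alpha - 1) * D_alpha * s^(alpha - 2)
  attr(C, "antiderivative") <- function(s) alpha * D_alpha * s^(alpha - 1)
  attr(C, "antiderivative2") <- function(s) D_alpha * s^alpha
  C
}

#' Stationary position-autocorrelation kernel for anomalous diffusion
#'
#' \eqn{\langle x(0)x(s)\rangle = X_0 - D_\alpha s^\alpha}. Under the
#' position-correlation attenuation form [lnS_general_position] the additive
#' constant `X0` cancels identically, so only the structure function part
#' matters.
#'
#' @inheritParams vacf_kernels
#' @param X0 additive constant (m^2), irrelevant to the attenuation.
#' @return A function of `s`.
#' @export
pacf_anomalous <- function(alpha, D_alpha, X0 = 0) {
  stopifnot(alpha > 0, alpha < 2, D_alpha > 0)
  function(s) X0 - D_alpha * s^alpha
}

# Safe wrapper around stats::integrate that fails loudly with the achieved
# tolerance when the adaptive quadrature does not converge.
.quad <- function(f, lower, upper, rel.tol = 1e-10, ...) {
  if (upper <= lower) return(0)
  r <- stats::integrate(f, lower, upper, rel.tol = rel.tol,
                        subdivisions = 500L, stop.on.error = FALSE, ...)
  if (r$message != "OK" &&
      !(abs(r$value) < 1e-300 && r$message == "the integral is probably divergent")) {
    stop("quadrature failed on [", lower, ", ", upper, "]: ", r$message,
         " (abs.error ", format(r$abs.error), ")")
  }
  r$value
}

#' General PFG log attenuation from a velocity autocorrelation function
#'
#' Evaluates, by adaptive quadrature, the five-integral attenuation expression
#' for a bipolar PFG pair driven by an arbitrary stationary velocity
#' autocorrelation `C(s)`:
#' \deqn{\ln\frac{S}{S_0} = -\gamma^2 g^2 \Big\{
#'  \delta^2\big[\textstyle\int_0^\delta C(s)\,ds\,(\Delta - \delta/3)
#'  + \int_\delta^\Delta C(s)(\Delta - s)\,ds\big]
#'  - \int_0^\delta C(s)\,s^2(\delta - s/3)\,ds
#'  - \tfrac16\int_{\Delta-\delta}^{\Delta} C(s)(\Delta-\delta-s)^3 ds
#'  + \tfrac16\int_{\Delta}^{\Delta+\delta} C(s)(\Delta+\delta-s)^3 ds\Big\}.}
#' If `C` carries an `"antiderivative"` attribute (see [vacf_kernels]) the
#' first integral uses it directly; this is required for kernels with a
#' non-integrable \eqn{s \to 0} singularity such as the power-law kernel with
#' \eqn{\alpha < 1}, where the antiderivative is the finite part.
#'
#' @param C velocity autocorrelation function of one argument, m^2/s^2.
#' @param p a [pfg_params] object.
#' @param rel.tol relative quadrature tolerance.
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_general_velocity <- function(C, p, rel.tol = 1e-10) {
  stopifnot(is.function(C), inherits(p, "pfg_params"))
  g <- p$g; delta <- p$delta; gamma <- p$gamma
  anti <- attr(C, "antiderivative")
  I0d <- if (is.function(anti)) anti(delta) else .quad(C, 0, delta, rel.tol)
  i3 <- .quad(function(s) C(s) * s^2 * (delta - s / 3), 0, delta, rel.tol)
  vapply(p$Delta, function(Delta) {
    i2 <- .quad(function(s) C(s) * (Delta - s), delta, Delta, rel.tol)
    i4 <- .quad(function(s) C(s) * (Delta - delta - s)^3,
                Delta - delta, Delta, rel.tol)
    i5 <- .quad(function(s) C(s) * (Delta + delta - s)^3,
                Delta, Delta + delta, rel.tol)
    -gamma^2 * g^2 *
      (delta^2 * (I0d * (Delta - delta / 3) + i2) - i3 - i4 / 6 + i5 / 6)
  }, numeric(1))
}

#' General PFG log attenuation from a position autocorrelation function
#'
#' Evaluates the three-integral attenuation form driven by a stationary
#' position autocorrelation \eqn{X(s) = \langle x(0)x(s)\rangle}:
#' \deqn{\ln\frac{S}{S_0} = -\gamma^2 g^2\Big\{
#'  2\int_0^\delta X(s)(\delta - s)\,ds
#'  + \int_{\Delta-\delta}^{\Delta} X(s)(\Delta-\delta-s)\,ds
#'  - \int_{\Delta}^{\Delta+\delta} X(s)(\Delta+\delta-s)\,ds\Big\}.}
#' Any additive constant in `X` cancels between the three terms. Note that a
#' freely diffusing process has no stationary position autocorrelation in the
#' strict sense; the form is implemented literally, and with
#' \eqn{X(s) = -D_\alpha s^\alpha} (see [pacf_anomalous]) it reproduces the
#' anomalous closed form [lnS_anomalous_full] — see the methods vignette for
#' the discussion of this stationarity caveat.
#'
#' @param X position autocorrelation function of one argument, m^2.
#' @inheritParams lnS_general_velocity
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_general_position <- function(X, p, rel.tol = 1e-10) {
  stopifnot(is.function(X), inherits(p, "pfg_params"))
  g <- p$g; delta <- p$delta; gamma <- p$gamma
  i1 <- .quad(function(s) X(s) * (delta - s), 0, delta, rel.tol)
  vapply(p$Delta, function(Delta) {
    i2 <- .quad(function(s) X(s) * (Delta - delta - s),
                Delta - delta, Delta, rel.tol)
    i3 <- .quad(function(s) X(s) * (Delta + delta - s),
                Delta, Delta + delta, rel.tol)
    -gamma^2 * g^2 * (2 * i1 + i2 - i3)
  }, numeric(1))
}

#' Mean squared displacement from a velocity autocorrelation function
#'
#' \eqn{\langle [x(t)-x(0)]^2\rangle = 2\int_0^t C(s)(t-s)\,ds}, computed, via
#' integration by parts, as \eqn{2\int_0^t I(s)\,ds} with
#' \eqn{I(s)=\int_0^s C}; the by-parts route also covers kernels whose
#' antiderivative is only defined as a finite part (power law with
#' \eqn{\alpha<1}).
#'
#' @param C velocity autocorrelation function (see [vacf_kernels]).
#' @param t times, s (vectorized).
#' @param rel.tol relative quadrature tolerance.
#' @return MSD values, m^2.
#' @export
msd_from_vacf <- function(C, t, rel.tol = 1e-10) {
  stopifnot(is.function(C), all(t >= 0))
  anti <- attr(C, "antiderivative")
  anti2 <- attr(C, "antiderivative2")
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    if (is.function(anti2)) {
      2 * anti2(ti)
    } else if (is.function(anti)) {
      2 * .quad(anti, 0, ti, rel.tol)
    } else {
      2 * .quad(function(s) C(s) * (ti - s), 0, ti, rel.tol)
    }
  }, numeric(1))
}

# ---- superstatistical (Brownian yet non-Gaussian) forms ---------------------

# log(erfc(x)) through the stable normal-tail path: erfc(x) = 2*P(Z > x*sqrt(2))
.log_erfc <- function(x) {
  log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

#' Superstatistical log attenuation, Gamma-distributed diffusivity
#'
#' Stejskal-Tanner attenuation averaged over a Gamma distribution of
#' per-trajectory diffusivities: \eqn{\ln S/S_0 = -k\ln(1 + b\theta)}, a
#' function of the acquisition only through the b-value.
#'
#' @param p a [pfg_params] object.
#' @param dist a [diffusivity_dist] of kind `"gamma"`.
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_ss_gamma <- function(p, dist) {
  stopifnot(inherits(dist, "diffusivity_dist"))
  if (dist$kind != "gamma") stop("dist must be of kind 'gamma'")
  -dist$k * log1p(b_value(p) * dist$theta)
}

#' Superstatistical log attenuation, truncated-Gaussian diffusivity
#'
#' Stejskal-Tanner attenuation averaged over a Gaussian diffusivity
#' distribution of mean `D_star` and spread `sigma_D`, truncated to
#' \eqn{D \ge 0}; with \eqn{a = \sigma_D/D_*}:
#' \deqn{\ln\frac{S}{S_0} = -D_* b + \tfrac12 a^2 D_*^2 b^2
#'  + \ln\mathrm{erfc}\!\left(-\frac{1}{\sqrt2 a} + \frac{a D_* b}{\sqrt2}\right)
#'  - \ln\mathrm{erfc}\!\left(-\frac{1}{\sqrt2 a}\right).}
#' The log-erfc terms are evaluated through the logarithmic normal-tail
#' routine, so the expression stays accurate when the naive erfc underflows at
#' large \eqn{a D_* b}. In the limit \eqn{a \to 0} the formula reduces to
#' \eqn{-D_* b}.
#'
#' @param p a [pfg_params] object.
#' @param dist a [diffusivity_dist] of kind `"truncated_gaussian"`.
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_ss_gaussian <- function(p, dist) {
  stopifnot(inherits(dist, "diffusivity_dist"))
  if (dist$kind != "truncated_gaussian")
    stop("dist must be of kind 'truncated_gaussian'")
  b <- b_value(p)
  a <- dist$a; Ds <- dist$D_star
  (-Ds * b + 0.5 * a^2 * Ds^2 * b^2) +
    .log_erfc(-1 / (sqrt(2) * a) + a * Ds * b / sqrt(2)) -
    .log_erfc(-1 / (sqrt(2) * a))
}

#' Superstatistical log attenuation for an arbitrary diffusivity density
#'
#' Numerical evaluation of
#' \eqn{\ln \int_0^\infty e^{-bD} p(D)\,dD} by adaptive quadrature; this is
#' the independent route against which the closed forms [lnS_ss_gamma] and
#' [lnS_ss_gaussian] can be checked.
#'
#' @param p a [pfg_params] object.
#' @param pdf density function of D, normalized on \eqn{[0, \infty)}; either a
#'   plain function or a [diffusivity_dist] (its [ddiffusivity] is used).
#' @param D_scale typical diffusivity magnitude, m^2/s, used to rescale the
#'   integration variable to order one (the quadrature would otherwise miss a
#'   density concentrated at the 1e-9 m^2/s scale). Taken from the
#'   distribution mean when `pdf` is a [diffusivity_dist].
#' @param rel.tol relative quadrature tolerance.
#' @return Log attenuation, one value per `Delta`.
#' @export
lnS_ss_numeric <- function(p, pdf, D_scale = NULL, rel.tol = 1e-12) {
  if (inherits(pdf, "diffusivity_dist")) {
    dist <- pdf
    if (is.null(D_scale)) D_scale <- dist$mean
    pdf <- function(D) ddiffusivity(dist, D)
  }
  stopifnot(is.function(pdf))
  if (is.null(D_scale)) stop("'D_scale' must be given for a plain density function")
  b <- b_value(p)
  vapply(b, function(bi) {
    # substitute D = D_scale * u so the integrand has order-one support
    val <- .quad(function(u) exp(-bi * D_scale * u) * pdf(D_scale * u) * D_scale,
                 0, Inf, rel.tol)
    log(val)
  }, numeric(1))
}
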