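# Model-discrimination checks: rescaling collapses that decide whether a set
# of attenuation curves may legitimately be fitted with the Gaussian
# stationary-increment formulas, the superstatistical formulas, or neither,
# plus the flowchart classifier combining them.

.new_check <- function(check, statistic, threshold, verdict, details,
                       note = NULL) {
  structure(list(check = check, statistic = statistic, threshold = threshold,
                 verdict = verdict, details = details, note = note),
            class = "pfg_check")
}

#' @export
print.pfg_check <- function(x, ...) {
  cat(sprintf("Validation check '%s': statistic = %.4g, threshold = %.3g -> %s\n",
              x$check, x$statistic, x$threshold,
              if (isTRUE(x$verdict)) "PASS" else "FAIL"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Interpolate curves linearly in lnS onto the common support of a coordinate
# (Delta or b). No extrapolation: the grid is the first curve's points inside
# the intersection of ranges.
.common_grid <- function(xs, ys, ses = NULL) {
  lo <- max(vapply(xs, min, numeric(1)))
  hi <- min(vapply(xs, max, numeric(1)))
  if (lo >= hi) stop("curves have empty common support")
  grid <- xs[[1]][xs[[1]] >= lo & xs[[1]] <= hi]
  if (length(grid) < 3) stop("fewer than 3 points on the common support")
  Y <- vapply(seq_along(xs), function(i) {
    stats::approx(xs[[i]], ys[[i]], xout = grid)$y
  }, numeric(length(grid)))
  SE <- NULL
  if (!is.null(ses) && all(!vapply(ses, is.null, logical(1)))) {
    SE <- vapply(seq_along(xs), function(i) {
      stats::approx(xs[[i]], ses[[i]], xout = grid)$y
    }, numeric(length(grid)))
  }
  list(grid = grid, Y = Y, SE = SE)
}

# Normalized RMS of pairwise differences between rescaled curves; if per-point
# standard errors are available the pairwise differences are inverse-variance
# weighted, which keeps noisy large-Delta points from dominating.
.collapse_statistic <- function(Y, SE = NULL) {
  nc <- ncol(Y)
  num <- 0; den <- 0
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    d2 <- (Y[, i] - Y[, j])^2
    w <- if (is.null(SE)) rep(1, nrow(Y)) else 1 / (SE[, i]^2 + SE[, j]^2 + 1e-300)
    num <- num + sum(w * d2)
    den <- den + sum(w)
  }
  rms_diff <- sqrt(num / den)
  rms_mag <- sqrt(mean(Y^2))
  rms_diff / rms_mag
}

.check_curves_arg <- function(curves, n_min = 2L) {
  if (inherits(curves, "attenuation_curve")) curves <- list(curves)
  if (length(curves) < n_min)
    stop("needs >= ", n_min, " acquisition conditions (attenuation curves)")
  lapply(curves, function(c) stopifnot(inherits(c, "attenuation_curve")))
  curves
}

.drop_na_pts <- function(c) {
  k <- !is.na(c$lnS)
  list(Delta = c$Delta[k], lnS = c$lnS[k],
       se = if (is.null(c$se_lnS)) NULL else c$se_lnS[k])
}

#' g-squared collapse check
#'
#' For curves acquired with equal pulse duration `delta` but different
#' gradient strengths, the rescaled signals \eqn{g^{-2}\ln S/S(0)} collapse
#' onto one curve if (and only if) the underlying process is Gaussian with
#' stationary increments. The statistic is the RMS of pairwise differences of
#' the rescaled signals on the common `Delta` support, normalized by the RMS
#' magnitude of the pooled rescaled signal; the check passes when it is below
#' `threshold`.
#'
#' @param curves list of >= 2 [attenuation_curve]s with equal `delta` and at
#'   least two distinct `g`.
#' @param threshold pass threshold on the normalized RMS statistic.
#' @return A `"pfg_check"` object.
#' @export
g2_collapse_check <- function(curves, threshold = 0.05) {
  curves <- .check_curves_arg(curves)
  deltas <- vapply(curves, `[[`, numeric(1), "delta")
  gs <- vapply(curves, `[[`, numeric(1), "g")
  if (length(unique(deltas)) != 1L)
    stop("g2 collapse check needs equal 'delta' across curves")
  if (length(unique(gs)) < 2L)
    stop("g2 collapse check needs at least two distinct 'g'")
  pts <- lapply(curves, .drop_na_pts)
  cg <- .common_grid(lapply(pts, `[[`, "Delta"),
                     Map(function(p, g) p$lnS / g^2, pts, gs),
                     Map(function(p, g) if (is.null(p$se)) NULL else p$se / g^2,
                         pts, gs))
  stat <- .collapse_statistic(cg$Y, cg$SE)
  .new_check("g2_collapse", stat, threshold, stat < threshold,
             data.frame(Delta = cg$grid, cg$Y))
}

#' Pulse-duration difference check (f constancy)
#'
#' For two curves acquired at the same `g` but different pulse durations
#' \eqn{\delta_1, \delta_2}, the function
#' \deqn{f(\delta_1,\delta_2)(\Delta) = (\gamma g)^{-2}
#'  \left[\delta_1^{-2}\ln S_1 - \delta_2^{-2}\ln S_2\right]}
#' is independent of \eqn{\Delta} for Gaussian stationary-increment
#' processes (for the anomalous closed form it equals
#' \eqn{2 D_\alpha(\delta_1^\alpha - \delta_2^\alpha)/((\alpha+1)(\alpha+2))}).
#' The statistic is the relative drift of the regression line of f over the
#' common `Delta` window: `|slope| * (Delta_max - Delta_min) / |mean f|`.
#'
#' @param curves list of 2 [attenuation_curve]s with equal `g`.
#' @param threshold pass threshold on the relative drift.
#' @return A `"pfg_check"` object.
#' @export
delta_f_check <- function(curves, threshold = 0.1) {
  curves <- .check_curves_arg(curves)
  if (length(curves) != 2L) stop("delta_f check takes exactly 2 curves")
  gs <- vapply(curves, `[[`, numeric(1), "g")
  gammas <- vapply(curves, `[[`, numeric(1), "gamma")
  if (gs[1] != gs[2]) stop("delta_f check needs equal 'g'")
  d1 <- curves[[1]]$delta; d2 <- curves[[2]]$delta
  pts <- lapply(curves, .drop_na_pts)
  if (d1 == d2) {
    cg <- .common_grid(lapply(pts, `[[`, "Delta"), lapply(pts, `[[`, "lnS"))
    f <- (cg$Y[, 1] - cg$Y[, 2]) / (gammas[1] * gs[1] * d1)^2
    return(.new_check("delta_f_constancy", 0, threshold, TRUE,
                      data.frame(Delta = cg$grid, f = f),
                      note = "degenerate: delta_1 = delta_2, f identically 0"))
  }
  cg <- .common_grid(lapply(pts, `[[`, "Delta"),
                     Map(function(p, d) p$lnS / d^2, pts, c(d1, d2)))
  f <- (cg$Y[, 1] - cg$Y[, 2]) / (gammas[1] * gs[1])^2
  sl <- stats::coef(stats::lm(f ~ cg$grid))[2]
  drift <- abs(sl) * diff(range(cg$grid))
  stat <- drift / max(abs(mean(f)), 1e-300)
  .new_check("delta_f_constancy", stat, threshold, stat < threshold,
             data.frame(Delta = cg$grid, f = f))
}

#' b-value collapse check
#'
#' Superstatistical (Brownian yet non-Gaussian) signals depend on the
#' acquisition only through the b-value, so curves acquired at different
#' `(g, delta)` collapse when re-indexed by
#' \eqn{b = \gamma^2 g^2 \delta^2(\Delta - \delta/3)}. The statistic is the
#' normalized RMS pairwise difference on the common b support.
#'
#' @param curves list of >= 2 [attenuation_curve]s differing in `g` and/or
#'   `delta`.
#' @param threshold pass threshold on the normalized RMS statistic.
#' @return A `"pfg_check"` object.
#' @export
b_collapse_check <- function(curves, threshold = 0.05) {
  curves <- .check_curves_arg(curves)
  cond <- vapply(curves, function(c) paste(c$g, c$delta), character(1))
  if (length(unique(cond)) < 2L)
    stop("b collapse check needs at least two distinct (g, delta) conditions")
  pts <- lapply(curves, .drop_na_pts)
  bs <- Map(function(c, p) {
    c$gamma^2 * c$g^2 * c$delta^2 * (p$Delta - c$delta / 3)
  }, curves, pts)
  cg <- .common_grid(bs, lapply(pts, `[[`, "lnS"), lapply(pts, `[[`, "se"))
  stat <- .collapse_statistic(cg$Y, cg$SE)
  .new_check("b_collapse", stat, threshold, stat < threshold,
             data.frame(b = cg$grid, cg$Y))
}

#' Flowchart classification of a set of attenuation curves
#'
#' Implements the validation-rule sequence that selects the legitimate
#' fitting formula. (1) Curves acquired at different `g` (equal `delta`)
#' and/or different `delta` (equal `g`) are rescaled and tested for collapse
#' ([g2_collapse_check], [delta_f_check]). (2) If the Gaussian-stationary
#' rescalings hold, the log-derivative trend ([classify_trend]) selects the
#' normal (full Brownian / Stejskal-Tanner) or anomalous formula. (3) If they
#' fail, a [b_collapse_check] passing indicates the superstatistical family.
#' (4) Otherwise the set is unclassified and none of the built-in formulas
#' applies.
#'
#' @param curves list of >= 2 [attenuation_curve]s spanning at least two
#'   acquisition conditions (two `g` at equal `delta`, or two `delta` at
#'   equal `g`).
#' @param g2_threshold,f_threshold,b_threshold check thresholds (see the
#'   individual checks).
#' @param level confidence level for the derivative-trend classification.
#' @return An object of class `"pfg_classification"`: the checks run, the
#'   final `classification` label (`gaussian_stationary_normal`,
#'   `gaussian_stationary_subdiffusive`, `gaussian_stationary_superdiffusive`,
#'   `brownian_non_gaussian` or `unclassified`) and the `recommended_formula`
#'   (`"bm"`, `"anomalous"`, `"ss_gamma/ss_gaussian"` or `"none"`).
#' @export
pfg_classify <- function(curves, g2_threshold = 0.05, f_threshold = 0.1,
                         b_threshold = 0.05, level = 0.95) {
  curves <- .check_curves_arg(curves, n_min = 1L)
  deltas <- vapply(curves, `[[`, numeric(1), "delta")
  gs <- vapply(curves, `[[`, numeric(1), "g")
  checks <- list()

  # g2 collapse within each equal-delta group holding >= 2 distinct g
  for (d in unique(deltas)) {
    idx <- which(deltas == d)
    if (length(unique(gs[idx])) >= 2)
      checks <- c(checks, list(g2_collapse_check(curves[idx], g2_threshold)))
  }
  # delta_f across pairs with equal g and distinct delta
  for (gv in unique(gs)) {
    idx <- which(gs == gv)
    dd <- unique(deltas[idx])
    if (length(dd) >= 2) {
      i1 <- idx[match(dd[1], deltas[idx])]
      i2 <- idx[match(dd[2], deltas[idx])]
      checks <- c(checks, list(delta_f_check(curves[c(i1, i2)], f_threshold)))
    }
  }
  if (length(checks) == 0)
    stop("cannot classify: need two acquisition conditions ",
         "(two g at equal delta, or two delta at equal g)")

  gaussian_ok <- all(vapply(checks, `[[`, logical(1), "verdict"))
  if (gaussian_ok) {
    trends <- vapply(curves, function(c) {
      # noisy simulated curves get a wider difference baseline: the
      # pointwise derivative of a Monte-Carlo curve is too scattered for a
      # useful trend regression
      stride <- if (is.null(c$se_lnS)) 1L else 3L
      tryCatch(classify_trend(log_derivative(c, stride = stride), level)$trend,
               error = function(e) "unclassified")
    }, character(1))
    # majority vote among classifiable curves; ties go to the least
    # attenuated curve (smallest g^2 delta^2), whose derivative estimate is
    # the most reliable
    ord <- order(vapply(curves, function(c) c$g^2 * c$delta^2, numeric(1)))
    votes <- trends[ord]
    votes <- votes[votes != "unclassified"]
    trend <- if (length(votes) == 0) "unclassified" else {
      tb <- table(votes)
      winners <- names(tb)[tb == max(tb)]
      votes[votes %in% winners][1]
    }
    out <- switch(trend,
      normal = list(cls = "gaussian_stationary_normal", formula = "bm"),
      subdiffusive = list(cls = "gaussian_stationary_subdiffusive",
                          formula = "anomalous"),
      superdiffusive = list(cls = "gaussian_stationary_superdiffusive",
                            formula = "anomalous"),
      list(cls = "unclassified", formula = "none"))
    return(structure(list(checks = checks, trend = trend,
                          classification = out$cls,
                          recommended_formula = out$formula),
                     class = "pfg_classification"))
  }

  bchk <- tryCatch(b_collapse_check(curves, b_threshold), error = function(e) e)
  if (inherits(bchk, "error")) {
    return(structure(list(checks = checks, trend = NA_character_,
                          classification = "unclassified",
                          recommended_formula = "none",
                          note = conditionMessage(bchk)),
                     class = "pfg_classification"))
  }
  checks <- c(checks, list(bchk))
  if (bchk$verdict) {
    structure(list(checks = checks, trend = NA_character_,
                   classification = "brownian_non_gaussian",
                   recommended_formula = "ss_gamma/ss_gaussian"),
              class = "pfg_classification")
  } else {
    structure(list(checks = checks, trend = NA_character_,
                   classification = "unclassified",
                   recommended_formula = "none"),
              class = "pfg_classification")
  }
}

#' @export
print.pfg_classification <- function(x, ...) {
  cat("PFG validation-rule classification\n")
  for (ch in x$checks)
    cat(sprintf("  %-18s stat = %.4g (thr %.3g): %s\n", ch$check, ch$statistic,
                ch$threshold, if (ch$verdict) "pass" else "fail"))
  if (!is.na(x$trend)) cat("  derivative trend:", x$trend, "\n")
  cat(sprintf("  => %s; recommended fitting formula: %s\n",
              x$classification, x$recommended_formula))
  invisible(x)
}

#' Rescaled-overlay plot of a curve set
#'
#' Plots the curves rescaled by \eqn{1/g^2} against `Delta` (the
#' Gaussian-stationary collapse view) or as raw \eqn{\ln S/S(0)} against the
#' b-value (the superstatistical collapse view).
#'
#' @param curves list of [attenuation_curve]s.
#' @param by `"g2"` or `"b"`.
#' @param ... further arguments to [graphics::matplot].
#' @return Invisibly, the plotted matrix.
#' @export
plot_collapse <- function(curves, by = c("g2", "b"), ...) {
  by <- match.arg(by)
  curves <- .check_curves_arg(curves, n_min = 1L)
  if (by == "g2") {
    for (i in seq_along(curves)) {
      c <- curves[[i]]
      if (i == 1)
        graphics::plot(c$Delta, c$lnS / c$g^2, xlab = expression(Delta ~ "(s)"),
                       ylab = expression(g^-2 ~ ln ~ S / S[0]), col = i, ...)
      else graphics::points(c$Delta, c$lnS / c$g^2, col = i, ...)
    }
  } else {
    for (i in seq_along(curves)) {
      c <- curves[[i]]
      b <- c$gamma^2 * c$g^2 * c$delta^2 * (c$Delta - c$delta / 3)
      if (i == 1)
        graphics::plot(b, c$lnS, xlab = expression(b ~ (s / m^2)),
                       ylab = expression(ln ~ S / S[0]), col = i, ...)
      else graphics::points(b, c$lnS, col = i, ...)
    }
  }
  invisible(NULL)
}
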