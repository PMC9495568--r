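#' Classify the release mechanism from the power-law exponent
#'
#' For spherical particles the Korsmeyer-Peppas exponent `n` maps to a
#' transport regime: `n <= 0.43` Fickian diffusion (Case I),
#' `0.43 < n < 0.85` anomalous (non-Fickian) transport,
#' `0.85 <= n <= 1` Case II (relaxation-controlled) transport and
#' `n > 1` Super Case II. The published threshold remarks overlap at
#' exactly 0.43 and 0.85; the boundaries are assigned to the outer
#' categories (fickian at 0.43, case_II at 0.85), making the
#' classification a total piecewise-constant function of `n`.
#'
#' @param n release exponent (finite scalar).
#' @param geometry particle geometry; only `"sphere"` thresholds are
#'   implemented.
#' @return A `mechanism_call` list with `scheme = "kp_exponent"`,
#'   `category` and `evidence` (the exponent).
#' @examples
#' classify_kp_exponent(0.406)$category  # fickian
#' classify_kp_exponent(0.6389)$category # non_fickian
#' @export
classify_kp_exponent <- function(n, geometry = "sphere") {
  geometry <- match.arg(geometry, "sphere")
  stop_if_not_scalar_number(n, "n")
  category <- if (n <= 0.43) {
    "fickian"
  } else if (n < 0.85) {
    "non_fickian"
  } else if (n <= 1) {
    "case_II"
  } else {
    "super_case_II"
  }
  structure(list(scheme = "kp_exponent", category = category,
                 evidence = c(n = n), geometry = geometry),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s: %s\n", x$scheme, x$category))
  cat("  evidence:",
      paste(sprintf("%s = %.6g", names(x$evidence), x$evidence),
            collapse = ", "), "\n")
  invisible(x)
}

#' Diffusion vs relaxation dominance from a Peppas-Sahlin fit
#'
#' Integrates the diffusional term `k1 t^m` and the relaxational term
#' `k2 t^(2m)` over the observation window and calls the mechanism that
#' contributes more to release. With `dominance = "signed"` (default)
#' the larger *signed* integrated contribution wins: a term with a
#' negative coefficient opposes release and cannot be the dominant
#' release mechanism, which is what makes fits with one negative
#' coefficient (common in published tables) classify by the sign
#' pattern. `dominance = "absolute"` compares absolute integrated
#' contributions instead.
#'
#' The pointwise relaxation/Fickian ratio `R/F = (k2/k1) t^m` is
#' reported at the window end when `k1 != 0`.
#'
#' @param fit a `model_fit` from [fit_peppas_sahlin()].
#' @param window numeric `c(t_min, t_max)` in minutes; defaults to the
#'   fitted time range.
#' @param dominance `"signed"` or `"absolute"`.
#' @return A `mechanism_call` with `scheme = "ps_dominance"`, `category`
#'   `"mainly_diffusion"` or `"mainly_relaxation"`, and `evidence`
#'   holding both integrated contributions and the endpoint R/F ratio.
#' @export
ps_contributions <- function(fit, window = NULL,
                             dominance = c("signed", "absolute")) {
  dominance <- match.arg(dominance)
  stopifnot(inherits(fit, "model_fit"),
            identical(fit$model_id, "peppas_sahlin"))
  p <- fit$params
  if (p$k1 == 0 && p$k2 == 0) {
    stop("k1 and k2 are both zero: no transport contributions")
  }
  if (is.null(window)) window <- range(fit$time)
  t0 <- max(0, window[1L])
  t1 <- window[2L]
  if (!(t1 > t0)) stop("`window` must span a positive time interval")
  int_pow <- function(a, e) a / (e + 1) * (t1^(e + 1) - t0^(e + 1))
  diff_int <- int_pow(p$k1, p$m)
  relax_int <- int_pow(p$k2, 2 * p$m)
  if (dominance == "signed") {
    category <- if (diff_int >= relax_int) "mainly_diffusion" else
      "mainly_relaxation"
  } else {
    category <- if (abs(diff_int) >= abs(relax_int)) "mainly_diffusion" else
      "mainly_relaxation"
  }
  rf_end <- if (p$k1 != 0) (p$k2 / p$k1) * t1^p$m else NA_real_
  structure(list(scheme = "ps_dominance", category = category,
                 evidence = c(diffusion_integral = diff_int,
                              relaxation_integral = relax_int,
                              rf_ratio_end = rf_end),
                 dominance = dominance, window = c(t0, t1)),
            class = "mechanism_call")
}

#' Estimate growth and release rates for the Damkohler number
#'
#' The growth rate is the specific (exponential) growth rate: the slope
#' of `ln(density)` against time over the window. The release rate is a
#' first-order release constant: the negated slope of `ln(1 - Mt/Minf)`
#' against time. Both are returned in per-minute units; growth curves
#' tagged in hours are converted. The two raw regression slopes are
#' attached for transparency.
#'
#' @param growth a [growth_curve()].
#' @param release a [release_curve()].
#' @param window numeric `c(t_min, t_max)` in minutes.
#' @return List with `growth_rate` and `release_rate` (per minute) and
#'   attribute `slopes`.
#' @export
estimate_rates <- function(growth, release,
                           window = range(release$time_min)) {
  stopifnot(inherits(growth, "growth_curve"),
            inherits(release, "release_curve"))
  g_scale <- if (attr(growth, "time_unit") == "hours") 60 else 1
  g_t <- growth$time * g_scale
  g_in <- g_t >= window[1L] & g_t <= window[2L]
  r_in <- release$time_min >= window[1L] & release$time_min <= window[2L]
  if (sum(g_in) < 3L || sum(r_in) < 3L) {
    stop("need at least 3 points of each series inside the window")
  }
  dens <- growth$density[g_in]
  if (any(dens <= 0)) stop("nonpositive densities in log transform")
  f <- release$fraction_released[r_in]
  if (any(f >= 1)) stop("release fraction >= 1 inside window")
  if (any(f < 0)) stop("negative release fraction inside window")
  g_slope <- ls_line(g_t[g_in], log(dens))[["slope"]]
  r_slope <- ls_line(release$time_min[r_in], log(1 - f))[["slope"]]
  structure(list(growth_rate = g_slope, release_rate = -r_slope),
            slopes = c(log_density_slope = g_slope,
                       log_unreleased_slope = r_slope))
}

#' Damkohler number of growth/release coupling
#'
#' `Da = growth_rate / release_rate`, the dimensionless ratio of the
#' reaction rate (cell growth inside the bead) to the transport rate
#' (cell release into the medium). `Da > 1` means the system is
#' reaction-governed (cells accumulate in / are trapped by the bead);
#' `Da < 1` means transport governs and cells leave faster than they
#' are produced.
#'
#' @param growth_rate specific growth rate (per minute).
#' @param release_rate first-order release constant (per minute), > 0.
#' @return A `damkohler_result` list with `growth_rate`, `release_rate`,
#'   `da` and `regime` (`"reaction_governed"`, `"transport_governed"` or
#'   `"boundary"`).
#' @examples
#' damkohler(0.012, 0.010)$da # 1.2
#' @export
damkohler <- function(growth_rate, release_rate) {
  stop_if_not_scalar_number(growth_rate, "growth_rate")
  stop_if_not_scalar_number(release_rate, "release_rate", 0,
                            strict_lower = TRUE)
  da <- growth_rate / release_rate
  regime <- if (da > 1) "reaction_governed" else if (da < 1)
    "transport_governed" else "boundary"
  structure(list(growth_rate = growth_rate, release_rate = release_rate,
                 da = da, regime = regime),
            class = "damkohler_result")
}

#' @export
print.damkohler_result <- function(x, ...) {
  cat(sprintf("<damkohler> Da = %.4g (%s)\n", x$da, x$regime))
  invisible(x)
}

#' Find the release/viability equilibrium point
#'
#' First time at which the released (medium) and retained (in-bead)
#' viable cell series are equal: the first sign change of
#' `medium - inbead`, located by linear interpolation between the
#' bracketing samples. Exact equality at a sample returns that sample
#' time. Returns `NA` when the series never cross.
#'
#' @param medium,inbead CFU/mL series of equal length >= 2.
#' @param times sampling times in minutes.
#' @return Equilibrium time in minutes, or `NA_real_` if none.
#' @export
find_equilibrium_time <- function(medium, inbead, times) {
  if (length(medium) != length(inbead) ||
      length(medium) != length(times)) {
    stop("`medium`, `inbead` and `times` must have equal length")
  }
  if (length(times) < 2L) stop("need at least 2 samples")
  d <- medium - inbead
  if (d[1L] == 0) return(times[1L])
  for (i in seq_len(length(d) - 1L)) {
    if (d[i + 1L] == 0) return(times[i + 1L])
    if (sign(d[i]) != sign(d[i + 1L])) {
      # linear interpolation between the bracketing samples
      w <- d[i] / (d[i] - d[i + 1L])
      return(times[i] + w * (times[i + 1L] - times[i]))
    }
  }
  NA_real_
}
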