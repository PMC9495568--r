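#' Simulate a paired medium / in-bead viability experiment
#'
#' Couples a release law with in-bead population dynamics over the
#' digestion timeline. At every time the medium holds
#' `total_cfu * f(t)` cells (f = noiseless clipped release fraction)
#' while the bead retains `total_cfu * (1 - f(t))` cells whose viable
#' count is additionally scaled by a net growth/death factor
#' `G(t) = exp(integral of (mu/60 - death(phase)) dt)` with `mu` the
#' specific growth rate per hour of `inbead_growth` and `death` the
#' per-minute death rate of the current phase. Growth is treated as
#' exponential over the (short) digestion window; logistic saturation of
#' the interior population is deliberately not modelled here.
#'
#' The analytic crossing time of the two noiseless series (the
#' "equilibrium point" where released and retained viable cells are
#' equal) is located by scanning followed by bisection and returned as
#' ground truth, or `NA` when the curves do not cross.
#'
#' Observed CFU series receive multiplicative log-normal noise of
#' `cfu_noise_sd_log10` decades, the conventional plate-count error
#' scale.
#'
#' @param total_cfu total encapsulated viable cells (CFU), > 0. Used as
#'   `m_infinity` of the returned curve.
#' @param release_truth [kinetic_truth()] for the release fraction.
#' @param inbead_growth optional [growth_truth()]; only its `mu` (per
#'   hour) is used. `NULL` means no growth.
#' @param death_rate_per_phase named per-minute death rates covering
#'   every phase of the timeline, e.g.
#'   `c(oral = 0, gastric = 0.001, intestinal = 0)`.
#' @param timepoints sampling times in minutes.
#' @param cfu_noise_sd_log10 sd of log10 multiplicative noise on both
#'   CFU series (default 0.1; 0 for noiseless pairs).
#' @param seed integer seed.
#' @param timeline [phase_timeline()].
#' @return A list of class `digestion_pair` with elements `curve` (a
#'   [release_curve()] carrying `cfu_medium_per_ml` and
#'   `cfu_inbead_per_ml`), `crossing_min` (analytic noiseless crossing
#'   time, or `NA` if none) and `noiseless` (data.frame of the exact
#'   series).
#' @export
simulate_digestion_pair <- function(total_cfu, release_truth,
                                    inbead_growth = NULL,
                                    death_rate_per_phase = c(
                                      oral = 0, gastric = 0, intestinal = 0),
                                    timepoints = release_schedule(),
                                    cfu_noise_sd_log10 = 0.1,
                                    seed = 1L,
                                    timeline = phase_timeline()) {
  stop_if_not_scalar_number(total_cfu, "total_cfu", 0, strict_lower = TRUE)
  stopifnot(inherits(release_truth, "kinetic_truth"))
  if (!is.null(inbead_growth)) stopifnot(inherits(inbead_growth,
                                                  "growth_truth"))
  check_increasing_times(timepoints)
  missing <- setdiff(timeline$phase, names(death_rate_per_phase))
  if (length(missing)) {
    stop(sprintf("`death_rate_per_phase` is missing phase(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (any(death_rate_per_phase < 0)) stop("death rates must be >= 0")

  mu_min <- if (is.null(inbead_growth)) 0 else inbead_growth$mu / 60

  frac_fun <- function(t) {
    clip01(release_model_fraction(release_truth$model_id,
                                  release_truth$params, t))
  }
  # cumulative net log-growth: piecewise-linear in t (rates constant per
  # phase), evaluated exactly from the timeline boundaries
  net_rate <- mu_min - death_rate_per_phase[timeline$phase]
  growth_factor <- function(t) {
    expo <- numeric(length(t))
    for (i in seq_len(nrow(timeline))) {
      lo <- timeline$start_min[i]
      hi <- timeline$end_min[i]
      dur <- pmin(pmax(t, lo), hi) - lo
      dur[dur < 0] <- 0
      # beyond the timeline end: carry the last phase's rate forward
      if (i == nrow(timeline)) dur <- pmax(t, lo) - lo
      expo <- expo + net_rate[i] * pmax(dur, 0)
    }
    exp(expo)
  }

  medium_fun <- function(t) total_cfu * frac_fun(t)
  inbead_fun <- function(t) total_cfu * (1 - frac_fun(t)) * growth_factor(t)

  crossing <- find_crossing_bisection(function(t) medium_fun(t) - inbead_fun(t),
                                      lower = min(timepoints),
                                      upper = max(timepoints))

  med0 <- medium_fun(timepoints)
  inb0 <- inbead_fun(timepoints)
  noisy <- with_seed(seed, {
    ln_sd <- cfu_noise_sd_log10 * log(10)
    list(med = med0 * exp(rnorm(length(med0), 0, ln_sd)),
         inb = inb0 * exp(rnorm(length(inb0), 0, ln_sd)))
  })

  curve <- release_curve(timepoints, frac_fun(timepoints),
                         cfu_medium = noisy$med, cfu_inbead = noisy$inb,
                         m_infinity = total_cfu, timeline = timeline)
  attr(curve, "truth") <- release_truth
  structure(list(curve = curve,
                 crossing_min = crossing,
                 noiseless = data.frame(time_min = timepoints,
                                        cfu_medium = med0,
                                        cfu_inbead = inb0)),
            class = "digestion_pair")
}

# First sign change of a continuous function on [lower, upper], located
# by a fine scan followed by bisection. Returns NA when no change.
find_crossing_bisection <- function(fn, lower, upper, scan_by = 0.1,
                                    tol = 1e-6) {
  grid <- seq(lower, upper, by = scan_by)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  v <- fn(grid)
  if (v[1L] == 0) return(grid[1L])
  sgn <- sign(v)
  idx <- which(sgn[-1L] * sgn[-length(sgn)] <= 0 & sgn[-1L] != sgn[-length(sgn)])
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  lo <- grid[i]; hi <- grid[i + 1L]
  if (v[i + 1L] == 0) return(hi)
  stats::uniroot(fn, c(lo, hi), tol = tol)$root
}
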