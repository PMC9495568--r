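#' Kinetic ground truth for synthetic release curves
#'
#' Describes the noiseless release law and the noise level used by
#' [simulate_release_curve()]. The four supported laws are
#'
#' * `zero_order`: Mt/Minf = k t
#' * `higuchi`: Mt/Minf = k sqrt(t)
#' * `korsmeyer_peppas`: Mt/Minf = k t^n
#' * `peppas_sahlin`: Mt/Minf = k1 t^m + k2 t^(2m)
#'
#' @param model_id one of `"zero_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`, `"peppas_sahlin"`.
#' @param params named numeric vector/list with the parameters the model
#'   requires (`k`; `k, n`; or `k1, k2, m`). Units follow the model:
#'   `k` is per min (zero-order), per min^0.5 (Higuchi) or per min^n
#'   (Korsmeyer-Peppas); `k1` is per min^m and `k2` per min^(2m).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   fraction released (dimensionless, >= 0). Default 0.02, a
#'   conventional triplicate-scale measurement error.
#' @param seed integer seed making the generated curve reproducible.
#' @return An object of class `kinetic_truth`.
#' @examples
#' kinetic_truth("korsmeyer_peppas", c(k = 0.05, n = 0.5), noise_sd = 0)
#' @export
kinetic_truth <- function(model_id, params, noise_sd = 0.02, seed = 1L) {
  model_id <- match.arg(model_id, release_model_ids())
  params <- as.list(params)
  req <- release_model_params(model_id)
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    stop(sprintf("model '%s' requires parameter(s): %s",
                 model_id, paste(missing, collapse = ", ")))
  }
  for (p in req) stop_if_not_scalar_number(params[[p]], p)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(model_id = model_id, params = params[req],
                 noise_sd = noise_sd, seed = seed),
            class = "kinetic_truth")
}

release_model_ids <- function() {
  c("zero_order", "higuchi", "korsmeyer_peppas", "peppas_sahlin")
}

release_model_params <- function(model_id) {
  switch(model_id,
         zero_order = "k",
         higuchi = "k",
         korsmeyer_peppas = c("k", "n"),
         peppas_sahlin = c("k1", "k2", "m"),
         stop(sprintf("unknown model_id '%s'", model_id)))
}

#' Evaluate a release model
#'
#' Noiseless model fraction at given times (not clipped).
#'
#' @param model_id model identifier, see [kinetic_truth()].
#' @param params named parameters for that model.
#' @param t times in minutes.
#' @return Numeric vector of model fractions.
#' @export
release_model_fraction <- function(model_id, params, t) {
  model_id <- match.arg(model_id, release_model_ids())
  p <- as.list(params)
  switch(model_id,
         zero_order = p$k * t,
         higuchi = p$k * sqrt(t),
         korsmeyer_peppas = p$k * t^p$n,
         peppas_sahlin = p$k1 * t^p$m + p$k2 * t^(2 * p$m))
}

#' Simulate a release curve
#'
#' Evaluates the noiseless model curve at the sampling times, clips it to
#' `[0, 1]`, adds Gaussian noise of sd `noise_sd` and clips again to the
#' physical range. The generating truth is attached to the result so that
#' recovery can be validated.
#'
#' @param truth a [kinetic_truth()].
#' @param timepoints sampling times in minutes, strictly increasing,
#'   first >= 0. Defaults to the 15-point schedule [release_schedule()].
#' @param timeline [phase_timeline()] used for phase labels.
#' @return A [release_curve()] with attribute `truth`.
#' @examples
#' tr <- kinetic_truth("korsmeyer_peppas", c(k = 0.05, n = 0.5),
#'                     noise_sd = 0)
#' simulate_release_curve(tr)
#' @export
simulate_release_curve <- function(truth, timepoints = release_schedule(),
                                   timeline = phase_timeline()) {
  stopifnot(inherits(truth, "kinetic_truth"))
  check_increasing_times(timepoints)
  f0 <- clip01(release_model_fraction(truth$model_id, truth$params,
                                      timepoints))
  f <- with_seed(truth$seed, f0 + rnorm(length(f0), 0, truth$noise_sd))
  f <- clip01(f)
  out <- release_curve(timepoints, f, timeline = timeline)
  attr(out, "truth") <- truth
  out
}

#' Growth ground truth (logistic)
#'
#' Logistic growth `n(t) = K / (1 + ((K - n0)/n0) exp(-mu t))`. Defaults
#' are calibrated so that the noiseless curve plateaus near an optical
#' density of 1.34 by 12 h, the scale at which a yeast preculture peaks
#' at the end of its logarithmic phase.
#'
#' @param n0 initial density (> 0); O.D. or CFU/mL units.
#' @param capacity carrying capacity (>= n0).
#' @param mu specific growth rate per hour (>= 0). Default 0.55/h.
#' @param noise_sd additive Gaussian noise sd on density.
#' @param seed integer seed.
#' @return Object of class `growth_truth`.
#' @export
growth_truth <- function(n0 = 0.05, capacity = 1.34, mu = 0.55,
                         noise_sd = 0.02, seed = 1L) {
  stop_if_not_scalar_number(n0, "n0", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(capacity, "capacity", n0)
  stop_if_not_scalar_number(mu, "mu", 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(n0 = n0, capacity = capacity, mu = mu,
                 noise_sd = noise_sd, seed = seed),
            class = "growth_truth")
}

logistic_density <- function(truth, t_hours) {
  K <- truth$capacity
  A <- (K - truth$n0) / truth$n0
  K / (1 + A * exp(-truth$mu * t_hours))
}

#' Simulate a growth curve
#'
#' Logistic density evaluated at the sampling times plus Gaussian noise,
#' floored at 0.
#'
#' @param truth a [growth_truth()].
#' @param timepoints sampling times in hours, strictly increasing.
#' @return A [growth_curve()] (hours, O.D. units) with attribute `truth`.
#' @export
simulate_growth_curve <- function(truth, timepoints = seq(0, 24, by = 1)) {
  stopifnot(inherits(truth, "growth_truth"))
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing")
  }
  d0 <- logistic_density(truth, timepoints)
  d <- with_seed(truth$seed, d0 + rnorm(length(d0), 0, truth$noise_sd))
  d <- pmax(0, d)
  out <- growth_curve(timepoints, d, time_unit = "hours",
                      density_unit = "OD")
  attr(out, "truth") <- truth
  out
}
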