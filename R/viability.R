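#' Digestion-phase timeline
#'
#' Constructs the ordered oral/gastric/intestinal phase timeline used to
#' label sampling times during simulated gastrointestinal digestion. The
#' default follows the standardized static in vitro digestion protocol:
#' a 2-minute oral phase at pH 7, a 2-hour gastric phase at pH 3 and a
#' 2-hour intestinal phase at pH 7. The intestinal phase is extended to
#' 250 min so that a sampling schedule that outlasts the nominal 242-min
#' protocol can still be labelled.
#'
#' Intervals are half-open `[start, end)`; the final endpoint is
#' inclusive, so every time in `[0, end]` receives exactly one label.
#'
#' @param phases data.frame with columns `phase`, `start_min`, `end_min`,
#'   `ph`. Must be contiguous, non-overlapping and increasing.
#' @return An object of class `phase_timeline`.
#' @examples
#' tl <- phase_timeline()
#' label_phases(c(0, 2, 125, 250), tl)
#' @export
phase_timeline <- function(phases = data.frame(
                             phase = c("oral", "gastric", "intestinal"),
                             start_min = c(0, 2, 122),
                             end_min = c(2, 122, 250),
                             ph = c(7, 3, 7))) {
  stopifnot(is.data.frame(phases),
            all(c("phase", "start_min", "end_min", "ph") %in% names(phases)))
  if (nrow(phases) < 1L) stop("timeline needs at least one phase")
  if (any(phases$end_min <= phases$start_min)) {
    stop("each phase must have end_min > start_min")
  }
  if (nrow(phases) > 1L) {
    if (any(abs(phases$start_min[-1L] -
                phases$end_min[-nrow(phases)]) > 1e-9)) {
      stop("phases must be contiguous and non-overlapping")
    }
  }
  structure(phases, class = c("phase_timeline", "data.frame"))
}

#' Label sampling times with their digestion phase
#'
#' Assigns each time its phase by half-open interval membership
#' `[start, end)`; the final endpoint of the timeline is inclusive.
#'
#' @param times numeric vector of times in minutes, all within
#'   `[0, max(end)]` of the timeline.
#' @param timeline a [phase_timeline()].
#' @return Character vector of phase labels, one per time.
#' @export
label_phases <- function(times, timeline = phase_timeline()) {
  stopifnot(inherits(timeline, "phase_timeline"))
  if (!is.numeric(times) || anyNA(times)) {
    stop("`times` must be numeric without NA")
  }
  lo <- timeline$start_min[1L]
  hi <- timeline$end_min[nrow(timeline)]
  if (any(times < lo | times > hi)) {
    stop(sprintf("all times must lie within the timeline [%g, %g] min",
                 lo, hi))
  }
  idx <- findInterval(times, timeline$start_min)
  # final endpoint inclusive
  idx[times == hi] <- nrow(timeline)
  timeline$phase[idx]
}

#' Encapsulation efficiency
#'
#' Percentage of initially loaded cells detected in the formulation:
#' `%EE = 100 * w_detected / w_initial`.
#'
#' @param w_detected detected concentration of incorporated cells (CFU).
#' @param w_initial initial concentration used for encapsulation (CFU),
#'   must be positive.
#' @return Efficiency percentage (scalar).
#' @examples
#' encapsulation_efficiency(9.6775e6, 1e7) # 96.775
#' @export
encapsulation_efficiency <- function(w_detected, w_initial) {
  stop_if_not_scalar_number(w_initial, "w_initial", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(w_detected, "w_detected", 0)
  100 * w_detected / w_initial
}

#' Viable count from a serial-dilution plate count
#'
#' Converts a microdrop (Miles-Misra style) colony count at a known
#' dilution into CFU per mL of the undiluted sample:
#' `CFU/mL = colonies / plated_volume * 10^dilution_exponent`.
#'
#' @param colonies colony count on the plated aliquot (>= 0).
#' @param dilution_exponent positive integer `e` for a `10^-e` dilution.
#' @param plated_volume_ml plated aliquot volume in mL (> 0).
#' @return CFU per mL.
#' @examples
#' cfu_from_plate_count(30, 5, 0.01) # 3e8
#' @export
cfu_from_plate_count <- function(colonies, dilution_exponent,
                                 plated_volume_ml) {
  stop_if_not_scalar_number(colonies, "colonies", 0)
  stop_if_not_scalar_number(dilution_exponent, "dilution_exponent")
  stop_if_not_scalar_number(plated_volume_ml, "plated_volume_ml", 0,
                            strict_lower = TRUE)
  colonies / plated_volume_ml * 10^dilution_exponent
}

#' Percent survival of viable cells
#'
#' Survival of a population across a treatment, either as a linear ratio
#' of concentrations or as the ratio of their log10 values (the usual
#' convention for CFU survival through digestion). The scale used is
#' recorded on the result.
#'
#' @param final,initial viable concentrations (CFU/mL), both positive.
#' @param scale `"log10"` (default) or `"linear"`.
#' @return Percentage with attribute `scale`.
#' @examples
#' survival_percent(1e7, 1e8, scale = "log10")  # 87.5
#' survival_percent(1e7, 1e8, scale = "linear") # 10
#' @export
survival_percent <- function(final, initial, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stop_if_not_scalar_number(final, "final", 0, strict_lower = TRUE)
  stop_if_not_scalar_number(initial, "initial", 0, strict_lower = TRUE)
  pct <- if (scale == "linear") {
    100 * final / initial
  } else {
    100 * log10(final) / log10(initial)
  }
  structure(pct, scale = scale)
}
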