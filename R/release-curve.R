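#' Release curve container
#'
#' A release curve holds a sampled fraction-released time series
#' (Mt/Minf), optionally paired CFU series for the digestion medium and
#' the bead interior, and a digestion-phase label per timepoint.
#'
#' @param time_min sampling times in minutes, strictly increasing, >= 0.
#' @param fraction_released Mt/Minf values; small negative / >1 excursions
#'   from measurement noise are tolerated within `[-0.05, 1.05]`.
#' @param cfu_medium,cfu_inbead optional CFU/mL series of the same length.
#' @param phase optional phase label per timepoint; derived from
#'   `timeline` when omitted.
#' @param m_infinity normalization total (CFU) used to form Mt/Minf;
#'   required positive when CFU series are present.
#' @param timeline [phase_timeline()] used to label times.
#' @return A `release_curve` (data.frame subclass) with attribute
#'   `m_infinity`.
#' @export
release_curve <- function(time_min, fraction_released,
                          cfu_medium = NULL, cfu_inbead = NULL,
                          phase = NULL, m_infinity = NA_real_,
                          timeline = phase_timeline()) {
  check_increasing_times(time_min, "time_min")
  if (length(fraction_released) != length(time_min)) {
    stop("`fraction_released` and `time_min` must have equal length")
  }
  if (any(fraction_released < -0.05 | fraction_released > 1.05)) {
    stop("`fraction_released` must lie within [-0.05, 1.05]")
  }
  n <- length(time_min)
  for (s in list(cfu_medium = cfu_medium, cfu_inbead = cfu_inbead)) {
    if (!is.null(s) && length(s) != n) {
      stop("CFU series must match the length of `time_min`")
    }
  }
  if ((!is.null(cfu_medium) || !is.null(cfu_inbead))) {
    if (!is.finite(m_infinity) || m_infinity <= 0) {
      stop("`m_infinity` must be positive when CFU series are present")
    }
  }
  if (is.null(phase)) {
    phase <- label_phases(pmin(time_min, max(timeline$end_min)), timeline)
  }
  df <- data.frame(
    time_min = as.numeric(time_min),
    fraction_released = as.numeric(fraction_released),
    cfu_medium_per_ml = if (is.null(cfu_medium)) NA_real_ else cfu_medium,
    cfu_inbead_per_ml = if (is.null(cfu_inbead)) NA_real_ else cfu_inbead,
    phase = phase,
    stringsAsFactors = FALSE
  )
  structure(df, m_infinity = m_infinity,
            class = c("release_curve", "data.frame"))
}

#' Default in vitro digestion sampling schedule
#'
#' The 15-point sampling schedule (minutes) spanning the oral, gastric
#' and intestinal phases used throughout the package as the default
#' sampling design.
#'
#' @return Numeric vector of 15 sampling times in minutes.
#' @export
release_schedule <- function() {
  c(0, 1, 2, 5, 20, 35, 65, 95, 125, 130, 145, 160, 190, 220, 250)
}

#' Write / read release curves as CSV
#'
#' Columns: `time_min`, `fraction_released`, `cfu_medium_per_ml`,
#' `cfu_inbead_per_ml`, `phase`. `m_infinity` is stored in a
#' `# m_infinity:` comment header line.
#'
#' @param curve a [release_curve()].
#' @param path file path.
#' @return `write_release_csv` returns `path` invisibly;
#'   `read_release_csv` returns a [release_curve()].
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m_infinity: %.17g", attr(curve, "m_infinity")), con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_release_csv
#' @export
read_release_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m_inf <- NA_real_
  if (grepl("^# m_infinity:", first)) {
    m_inf <- as.numeric(sub("^# m_infinity:\\s*", "", first))
  }
  df <- read.csv(path, comment.char = "#")
  cm <- if (all(is.na(df$cfu_medium_per_ml))) NULL else df$cfu_medium_per_ml
  ci <- if (all(is.na(df$cfu_inbead_per_ml))) NULL else df$cfu_inbead_per_ml
  release_curve(df$time_min, df$fraction_released,
                cfu_medium = cm, cfu_inbead = ci,
                phase = df$phase, m_infinity = m_inf)
}

#' Growth curve container
#'
#' @param time sampling times (strictly increasing).
#' @param density optical density or CFU/mL, all >= 0.
#' @param time_unit `"hours"` or `"minutes"`.
#' @param density_unit free-text unit tag (e.g. `"OD"`, `"CFU/mL"`).
#' @return A `growth_curve` data.frame subclass with unit attributes.
#' @export
growth_curve <- function(time, density, time_unit = c("hours", "minutes"),
                         density_unit = "OD") {
  time_unit <- match.arg(time_unit)
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (length(density) != length(time)) {
    stop("`density` and `time` must have equal length")
  }
  if (any(density < 0)) stop("`density` must be >= 0")
  structure(data.frame(time = time, density = density),
            time_unit = time_unit, density_unit = density_unit,
            class = c("growth_curve", "data.frame"))
}
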