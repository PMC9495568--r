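# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  } else {
    code
  }
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

check_increasing_times <- function(times, name = "timepoints") {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop(sprintf("`%s` must be a numeric vector without NA", name),
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
  }
  if (times[1L] < 0) {
    stop(sprintf("`%s` must start at or after 0", name), call. = FALSE)
  }
  invisible(times)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# linear-model slope/intercept without formula overhead
ls_line <- function(x, y) {
  fit <- lm.fit(cbind(1, x), y)
  c(intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L]))
}
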