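#' The 3x3 factorial design grid over wall-material composition
#'
#' Nine treatments crossing agavin and whey-protein percentages at
#' levels 2.5 / 3.75 / 5 (%), using the conventional bead nomenclature
#' AWB1..AWB9 (whey level varying slowest).
#'
#' @return data.frame with columns `treatment`, `agavin_pct`, `whey_pct`.
#' @export
factorial_design_grid <- function() {
  g <- expand.grid(agavin_pct = c(2.5, 3.75, 5),
                   whey_pct = c(2.5, 3.75, 5))
  g <- g[order(g$whey_pct, g$agavin_pct), ]
  data.frame(treatment = paste0("AWB", seq_len(nrow(g))),
             agavin_pct = g$agavin_pct, whey_pct = g$whey_pct,
             row.names = NULL)
}

#' Ground truth for a synthetic factorial experiment
#'
#' Each response is a quadratic surface on coded units
#' `y = b0 + bA a + bW w + bAA a^2 + bWW w^2 + bAW a w`, where
#' `(a, w)` are the coded levels (-1/0/+1) of agavin and whey-protein
#' percentage (see [code_levels()]), plus Gaussian replicate noise.
#'
#' @param coefficients named list; one numeric vector
#'   `c(b0, bA, bW, bAA, bWW, bAW)` per response name.
#' @param replicate_count replicates per treatment (>= 1, default 3).
#' @param noise_sd named vector of per-response noise sds (recycled from
#'   a scalar).
#' @param seed integer seed.
#' @return Object of class `factorial_truth`.
#' @export
factorial_truth <- function(coefficients, replicate_count = 3L,
                            noise_sd = 0, seed = 1L) {
  stopifnot(is.list(coefficients), length(coefficients) >= 1L,
            !is.null(names(coefficients)))
  for (nm in names(coefficients)) {
    b <- coefficients[[nm]]
    if (length(b) != 6L || !is.numeric(b)) {
      stop(sprintf("response '%s' needs 6 coefficients (b0,bA,bW,bAA,bWW,bAW)",
                   nm))
    }
  }
  if (replicate_count < 1L) stop("`replicate_count` must be >= 1")
  if (length(noise_sd) == 1L) {
    noise_sd <- setNames(rep(noise_sd, length(coefficients)),
                         names(coefficients))
  }
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0")
  structure(list(coefficients = coefficients,
                 replicate_count = as.integer(replicate_count),
                 noise_sd = noise_sd, seed = seed),
            class = "factorial_truth")
}

quad_surface_value <- function(b, a, w) {
  b[1] + b[2] * a + b[3] * w + b[4] * a^2 + b[5] * w^2 + b[6] * a * w
}

#' Simulate a factorial dataset
#'
#' One row per treatment x replicate x response, with
#' `value = surface(a, w) + N(0, noise_sd)`.
#'
#' @param truth a [factorial_truth()].
#' @param seed optional seed overriding the truth's.
#' @return Long-format data.frame with columns `treatment`,
#'   `agavin_pct`, `whey_pct`, `replicate`, `response`, `value`.
#' @export
simulate_factorial_experiment <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "factorial_truth"))
  grid <- factorial_design_grid()
  coded <- code_levels(grid$agavin_pct, grid$whey_pct)
  rows <- list()
  with_seed(seed, {
    for (resp in names(truth$coefficients)) {
      b <- truth$coefficients[[resp]]
      mu <- quad_surface_value(b, coded$a, coded$w)
      for (r in seq_len(truth$replicate_count)) {
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = grid$treatment,
          agavin_pct = grid$agavin_pct,
          whey_pct = grid$whey_pct,
          replicate = r,
          response = resp,
          value = mu + rnorm(nrow(grid), 0, truth$noise_sd[[resp]])
        )
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
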