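#' Canonical Peppas-Sahlin sign-pattern scenarios
#'
#' Published Peppas-Sahlin fits for probiotic alginate beads fall into
#' two sign groups: control-type beads with `k1 < 0, k2 > 0`
#' (relaxation-driven release after a lag) and mixed agavin/whey beads
#' with `k1 > 0, k2 < 0` (diffusion-driven release that saturates).
#' This function builds six bead scenarios with those sign patterns and
#' magnitudes chosen so every noiseless curve is a valid release
#' fraction over the 0-250 min digestion window:
#'
#' * relaxation pattern: parameterized by the lag time `t0` at which
#'   release starts and the fraction reached at 250 min;
#' * diffusion pattern: parameterized by the coefficient ratio
#'   `|k2|/|k1|` (small enough that the curve is monotone up to
#'   250 min) and the fraction reached at 250 min.
#'
#' @param m Peppas-Sahlin exponent (default 0.43, spheres).
#' @param t_end end of the observation window in minutes.
#' @return data.frame with columns `bead`, `k1`, `k2`, `m`,
#'   `expected_dominance`.
#' @export
ps_sign_scenarios <- function(m = 0.43, t_end = 250) {
  em <- t_end^m
  e2m <- t_end^(2 * m)
  relax <- function(bead, t0, f_end) {
    k2 <- f_end / (e2m - t0^m * em)
    data.frame(bead = bead, k1 = -k2 * t0^m, k2 = k2, m = m,
               expected_dominance = "mainly_relaxation")
  }
  diffu <- function(bead, ratio, f_end) {
    stopifnot(1 / (2 * ratio) > em) # monotone within the window
    k1 <- f_end / (em - ratio * e2m)
    data.frame(bead = bead, k1 = k1, k2 = -ratio * k1, m = m,
               expected_dominance = "mainly_diffusion")
  }
  out <- rbind(
    relax("B", t0 = 25, f_end = 1.00),
    relax("AB", t0 = 35, f_end = 0.95),
    relax("WB", t0 = 30, f_end = 0.97),
    relax("AWB5", t0 = 45, f_end = 0.85),
    diffu("AWB6", ratio = 1 / 40, f_end = 0.45),
    diffu("AWB8", ratio = 1 / 35, f_end = 0.60)
  )
  rownames(out) <- NULL
  out
}
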