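#' Grey-level co-occurrence matrix texture features
#'
#' Quantizes intensities to `levels` equal-width bins on the 0-255
#' scale, accumulates a symmetric co-occurrence matrix over the given
#' angle set at pixel offset `distance`, normalizes it to sum 1 and
#' derives the classical texture features:
#'
#' * `asm` (angular second moment / energy): `sum(p^2)`
#' * `contrast`: `sum((i - j)^2 p)`
#' * `correlation`: `sum((i - mu_i)(j - mu_j) p) / (sigma_i sigma_j)`
#' * `idm` (inverse difference moment / homogeneity):
#'   `sum(p / (1 + (i - j)^2))`
#' * `entropy`: `-sum(p log p)` with `0 log 0 = 0`; natural log by
#'   default, `log2` available.
#'
#' For a constant image the matrix has a single cell, so `asm = 1`,
#' `contrast = 0`, `idm = 1`, `entropy = 0` and correlation is
#' undefined (`NA`).
#'
#' @param img numeric matrix, intensities in `[0, 255]`.
#' @param mask optional logical matrix; only pixel pairs with both
#'   pixels inside the mask are counted.
#' @param levels number of grey levels G (>= 2), default 8.
#' @param distance pixel offset d (>= 1), default 1.
#' @param angles angles in degrees, subset of {0, 45, 90, 135};
#'   co-occurrences are accumulated (averaged) over the set.
#' @param entropy_base `"e"` (natural log, default) or `"2"`.
#' @return Object of class `glcm_features`: list with the five features,
#'   the normalized matrix `p` and the parameters used.
#' @export
glcm_features <- function(img, mask = NULL, levels = 8L, distance = 1L,
                          angles = c(0, 45, 90, 135),
                          entropy_base = c("e", "2")) {
  entropy_base <- match.arg(entropy_base)
  stopifnot(is.matrix(img))
  if (levels < 2L) stop("`levels` must be >= 2")
  if (distance < 1L) stop("`distance` must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop("`angles` must be a subset of {0, 45, 90, 135}")
  }
  nr <- nrow(img); nc <- ncol(img)
  if (nr <= distance && nc <= distance) {
    stop("image must be larger than `distance`")
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(img)))
  }
  g <- as.integer(levels)
  q <- pmin(floor(img / (256 / g)), g - 1L) # levels 0..G-1
  counts <- matrix(0, g, g)
  d <- as.integer(distance)
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L),
                  `135` = c(-d, -d))
  for (ang in angles) {
    o <- offsets[[as.character(ang)]]
    r1 <- max(1L, 1L - o[1L]):min(nr, nr - o[1L])
    c1 <- max(1L, 1L - o[2L]):min(nc, nc - o[2L])
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1L], c1 + o[2L], drop = FALSE]
    keep <- rep(TRUE, length(a))
    if (!is.null(mask)) {
      keep <- mask[r1, c1, drop = FALSE] &
        mask[r1 + o[1L], c1 + o[2L], drop = FALSE]
    }
    idx <- (a[keep] * g + b[keep]) + 1L
    tab <- tabulate(idx, nbins = g * g)
    mcount <- matrix(tab, g, g, byrow = TRUE)
    counts <- counts + mcount + t(mcount) # symmetric accumulation
  }
  total <- sum(counts)
  if (total == 0) stop("no valid pixel pairs for the GLCM")
  p <- counts / total
  i <- matrix(0:(g - 1L), g, g)
  j <- t(i)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  lg <- if (entropy_base == "e") log else log2
  nz <- p > 0
  entropy <- -sum(p[nz] * lg(p[nz]))
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p))
  s_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (s_i > 0 && s_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  } else {
    NA_real_ # undefined for a constant (single-level) image
  }
  structure(list(asm = asm, contrast = contrast,
                 correlation = correlation, idm = idm,
                 entropy = entropy, p = p,
                 levels = g, distance = d, angles = angles,
                 entropy_base = entropy_base),
            class = "glcm_features")
}

#' @export
print.glcm_features <- function(x, ...) {
  cat(sprintf(paste0("<glcm_features> G = %d, d = %d, angles = {%s}\n",
                     "  asm = %.4g, contrast = %.4g, correlation = %s,",
                     " idm = %.4g, entropy = %.4g\n"),
              x$levels, x$distance, paste(x$angles, collapse = ", "),
              x$asm, x$contrast,
              ifelse(is.na(x$correlation), "NA",
                     sprintf("%.4g", x$correlation)),
              x$idm, x$entropy))
  invisible(x)
}
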