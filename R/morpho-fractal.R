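log_log_slope <- function(sizes, counts) {
  keep <- counts > 0
  if (sum(keep) < 3L) stop("need at least 3 usable box sizes")
  x <- log(1 / sizes[keep])
  y <- log(counts[keep])
  sl <- ls_line(x, y)
  r2 <- r_squared(y, sl[["intercept"]] + sl[["slope"]] * x)
  list(slope = sl[["slope"]], r2 = r2)
}

default_box_sizes <- function(extent) {
  s <- 2^(0:floor(log2(max(extent / 2, 2))))
  s[s <= extent / 2 & s >= 1]
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts, for each grid size `s`, the number `N(s)` of `s x s` cells
#' (grid anchored at the mask's bounding-box origin) containing at
#' least one foreground pixel; the dimension is the least-squares slope
#' of `log N` against `log(1/s)`.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param sizes box sizes in pixels (>= 3 values). Default: powers of 2
#'   up to half the bounding-box extent.
#' @return Object of class `fractal_fit`: list with `dimension`,
#'   `sizes`, `counts` and the regression `r2`.
#' @export
boxcount_dimension <- function(mask, sizes = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  pix <- which(mask, arr.ind = TRUE)
  r0 <- min(pix[, 1L]); c0 <- min(pix[, 2L])
  rr <- pix[, 1L] - r0 # 0-based within the bounding box
  cc <- pix[, 2L] - c0
  extent <- max(max(rr), max(cc)) + 1L
  if (is.null(sizes)) sizes <- default_box_sizes(extent)
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) < 3L) stop("need at least 3 box sizes")
  counts <- vapply(sizes, function(s) {
    length(unique((rr %/% s) * ceiling(extent / s) + (cc %/% s)))
  }, numeric(1))
  fit <- log_log_slope(sizes, counts)
  structure(list(dimension = fit$slope, sizes = sizes, counts = counts,
                 r2 = fit$r2, kind = "boxcount"),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> %s dimension = %.4f (regression R2 = %.4f)\n",
              x$kind, x$dimension, x$r2))
  invisible(x)
}

#' Gliding-box lacunarity of a binary mask
#'
#' For each box size `r`, an `r x r` window glides over every position
#' of the mask; with `M` the box mass (foreground count),
#' `lambda(r) = var(M) / mean(M)^2` (population moments). The returned
#' lacunarity is the mean of `lambda(r)` over the sizes; per-size
#' values are exposed. A homogeneous all-true mask has zero variance at
#' every size, hence lacunarity 0.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param sizes box sizes (>= 2 values), each no larger than the mask
#'   extent. Default `c(2, 4, 8, 16)` (truncated to the extent).
#' @return Object of class `lacunarity_fit`: list with `lacunarity`,
#'   `sizes` and `per_size`.
#' @export
gliding_box_lacunarity <- function(mask, sizes = c(2, 4, 8, 16)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask: mean box mass is zero")
  nr <- nrow(mask); nc <- ncol(mask)
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes <= min(nr, nc)]
  if (length(sizes) < 2L) stop("need at least 2 usable box sizes")
  # summed-area table with zero padding
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- apply(apply(mask, 2L, cumsum), 1L, cumsum) |> t()
  per_size <- vapply(sizes, function(s) {
    rmax <- nr - s + 1L
    cmax <- nc - s + 1L
    m <- sat[(1L + s):(nr + 1L), (1L + s):(nc + 1L), drop = FALSE] -
      sat[1L:rmax, (1L + s):(nc + 1L), drop = FALSE] -
      sat[(1L + s):(nr + 1L), 1L:cmax, drop = FALSE] +
      sat[1L:rmax, 1L:cmax, drop = FALSE]
    mu <- mean(m)
    if (mu == 0) return(NA_real_)
    mean((m - mu)^2) / mu^2
  }, numeric(1))
  structure(list(lacunarity = mean(per_size, na.rm = TRUE),
                 sizes = sizes,
                 per_size = setNames(per_size, sizes)),
            class = "lacunarity_fit")
}

#' @export
print.lacunarity_fit <- function(x, ...) {
  cat(sprintf("<lacunarity_fit> mean lambda = %.4g over sizes {%s}\n",
              x$lacunarity, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

block_stat <- function(img, s, stat) {
  nr <- nrow(img); nc <- ncol(img)
  nrb <- ceiling(nr / s); ncb <- ceiling(nc / s)
  padded <- matrix(NA_real_, nrb * s, ncb * s)
  padded[seq_len(nr), seq_len(nc)] <- img
  a <- array(padded, dim = c(s, nrb, s * ncb))
  # padded-only strips reduce over empty sets; the +/-Inf they produce
  # is absorbed by the second reduction, so silence the warnings
  red1 <- suppressWarnings(apply(a, c(2L, 3L), stat, na.rm = TRUE))
  a2 <- array(t(red1), dim = c(s, ncb, nrb))
  suppressWarnings(t(apply(a2, c(2L, 3L), stat, na.rm = TRUE)))
}

#' Shifting differential box-counting (SDBC) grayscale fractal dimension
#'
#' Treats the image as an intensity surface. For grid size `s` the
#' image is partitioned into `s x s` cells and the intensity axis into
#' boxes of height `h = s * 256 / min(nrow, ncol)`. In the shifting
#' variant each cell's box stack starts at the cell's own minimum, so
#' the cell contributes `n = floor((max - min) / h) + 1` boxes;
#' `N(s) = sum(n)` and the dimension is the slope of `log N` vs
#' `log(1/s)`. A constant image contributes one box per cell at every
#' size, giving dimension 2 up to partial-cell effects.
#'
#' Partial cells at the image border are included; grid sizes that
#' divide the image side avoid the (small) count inflation they cause,
#' hence the power-of-two default.
#'
#' @param img numeric matrix (>= 8 x 8), intensities in `[0, 255]`.
#' @param sizes grid sizes in pixels (>= 3 values >= 2), truncated to a
#'   quarter of the smaller image side. Default: powers of two
#'   `2, 4, 8, ...`.
#' @return Object of class `fractal_fit` with `dimension`, `sizes`,
#'   `counts`, `r2`.
#' @export
sdbc_dimension <- function(img, sizes = 2^(1:7)) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 8L || nc < 8L) stop("image must be at least 8 x 8")
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes >= 2L & sizes <= min(nr, nc) / 4]
  if (length(sizes) < 3L) stop("need at least 3 usable grid sizes")
  counts <- vapply(sizes, function(s) {
    h <- s * 256 / min(nr, nc)
    mx <- block_stat(img, s, max)
    mn <- block_stat(img, s, min)
    sum(floor((mx - mn) / h) + 1)
  }, numeric(1))
  fit <- log_log_slope(sizes, counts)
  structure(list(dimension = fit$slope, sizes = sizes, counts = counts,
                 r2 = fit$r2, kind = "sdbc"),
            class = "fractal_fit")
}

#' Sierpinski carpet test pattern
#'
#' Deterministic self-similar mask of side `3^order` whose box-counting
#' dimension is `log(8)/log(3) = 1.8928`; used as an analytic reference
#' case for fractal estimators.
#'
#' @param order recursion order (side length `3^order`).
#' @return Logical matrix.
#' @export
sierpinski_carpet <- function(order = 5L) {
  stopifnot(order >= 1L, order <= 7L)
  m <- matrix(TRUE, 1L, 1L)
  for (i in seq_len(order)) {
    n <- nrow(m)
    out <- matrix(FALSE, 3L * n, 3L * n)
    for (br in 0:2) {
      for (bc in 0:2) {
        if (br == 1L && bc == 1L) next
        out[br * n + seq_len(n), bc * n + seq_len(n)] <- m
      }
    }
    m <- out
  }
  m
}
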