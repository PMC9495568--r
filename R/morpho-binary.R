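#' Threshold a grayscale image to a binary mask
#'
#' A pixel is foreground iff `lo <= intensity <= hi`, mirroring manual
#' grayscale-range thresholding.
#'
#' @param img numeric matrix with intensities in `[0, 255]`.
#' @param lo,hi inclusive intensity bounds, `0 <= lo <= hi <= 255`.
#' @return Logical matrix of the same shape.
#' @export
binarize_threshold <- function(img, lo, hi) {
  stopifnot(is.matrix(img))
  stop_if_not_scalar_number(lo, "lo", 0, 255)
  stop_if_not_scalar_number(hi, "hi", 0, 255)
  if (lo > hi) stop("inverted bounds: `lo` must be <= `hi`")
  img >= lo & img <= hi
}

#' Label connected components of a binary mask
#'
#' Run-based two-pass labelling with union-find; 8- or 4-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 = background, components numbered from 1
#'   in decreasing size order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  off <- if (connectivity == "8") 1L else 0L
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  prev_runs <- NULL
  all_runs <- vector("list", nr)
  next_id <- 0L
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) {
      prev_runs <- NULL
      next
    }
    d <- diff(c(FALSE, v, FALSE))
    s <- which(d == 1L)
    e <- which(d == -1L) - 1L
    ids <- next_id + seq_along(s)
    next_id <- next_id + length(s)
    parent <- c(parent, ids)
    runs <- cbind(s, e, ids)
    if (!is.null(prev_runs)) {
      i <- 1L; j <- 1L
      np <- nrow(prev_runs)
      while (i <= np && j <= length(s)) {
        if (prev_runs[i, 2L] + off < s[j]) {
          i <- i + 1L
        } else if (e[j] + off < prev_runs[i, 1L]) {
          j <- j + 1L
        } else {
          union2(prev_runs[i, 3L], ids[j])
          if (prev_runs[i, 2L] <= e[j]) i <- i + 1L else j <- j + 1L
        }
      }
    }
    all_runs[[r]] <- runs
    prev_runs <- runs
  }
  if (next_id == 0L) return(labels)
  roots <- vapply(seq_len(next_id), find_root, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  for (r in seq_len(nr)) {
    runs <- all_runs[[r]]
    if (is.null(runs)) next
    for (q in seq_len(nrow(runs))) {
      labels[r, runs[q, 1L]:runs[q, 2L]] <- relabel[runs[q, 3L]]
    }
  }
  # renumber by decreasing component size
  sizes <- tabulate(labels[labels > 0L])
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  labels
}

largest_component <- function(mask, connectivity = 8) {
  labels <- label_components(mask, connectivity)
  labels == 1L & mask
}

# Moore-neighbour boundary tracing of a connected component.
# Returns the chain of 8-direction codes around the outer boundary.
boundary_chain <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad to avoid bound checks
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # directions 1..8: E, NE, N, NW, W, SW, S, SE (row decreases upwards)
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(p, arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  if (sum(p) == 1L) return(integer(0))
  # start pixel is topmost-leftmost; begin searching from W (coming
  # from outside above-left guarantees correct orientation)
  cur <- start
  chain <- integer(0)
  # initial backtrack direction: W (index 5)
  b <- 5L
  start_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (step in 0:7) {
      d <- ((b - 1L + 1L + step) %% 8L) + 1L # start just after backtrack
      r2 <- cur[1L] + dr[d]
      c2 <- cur[2L] + dc[d]
      if (p[r2, c2]) {
        chain <- c(chain, d)
        cur <- c(r2, c2)
        b <- ((d - 1L + 4L) %% 8L) + 1L # opposite of d
        found <- TRUE
        break
      }
    }
    if (!found) return(integer(0)) # isolated pixel (handled above)
    if (is.na(start_dir)) {
      start_dir <- chain[1L]
    } else if (cur[1L] == start[1L] && cur[2L] == start[2L] &&
               length(chain) > 1L) {
      break
    }
    if (length(chain) > 8L * sum(p)) break # safety net
  }
  chain
}

# Perimeter estimators from an 8-direction chain code.
# "chain": axial steps count 1, diagonal steps sqrt(2).
# "corrected": corner-corrected estimator (0.980 axial + 1.406 diagonal
# - 0.091 per direction change), accurate for smooth digitized outlines.
perimeter_from_chain <- function(chain, method = c("corrected", "chain")) {
  method <- match.arg(method)
  if (!length(chain)) return(4) # single pixel: its square outline
  diag_step <- chain %% 2L == 0L # directions 2,4,6,8 are diagonal
  n_ax <- sum(!diag_step)
  n_di <- sum(diag_step)
  if (method == "chain") {
    n_ax + sqrt(2) * n_di
  } else {
    corners <- sum(chain != c(chain[-1L], chain[1L]))
    0.980 * n_ax + 1.406 * n_di - 0.091 * corners
  }
}

#' Size and shape descriptors of a binary mask
#'
#' Computed on the largest 8-connected component. The perimeter is
#' estimated from the 8-direction boundary chain; the default
#' `"corrected"` estimator applies corner-count correction
#' (0.980/1.406/-0.091 weights), which is accurate for smooth digitized
#' outlines and keeps the circularity of rasterized discs near 1. The
#' plain `"chain"` estimator (1 per axial step, sqrt(2) per diagonal)
#' is also available; it overestimates smooth perimeters by ~5% and
#' correspondingly depresses circularity.
#'
#' Circularity is `min(1, 4 pi area / perimeter^2)`; solidity is pixel
#' area over the area of the convex hull of the pixel squares.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param pixel_size physical size of a pixel edge (micrometres per
#'   pixel); areas scale with its square.
#' @param perimeter_method `"corrected"` (default) or `"chain"`.
#' @return Object of class `shape_descriptors`: a list with `area`,
#'   `perimeter`, `circularity`, `solidity`, `n_pixels`, `pixel_size`,
#'   `perimeter_method`.
#' @export
shape_descriptors <- function(mask, pixel_size = 1,
                              perimeter_method = c("corrected", "chain")) {
  perimeter_method <- match.arg(perimeter_method)
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0,
                            strict_lower = TRUE)
  comp <- largest_component(mask)
  n_pix <- sum(comp)
  chain <- boundary_chain(comp)
  per_px <- perimeter_from_chain(chain, perimeter_method)
  area <- n_pix * pixel_size^2
  perimeter <- per_px * pixel_size
  circularity <- min(1, 4 * pi * n_pix / per_px^2)
  # convex hull over the pixel squares (each pixel contributes its 4
  # corners), so a filled rectangle has solidity exactly 1
  pix <- which(comp, arr.ind = TRUE)
  xs <- c(pix[, 2L] - 0.5, pix[, 2L] + 0.5, pix[, 2L] - 0.5,
          pix[, 2L] + 0.5)
  ys <- c(pix[, 1L] - 0.5, pix[, 1L] - 0.5, pix[, 1L] + 0.5,
          pix[, 1L] + 0.5)
  h <- chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  hull_area <- abs(sum(hx * c(hy[-1L], hy[1L]) -
                       c(hx[-1L], hx[1L]) * hy)) / 2
  solidity <- min(1, n_pix / hull_area)
  structure(list(area = area, perimeter = perimeter,
                 circularity = circularity, solidity = solidity,
                 n_pixels = n_pix, pixel_size = pixel_size,
                 perimeter_method = perimeter_method),
            class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(paste0("<shape_descriptors> area = %.4g, perimeter = %.4g,",
                     " circularity = %.4f, solidity = %.4f\n"),
              x$area, x$perimeter, x$circularity, x$solidity))
  invisible(x)
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask
#'
#' Topology-preserving iterative thinning (Zhang-Suen) producing a
#' one-pixel-wide medial-axis approximation. The skeleton is a subset
#' of the input mask and isolated pixels are fixed points.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  m <- mask
  neighbors <- function(m) {
    # clockwise from north: P2..P9
    list(p2 = shift_mat(m, 1L, 0L),   # north neighbour (row - 1)
         p3 = shift_mat(m, 1L, -1L),
         p4 = shift_mat(m, 0L, -1L),
         p5 = shift_mat(m, -1L, -1L),
         p6 = shift_mat(m, -1L, 0L),
         p7 = shift_mat(m, -1L, 1L),
         p8 = shift_mat(m, 0L, 1L),
         p9 = shift_mat(m, 1L, 1L))
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- neighbors(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8,
                   nb$p9, nb$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        a <- a + (!seqs[[i]] & seqs[[i + 1L]])
      }
      if (pass == 1L) {
        cond1 <- !(nb$p2 & nb$p4 & nb$p6)
        cond2 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond1 <- !(nb$p2 & nb$p4 & nb$p8)
        cond2 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & b >= 2 & b <= 6 & a == 1L & cond1 & cond2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
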