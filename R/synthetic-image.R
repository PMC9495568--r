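#' Specification of a synthetic bead phantom image
#'
#' Parameters for [simulate_bead_image()], which draws a rough-edged
#' bright disc (the bead) over a darker background, an internal filament
#' network emulating the crosslinked wall-material mesostructure that
#' cells deposit on, and multiplicative speckle texture. Phantoms are
#' synthetic stand-ins for bead micrographs and carry their own ground
#' truth masks.
#'
#' @param image_size side length in pixels (square image).
#' @param disc_radius bead radius in pixels; the disc (radius plus
#'   roughness) must fit inside the image.
#' @param boundary_roughness amplitude (pixels) of smooth radial
#'   perturbation of the disc edge; 0 gives a perfect disc.
#' @param network_density expected number of filament branches grown
#'   from the disc centre; 0 disables the network.
#' @param texture_contrast multiplicative speckle amplitude on the 0-255
#'   intensity scale; 0 gives a uniform disc.
#' @param background_level background intensity (0-255).
#' @param disc_level intensity of the disc interior (0-255), default
#'   `background_level + 80` capped at 255.
#' @param seed integer seed.
#' @return Object of class `bead_phantom_spec`.
#' @export
bead_phantom_spec <- function(image_size = 256L, disc_radius = 80,
                              boundary_roughness = 3,
                              network_density = 12,
                              texture_contrast = 40,
                              background_level = 30,
                              disc_level = min(background_level + 80, 255),
                              seed = 1L) {
  stop_if_not_scalar_number(image_size, "image_size", 8)
  stop_if_not_scalar_number(disc_radius, "disc_radius", 1)
  stop_if_not_scalar_number(boundary_roughness, "boundary_roughness", 0)
  stop_if_not_scalar_number(network_density, "network_density", 0)
  stop_if_not_scalar_number(texture_contrast, "texture_contrast", 0, 255)
  stop_if_not_scalar_number(background_level, "background_level", 0, 255)
  stop_if_not_scalar_number(disc_level, "disc_level", 0, 255)
  if (disc_radius + boundary_roughness >= image_size / 2) {
    stop("disc (radius + roughness) must fit inside the image")
  }
  structure(list(image_size = as.integer(image_size),
                 disc_radius = disc_radius,
                 boundary_roughness = boundary_roughness,
                 network_density = network_density,
                 texture_contrast = texture_contrast,
                 background_level = background_level,
                 disc_level = disc_level, seed = seed),
            class = "bead_phantom_spec")
}

# smooth random radial profile with zero mean and unit sd, built from a
# few low-order harmonics
radial_roughness_profile <- function(theta, n_harmonics = 5L) {
  z <- numeric(length(theta))
  for (k in 2:(n_harmonics + 1L)) {
    z <- z + rnorm(1) * cos(k * theta) + rnorm(1) * sin(k * theta)
  }
  s <- sd(z)
  if (s > 0) z / s else z
}

# smooth speckle field in [-1, 1]: white noise blurred with a small
# separable binomial kernel, rescaled to unit sd then clamped
speckle_field <- function(nr, nc) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  k <- c(1, 4, 6, 4, 1); k <- k / sum(k)
  blur1 <- function(m) {
    out <- m * k[3]
    padded <- rbind(m[1, , drop = FALSE], m[1, , drop = FALSE], m,
                    m[nr, , drop = FALSE], m[nr, , drop = FALSE])
    for (off in c(-2, -1, 1, 2)) {
      out <- out + k[3 + off] * padded[(3 + off):(nr + 2 + off), ,
                                       drop = FALSE]
    }
    out
  }
  z <- blur1(z)
  z <- t(blur1(t(z)))
  z <- z / sd(z)
  pmin(1, pmax(-1, z))
}

#' Simulate a bead phantom micrograph
#'
#' Renders an 8-bit grayscale phantom together with its ground-truth
#' disc mask and filament-network mask. Filaments are grown as random
#' walks with angular persistence from the disc centre outwards, a
#' pattern chosen so that skeletonization of the network is a meaningful
#' recovery problem.
#'
#' @param spec a [bead_phantom_spec()].
#' @return A list of class `bead_phantom` with elements `image` (numeric
#'   matrix, integer values 0-255), `disc_mask` and `network_mask`
#'   (logical matrices), and `spec`.
#' @export
simulate_bead_image <- function(spec) {
  stopifnot(inherits(spec, "bead_phantom_spec"))
  n <- spec$image_size
  with_seed(spec$seed, {
    centre <- (n + 1) / 2
    row <- matrix(seq_len(n), n, n)
    col <- matrix(seq_len(n), n, n, byrow = TRUE)
    dx <- col - centre
    dy <- row - centre
    theta <- atan2(dy, dx)
    rad <- sqrt(dx^2 + dy^2)

    r_edge <- spec$disc_radius
    if (spec$boundary_roughness > 0) {
      # one radial profile shared by all pixels at the same angle
      prof <- radial_roughness_profile(theta)
      r_edge <- spec$disc_radius + spec$boundary_roughness * prof
    }
    disc_mask <- rad <= r_edge

    network_mask <- matrix(FALSE, n, n)
    if (spec$network_density > 0) {
      n_branches <- rpois(1, spec$network_density)
      max_steps <- ceiling(4 * spec$disc_radius)
      for (b in seq_len(n_branches)) {
        heading <- runif(1, -pi, pi)
        x <- centre; y <- centre
        for (s in seq_len(max_steps)) {
          heading <- heading + rnorm(1, 0, 0.15)
          x <- x + cos(heading)
          y <- y + sin(heading)
          r <- round(y); c <- round(x)
          if (r < 1 || r > n || c < 1 || c > n || !disc_mask[r, c]) break
          network_mask[r, c] <- TRUE
        }
      }
    }

    img <- matrix(spec$background_level, n, n)
    img[disc_mask] <- spec$disc_level
    if (spec$texture_contrast > 0) {
      u <- speckle_field(n, n)
      img[disc_mask] <- spec$disc_level *
        (1 + (spec$texture_contrast / 255) * u[disc_mask])
    }
    img[network_mask] <- min(255, spec$disc_level + 60)
    img <- matrix(round(pmin(255, pmax(0, img))), n, n)

    structure(list(image = img, disc_mask = disc_mask,
                   network_mask = network_mask, spec = spec),
              class = "bead_phantom")
  })
}

#' Read and write 8-bit grayscale images
#'
#' Thin wrappers over the `tiff` and `png` packages working with plain
#' numeric matrices on the 0-255 intensity scale (rows = image rows).
#'
#' @param img numeric matrix with values in `[0, 255]`.
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return `write_gray_image` returns `path` invisibly;
#'   `read_gray_image` returns a numeric matrix in `[0, 255]`.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0 & img <= 255))
  norm <- img / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image extension: ", ext)
  }
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  round(arr * 255)
}
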