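# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's vectorized code
# paths: double loops and direct enumeration only.

# rasterized disc mask (pixel centre inside radius)
disc_mask <- function(radius, size = 2 * radius + 21) {
  ctr <- (size + 1) / 2
  rw <- matrix(seq_len(size), size, size)
  cl <- t(rw)
  (rw - ctr)^2 + (cl - ctr)^2 <= radius^2
}

# 8-neighbourhood binary dilation, `times` iterations
dilate8 <- function(mask, times = 1L) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(times)) {
    src <- out
    for (dr in -1:1) for (dc in -1:1) {
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- out[rs, cs] | src[rs - dr, cs - dc]
    }
  }
  out
}

# brute-force GLCM features: explicit double loop over pixels/offsets
glcm_oracle <- function(img, levels = 8, distance = 1,
                        angles = c(0, 45, 90, 135)) {
  G <- levels
  q <- pmin(floor(img / (256 / G)), G - 1)
  nr <- nrow(img); nc <- ncol(img)
  offs <- list(`0` = c(0, distance), `45` = c(-distance, distance),
               `90` = c(-distance, 0), `135` = c(-distance, -distance))
  cnt <- matrix(0, G, G)
  for (ang in as.character(angles)) {
    o <- offs[[ang]]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- q[r, c]; j <- q[r2, c2]
        cnt[i + 1, j + 1] <- cnt[i + 1, j + 1] + 1
        cnt[j + 1, i + 1] <- cnt[j + 1, i + 1] + 1
      }
    }
  }
  p <- cnt / sum(cnt)
  iv <- matrix(0:(G - 1), G, G)
  jv <- t(iv)
  asm <- 0; contrast <- 0; idm <- 0; entropy <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    pij <- p[i, j]
    asm <- asm + pij^2
    contrast <- contrast + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    if (pij > 0) entropy <- entropy - pij * log(pij)
  }
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  s_i <- sqrt(sum((iv - mu_i)^2 * p))
  s_j <- sqrt(sum((jv - mu_j)^2 * p))
  corr <- if (s_i > 0 && s_j > 0) {
    sum((iv - mu_i) * (jv - mu_j) * p) / (s_i * s_j)
  } else NA_real_
  list(asm = asm, contrast = contrast, correlation = corr, idm = idm,
       entropy = entropy, p = p)
}

# exhaustive gliding-box lacunarity at one size
lacunarity_oracle <- function(mask, sizes) {
  nr <- nrow(mask); nc <- ncol(mask)
  per <- vapply(sizes, function(s) {
    masses <- c()
    for (r in seq_len(nr - s + 1)) for (c in seq_len(nc - s + 1)) {
      masses <- c(masses, sum(mask[r:(r + s - 1), c:(c + s - 1)]))
    }
    mu <- mean(masses)
    mean((masses - mu)^2) / mu^2
  }, numeric(1))
  list(lacunarity = mean(per), per_size = per)
}

# clustered blob mask matched in density to a Bernoulli mask
clustered_mask <- function(n, target_count) {
  cl <- matrix(FALSE, n, n)
  while (sum(cl) < target_count) {
    r0 <- sample(5:(n - 4), 1)
    c0 <- sample(5:(n - 4), 1)
    cl[max(1, r0 - 4):min(n, r0 + 4), max(1, c0 - 4):min(n, c0 + 4)] <- TRUE
  }
  cl
}
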