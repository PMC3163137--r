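# Independent oracles and small fixture builders. The oracles deliberately
# avoid the package's vectorized code paths: plain loops and polyroot.

# Kapur criterion evaluated level by level; exhaustive argmax.
oracle_kapur <- function(hist) {
  counts <- hist$counts
  levels <- hist$level_offset + seq_along(counts) - 1L
  p <- counts / sum(counts)
  best_t <- NA_integer_; best <- -Inf
  for (k in seq_along(levels)) {
    Pb <- sum(p[1:k]); Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) next
    pb <- p[1:k][p[1:k] > 0] / Pb
    pf <- p[-(1:k)][p[-(1:k)] > 0] / Pf
    H <- -sum(pb * log(pb)) - sum(pf * log(pf))
    if (H > best + 1e-12) { best <- H; best_t <- levels[k] }
  }
  best_t
}

# Tsai moment preservation via polyroot on the representative-level
# quadratic; threshold from the cumulative fraction.
oracle_tsai <- function(hist) {
  counts <- hist$counts
  z <- hist$level_offset + seq_along(counts) - 1
  p <- counts / sum(counts)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  roots <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (roots[2] - m1) / (roots[2] - roots[1])
  cum <- cumsum(p)
  as.integer(z[which(cum >= p0 - 1e-12)[1]])
}

# O(N^2) nearest-tumor-pixel Euclidean distance, micrometres.
oracle_distance <- function(tumor, pixel_size_um = 1) {
  idx <- which(tumor, arr.ind = TRUE)
  out <- matrix(0, nrow(tumor), ncol(tumor))
  for (i in seq_len(nrow(tumor)))
    for (j in seq_len(ncol(tumor)))
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
  out * pixel_size_um
}

# Histogram from a mixture of discretized Gaussians.
gaussian_mix_histogram <- function(means, sds, ns, seed) {
  set.seed(seed)
  v <- unlist(mapply(function(m, s, n) round(rnorm(n, m, s)),
                     means, sds, ns, SIMPLIFY = FALSE))
  grey_histogram(v)
}

# Down-scaled synthetic slide for fast unit tests.
small_synth <- function(seed = 0, ...) {
  args <- list(image_size_px = c(700, 700), n_vessels = 12,
               vessel_radius_um = c(12, 25), wall_thickness_um = 5,
               tumor_radius_um = c(40, 70), noise_sigma = 5, seed = seed)
  args[names(list(...))] <- list(...)
  generate_slide(do.call(synth_config, args))
}

# Flat RGB image with optional painted disc, as a slide_image.
flat_slide <- function(nr, nc, rgb, pixel_size_um = 0.65) {
  px <- array(0L, c(nr, nc, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  slide_image(px, pixel_size_um)
}

paint_disc <- function(image, center_rc, radius, rgb) {
  d <- dim(image$pixels)
  rr <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  cc <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  sel <- (rr - center_rc[1])^2 + (cc - center_rc[2])^2 <= radius^2
  px <- image$pixels
  for (ch in 1:3) { pl <- px[, , ch]; pl[sel] <- rgb[ch]; px[, , ch] <- pl }
  list(image = slide_image(px, image$pixel_size_um), disc = sel)
}

disc_mask <- function(nr, nc, center_rc, radius, pixel_size_um = 1,
                      name = "tumor") {
  rr <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  binary_mask((rr - center_rc[1])^2 + (cc - center_rc[2])^2 <= radius^2,
              pixel_size_um, name)
}
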