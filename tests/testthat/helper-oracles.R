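# Shared fixtures and independent oracles for the test suite.

rand_gray <- function(h, w, scale = 1) {
  gray_image(matrix(as.integer(sample(0:255, h * w, replace = TRUE)), h, w),
             scale)
}

rand_mask <- function(h, w, p = 0.3, role = "Ma", scale = 1) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w), role = role,
              scale = scale)
}

# Histogram-equalization oracle: per-level counting, no vectorized tricks.
equalize_oracle <- function(px) {
  n <- length(px)
  counts <- integer(256)
  for (v in as.vector(px)) counts[v + 1] <- counts[v + 1] + 1
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  out <- px
  for (i in seq_along(px)) {
    v <- px[i]
    out[i] <- floor((cdf[v + 1] - cdf_min) / (n - cdf_min) * 255 + 0.5)
  }
  out
}

# Per-pixel double-loop oracles for expression / noise / fractions.
cex_oracle <- function(mc4, mt) {
  num <- 0; den <- 0
  for (j in seq_along(mt)) {
    if (mt[j]) {
      den <- den + 1
      if (mc4[j]) num <- num + 1
    }
  }
  100 * num / den
}

noise_oracle <- function(mc4, mt) {
  num <- 0; den <- 0
  for (j in seq_along(mt)) {
    if (!mt[j]) {
      den <- den + 1
      if (mc4[j]) num <- num + 1
    }
  }
  100 * num / den
}

fraction_oracle <- function(compartment_idx, mc4) {
  num <- 0
  for (j in compartment_idx) if (mc4[j]) num <- num + 1
  num / length(compartment_idx)
}

# Independent minimum-area rectangle oracle: for every convex-hull edge,
# project the hull points onto the edge direction and its normal with
# explicit dot products, and take the smallest width * height.
min_area_oracle <- function(pts) {
  hp <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hp)
  best <- Inf
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    e <- hp[k2, ] - hp[k, ]
    e <- e / sqrt(sum(e^2))
    nrm <- c(-e[2], e[1])
    pe <- apply(hp, 1, function(p) sum(p * e))
    pn <- apply(hp, 1, function(p) sum(p * nrm))
    area <- (max(pe) - min(pe)) * (max(pn) - min(pn))
    if (area < best) best <- area
  }
  best
}

# Direct evaluation of the diagonal vertex-projection formula.
expand_vertices_oracle <- function(vertices, h) {
  out <- vertices
  for (i in 1:4) {
    j <- if (i <= 2) i + 2 else i - 2
    d <- sqrt(sum((vertices[i, ] - vertices[j, ])^2))
    out[i, 1] <- vertices[i, 1] + h * (vertices[i, 1] - vertices[j, 1]) / d
    out[i, 2] <- vertices[i, 2] + h * (vertices[i, 2] - vertices[j, 2]) / d
  }
  out
}

# Match each detected record to the nearest ground-truth cell by center.
match_truth <- function(records, truth) {
  vapply(records, function(r) {
    which.min((truth$cx - r$box$center[1])^2 +
                (truth$cy - r$box$center[2])^2)
  }, integer(1))
}

# A channel set containing only a c1 image with the given foreground
# rectangles (axis-aligned, intensity 200).
c1_only_channels <- function(h, w, rects, scale = 1) {
  px <- matrix(0L, h, w)
  for (r in rects) px[r$rows, r$cols] <- 200L
  channel_set(gray_image(px, scale))
}

identity_config <- function(scale = 1, thr = 50, ...) {
  pipeline_config(c1 = channel_params(thr, 1, 1, 1),
                  c2 = channel_params(thr, 1, 1, 1),
                  c3 = channel_params(thr, 1, 1, 1),
                  scale = scale, ...)
}
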