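#' Synthetic fluorescence scene specification
#'
#' Describes a synthetic multi-channel field of view with exact vector
#' ground truth: rectangular cells at arbitrary orientations, thin CX43
#' bands at the cell poles plus a controllable lateral CX43 fraction, a
#' thin interstitial halo around each cell, and optional salt noise and
#' brightness heterogeneity. Cell geometry is sampled uniformly within the
#' given ranges and placed by rejection so that cells never overlap
#' (minimum 3 px gap); the per-cell lateral fraction `phi` is sampled
#' uniformly on \[0, 0.6\] unless given. All sampling is driven by `seed`,
#' so a scene specification is fully reproducible.
#'
#' Defaults emulate longitudinally sectioned ventricular tissue at
#' confocal resolution: 0.21 um/px, cell lengths 30-60 um and widths
#' 10-20 um (within the plausible 20-200 x 5-50 um morphometry window),
#' CX43 bands 4 px thick at the poles.
#'
#' @param n_cells number of cells to place.
#' @param image_size `c(H, W)` in pixels.
#' @param scale micrometers per pixel.
#' @param L_range_um,W_range_um cell length / width sampling ranges (um).
#' @param phi per-cell lateral CX43 fraction(s) in \[0, 1\], recycled to
#'   `n_cells`; `NULL` to sample uniformly on \[0, 0.6\].
#' @param cells optional data frame with columns `cx`, `cy` (px), `angle`
#'   (deg), `L_um`, `W_um`, `phi`, overriding the sampler.
#' @param cx43_band_px polar band thickness in pixels.
#' @param lateral_band_px thickness of the lateral CX43 strip.
#' @param noise_density fraction of salt pixels added per channel.
#' @param brightness_gradient `NULL`, or the left-edge intensity factor of
#'   a linear left-to-right ramp ending at 1.
#' @param body_intensity c1 intensity of the cell bodies.
#' @param seed integer seed for all scene randomness.
#' @return An object of class `synthetic_scene` with the resolved cell
#'   table in `$cells`.
#' @export
synthetic_scene <- function(n_cells = 5L,
                            image_size = c(768L, 768L),
                            scale = 0.21,
                            L_range_um = c(30, 60),
                            W_range_um = c(10, 20),
                            phi = NULL,
                            cells = NULL,
                            cx43_band_px = 4L,
                            lateral_band_px = 2L,
                            noise_density = 0,
                            brightness_gradient = NULL,
                            body_intensity = 200L,
                            seed = 1L) {
  if (!is.null(phi) && any(phi < 0 | phi > 1))
    stop("phi must lie in [0, 1]")
  if (noise_density < 0 || noise_density >= 1)
    stop("noise_density must lie in [0, 1)")
  sc <- structure(list(image_size = as.integer(image_size), scale = scale,
                       cx43_band_px = as.integer(cx43_band_px),
                       lateral_band_px = as.integer(lateral_band_px),
                       noise_density = noise_density,
                       brightness_gradient = brightness_gradient,
                       body_intensity = as.integer(body_intensity),
                       seed = as.integer(seed)),
                  class = "synthetic_scene")
  if (is.null(cells)) {
    cells <- with_scene_rng(seed, place_cells(n_cells, image_size, scale,
                                              L_range_um, W_range_um, phi))
  } else {
    cells <- as.data.frame(cells)
    need <- c("cx", "cy", "angle", "L_um", "W_um", "phi")
    if (!all(need %in% names(cells)))
      stop("`cells` must have columns ", paste(need, collapse = ", "))
  }
  boxes <- lapply(seq_len(nrow(cells)), function(i) {
    rotated_box(c(cells$cx[i], cells$cy[i]), cells$angle[i],
                cells$L_um[i] / scale, cells$W_um[i] / scale)
  })
  for (b in boxes) {
    v <- b$vertices
    if (min(v) < 0 || max(v[, 1]) > image_size[2] || max(v[, 2]) > image_size[1])
      stop("scene error: cell extends beyond the image bounds")
  }
  sc$cells <- cells
  sc$boxes <- boxes
  sc
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells, %d x %d px, %.3g um/px, seed %d\n",
              nrow(x$cells), x$image_size[1], x$image_size[2], x$scale,
              x$seed))
  invisible(x)
}

# Run `expr` under a scene-local RNG state, restoring the caller's state.
with_scene_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Separating-axis overlap test for two rotated rectangles inflated by
# `gap` (in px): TRUE if the inflated rectangles intersect.
boxes_intersect <- function(b1, b2, gap = 0) {
  axes <- function(b) {
    th <- b$angle * pi / 180
    rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  }
  for (ax in list(axes(b1)[1, ], axes(b1)[2, ], axes(b2)[1, ], axes(b2)[2, ])) {
    p1 <- b1$vertices %*% ax; p2 <- b2$vertices %*% ax
    if (max(p1) + gap < min(p2) || max(p2) + gap < min(p1)) return(FALSE)
  }
  TRUE
}

place_cells <- function(n_cells, image_size, scale, L_range_um, W_range_um,
                        phi) {
  if (n_cells == 0L)
    return(data.frame(cx = numeric(0), cy = numeric(0), angle = numeric(0),
                      L_um = numeric(0), W_um = numeric(0), phi = numeric(0)))
  phis <- if (is.null(phi)) stats::runif(n_cells, 0, 0.6)
          else rep_len(phi, n_cells)
  for (scene_try in 1:60) {
    placed <- list()
    ok <- TRUE
    for (i in seq_len(n_cells)) {
      success <- FALSE
      for (att in 1:300) {
        L <- stats::runif(1, L_range_um[1], L_range_um[2]) / scale
        W <- stats::runif(1, W_range_um[1], W_range_um[2]) / scale
        ang <- stats::runif(1, -90, 90)
        half_diag <- sqrt(L^2 + W^2) / 2
        m <- half_diag + 5
        if (2 * m >= min(image_size)) stop("image too small for the cell sizes")
        cx <- stats::runif(1, m, image_size[2] - m)
        cy <- stats::runif(1, m, image_size[1] - m)
        cand <- rotated_box(c(cx, cy), ang, L, W)
        if (!any(vapply(placed, boxes_intersect, logical(1), b2 = cand,
                        gap = 6))) {
          placed[[i]] <- cand
          success <- TRUE
          break
        }
      }
      if (!success) { ok <- FALSE; break }
    }
    if (ok) {
      return(data.frame(
        cx = vapply(placed, function(b) b$center[1], numeric(1)),
        cy = vapply(placed, function(b) b$center[2], numeric(1)),
        angle = vapply(placed, function(b) b$angle, numeric(1)),
        L_um = vapply(placed, function(b) b$long_px * scale, numeric(1)),
        W_um = vapply(placed, function(b) b$short_px * scale, numeric(1)),
        phi = phis))
    }
  }
  stop("scene error: could not place non-overlapping cells")
}

# Pixel sets for planting CX43 in one cell: polar bands of the stated
# thickness at both ends, and lateral strips along the long sides
# restricted to the middle half of the cell (clear of the quarter cuts).
cx43_pixel_sets <- function(box, dim, band_px, lateral_band_px) {
  fr <- box_pixel_frame(box, dim)
  eps <- 1e-7
  inside <- abs(fr$u) <= box$long_px / 2 + eps &
    abs(fr$v) <= box$short_px / 2 + eps
  idx <- which(inside, arr.ind = TRUE)
  lin <- as.integer((fr$cols[idx[, 2]] - 1L) * dim[1] + fr$rows[idx[, 1]])
  u01 <- fr$u[idx] + box$long_px / 2
  vabs <- abs(fr$v[idx])
  polar <- lin[u01 <= band_px | u01 >= box$long_px - band_px]
  lateral <- lin[vabs >= box$short_px / 2 - lateral_band_px &
                   u01 > box$long_px / 4 + 2 &
                   u01 < 3 * box$long_px / 4 - 2]
  list(polar = polar, lateral = lateral)
}

#' Render a synthetic scene into channels and ground truth
#'
#' Produces a `channel_set` with c1 = filled cell bodies, c2 = CX43
#' pixels at full intensity (polar bands carrying a fraction `1 - phi` of
#' each cell's CX43 pixel budget, lateral strips carrying `phi`), c3 = a
#' thin interstitial halo around each cell; salt noise and an optional
#' brightness ramp are added per channel. Rendering is deterministic for
#' a fixed scene seed.
#'
#' @param scene a [synthetic_scene()].
#' @return List with `channels` (a `channel_set`) and `truth` (the scene
#'   cell table with planted CX43 pixel counts `n_polar`, `n_lateral`).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  with_scene_rng(scene$seed + 1L, render_scene_impl(scene))
}

render_scene_impl <- function(scene) {
  dm <- scene$image_size
  c1 <- matrix(0L, dm[1], dm[2])
  c2 <- matrix(0L, dm[1], dm[2])
  c3 <- matrix(0L, dm[1], dm[2])
  truth <- scene$cells
  truth$n_polar <- 0L
  truth$n_lateral <- 0L
  for (i in seq_along(scene$boxes)) {
    b <- scene$boxes[[i]]
    body <- rasterize_box(b, dm)
    c1[body] <- scene$body_intensity
    halo <- setdiff(rasterize_box(expand_box(b, 2.5), dm), body)
    c3[halo] <- scene$body_intensity
    sets <- cx43_pixel_sets(b, dm, scene$cx43_band_px, scene$lateral_band_px)
    budget <- round(0.5 * min(length(sets$polar), length(sets$lateral)))
    phi <- truth$phi[i]
    n_lat <- round(phi * budget)
    n_pol <- budget - n_lat
    pol <- if (n_pol > 0) sample(sets$polar, n_pol) else integer(0)
    lat <- if (n_lat > 0) sample(sets$lateral, n_lat) else integer(0)
    c2[pol] <- 255L
    c2[lat] <- 255L
    truth$n_polar[i] <- n_pol
    truth$n_lateral[i] <- n_lat
  }
  if (scene$noise_density > 0) {
    n_salt <- round(scene$noise_density * length(c1))
    for (ch in c("c1", "c2", "c3")) {
      m <- get(ch)
      m[sample(length(m), n_salt)] <- 255L
      assign(ch, m)
    }
  }
  if (!is.null(scene$brightness_gradient)) {
    g0 <- scene$brightness_gradient
    ramp <- seq(g0, 1, length.out = dm[2])
    for (ch in c("c1", "c2", "c3")) {
      m <- get(ch)
      m <- matrix(as.integer(floor(sweep(m, 2, ramp, `*`) + 0.5)),
                  dm[1], dm[2])
      assign(ch, m)
    }
  }
  channels <- channel_set(gray_image(c1, scene$scale),
                          gray_image(c2, scene$scale),
                          gray_image(c3, scene$scale))
  list(channels = channels, truth = truth)
}

#' Ground-truth manual mask of a scene
#'
#' Union of the rasterized ground-truth cell rectangles; stands in for a
#' manually delineated cell mask in evaluation experiments.
#'
#' @param scene a [synthetic_scene()].
#' @return A `binary_mask` with role `Mm`.
#' @export
ground_truth_manual_mask <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dm <- scene$image_size
  px <- matrix(FALSE, dm[1], dm[2])
  for (b in scene$boxes) px[rasterize_box(b, dm)] <- TRUE
  binary_mask(px, role = "Mm", scale = scene$scale)
}

#' Detection configuration matched to a clean synthetic scene
#'
#' Identity morphology (pure thresholding) with a mid-range threshold:
#' appropriate for noise-free rendered scenes, where no opening or growth
#' is needed and hence no box padding compensation applies.
#'
#' @param scene a [synthetic_scene()].
#' @param thr binarization threshold for c1-c3.
#' @return A [pipeline_config()].
#' @export
synthetic_scene_config <- function(scene, thr = 50L) {
  pipeline_config(c1 = channel_params(thr, 1, 1, 1),
                  c2 = channel_params(thr, 1, 1, 1),
                  c3 = channel_params(thr, 1, 1, 1),
                  thr_c4 = 254L, scale = scene$scale)
}

#' Sample a truncated-exponential lateralization population
#'
#' Draws `n` values from an exponential distribution with the given decay
#' rate, truncated to `[0, hi]`, by inversion of the truncated CDF.
#' Mirrors the empirically observed exponential decay of lateralization
#' frequencies and feeds parameter-recovery tests of the histogram fit.
#'
#' @param n number of draws (>= 1).
#' @param rate exponential decay rate per percent (> 0).
#' @param hi truncation point in percent.
#' @param seed integer seed.
#' @return Numeric vector of `n` percentages in `[0, hi]`.
#' @export
sample_clat_population <- function(n, rate, hi = 100, seed = 1L) {
  if (n < 1 || rate <= 0 || hi <= 0) stop("invalid population parameters")
  with_scene_rng(as.integer(seed), {
    u <- stats::runif(n)
    -log(1 - u * (1 - exp(-rate * hi))) / rate
  })
}
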