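#' Calibrated 8-bit grayscale image
#'
#' Container for a single fluorescence channel: an integer matrix of
#' intensities in \[0, 255\] plus the physical scale of the raster in
#' micrometers per pixel. Matrices are row-major with the origin at the
#' top-left corner; pixel `(row, col)` occupies the unit square
#' `[col-1, col] x [row-1, row]` in continuous coordinates, so its center
#' sits at `(col - 0.5, row - 0.5)`. All geometry in the package uses this
#' convention, with the y axis pointing down.
#'
#' @param pixels integer matrix of intensities in \[0, 255\].
#' @param scale micrometers per pixel (> 0).
#' @return An object of class `gray_image` with fields `px` and `scale`.
#' @export
gray_image <- function(pixels, scale) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number (um/pixel)")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L))
    stop("intensities must lie in [0, 255]")
  structure(list(px = pixels, scale = as.numeric(scale)), class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$px)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px, intensity range [%d, %d]\n",
              nrow(x$px), ncol(x$px), x$scale, min(x$px), max(x$px)))
  invisible(x)
}

#' Multi-channel fluorescence image
#'
#' Bundles the calibrated channels of one field of view: `c1` marks the
#' myocyte bodies (SERCA2 or F-actin), `c2` the connexin-43 signal, `c3`
#' the interstitium (WGA). A fourth channel `c4` is kept as a raw duplicate
#' of `c2`: it is the channel that CX43 quantification operates on (it is
#' always histogram-equalized and binarized at a fixed high threshold,
#' independently of how `c2` itself is processed for cell-mask building).
#'
#' @param c1 `gray_image`, myocyte-body channel (required).
#' @param c2 `gray_image` or `NULL`, CX43 channel.
#' @param c3 `gray_image` or `NULL`, interstitium channel.
#' @return An object of class `channel_set` with fields `c1`, `c2`, `c3`,
#'   `c4`, `n_channels` and `scale`.
#' @export
channel_set <- function(c1, c2 = NULL, c3 = NULL) {
  stopifnot(inherits(c1, "gray_image"))
  for (ch in list(c2, c3)) {
    if (!is.null(ch)) {
      stopifnot(inherits(ch, "gray_image"))
      if (!identical(dim(ch$px), dim(c1$px)))
        stop("all channels must share identical dimensions")
      if (!isTRUE(all.equal(ch$scale, c1$scale)))
        stop("all channels must share the same scale")
    }
  }
  c4 <- if (!is.null(c2)) gray_image(c2$px, c2$scale) else NULL
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 n_channels = 1L + (!is.null(c2)) + (!is.null(c3)),
                 scale = c1$scale),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d channel(s), %d x %d px, %.4g um/px\n",
              x$n_channels, nrow(x$c1$px), ncol(x$c1$px), x$scale))
  invisible(x)
}

#' Convert an RGB raster to grayscale
#'
#' Averages the red, green and blue intensities of each pixel and rounds
#' half-up to the nearest integer.
#'
#' @param rgb numeric array `H x W x 3` of 8-bit intensities.
#' @param scale micrometers per pixel.
#' @return A `gray_image`.
#' @export
to_grayscale <- function(rgb, scale = 1) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array")
  m <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  px <- pmin(pmax(floor(m + 0.5), 0), 255)
  gray_image(matrix(as.integer(px), dim(rgb)[1], dim(rgb)[2]), scale)
}

#' Histogram equalization of an 8-bit image
#'
#' Standard cumulative-distribution equalization: intensity `v` is remapped
#' to `round((cdf(v) - cdf_min) / (N - cdf_min) * 255)`, where `cdf_min` is
#' the CDF value of the lowest occupied gray level. The remap is monotone
#' non-decreasing, the lowest occupied level maps to 0 and the highest to
#' 255. Degenerate histograms with a single occupied level are returned
#' unchanged (there is no distribution to spread).
#'
#' @param img a `gray_image`.
#' @return A `gray_image` of identical dimensions and scale, carrying the
#'   attribute `equalized = TRUE`.
#' @export
equalize_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  counts <- tabulate(img$px + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- cdf[256L]
  cdf_min <- min(cdf[cdf > 0L])
  if (cdf_min == n) {  # single occupied gray level
    out <- img
  } else {
    lut <- as.integer(floor((cdf - cdf_min) / (n - cdf_min) * 255 + 0.5))
    lut[lut < 0L] <- 0L
    px <- matrix(lut[img$px + 1L], nrow(img$px), ncol(img$px))
    out <- gray_image(px, img$scale)
  }
  attr(out, "equalized") <- TRUE
  out
}

# Extract one plane from an RGB array according to a selector:
# "R"/"G"/"B" pick a plane, "min" is the pixelwise minimum of the three
# (recovers a white signal without leaking pure-color planes), "mean" is
# the grayscale average.
extract_plane <- function(rgb, sel) {
  switch(sel,
    R = rgb[, , 1], G = rgb[, , 2], B = rgb[, , 3],
    min = pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3]),
    mean = floor((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3 + 0.5),
    stop(sprintf("unknown plane selector '%s' (use R, G, B, min or mean)", sel))
  )
}

#' Split a merged RGB image into channel roles
#'
#' Merged images carry several markers in one RGB raster (e.g. green
#' F-actin cell bodies and white CX43 puncta). `role_assignment` maps each
#' channel role to a plane selector: `"R"`, `"G"`, `"B"`, `"min"`
#' (pixelwise minimum of the three planes, which isolates a white signal
#' because white is high in all planes) or `"mean"`. Role `c1` is
#' mandatory. A single-plane (grayscale) input may be assigned to `c1`
#' only.
#'
#' @param rgb numeric `H x W x 3` array, or a plain matrix for
#'   single-channel input.
#' @param role_assignment named list/vector, e.g.
#'   `list(c1 = "G", c2 = "min", c3 = "R")`.
#' @param scale micrometers per pixel.
#' @return A `channel_set`.
#' @export
split_merged <- function(rgb, role_assignment, scale = 1) {
  roles <- names(role_assignment)
  if (!("c1" %in% roles))
    stop("role_assignment must assign channel role 'c1'")
  bad <- setdiff(roles, c("c1", "c2", "c3"))
  if (length(bad)) stop("unknown channel roles: ", paste(bad, collapse = ", "))
  if (is.matrix(rgb)) {
    if (!identical(roles, "c1"))
      stop("a single-plane image can only be assigned to role c1")
    return(channel_set(gray_image(as_int_mat(rgb), scale)))
  }
  grab <- function(role) {
    if (!(role %in% roles)) return(NULL)
    gray_image(as_int_mat(extract_plane(rgb, role_assignment[[role]])), scale)
  }
  channel_set(grab("c1"), grab("c2"), grab("c3"))
}

as_int_mat <- function(m) {
  out <- matrix(as.integer(m), nrow(m), ncol(m))
  out
}

# Read a raster file (TIFF or PNG) as integer data, linearly rescaled to
# the 8-bit range when the source has higher bit depth. Returns a matrix
# (single-plane) or an H x W x 3 array (RGB); an alpha plane is dropped.
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    v <- png::readPNG(path) * 255
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(v)) == 3L && dim(v)[3] >= 3L) v <- v[, , 1:3, drop = FALSE]
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1]
  mx <- max(v)
  if (mx > 255) v <- v * (255 / 65535)  # 16-bit source
  v <- floor(v + 0.5)
  if (is.matrix(v)) as_int_mat(v) else {
    storage.mode(v) <- "integer"
    v
  }
}

#' Write a grayscale image or binary mask to an 8-bit raster file
#'
#' Binary masks are written with foreground 255 and background 0. The
#' format follows the file extension (`.tif`/`.tiff` or `.png`). Writing
#' and re-loading an 8-bit TIFF round-trips bit-exactly.
#'
#' @param x a `gray_image` or `binary_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  px <- if (inherits(x, "binary_mask")) {
    matrix(as.integer(x$px) * 255L, nrow(x$px), ncol(x$px))
  } else if (inherits(x, "gray_image")) {
    x$px
  } else stop("`x` must be a gray_image or binary_mask")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(px / 255, path)
  } else stop("unsupported image format '", ext, "'")
  invisible(path)
}

#' Load calibrated channels from image files
#'
#' Accepts either per-channel single-plane files (`paths`, a named list
#' with entries `c1`, optionally `c2`, `c3`) or one merged RGB file
#' (`merged` plus `role_assignment`, see [split_merged()]). RGB inputs to
#' per-channel roles are collapsed with [to_grayscale()]. When the
#' configuration requests histogram equalization, every channel of the
#' returned set is equalized; `c4` always keeps the raw `c2` intensities
#' because CX43 quantification applies its own equalization.
#'
#' @param paths named list of file paths (`c1` required), or `NULL`.
#' @param merged path to a merged RGB image, or `NULL`.
#' @param role_assignment plane selectors for `merged` (see
#'   [split_merged()]).
#' @param config a [pipeline_config()]; supplies `scale` and the
#'   per-channel `equalize` flags.
#' @return A `channel_set`.
#' @export
load_channels <- function(paths = NULL, merged = NULL, role_assignment = NULL,
                          config = default_config()) {
  if (is.null(paths) == is.null(merged))
    stop("provide exactly one of `paths` or `merged`")
  if (!is.null(merged)) {
    if (is.null(role_assignment))
      stop("`role_assignment` is required for a merged image")
    raw <- read_raster(merged)
    cs <- split_merged(raw, role_assignment, scale = config$scale)
  } else {
    if (is.null(paths$c1)) stop("`paths` must contain an entry 'c1'")
    rd <- function(p) {
      if (is.null(p)) return(NULL)
      v <- read_raster(p)
      if (!is.matrix(v)) to_grayscale(v, config$scale)
      else gray_image(v, config$scale)
    }
    chans <- lapply(paths[intersect(c("c1", "c2", "c3"), names(paths))], rd)
    dims <- lapply(chans, function(g) dim(g$px))
    if (length(unique(dims)) > 1L)
      stop("channel files have mismatched dimensions")
    cs <- channel_set(chans$c1, chans$c2, chans$c3)
  }
  for (role in c("c1", "c2", "c3")) {
    p <- config$channels[[role]]
    if (!is.null(cs[[role]]) && isTRUE(p$equalize))
      cs[[role]] <- equalize_histogram(cs[[role]])
  }
  cs
}

#' Pixel-to-micrometer conversions
#'
#' Linear and quadratic scale-bar conversions: lengths in pixels times the
#' scale give micrometers, pixel counts times the squared scale give
#' square micrometers.
#'
#' @param value_px length in pixels (or pixel count for areas).
#' @param scale micrometers per pixel (> 0).
#' @return Micrometers (resp. square micrometers).
#' @export
px_to_um <- function(value_px, scale) {
  if (!is.numeric(scale) || any(scale <= 0)) stop("scale must be positive")
  value_px * scale
}

#' @rdname px_to_um
#' @export
area_px_to_um2 <- function(value_px, scale) {
  if (!is.numeric(scale) || any(scale <= 0)) stop("scale must be positive")
  value_px * scale^2
}
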