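#' Binary raster mask
#'
#' A logical matrix plus a role tag and the physical scale. Roles follow
#' the pipeline vocabulary: `Mc1`..`Mc4` are binarized channels, `Ma` is
#' the automatic cardiomyocyte mask, `Mm` a manually delineated mask and
#' `Mt` the tissue mask.
#'
#' @param pixels logical matrix (coerced with `!= 0` if numeric).
#' @param role one of `"Mc1"`, `"Mc2"`, `"Mc3"`, `"Mc4"`, `"Ma"`, `"Mm"`,
#'   `"Mt"`.
#' @param scale micrometers per pixel.
#' @return An object of class `binary_mask` with fields `px`, `role`,
#'   `scale`.
#' @export
binary_mask <- function(pixels, role = "Ma", scale = 1) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    pixels <- pixels != 0
  }
  role <- match.arg(role, c("Mc1", "Mc2", "Mc3", "Mc4", "Ma", "Mm", "Mt"))
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  structure(list(px = pixels, role = role, scale = as.numeric(scale)),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$px)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> role %s, %d x %d px, %d foreground px\n",
              x$role, nrow(x$px), ncol(x$px), sum(x$px)))
  invisible(x)
}

#' Read a binary mask from an 8-bit raster file
#'
#' Any pixel with intensity above 127 is foreground; this accepts both
#' 0/1 and 0/255 encodings of externally drawn masks.
#'
#' @param path TIFF or PNG file.
#' @param role mask role tag (default `"Mm"`, a manual mask).
#' @param scale micrometers per pixel.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, role = "Mm", scale = 1) {
  v <- read_raster(path)
  if (!is.matrix(v)) v <- floor((v[, , 1] + v[, , 2] + v[, , 3]) / 3 + 0.5)
  binary_mask(v > 127, role = role, scale = scale)
}

# ---- square-kernel binary morphology ---------------------------------------
#
# Structuring elements are n x n squares of ones ("rank n"). The anchor is
# the central pixel for odd n; for even n it is the top-left pixel of the
# central 2 x 2 block, giving kernel offsets -floor((n-1)/2) .. n-1-floor((n-1)/2).
# Out-of-image pixels are treated as background (zero padding), which makes
# erosion strip foreground touching the border and keeps dilation confined
# to the raster.

kernel_offsets <- function(n) {
  if (n < 1) stop("kernel rank must be >= 1")
  (0:(n - 1L)) - (n - 1L) %/% 2L
}

# Shift a logical matrix by (dy, dx), filling with FALSE.
shift_mask <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rd <- (max(1L, 1L + dy)):(min(H, H + dy))
  cd <- (max(1L, 1L + dx)):(min(W, W + dx))
  if (length(rd) < 1L || length(cd) < 1L || rd[1] > rd[length(rd)]) return(out)
  out[rd, cd] <- m[rd - dy, cd - dx, drop = FALSE]
  out
}

binary_dilate_once <- function(m, n) {
  if (n == 1L) return(m)
  offs <- kernel_offsets(n)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dy in offs) for (dx in offs) out <- out | shift_mask(m, dy, dx)
  out
}

binary_erode_once <- function(m, n) {
  if (n == 1L) return(m)
  offs <- kernel_offsets(n)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (dy in offs) for (dx in offs) out <- out & shift_mask(m, -dy, -dx)
  out
}

#' Binarize a grayscale channel
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.
#'
#' @param img a `gray_image`.
#' @param thr integer threshold in \[0, 255\].
#' @param role role tag of the resulting mask.
#' @return A `binary_mask`.
#' @export
binarize <- function(img, thr, role = "Mc1") {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(thr) || length(thr) != 1L || thr < 0 || thr > 255)
    stop("threshold must lie in [0, 255]")
  binary_mask(img$px > thr, role = role, scale = img$scale)
}

#' Morphological opening for noise removal
#'
#' Erosion followed by dilation with an `nr x nr` square structuring
#' element. Small isolated objects (typically noise) vanish because the
#' erosion deletes them entirely and the dilation cannot restore what is
#' gone; large objects are preserved up to boundary re-growth. Rank 1 is
#' the identity.
#'
#' @param mask a `binary_mask`.
#' @param nr kernel rank (side length of the square window, >= 1).
#' @return A `binary_mask` of the same role.
#' @export
denoise_open <- function(mask, nr) {
  stopifnot(inherits(mask, "binary_mask"), nr >= 1)
  nr <- as.integer(nr)
  if (nr == 1L) return(mask)
  binary_mask(binary_dilate_once(binary_erode_once(mask$px, nr), nr),
              role = mask$role, scale = mask$scale)
}

#' Iterated dilation for boundary growth
#'
#' Applies `ng_it` successive dilations with an `ng x ng` square
#' structuring element, enlarging foreground objects to compensate for
#' pixels removed by noise suppression. Rank 1 is the identity; the output
#' always contains the input.
#'
#' @param mask a `binary_mask`.
#' @param ng kernel rank (>= 1).
#' @param ng_it number of dilation iterations (>= 1).
#' @return A `binary_mask` of the same role.
#' @export
grow <- function(mask, ng, ng_it = 1L) {
  stopifnot(inherits(mask, "binary_mask"), ng >= 1, ng_it >= 1)
  ng <- as.integer(ng); ng_it <- as.integer(ng_it)
  if (ng == 1L) return(mask)
  px <- mask$px
  for (i in seq_len(ng_it)) px <- binary_dilate_once(px, ng)
  binary_mask(px, role = mask$role, scale = mask$scale)
}

#' Per-channel processing parameters
#'
#' One set of Table-style parameters for a channel: binarization threshold
#' `thr`, noise-removal opening rank `nr`, growth rank `ng` with `ng_it`
#' iterations, and whether the channel is histogram-equalized before
#' thresholding. Rank 1 means no morphological transformation.
#'
#' @param thr integer threshold in \[0, 255\].
#' @param nr opening rank (>= 1).
#' @param ng growth rank (>= 1).
#' @param ng_it growth iterations (>= 1).
#' @param equalize logical; equalize the channel histogram before
#'   thresholding.
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(thr, nr = 1L, ng = 1L, ng_it = 1L, equalize = FALSE) {
  if (thr < 0 || thr > 255) stop("thr must lie in [0, 255]")
  if (nr < 1 || ng < 1 || ng_it < 1) stop("kernel ranks and iterations must be >= 1")
  structure(list(thr = as.integer(thr), nr = as.integer(nr),
                 ng = as.integer(ng), ng_it = as.integer(ng_it),
                 equalize = isTRUE(equalize)),
            class = "channel_params")
}

#' Build the binary mask of one channel
#'
#' Full per-channel pipeline: optional histogram equalization,
#' binarization, opening for noise removal, then iterated growth. With
#' `nr = ng = ng_it = 1` the result equals pure thresholding. Channels
#' already equalized on load (attribute `equalized`) are not equalized a
#' second time.
#'
#' @param img a `gray_image`.
#' @param p a [channel_params()].
#' @param role role tag of the resulting mask.
#' @return A `binary_mask`.
#' @export
build_channel_mask <- function(img, p, role = "Mc1") {
  stopifnot(inherits(img, "gray_image"), inherits(p, "channel_params"))
  if (p$equalize && !isTRUE(attr(img, "equalized"))) img <- equalize_histogram(img)
  grow(denoise_open(binarize(img, p$thr, role = role), p$nr), p$ng, p$ng_it)
}

all_zero_like <- function(m, role) {
  binary_mask(matrix(FALSE, nrow(m$px), ncol(m$px)), role = role, scale = m$scale)
}

check_same_dim <- function(...) {
  ms <- Filter(Negate(is.null), list(...))
  dims <- lapply(ms, function(m) dim(m$px))
  if (length(unique(dims)) > 1L) stop("masks have mismatched dimensions")
  invisible(TRUE)
}

#' Combine channel masks into the automatic cardiomyocyte mask
#'
#' A `Mc1` pixel stays active unless it is active in both the CX43 mask
#' `Mc2` and the interstitium mask `Mc3`: the combination is the union of
#' `Mc1 & !Mc2` and `Mc1 & !Mc3`. Absent channels enter as all-zero masks,
#' so with one channel the automatic mask degenerates to `Mc1`.
#'
#' @param Mc1,Mc2,Mc3 `binary_mask` objects (`Mc2`, `Mc3` may be `NULL`).
#' @return A `binary_mask` with role `Ma`.
#' @export
combine_automatic_mask <- function(Mc1, Mc2 = NULL, Mc3 = NULL) {
  stopifnot(inherits(Mc1, "binary_mask"))
  if (is.null(Mc2)) Mc2 <- all_zero_like(Mc1, "Mc2")
  if (is.null(Mc3)) Mc3 <- all_zero_like(Mc1, "Mc3")
  check_same_dim(Mc1, Mc2, Mc3)
  px <- (Mc1$px & !Mc2$px) | (Mc1$px & !Mc3$px)
  binary_mask(px, role = "Ma", scale = Mc1$scale)
}

#' Build the CX43 quantification mask
#'
#' The raw duplicate of the CX43 channel is histogram-equalized and
#' binarized at a fixed high threshold (default 254, i.e. roughly the top
#' 1% of the equalized intensity distribution), with no noise removal and
#' no dilation. On a constant channel the equalization convention leaves
#' intensities unchanged, so the mask is all-ones only if the constant
#' exceeds the threshold.
#'
#' @param c2 a `gray_image` (the raw CX43 channel, i.e. `c4`).
#' @param thr_c4 threshold on the equalized channel (default 254).
#' @return A `binary_mask` with role `Mc4`.
#' @export
build_cx43_mask <- function(c2, thr_c4 = 254L) {
  if (is.null(c2)) stop("CX43 channel c2 is absent")
  stopifnot(inherits(c2, "gray_image"))
  eq <- equalize_histogram(gray_image(c2$px, c2$scale))
  binarize(eq, thr_c4, role = "Mc4")
}

#' Build the tissue mask
#'
#' Pixelwise union of the binarized channels: a pixel belongs to tissue if
#' it is active in `Mc1`, `Mc2` or `Mc3`. Absent channels contribute
#' nothing.
#'
#' @param Mc1,Mc2,Mc3 `binary_mask` objects (`Mc2`, `Mc3` may be `NULL`).
#' @return A `binary_mask` with role `Mt`.
#' @export
build_tissue_mask <- function(Mc1, Mc2 = NULL, Mc3 = NULL) {
  stopifnot(inherits(Mc1, "binary_mask"))
  check_same_dim(Mc1, Mc2, Mc3)
  px <- Mc1$px
  if (!is.null(Mc2)) px <- px | Mc2$px
  if (!is.null(Mc3)) px <- px | Mc3$px
  binary_mask(px, role = "Mt", scale = Mc1$scale)
}

#' Pipeline configuration
#'
#' All tunable parameters of the detection and quantification pipeline:
#' per-channel processing parameters, the fixed CX43 threshold, the
#' physical scale, the contour and box plausibility filters, and the box
#' padding `h`. Defaults reproduce the standard three-channel human
#' ventricular configuration: thresholds 8/15/2 for c1/c2/c3, opening and
#' growth ranks 3 with 3 growth iterations for c1 and c3 and 5 for c2,
#' CX43 threshold 254, scale 0.21 um/px, contour filters
#' `area > 100 um^2` and `perimeter > 40 um`, box filters
#' `20 < L < 200 um` and `5 < W < 50 um`.
#'
#' When `h` is `NULL` it is derived from the c2 growth parameters as
#' `2 * ng_c2 * ng_it_c2`, the outward padding that compensates the cell
#' mask shrinkage caused by CX43 mask dilation; when c2 is absent or its
#' growth rank is 1 (no dilation applied) no compensation is needed and
#' the derived padding is 0.
#'
#' @param c1,c2,c3 [channel_params()] for the three channels (`c2`, `c3`
#'   may be `NULL` for one/two-channel inputs).
#' @param thr_c4 fixed threshold for the equalized CX43 quantification
#'   channel.
#' @param scale micrometers per pixel.
#' @param min_area_um2,min_perim_um contour plausibility filters (strict
#'   lower bounds).
#' @param L_range,W_range box plausibility filters in micrometers (strict
#'   open intervals).
#' @param h box padding in pixels, or `NULL` to derive it from the c2
#'   growth parameters.
#' @param invert_c3 when `TRUE` and no c3 channel exists, use the
#'   complement of `Mc1` as interstitium mask.
#' @param clat_bin_width histogram bin width (lateralization percent) for
#'   the exponential fit.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(c1 = channel_params(8, 3, 3, 3),
                            c2 = channel_params(15, 3, 3, 5),
                            c3 = channel_params(2, 3, 3, 3),
                            thr_c4 = 254L,
                            scale = 0.21,
                            min_area_um2 = 100,
                            min_perim_um = 40,
                            L_range = c(20, 200),
                            W_range = c(5, 50),
                            h = NULL,
                            invert_c3 = FALSE,
                            clat_bin_width = 5) {
  stopifnot(inherits(c1, "channel_params"))
  if (scale <= 0) stop("scale must be positive")
  if (L_range[1] >= L_range[2] || W_range[1] >= W_range[2] ||
      any(c(L_range, W_range) < 0))
    stop("filter bounds must be positive and ordered")
  if (!is.null(h) && h < 0) stop("h must be >= 0")
  structure(list(channels = list(c1 = c1, c2 = c2, c3 = c3),
                 thr_c4 = as.integer(thr_c4), scale = scale,
                 min_area_um2 = min_area_um2, min_perim_um = min_perim_um,
                 L_range = L_range, W_range = W_range, h = h,
                 invert_c3 = isTRUE(invert_c3),
                 clat_bin_width = clat_bin_width),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_config <- function() pipeline_config()

#' Effective box padding of a configuration
#'
#' @param config a [pipeline_config()].
#' @return Padding `h` in pixels.
#' @export
config_h <- function(config) {
  if (!is.null(config$h)) return(config$h)
  p2 <- config$channels$c2
  if (is.null(p2) || p2$ng <= 1L) 0 else 2 * p2$ng * p2$ng_it
}

#' Read / write a pipeline configuration as YAML
#'
#' The file mirrors the parameter table layout: one section per channel
#' with keys `thr`, `nr`, `ng`, `ng_it`, `equalize`, plus top-level keys
#' for the scale, filters and padding.
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cp <- function(s) {
    if (is.null(s)) return(NULL)
    channel_params(s$thr, s$nr %||% 1L, s$ng %||% 1L, s$ng_it %||% 1L,
                   s$equalize %||% FALSE)
  }
  pipeline_config(
    c1 = cp(y$c1), c2 = cp(y$c2), c3 = cp(y$c3),
    thr_c4 = y$thr_c4 %||% 254L,
    scale = y$scale %||% 0.21,
    min_area_um2 = y$min_area_um2 %||% 100,
    min_perim_um = y$min_perim_um %||% 40,
    L_range = unlist(y$L_range %||% c(20, 200)),
    W_range = unlist(y$W_range %||% c(5, 50)),
    h = y$h,
    invert_c3 = y$invert_c3 %||% FALSE,
    clat_bin_width = y$clat_bin_width %||% 5)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cp <- function(p) if (is.null(p)) NULL else
    list(thr = p$thr, nr = p$nr, ng = p$ng, ng_it = p$ng_it,
         equalize = p$equalize)
  y <- list(c1 = cp(config$channels$c1), c2 = cp(config$channels$c2),
            c3 = cp(config$channels$c3),
            thr_c4 = config$thr_c4, scale = config$scale,
            min_area_um2 = config$min_area_um2,
            min_perim_um = config$min_perim_um,
            L_range = config$L_range, W_range = config$W_range,
            h = config$h, invert_c3 = config$invert_c3,
            clat_bin_width = config$clat_bin_width)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
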