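#' Rotated rectangle
#'
#' Minimum-area enclosing rectangle of a cell contour. The long axis makes
#' `angle` degrees with the image x axis, measured counterclockwise in the
#' (x, y-down) raster frame and normalized to `(-90, 90]`. Vertices are
#' stored as a 4 x 2 matrix in consecutive order around the rectangle, so
#' that vertex pairs (1, 3) and (2, 4) are the diagonals.
#'
#' @param center numeric `(x, y)` in continuous pixel coordinates.
#' @param angle long-axis angle in degrees, `(-90, 90]`.
#' @param long_px,short_px side lengths in pixels, `long_px >= short_px > 0`.
#' @param vertices optional pre-computed 4 x 2 vertex matrix; by default
#'   derived from center, angle and side lengths.
#' @return An object of class `rotated_box`.
#' @export
rotated_box <- function(center, angle, long_px, short_px, vertices = NULL) {
  if (short_px <= 0 || long_px < short_px)
    stop("side lengths must satisfy long_px >= short_px > 0")
  angle <- normalize_angle(angle)
  if (is.null(vertices)) {
    th <- angle * pi / 180
    e <- c(cos(th), sin(th)); f <- c(-sin(th), cos(th))
    l2 <- long_px / 2; s2 <- short_px / 2
    vertices <- rbind(center + l2 * e + s2 * f,
                      center - l2 * e + s2 * f,
                      center - l2 * e - s2 * f,
                      center + l2 * e - s2 * f)
  }
  structure(list(center = as.numeric(center), angle = angle,
                 long_px = long_px, short_px = short_px,
                 vertices = vertices),
            class = "rotated_box")
}

normalize_angle <- function(a) {
  a <- a %% 180
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' @export
print.rotated_box <- function(x, ...) {
  cat(sprintf("<rotated_box> center (%.1f, %.1f), %.1f x %.1f px, %.1f deg\n",
              x$center[1], x$center[2], x$long_px, x$short_px, x$angle))
  invisible(x)
}

#' Fit the minimum-area rotated rectangle around a contour
#'
#' Rotating-calipers search: the minimum-area enclosing rectangle of a
#' point set has one side collinear with an edge of the convex hull, so
#' the hull edges enumerate all candidate orientations and the smallest
#' axis-aligned bounding box over the correspondingly rotated points is
#' exact. Ties (e.g. square boxes) are broken by the first hull edge
#' attaining the minimum.
#'
#' @param x a `contour` or an n x 2 matrix of points.
#' @return A `rotated_box`.
#' @export
fit_min_area_box <- function(x) {
  pts <- if (inherits(x, "contour")) x$vertices else as.matrix(x)
  pts <- unique(pts)
  if (nrow(pts) < 3L) stop("degenerate contour: need >= 3 non-collinear points")
  hidx <- grDevices::chull(pts)
  if (length(hidx) < 3L) stop("degenerate contour: points are collinear")
  hp <- pts[hidx, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (k in seq_len(nh)) {
    k2 <- if (k == nh) 1L else k + 1L
    vx <- hp[k2, 1] - hp[k, 1]; vy <- hp[k2, 2] - hp[k, 2]
    len <- sqrt(vx^2 + vy^2)
    if (len == 0) next
    ca <- vx / len; sa <- vy / len
    xr <- hp[, 1] * ca + hp[, 2] * sa
    yr <- -hp[, 1] * sa + hp[, 2] * ca
    w <- max(xr) - min(xr); ht <- max(yr) - min(yr)
    area <- w * ht
    if (is.null(best) || area < best$area - 1e-12 * max(area, best$area)) {
      best <- list(area = area, ca = ca, sa = sa,
                   xc = (min(xr) + max(xr)) / 2, yc = (min(yr) + max(yr)) / 2,
                   w = w, h = ht)
    }
  }
  if (is.null(best) || best$w <= 0 || best$h <= 0)
    stop("degenerate contour: zero-area enclosing rectangle")
  cx <- best$xc * best$ca - best$yc * best$sa
  cy <- best$xc * best$sa + best$yc * best$ca
  edge_angle <- atan2(best$sa, best$ca) * 180 / pi
  if (best$w >= best$h) {
    rotated_box(c(cx, cy), edge_angle, best$w, best$h)
  } else {
    rotated_box(c(cx, cy), edge_angle + 90, best$h, best$w)
  }
}

#' Expand a rotated box by diagonal vertex projection
#'
#' Each vertex is pushed away from its diagonal partner by a distance `h`
#' along the diagonal (an intercept-theorem construction): vertex `i` with
#' diagonal partner `i + 2` maps to
#' `v_i + h * (v_i - v_{i+2}) / d`, where `d` is the diagonal length. The
#' result is a rectangle similar to the input, scaled by `(d + 2h) / d`,
#' with the same center and orientation. The padding compensates the cell
#' mask shrinkage caused by dilating the CX43 mask.
#'
#' @param box a `rotated_box`.
#' @param h padding distance in pixels (>= 0).
#' @return A `rotated_box`.
#' @export
expand_box <- function(box, h) {
  stopifnot(inherits(box, "rotated_box"))
  if (h < 0) stop("h must be >= 0")
  if (h == 0) return(box)
  v <- box$vertices
  partner <- c(3L, 4L, 1L, 2L)
  d <- sqrt((v[1, 1] - v[3, 1])^2 + (v[1, 2] - v[3, 2])^2)
  if (d == 0) stop("degenerate box: zero diagonal")
  vstar <- v + h * (v - v[partner, , drop = FALSE]) / d
  s <- (d + 2 * h) / d
  rotated_box(box$center, box$angle, box$long_px * s, box$short_px * s,
              vertices = vstar)
}

#' Morphometric measures of a cell box
#'
#' Length is the average of the long sides of the fitted and the expanded
#' rectangle (converted to micrometers); width is the short side of the
#' fitted rectangle. Aspect ratio and box area follow as `R = L / W` and
#' `A = L * W`.
#'
#' @param box fitted `rotated_box`.
#' @param box_expanded padded `rotated_box` (see [expand_box()]).
#' @param scale micrometers per pixel.
#' @return A list with elements `L`, `W` (um), `R` and `A` (um^2).
#' @export
measure_cm <- function(box, box_expanded, scale) {
  if (scale <= 0) stop("scale must be positive")
  L <- px_to_um((box$long_px + box_expanded$long_px) / 2, scale)
  W <- px_to_um(box$short_px, scale)
  if (W <= 0) stop("zero cell width")
  list(L = L, W = W, R = L / W, A = L * W)
}

# Local coordinates of pixel centers in a window around a box: returns the
# candidate (row, col) grid restricted to the image together with the
# coordinates (u, v) along the long/short axes relative to the center.
box_pixel_frame <- function(box, dim) {
  H <- dim[1]; W <- dim[2]
  v <- box$vertices
  # pixel (row, col) has center (col - 0.5, row - 0.5); widen by one pixel
  # on each side so boundary-tolerance pixels are never missed
  r0 <- max(1L, as.integer(floor(min(v[, 2]) - 0.5)))
  r1 <- min(H, as.integer(ceiling(max(v[, 2]) + 1.5)))
  c0 <- max(1L, as.integer(floor(min(v[, 1]) - 0.5)))
  c1 <- min(W, as.integer(ceiling(max(v[, 1]) + 1.5)))
  if (r0 > r1 || c0 > c1)
    return(list(rows = integer(0), cols = integer(0), u = NULL, v = NULL))
  rows <- r0:r1; cols <- c0:c1
  xc <- cols - 0.5; yc <- rows - 0.5
  th <- box$angle * pi / 180
  ca <- cos(th); sa <- sin(th)
  dx <- xc - box$center[1]; dy <- yc - box$center[2]
  u <- outer(dy * sa, dx * ca, "+")
  vv <- outer(dy * ca, -dx * sa, "+")
  list(rows = rows, cols = cols, u = u, v = vv)
}

#' Rasterize a rotated box on the image grid
#'
#' A pixel belongs to the box iff its center lies inside or on the box
#' boundary (with a 1e-7 px tolerance for boundary membership). This
#' single rule is shared by the compartment partition and the
#' manual-vs-automatic overlap computation so that both operate on
#' identical pixel sets. Pixels outside the image are dropped.
#'
#' @param box a `rotated_box`.
#' @param dim image dimensions `c(H, W)`.
#' @return Sorted integer vector of linear (column-major) pixel indices.
#' @export
rasterize_box <- function(box, dim) {
  fr <- box_pixel_frame(box, dim)
  if (!length(fr$rows)) return(integer(0))
  eps <- 1e-7
  inside <- abs(fr$u) <= box$long_px / 2 + eps &
    abs(fr$v) <= box$short_px / 2 + eps
  idx <- which(inside, arr.ind = TRUE)
  if (!nrow(idx)) return(integer(0))
  sort(as.integer((fr$cols[idx[, 2]] - 1L) * dim[1] + fr$rows[idx[, 1]]))
}

#' Partition a box into four compartments along its long axis
#'
#' The rasterized box is cut by three lines perpendicular to the long axis
#' at 1/4, 1/2 and 3/4 of the long side. `H0` and `H3` are the polar (end)
#' quarters, `H1` and `H2` the middle (lateral) quarters. Each pixel
#' belongs to exactly one compartment; a pixel whose center falls exactly
#' on a cut is assigned to the lower-index quarter.
#'
#' @param box a `rotated_box` (normally the expanded box).
#' @param dim image dimensions `c(H, W)`.
#' @return An object of class `compartment_partition`: a list with
#'   `compartments` (list of four sorted linear-index vectors `H0`..`H3`)
#'   and `sizes` (`N0`..`N3`).
#' @export
partition_box <- function(box, dim) {
  fr <- box_pixel_frame(box, dim)
  eps <- 1e-7
  if (!length(fr$rows)) stop("degenerate box: no pixels inside the image")
  inside <- abs(fr$u) <= box$long_px / 2 + eps &
    abs(fr$v) <= box$short_px / 2 + eps
  idx <- which(inside, arr.ind = TRUE)
  if (!nrow(idx)) stop("degenerate box: no pixels inside the image")
  lin <- as.integer((fr$cols[idx[, 2]] - 1L) * dim[1] + fr$rows[idx[, 1]])
  u01 <- fr$u[idx] + box$long_px / 2
  q <- ceiling((u01 - eps) / (box$long_px / 4)) - 1
  q <- pmin(pmax(q, 0), 3)
  comps <- lapply(0:3, function(k) sort(lin[q == k]))
  names(comps) <- paste0("H", 0:3)
  structure(list(compartments = comps,
                 sizes = vapply(comps, length, integer(1))),
            class = "compartment_partition")
}
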