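#' Traced cell contour
#'
#' Ordered outer boundary of one 8-connected foreground component, as
#' returned by border following. `vertices` holds the boundary pixel
#' centers in continuous coordinates `(x, y) = (col - 0.5, row - 0.5)`,
#' in clockwise trace order (image y axis pointing down). `area_px2` is
#' the number of raster pixels enclosed by the outer boundary (holes are
#' counted as enclosed, matching the suppression of internal contours):
#' it is obtained from the shoelace area of the boundary polygon with the
#' lattice-point correction `area = shoelace + B/2 + 1`, where `B` is the
#' number of distinct boundary pixels. `perim_px` is the Euclidean length
#' of the closed boundary path.
#'
#' @name contour
NULL

new_contour <- function(vertices) {
  n <- nrow(vertices)
  if (n == 1L) {
    area <- 1
    perim <- 0
  } else {
    xs <- vertices[, 1]; ys <- vertices[, 2]
    xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
    shoelace <- abs(sum(xs * yn - xn * ys)) / 2
    b <- nrow(unique(vertices))
    area <- shoelace + b / 2 + 1
    perim <- sum(sqrt((xn - xs)^2 + (yn - ys)^2))
  }
  structure(list(vertices = vertices, area_px2 = area, perim_px = perim),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d boundary px, area %.1f px^2, perimeter %.2f px\n",
              nrow(x$vertices), x$area_px2, x$perim_px))
  invisible(x)
}

# ---- 8-connected component labeling ----------------------------------------
#
# Row-run encoding with union-find: foreground runs are extracted per row,
# runs in consecutive rows are merged when they touch under
# 8-connectivity (column ranges overlapping or diagonally adjacent).
# Components are numbered by the raster position of their first run, which
# fixes a deterministic top-to-bottom, left-to-right discovery order.

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

label_components <- function(px) {
  H <- nrow(px); W <- ncol(px)
  row_s <- vector("list", H); row_e <- vector("list", H)
  nrun <- 0L
  for (i in seq_len(H)) {
    r <- px[i, ]
    d <- diff(c(FALSE, r, FALSE))
    s <- which(d == 1L)
    if (!length(s)) next
    e <- which(d == -1L) - 1L
    row_s[[i]] <- s; row_e[[i]] <- e
    nrun <- nrun + length(s)
  }
  if (nrun == 0L)
    return(list(labels = matrix(0L, H, W), n = 0L))
  parent <- seq_len(nrun)
  run_id0 <- 0L
  prev_ids <- integer(0); prev_row <- -2L
  run_row <- integer(nrun); run_sc <- integer(nrun); run_ec <- integer(nrun)
  for (i in seq_len(H)) {
    s <- row_s[[i]]
    if (is.null(s)) next
    e <- row_e[[i]]
    k <- length(s)
    ids <- run_id0 + seq_len(k)
    run_row[ids] <- i; run_sc[ids] <- s; run_ec[ids] <- e
    if (prev_row == i - 1L && length(prev_ids)) {
      ps <- run_sc[prev_ids]; pe <- run_ec[prev_ids]
      a <- 1L
      for (j in seq_len(k)) {
        while (a <= length(prev_ids) && pe[a] < s[j] - 1L) a <- a + 1L
        b <- a
        while (b <= length(prev_ids) && ps[b] <= e[j] + 1L) {
          ra <- uf_find(parent, prev_ids[b]); rb <- uf_find(parent, ids[j])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          b <- b + 1L
        }
      }
    }
    prev_ids <- ids; prev_row <- i; run_id0 <- run_id0 + k
  }
  roots <- vapply(seq_len(nrun), function(i) uf_find(parent, i), integer(1))
  comp_of_root <- integer(nrun)
  n_comp <- 0L
  lab_of_run <- integer(nrun)
  for (i in seq_len(nrun)) {  # runs are in raster order: discovery order
    r <- roots[i]
    if (comp_of_root[r] == 0L) {
      n_comp <- n_comp + 1L
      comp_of_root[r] <- n_comp
    }
    lab_of_run[i] <- comp_of_root[r]
  }
  labels <- matrix(0L, H, W)
  for (i in seq_len(nrun))
    labels[run_row[i], run_sc[i]:run_ec[i]] <- lab_of_run[i]
  list(labels = labels, n = n_comp)
}

# ---- Moore border following -------------------------------------------------
#
# Clockwise Moore-neighbor tracing (image coordinates, y down) with
# Jacob's stopping criterion. `px` must be a logical matrix; tracing
# starts at the topmost, then leftmost foreground pixel of the component.
# Returns an m x 2 matrix of (row, col) indices in trace order.

.moore_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)  # E SE S SW W NW N NE
.moore_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

trace_boundary <- function(px, start_row, start_col) {
  H <- nrow(px); W <- ncol(px)
  at <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && px[r, c]
  sr <- start_row; sc <- start_col
  path_r <- integer(256); path_c <- integer(256); np <- 0L
  push <- function(r, c) {
    np <<- np + 1L
    if (np > length(path_r)) {
      path_r <<- c(path_r, integer(length(path_r)))
      path_c <<- c(path_c, integer(length(path_c)))
    }
    path_r[np] <<- r; path_c[np] <<- c
  }
  push(sr, sc)
  # backtrack starts W of the start pixel (background: start is the
  # topmost-leftmost pixel of its component)
  bdir <- 5L
  cur_r <- sr; cur_c <- sc
  first_move <- NA_integer_
  max_steps <- 8L * (sum(px) + 2L)
  steps <- 0L
  repeat {
    found <- FALSE
    start_scan <- bdir %% 8L + 1L
    for (k in 0:7) {
      d <- (start_scan - 1L + k) %% 8L + 1L
      nr <- cur_r + .moore_dy[d]; nc <- cur_c + .moore_dx[d]
      if (at(nr, nc)) {
        if (is.na(first_move)) first_move <- d
        else if (cur_r == sr && cur_c == sc && d == first_move) {
          return(cbind(path_r[1:(np - 1L)], path_c[1:(np - 1L)]))
        }
        # new backtrack: the neighbor scanned just before the hit,
        # expressed as a direction from the *new* current pixel
        prev_d <- (d - 2L) %% 8L + 1L
        pr <- cur_r + .moore_dy[prev_d]; pc <- cur_c + .moore_dx[prev_d]
        bdir <- dir_between(nr, nc, pr, pc)
        cur_r <- nr; cur_c <- nc
        push(cur_r, cur_c)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    steps <- steps + 1L
    if (steps > max_steps) stop("boundary tracing failed to terminate")
  }
  cbind(path_r[1:np], path_c[1:np])
}

dir_between <- function(fr, fc, tr, tc) {
  dy <- tr - fr; dx <- tc - fc
  dy <- sign(dy); dx <- sign(dx)
  which(.moore_dy == dy & .moore_dx == dx)[1]
}

#' Extract external contours from a binary mask
#'
#' Labels the 8-connected foreground components of the mask and traces the
#' outer boundary of each by clockwise Moore border following. Internal
#' (hole) contours are never produced. Components are returned in
#' deterministic discovery order: top-to-bottom, then left-to-right, by
#' the position of the first foreground pixel of each component.
#'
#' @param mask a `binary_mask`.
#' @return A list of `contour` objects (empty list for an empty mask).
#' @export
find_external_contours <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components(mask$px)
  if (lab$n == 0L) return(list())
  H <- nrow(lab$labels)
  idx_all <- which(lab$labels > 0L)
  by_comp <- split(idx_all, lab$labels[idx_all])
  out <- vector("list", lab$n)
  for (id in seq_len(lab$n)) {
    idx <- by_comp[[as.character(id)]]
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    # start at topmost-leftmost pixel of the component
    top <- which(rows == r0)
    sc <- min(cols[top])
    path <- trace_boundary(sub, 1L, sc - c0 + 1L)
    verts <- cbind(path[, 2] + (c0 - 1L) - 0.5,   # x
                   path[, 1] + (r0 - 1L) - 0.5)   # y
    out[[id]] <- new_contour(verts)
  }
  out
}

#' Filter contours by plausible area and perimeter
#'
#' Keeps a contour iff its enclosed area exceeds `min_area_um2` and its
#' perimeter exceeds `min_perim_um` (both strict, in physical units).
#' Applied before rectangle fitting, this discards contours that cannot
#' correspond to cardiomyocytes and speeds up the downstream stages.
#'
#' @param contours list of `contour` objects.
#' @param scale micrometers per pixel.
#' @param min_area_um2 strict lower bound on the enclosed area, um^2.
#' @param min_perim_um strict lower bound on the perimeter, um.
#' @return The retained contours, in their original order.
#' @export
filter_contours <- function(contours, scale, min_area_um2 = 100,
                            min_perim_um = 40) {
  if (scale <= 0) stop("scale must be positive")
  keep <- vapply(contours, function(ct) {
    area_px_to_um2(ct$area_px2, scale) > min_area_um2 &&
      px_to_um(ct$perim_px, scale) > min_perim_um
  }, logical(1))
  contours[keep]
}
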