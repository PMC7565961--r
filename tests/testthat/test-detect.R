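test_that("external contours are traced with holes suppressed", {
  expect_length(find_external_contours(binary_mask(matrix(FALSE, 8, 8))), 0)
  sq <- matrix(FALSE, 20, 20); sq[5:14, 3:12] <- TRUE
  cts <- find_external_contours(binary_mask(sq))
  expect_length(cts, 1)
  expect_equal(cts[[1]]$area_px2, 100)
  expect_equal(cts[[1]]$perim_px, 36)
  holed <- sq; holed[8:11, 6:9] <- FALSE
  cts2 <- find_external_contours(binary_mask(holed))
  expect_length(cts2, 1)
  expect_equal(cts2[[1]]$area_px2, 100)  # enclosed area includes the hole
})

test_that("diagonally touching pixels form one 8-connected component", {
  px <- matrix(FALSE, 6, 6)
  px[2, 2] <- TRUE; px[3, 3] <- TRUE; px[4, 4] <- TRUE
  expect_length(find_external_contours(binary_mask(px)), 1)
})

test_that("contours are discovered top-to-bottom, left-to-right", {
  px <- matrix(FALSE, 30, 30)
  px[20:24, 2:6] <- TRUE    # lower-left blob
  px[3:7, 20:24] <- TRUE    # upper-right blob
  px[10:14, 10:14] <- TRUE  # middle blob
  cts <- find_external_contours(binary_mask(px))
  tops <- vapply(cts, function(ct) min(ct$vertices[, 2]), numeric(1))
  expect_equal(order(tops), 1:3)
})

test_that("contour filtering applies strict area and perimeter bounds", {
  fake <- function(area, perim) {
    structure(list(vertices = matrix(0, 3, 2), area_px2 = area,
                   perim_px = perim), class = "contour")
  }
  # scale 1 => px^2 == um^2
  kept <- filter_contours(list(fake(99, 50), fake(150, 39), fake(150, 50),
                               fake(100, 50), fake(150, 40)), scale = 1)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$area_px2, 150)
  expect_equal(kept[[1]]$perim_px, 50)
})

test_that("minimum-area rectangles are exact on known rectangles", {
  b <- fit_min_area_box(rbind(c(0, 0), c(10, 0), c(10, 4), c(0, 4)))
  expect_equal(b$long_px, 10)
  expect_equal(b$short_px, 4)
  expect_equal(b$angle, 0)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  pts <- rbind(c(0, 0), c(10, 0), c(10, 4), c(0, 4)) %*% t(R)
  b2 <- fit_min_area_box(pts)
  expect_equal(b2$long_px, 10, tolerance = 1e-9)
  expect_equal(b2$short_px, 4, tolerance = 1e-9)
  expect_equal(abs(b2$angle), 30, tolerance = 1e-9)
  expect_error(fit_min_area_box(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("minimum-area rectangle matches the hull-edge oracle on random clouds", {
  set.seed(31)
  for (i in 1:40) {
    pts <- cbind(stats::rnorm(20, sd = 10), stats::rnorm(20, sd = 4))
    b <- fit_min_area_box(pts)
    expect_equal(b$long_px * b$short_px, min_area_oracle(pts),
                 tolerance = 1e-9)
    aabb <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
    expect_lte(b$long_px * b$short_px, aabb + 1e-9)
    # all points enclosed
    th <- b$angle * pi / 180
    u <- (pts[, 1] - b$center[1]) * cos(th) + (pts[, 2] - b$center[2]) * sin(th)
    v <- -(pts[, 1] - b$center[1]) * sin(th) + (pts[, 2] - b$center[2]) * cos(th)
    expect_true(all(abs(u) <= b$long_px / 2 + 1e-9))
    expect_true(all(abs(v) <= b$short_px / 2 + 1e-9))
  }
})

test_that("box expansion projects vertices along the diagonals", {
  sq <- fit_min_area_box(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_identical(expand_box(sq, 0), sq)
  e <- expand_box(sq, sqrt(2))
  expect_equal(sort(e$vertices[, 1]), c(-1, -1, 11, 11))
  expect_equal(sort(e$vertices[, 2]), c(-1, -1, 11, 11))
  expect_equal(e$long_px, 12)
  set.seed(32)
  for (i in 1:20) {
    b <- rotated_box(stats::runif(2, 20, 80), stats::runif(1, -90, 90),
                     stats::runif(1, 30, 60), stats::runif(1, 5, 25))
    h <- stats::runif(1, 0, 10)
    e <- expand_box(b, h)
    # vertex projection equals the direct formula
    expect_equal(e$vertices, expand_vertices_oracle(b$vertices, h),
                 tolerance = 1e-9)
    # similarity: aspect ratio preserved, diagonal grows by 2h
    expect_equal(e$long_px / e$short_px, b$long_px / b$short_px,
                 tolerance = 1e-9)
    d0 <- sqrt(b$long_px^2 + b$short_px^2)
    expect_equal(sqrt(e$long_px^2 + e$short_px^2), d0 + 2 * h,
                 tolerance = 1e-9)
    expect_equal(e$center, b$center, tolerance = 1e-9)
  }
  expect_error(expand_box(sq, -1), ">= 0")
})

test_that("morphometry averages the fitted and expanded long sides", {
  b <- rotated_box(c(0, 0), 0, 100, 40)
  e <- rotated_box(c(0, 0), 0, 120, 48)
  m <- measure_cm(b, e, 0.21)
  expect_equal(m$L, 0.21 * 110)
  expect_equal(m$L, 23.1)
  expect_equal(m$W, 0.21 * 40)   # width from the fitted box only
  expect_equal(m$R, m$L / m$W)
  expect_equal(m$A, m$L * m$W)
  m0 <- measure_cm(b, b, 0.21)   # h = 0: L from the fitted box alone
  expect_equal(m0$L, 0.21 * 100)
})

test_that("box filtering applies strict open intervals on L and W", {
  fake <- function(L, W) structure(list(L = L, W = W), class = "cm_record")
  recs <- list(fake(19, 10), fake(21, 10), fake(100, 55), fake(200, 10),
               fake(150, 5), fake(199.9, 49.9))
  kept <- filter_boxes(recs)
  expect_equal(vapply(kept, function(r) r$L, numeric(1)), c(21, 199.9))
})

test_that("detection recovers disjoint rectangles with accurate morphometry", {
  rects <- list(list(rows = 10:59, cols = 10:24),    # 50 x 15
                list(rows = 10:89, cols = 40:64),    # 80 x 25
                list(rows = 120:180, cols = 15:34),  # 61 x 20
                list(rows = 110:150, cols = 60:75))  # 41 x 16
  ch <- c1_only_channels(200, 100, rects, scale = 1)
  cfg <- identity_config(scale = 1)
  recs <- detect_myocytes(ch, cfg)
  expect_length(recs, 4)
  true_L <- c(50, 80, 61, 41); true_W <- c(15, 25, 20, 16)
  # records are in discovery order = rect order (sorted by top row)
  ord <- order(vapply(rects, function(r) min(r$rows), numeric(1)))
  got_L <- vapply(recs, function(r) r$L, numeric(1))
  got_W <- vapply(recs, function(r) r$W, numeric(1))
  expect_true(all(abs(got_L - true_L[ord]) <= 2))
  expect_true(all(abs(got_W - true_W[ord]) <= 2))
  # every returned record satisfies the plausibility filters
  expect_true(all(got_L > cfg$L_range[1] & got_L < cfg$L_range[2]))
  expect_true(all(got_W > cfg$W_range[1] & got_W < cfg$W_range[2]))
})

test_that("implausibly small objects and empty inputs yield no records", {
  small <- c1_only_channels(60, 60, list(list(rows = 10:14, cols = 10:14),
                                         list(rows = 30:37, cols = 30:37)),
                            scale = 1)
  expect_length(detect_myocytes(small, identity_config(scale = 1)), 0)
  empty <- c1_only_channels(40, 40, list(), scale = 1)
  expect_length(detect_myocytes(empty, identity_config(scale = 1)), 0)
})

test_that("detection is deterministic", {
  sc <- synthetic_scene(n_cells = 3, image_size = c(400L, 400L), seed = 5)
  r <- render_scene(sc)
  cfg <- synthetic_scene_config(sc)
  t1 <- cm_table(detect_myocytes(r$channels, cfg))
  t2 <- cm_table(detect_myocytes(r$channels, cfg))
  expect_identical(t1, t2)
})

test_that("selection manifests subset records non-interactively", {
  fake <- function(id) structure(list(id = id), class = "cm_record")
  recs <- lapply(1:5, fake)
  expect_identical(apply_selection(recs, 1:5), recs)
  expect_length(apply_selection(recs, integer(0)), 0)
  expect_identical(apply_selection(recs, 1:2), recs[1:2])
  expect_identical(apply_selection(recs, c(4, 2)), recs[c(2, 4)])
  expect_error(apply_selection(recs, c(2, 9)), "unknown ids")
})
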