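test_that("expression and noise ratios match direct pixel counting", {
  mt <- matrix(FALSE, 20, 20); mt[1:10, ] <- TRUE    # 200 tissue px
  mc4 <- matrix(FALSE, 20, 20); mc4[1:5, 1:10] <- TRUE  # 50 px inside tissue
  Mt <- binary_mask(mt, "Mt"); Mc4 <- binary_mask(mc4, "Mc4")
  expect_equal(compute_cex(Mc4, Mt), 25.0)
  expect_equal(compute_cex(binary_mask(matrix(FALSE, 20, 20), "Mc4"), Mt), 0)
  expect_equal(compute_noise(Mc4, Mt), 0)  # Mc4 inside Mt: no noise
  off <- matrix(FALSE, 20, 20); off[15:16, 1:10] <- TRUE
  expect_equal(compute_noise(binary_mask(off, "Mc4"), Mt), 100 * 20 / 200)
  set.seed(41)
  for (i in 1:25) {
    mt <- rand_mask(12, 12, p = 0.5, role = "Mt")
    mc <- rand_mask(12, 12, p = 0.3, role = "Mc4")
    if (sum(mt$px) > 0)
      expect_equal(compute_cex(mc, mt), cex_oracle(mc$px, mt$px))
    if (any(!mt$px))
      expect_equal(compute_noise(mc, mt), noise_oracle(mc$px, mt$px))
  }
})

test_that("degenerate tissue masks raise undefined-ratio errors", {
  full <- binary_mask(matrix(TRUE, 5, 5), "Mt")
  empty <- binary_mask(matrix(FALSE, 5, 5), "Mt")
  mc <- binary_mask(matrix(FALSE, 5, 5), "Mc4")
  expect_error(compute_cex(mc, empty), "empty")
  expect_error(compute_noise(mc, full), "whole image")
})

test_that("tissue area converts pixel counts and maximum contours to mm^2", {
  empty <- binary_mask(matrix(FALSE, 10, 10), "Mt")
  expect_equal(tissue_area(empty, 0.21, "pixel_count"), 0)
  expect_equal(tissue_area(empty, 0.21, "max_contour"), 0)
  solid <- binary_mask(matrix(TRUE, 1000, 1000), "Mt", scale = 0.21)
  expect_equal(tissue_area(solid, 0.21, "pixel_count"), 0.0441)
  expect_equal(tissue_area(solid, 0.21, "max_contour"), 0.0441)
  # max_contour keeps only the largest region
  two <- matrix(FALSE, 60, 60); two[2:41, 2:41] <- TRUE; two[50:54, 50:54] <- TRUE
  m <- binary_mask(two, "Mt")
  expect_equal(tissue_area(m, 1, "max_contour"), 1600 * 1e-6)
  expect_equal(tissue_area(m, 1, "pixel_count"), (1600 + 25) * 1e-6)
})

test_that("an axis-aligned box partitions into four equal compartments", {
  # 40 x 8 px box on the grid: x in [0,40], y in [0,8]
  b <- rotated_box(c(20, 4), 0, 40, 8)
  part <- partition_box(b, c(20, 50))
  expect_equal(unname(part$sizes), rep(80L, 4))
  # compartment H0 is the low-u end: columns 1..10
  cols0 <- (part$compartments$H0 - 1L) %/% 20L + 1L
  expect_true(all(cols0 %in% 1:10))
  cols3 <- (part$compartments$H3 - 1L) %/% 20L + 1L
  expect_true(all(cols3 %in% 31:40))
})

test_that("partition compartments are disjoint and cover the rasterized box", {
  set.seed(42)
  for (i in 1:15) {
    b <- rotated_box(stats::runif(2, 30, 70), stats::runif(1, -90, 90),
                     stats::runif(1, 25, 50), stats::runif(1, 6, 20))
    dim <- c(100L, 100L)
    part <- partition_box(b, dim)
    all_px <- unlist(part$compartments, use.names = FALSE)
    expect_equal(length(all_px), length(unique(all_px)))  # disjoint
    expect_setequal(all_px, rasterize_box(b, dim))        # union = raster
  }
})

test_that("square boxes still partition along the designated long axis", {
  b <- rotated_box(c(25, 25), 45, 20, 20)
  part <- partition_box(b, c(50, 50))
  expect_equal(sum(part$sizes), length(rasterize_box(b, c(50, 50))))
  expect_true(all(part$sizes >= 1))
})

test_that("compartment fractions count CX43 pixels against box pixels", {
  b <- rotated_box(c(20, 4), 0, 40, 8)
  dimg <- c(20L, 50L)
  part <- partition_box(b, dimg)
  empty <- binary_mask(matrix(FALSE, dimg[1], dimg[2]), "Mc4")
  expect_equal(unname(compartment_fractions(part, empty)), rep(0, 4))
  full <- binary_mask(matrix(TRUE, dimg[1], dimg[2]), "Mc4")
  expect_equal(unname(compartment_fractions(part, full)), rep(1, 4))
  set.seed(43)
  for (i in 1:10) {
    mc4 <- rand_mask(dimg[1], dimg[2], p = 0.3, role = "Mc4")
    got <- compartment_fractions(part, mc4)
    want <- vapply(part$compartments, fraction_oracle, numeric(1),
                   mc4 = mc4$px)
    expect_equal(unname(got), unname(want))
    # conservation: compartment counts sum to the box-level count
    n_in_box <- sum(mc4$px[rasterize_box(b, dimg)])
    expect_equal(sum(got * part$sizes), n_in_box)
  }
})

test_that("lateralization percentage behaves at its anchor points", {
  expect_equal(compute_clat(c(0.1, 0, 0, 0.2))$clat, 0)
  expect_equal(compute_clat(c(0, 0.3, 0.1, 0))$clat, 100)
  expect_equal(compute_clat(c(0.1, 0.1, 0.1, 0.1))$clat, 50)
  z <- compute_clat(c(0, 0, 0, 0))
  expect_true(z$no_signal)
  expect_true(is.na(z$clat))
  set.seed(44)
  for (i in 1:20) {
    f <- stats::runif(4)
    a <- compute_clat(f)$clat
    b <- compute_clat(f[c(2, 1, 4, 3)])$clat  # polar/lateral swap
    expect_equal(a + b, 100)
  }
})

test_that("exponential fit inverts a noiseless model histogram", {
  a <- 0.03425; b <- 0.033
  centers <- seq(2.5, 97.5, by = 5)
  model <- fit_exp_curve(centers, a * exp(-b * centers), bin_width = 5)
  expect_equal(model$a, a, tolerance = 1e-6)
  expect_equal(model$b, b, tolerance = 1e-6)
})

test_that("exponential fit requires at least two occupied bins", {
  expect_error(fit_exponential(rep(12, 500)), "two non-empty bins")
  expect_error(fit_exp_curve(c(10, 20), c(0.5, 0)), "two non-empty bins")
})

test_that("model integration matches closed form and numerical quadrature", {
  m <- exp_fit_model(0.03425, 0.033)
  expect_equal(integrate_fraction(m, 30, 30), 0)
  set.seed(45)
  for (i in 1:10) {
    lo <- stats::runif(1, 0, 50); hi <- lo + stats::runif(1, 0, 50)
    num <- stats::integrate(function(x) m$a * exp(-m$b * x), lo, hi,
                            rel.tol = 1e-12)$value
    expect_equal(integrate_fraction(m, lo, hi), num, tolerance = 1e-10)
  }
  expect_error(integrate_fraction(m, 10, 5), "lo")
})
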