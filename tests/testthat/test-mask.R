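test_that("binarization thresholds strictly and respects bounds", {
  img <- gray_image(matrix(c(8L, 9L, 7L, 8L), 2, 2), 1)
  expect_equal(binarize(img, 8)$px, matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_true(all(binarize(gray_image(matrix(255L, 3, 3), 1), 254)$px))
  expect_false(any(binarize(gray_image(matrix(0L, 3, 3), 1), 0)$px))
  expect_error(binarize(img, 300), "255")
})

test_that("binarization is monotone in the threshold", {
  set.seed(21)
  img <- rand_gray(15, 15)
  for (i in 1:10) {
    t1 <- sample(0:254, 1); t2 <- sample(t1:255, 1)
    m1 <- binarize(img, t1)$px; m2 <- binarize(img, t2)$px
    expect_true(all(m1[m2]))  # mask(t2) subset of mask(t1)
  }
})

test_that("opening removes isolated noise, preserves large objects, rank 1 is identity", {
  set.seed(22)
  m <- rand_mask(12, 12)
  expect_identical(denoise_open(m, 1)$px, m$px)
  lone <- matrix(FALSE, 15, 15); lone[8, 8] <- TRUE
  expect_equal(sum(denoise_open(binary_mask(lone), 3)$px), 0)
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  expect_identical(denoise_open(binary_mask(sq), 3)$px, sq)
})

test_that("opening is idempotent and matches the EBImage oracle", {
  set.seed(23)
  for (i in 1:8) {
    px <- matrix(stats::runif(576) < 0.25, 24, 24)
    px[c(1:4, 21:24), ] <- FALSE; px[, c(1:4, 21:24)] <- FALSE
    m <- binary_mask(px)
    o1 <- denoise_open(m, 3)
    expect_identical(denoise_open(o1, 3)$px, o1$px)
    eb <- EBImage::opening(EBImage::Image(px * 1),
                           EBImage::makeBrush(3, "box"))
    expect_identical(o1$px, matrix(as.logical(eb > 0.5), 24, 24))
  }
})

test_that("growth dilates iteratively, is extensive and matches EBImage", {
  set.seed(24)
  m <- rand_mask(12, 12)
  expect_identical(grow(m, 1, 5)$px, m$px)
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  g <- grow(binary_mask(lone), 3, 1)$px
  expect_identical(which(g), which(row(g) %in% 4:6 & col(g) %in% 4:6))
  for (i in 1:5) {
    px <- matrix(stats::runif(400) < 0.2, 20, 20)
    px[c(1:6, 15:20), ] <- FALSE; px[, c(1:6, 15:20)] <- FALSE
    ng <- sample(c(2L, 3L, 5L), 1); it <- sample(1:2, 1)
    out <- grow(binary_mask(px), ng, it)$px
    expect_true(all(out[px]))  # input subset of output
    if (ng %% 2 == 1) {
      eb <- EBImage::Image(px * 1)
      for (k in seq_len(it)) eb <- EBImage::dilate(eb,
                                                   EBImage::makeBrush(ng, "box"))
      expect_identical(out, matrix(as.logical(eb > 0.5), 20, 20))
    }
  }
})

test_that("even growth ranks use the documented top-left anchor", {
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  g <- grow(binary_mask(lone), 4, 1)$px
  # offsets -1..2: rows/cols 4..7
  expect_identical(which(g), which(row(g) %in% 4:7 & col(g) %in% 4:7))
})

test_that("channel mask pipeline equals composed stages and pure thresholding at rank 1", {
  set.seed(25)
  img <- rand_gray(30, 30)
  p_id <- channel_params(thr = 8, nr = 1, ng = 1, ng_it = 1)
  expect_identical(build_channel_mask(img, p_id)$px, binarize(img, 8)$px)
  p <- channel_params(thr = 8, nr = 3, ng = 3, ng_it = 3)
  manual <- grow(denoise_open(binarize(img, 8), 3), 3, 3)
  expect_identical(build_channel_mask(img, p)$px, manual$px)
  empty <- gray_image(matrix(0L, 10, 10), 1)
  expect_false(any(build_channel_mask(empty, p)$px))
})

test_that("automatic mask combination follows the stated boolean rule", {
  tt <- expand.grid(c1 = c(FALSE, TRUE), c2 = c(FALSE, TRUE),
                    c3 = c(FALSE, TRUE))
  mk <- function(v) binary_mask(matrix(v, 1, 1))
  for (i in seq_len(nrow(tt))) {
    got <- combine_automatic_mask(mk(tt$c1[i]), mk(tt$c2[i]),
                                  mk(tt$c3[i]))$px[1, 1]
    want <- (tt$c1[i] && !tt$c2[i]) || (tt$c1[i] && !tt$c3[i])
    expect_identical(got, want)
  }
  # spot values from the truth table
  expect_true(combine_automatic_mask(mk(TRUE), mk(FALSE), mk(FALSE))$px[1, 1])
  expect_false(combine_automatic_mask(mk(TRUE), mk(TRUE), mk(TRUE))$px[1, 1])
  expect_true(combine_automatic_mask(mk(TRUE), mk(TRUE), mk(FALSE))$px[1, 1])
  expect_false(combine_automatic_mask(mk(FALSE), mk(TRUE), mk(FALSE))$px[1, 1])
})

test_that("automatic mask equals the algebraic oracle on random masks", {
  set.seed(26)
  for (i in 1:10) {
    m1 <- rand_mask(10, 10); m2 <- rand_mask(10, 10); m3 <- rand_mask(10, 10)
    got <- combine_automatic_mask(m1, m2, m3)$px
    expect_identical(got, m1$px & !(m2$px & m3$px))
    expect_true(all(m1$px[got]))  # Ma subset of Mc1
  }
  m1 <- rand_mask(8, 8)
  expect_identical(combine_automatic_mask(m1)$px, m1$px)
  expect_error(combine_automatic_mask(m1, rand_mask(9, 8)), "mismatched")
})

test_that("CX43 mask keeps only the top tail of the equalized channel", {
  set.seed(27)
  # 1% of pixels at the top intensity, the rest spread below
  px <- matrix(as.integer(sample(0:200, 10000, replace = TRUE)), 100, 100)
  top <- sample(10000, 100)
  px[top] <- 255L
  mc4 <- build_cx43_mask(gray_image(px, 1))
  expect_setequal(which(mc4$px), top)
  expect_equal(mc4$role, "Mc4")
  # constant channel: equalization leaves it unchanged
  expect_false(any(build_cx43_mask(gray_image(matrix(200L, 5, 5), 1))$px))
  expect_true(all(build_cx43_mask(gray_image(matrix(255L, 5, 5), 1))$px))
  expect_error(build_cx43_mask(NULL), "absent")
})

test_that("tissue mask is the union of the channel masks", {
  mk <- function(v) binary_mask(matrix(v, 1, 1))
  expect_false(build_tissue_mask(mk(FALSE), mk(FALSE), mk(FALSE))$px[1, 1])
  expect_true(build_tissue_mask(mk(TRUE), mk(FALSE), mk(FALSE))$px[1, 1])
  set.seed(28)
  for (i in 1:10) {
    m1 <- rand_mask(10, 10); m2 <- rand_mask(10, 10); m3 <- rand_mask(10, 10)
    mt <- build_tissue_mask(m1, m2, m3)$px
    expect_equal(sum(mt), sum(m1$px | m2$px | m3$px))
    expect_true(all(mt[m1$px]) && all(mt[m2$px]) && all(mt[m3$px]))
  }
  empty <- binary_mask(matrix(FALSE, 5, 5))
  expect_false(any(build_tissue_mask(empty, empty, empty)$px))
})

test_that("configuration round-trips through YAML and derives the padding", {
  cfg <- default_config()
  expect_equal(config_h(cfg), 30)  # 2 * ng_c2(3) * ng_it_c2(5)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back$channels$c1$thr, 8L)
  expect_equal(back$channels$c2$ng_it, 5L)
  expect_equal(back$scale, 0.21)
  expect_equal(config_h(back), 30)
  # identity growth on c2 needs no compensation
  cfg2 <- pipeline_config(c2 = channel_params(15, 1, 1, 1))
  expect_equal(config_h(cfg2), 0)
  cfg3 <- pipeline_config(h = 12)
  expect_equal(config_h(cfg3), 12)
})
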