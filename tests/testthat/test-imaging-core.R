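test_that("read_eye_image round-trips written frames and resizes larger input", {
  dir <- withr::local_tempdir()
  img <- small_rgb(seed = 3, h = 250, w = 333)
  path <- file.path(dir, "frame_000.png")
  write_eye_image(img, path)
  back <- read_eye_image(path)
  expect_identical(dim(back), c(250L, 333L))
  expect_equal(back$r, img$r)
  expect_equal(back$g, img$g)
  expect_equal(back$b, img$b)

  big <- small_rgb(seed = 4, h = 500, w = 666)
  write_eye_image(big, file.path(dir, "big.png"))
  shrunk <- read_eye_image(file.path(dir, "big.png"))
  expect_identical(dim(shrunk), c(250L, 333L))
})

test_that("read_eye_image fails loudly on missing or corrupt files", {
  expect_error(read_eye_image("/nonexistent/nowhere.png"), "no such file")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_eye_image(bad), "cannot decode")
})

test_that("enhance_exposure multiplies, clips, and rejects bad factors", {
  img <- rgb_image(matrix(50, 2, 2), matrix(100, 2, 2), matrix(200, 2, 2))
  expect_equal(enhance_exposure(img, 1), img)
  out <- enhance_exposure(img, 3)
  expect_equal(out$r[1, 1], 150)
  expect_equal(out$g[1, 1], 255) # 300 clipped
  expect_equal(out$b[1, 1], 255)
  expect_error(enhance_exposure(img, 0), "positive")
  expect_error(enhance_exposure(img, -2), "positive")

  # monotone in the factor
  rnd <- small_rgb(seed = 9)
  lo <- enhance_exposure(rnd, 1.3)
  hi <- enhance_exposure(rnd, 2.1)
  expect_true(all(hi$r >= lo$r) && all(hi$g >= lo$g) && all(hi$b >= lo$b))
})

test_that("sliding_mean_3x3 matches the brute-force oracle and its size contract", {
  m <- sliding_mean_3x3(small_rgb(seed = 2, h = 250, w = 333), "red")
  expect_identical(dim(m), c(248L, 331L))
  expect_identical(length(m), 82088L)

  const <- rgb_image(matrix(7, 5, 6), matrix(7, 5, 6), matrix(7, 5, 6))
  expect_true(all(sliding_mean_3x3(const, "green") == 7))

  tiny <- rgb_image(matrix(1:9, 3, 3, byrow = TRUE),
                    matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(as.numeric(sliding_mean_3x3(tiny, "red")), 5)

  for (seed in 1:5) {
    set.seed(seed)
    h <- sample(3:20, 1); w <- sample(3:20, 1)
    img <- small_rgb(seed = seed + 100, h = h, w = w)
    for (ch in c("red", "green", "blue")) {
      got <- sliding_mean_3x3(img, ch)
      ref <- oracle_mean_3x3(img[[substr(ch, 1, 1)]])
      expect_equal(unclass(got), ref, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }

  expect_error(sliding_mean_3x3(rgb_image(matrix(0, 2, 5), matrix(0, 2, 5),
                                          matrix(0, 2, 5))),
               "at least 3x3")
})

test_that("rgb_to_hsv follows the 8-bit half-degree convention", {
  px <- function(r, g, b) {
    rgb_image(matrix(r, 1, 1), matrix(g, 1, 1), matrix(b, 1, 1))
  }
  gray <- rgb_to_hsv(px(90, 90, 90))
  expect_equal(gray$s[1, 1], 0)
  expect_equal(gray$v[1, 1], 90)

  red <- rgb_to_hsv(px(255, 0, 0))
  expect_equal(c(red$h, red$s, red$v), c(0, 255, 255))
  blue <- rgb_to_hsv(px(0, 0, 255))
  expect_equal(c(blue$h, blue$s, blue$v), c(120, 255, 255))

  # six primaries/secondaries hit the expected half-degree hues
  cases <- list(list(c(255, 255, 0), 30), list(c(0, 255, 0), 60),
                list(c(0, 255, 255), 90), list(c(255, 0, 255), 150))
  for (cs in cases) {
    expect_equal(rgb_to_hsv(px(cs[[1]][1], cs[[1]][2], cs[[1]][3]))$h[1, 1],
                 cs[[2]])
  }

  # value channel is the per-pixel max
  img <- small_rgb(seed = 11)
  hsv <- rgb_to_hsv(img)
  expect_equal(hsv$v, pmax(img$r, img$g, img$b))
  expect_true(all(hsv$s[img$r == img$g & img$g == img$b] == 0))
})

test_that("both grayscale operators apply their channel weights", {
  px <- function(r, g, b) {
    rgb_image(matrix(r, 1, 1), matrix(g, 1, 1), matrix(b, 1, 1))
  }
  expect_equal(grayscale_standard(px(255, 255, 255))[1, 1], 255)
  expect_equal(grayscale_standard(px(0, 0, 0))[1, 1], 0)
  expect_equal(grayscale_standard(px(100, 50, 200))[1, 1], 82)

  expect_equal(grayscale_blue_weighted(px(255, 255, 255))[1, 1], 255)
  expect_equal(grayscale_blue_weighted(px(0, 255, 0))[1, 1], 0)
  expect_equal(grayscale_blue_weighted(px(100, 50, 200))[1, 1], 170)

  # bounded for arbitrary input
  g <- grayscale_blue_weighted(small_rgb(seed = 5))
  expect_true(min(g) >= 0 && max(g) <= 255)
})

test_that("histogram equalization preserves ranks and handles degenerate input", {
  const <- gray_image(matrix(128, 8, 8))
  expect_equal(equalize_histogram(const), const)

  two <- gray_image(matrix(c(rep(40, 25), rep(200, 75)), 10, 10))
  eq <- equalize_histogram(two)
  lv <- sort(unique(as.vector(eq)))
  expect_length(lv, 2)
  # CDF mapping: level occupying the first quartile maps to ~0.25 * 255
  expect_equal(lv[1], round(0.25 * 255))
  expect_equal(lv[2], 255)

  # already-uniform histogram is (near) identity
  uni <- gray_image(matrix(rep(0:255, length.out = 256 * 4), 32, 32))
  eq2 <- equalize_histogram(uni)
  expect_true(max(abs(as.numeric(eq2) - as.numeric(uni))) <= 1)

  # rank preservation on random data
  set.seed(21)
  rnd <- gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  eq3 <- equalize_histogram(rnd)
  ord <- order(as.vector(unclass(rnd)))
  expect_true(all(diff(as.vector(unclass(eq3))[ord]) >= 0))
})

test_that("gaussian_blur conserves mass, is identity at size 1, rejects even kernels", {
  const <- gray_image(matrix(99, 9, 9))
  expect_equal(gaussian_blur(const, 5), const)
  img <- gray_image(matrix(sample(0:255, 81, TRUE), 9, 9))
  expect_equal(gaussian_blur(img, 1), img)
  expect_error(gaussian_blur(img, 4), "odd")

  spot <- matrix(0, 21, 21); spot[11, 11] <- 255
  bl <- unclass(gaussian_blur(gray_image(spot), 5))
  expect_equal(sum(bl), 255, tolerance = 0.02)
  expect_equal(bl, bl[21:1, ], ignore_attr = TRUE)      # vertical symmetry
  expect_equal(bl, t(bl), ignore_attr = TRUE)           # diagonal symmetry
  expect_true(bl[11, 11] == max(bl))
})
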