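test_that("running_min_filter equals the prefix-minimum oracle", {
  expect_equal(running_min_filter(c(5, 7, 3, 4, 2)), c(5, 5, 3, 3, 2))
  expect_equal(running_min_filter(c(9, 7, 7, 3)), c(9, 7, 7, 3)) # non-increasing
  expect_equal(running_min_filter(4.2), 4.2)
  expect_error(running_min_filter(numeric(0)), "empty")

  set.seed(31)
  for (i in 1:200) {
    x <- stats::rnorm(sample(1:50, 1), sd = 20)
    got <- running_min_filter(x)
    expect_identical(got, oracle_prefix_min(x))
    expect_identical(running_min_filter(got), got)  # idempotent
    expect_true(all(got <= x))                       # pointwise below input
    expect_true(all(diff(got) <= 0))                 # non-increasing
  }
})

test_that("extract_dark_interval windows forward from the raster-order minimum", {
  m <- structure(matrix(c(9, 2, 7, 8, 3, 6), 2, 3, byrow = TRUE),
                 channel = "red", src_dim = c(2L, 3L),
                 class = c("mean_matrix", "matrix", "array"))
  di <- extract_dark_interval(m, 3)
  expect_equal(di$values, c(2, 7, 8))
  expect_equal(di$start_index, 2)
  expect_false(di$truncated)

  # minimum at the last flattened position truncates to length 1
  m2 <- structure(matrix(c(5, 6, 7, 8, 9, 1), 2, 3, byrow = TRUE),
                  channel = "red", src_dim = c(2L, 3L),
                  class = c("mean_matrix", "matrix", "array"))
  expect_warning(di2 <- extract_dark_interval(m2, 3), "truncated")
  expect_equal(di2$values, 1)
  expect_true(di2$truncated)

  # ties broken by first occurrence in raster order
  m3 <- structure(matrix(c(4, 1, 6, 1, 5, 2), 2, 3, byrow = TRUE),
                  channel = "red", src_dim = c(2L, 3L),
                  class = c("mean_matrix", "matrix", "array"))
  expect_equal(extract_dark_interval(m3, 2)$start_index, 2)

  expect_error(extract_dark_interval(m, 1), ">= 2")

  # full-size matrix: 5000 entries starting at the global minimum
  img <- small_rgb(seed = 42, h = 250, w = 333)
  mm <- sliding_mean_3x3(img, "red")
  flat <- as.vector(t(unclass(mm)))
  di3 <- extract_dark_interval(mm, 5000)
  expect_length(di3$values, 5000)
  expect_equal(di3$values[1], min(flat))
  expect_equal(di3$start_index, which.min(flat))
})

test_that("smooth_dark_interval is the suffix minimum: non-decreasing from the global min", {
  expect_equal(smooth_dark_interval(c(2, 7, 5, 8)), c(2, 5, 5, 8))
  expect_equal(smooth_dark_interval(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(smooth_dark_interval(c(4, 4, 4)), c(4, 4, 4))

  set.seed(17)
  for (i in 1:50) {
    x <- stats::runif(sample(2:80, 1), 0, 255)
    s <- smooth_dark_interval(x)
    expect_true(all(diff(s) >= 0))
    expect_equal(s[1], min(x))
    expect_true(all(s <= x))
  }
})

test_that("decide_component_threshold finds the first band jump", {
  th <- decide_component_threshold(c(10, 11, 12, 20, 21), jump = 5)
  expect_equal(th$lower, 10)
  expect_equal(th$upper, 12)
  expect_equal(th$final, 11)

  const <- decide_component_threshold(rep(3.5, 6))
  expect_equal(c(const$lower, const$upper, const$final), c(3.5, 3.5, 3.5))

  rising <- decide_component_threshold(1:30, jump = 5) # no qualifying jump
  expect_equal(rising$upper, 30)
  expect_true(is.na(rising$jump_index))

  # threshold bounded by the component limits, invariant to trailing values
  # above the jump
  s <- c(4, 5, 6, 30, 31, 32)
  a <- decide_component_threshold(s)
  b <- decide_component_threshold(c(s, 200, 240))
  expect_equal(a$final, b$final)
  expect_true(a$final >= a$lower && a$final <= a$upper)

  expect_error(decide_component_threshold(5), "at least 2")
  expect_error(decide_component_threshold(c(3, 2, 1)), "non-decreasing")
  expect_error(decide_component_threshold(c(1, 2), jump = 0), "positive")
})

test_that("cclpf_mask places sub-threshold cells at their window centers", {
  m <- structure(matrix(100, 3, 4), channel = "red", src_dim = c(5L, 6L),
                 class = c("mean_matrix", "matrix", "array"))
  empty <- cclpf_mask(m, 50) # all means above threshold
  expect_identical(dim(empty), c(5L, 6L))
  expect_false(any(empty))

  m[1, 1] <- 10
  one <- cclpf_mask(m, 50)
  expect_equal(sum(one), 1)
  expect_true(one[2, 2]) # matrix cell (0,0) -> image pixel (1,1), 0-based

  # foreground count is monotone in the threshold
  mm <- sliding_mean_3x3(small_rgb(seed = 8), "red")
  counts <- vapply(c(40, 90, 140, 200, 260),
                   function(t) sum(cclpf_mask(mm, t)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("run_cclpf handles single frames, repeats, and bad frames gracefully", {
  sc <- eye_scene(mode = "outdoor", pupil_radius = 30, noise_sd = 0, seed = 5)
  frame <- render_eye(sc)$image
  one <- run_cclpf(list(frame))
  expect_s3_class(one, "diameter_series")
  expect_equal(one$corrected_px, one$raw_px) # correction is identity on 1 frame
  expect_gt(one$raw_px, 0)

  three <- run_cclpf(list(frame, frame, frame))
  expect_equal(unique(three$raw_px), one$raw_px) # deterministic pipeline

  expect_error(run_cclpf(list()), "non-empty")

  # a frame the pipeline cannot segment is flagged, not fatal
  blank <- rgb_image(matrix(255, 250, 333), matrix(255, 250, 333),
                     matrix(255, 250, 333))
  mixed <- run_cclpf(list(frame, blank, frame))
  expect_true(mixed$flagged[2])
  expect_equal(mixed$raw_px[2], 0)
  expect_equal(mixed$corrected_px[2], mixed$corrected_px[1]) # carried forward
})

test_that("cclpf recovers noise-free outdoor disk diameters to within the boundary bias", {
  for (r in c(20, 30, 40)) {
    sc <- eye_scene(mode = "outdoor", pupil_radius = r,
                    noise_sd = 0, blur_sigma = 0)
    got <- run_cclpf(list(render_eye(sc)$image))$raw_px
    expect_lte(abs(got - 2 * r), 4)
  }
})
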