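test_that("scene validation enforces the regime invariants", {
  expect_error(eye_scene(pupil_radius = 80, iris_radius = 70), "smaller")
  # indoor saturation ordering with margins
  expect_error(eye_scene(mode = "indoor", pupil = c(200, 195, 190)),
               "saturation")
  # outdoor red ordering and low-contrast gap
  expect_error(eye_scene(mode = "outdoor", pupil = c(120, 40, 35)), "red")
  expect_error(eye_scene(mode = "outdoor", pupil = c(20, 15, 12)), "gap")

  sc <- eye_scene(mode = "indoor")
  sat <- function(v) 255 * (1 - min(v) / max(v))
  expect_gte(sat(sc$pupil), sat(sc$iris) + 30)
  expect_gte(sat(sc$iris), sat(sc$sclera) + 30)
})

test_that("rendering is seed-deterministic and seed-sensitive", {
  sc <- eye_scene(mode = "indoor", seed = 99)
  a <- render_eye(sc)
  b <- render_eye(sc)
  expect_identical(a$image, b$image)
  expect_equal(a$true_diameter, 2 * sc$pupil_radius)

  sc2 <- eye_scene(mode = "indoor", seed = 100)
  expect_false(identical(render_eye(sc2)$image, a$image))
})

test_that("noiseless pupil pixel count matches the disk area", {
  sc <- eye_scene(mode = "outdoor", pupil_radius = 30, noise_sd = 0,
                  blur_sigma = 0, band_depth = 0, highlight = FALSE)
  img <- render_eye(sc)$image
  n_pupil <- sum(img$r == sc$pupil[1] & img$g == sc$pupil[2] &
                 img$b == sc$pupil[3])
  expect_lte(abs(n_pupil - pi * 30^2) / (pi * 30^2), 0.04)
})

test_that("indoor scenes order per-region mean saturation pupil > iris > sclera", {
  sc <- eye_scene(mode = "indoor", pupil_radius = 30, seed = 55)
  img <- render_eye(sc)$image
  hsv <- rgb_to_hsv(img)
  xs <- matrix(seq_len(sc$width) - 1, sc$height, sc$width, byrow = TRUE)
  ys <- matrix(seq_len(sc$height) - 1, sc$height, sc$width)
  d <- sqrt((xs - sc$center[1])^2 + (ys - sc$center[2])^2)
  s_pupil <- mean(hsv$s[d < sc$pupil_radius - 3])
  s_iris <- mean(hsv$s[d > sc$pupil_radius + 3 & d < sc$iris_radius - 3])
  s_sclera <- mean(hsv$s[d > sc$iris_radius + 3])
  expect_gt(s_pupil, s_iris)
  expect_gt(s_iris, s_sclera)
})

test_that("generated sequences follow the constriction profile with ground truth", {
  seqd <- generate_eye_sequence(n = 80, scene = eye_scene(mode = "indoor"),
                                seed = 7)
  expect_length(seqd$frames, 80)
  expect_equal(nrow(seqd$truth), 80)
  expect_equal(seqd$truth$frame_index, 0:79)
  expect_true(all(diff(seqd$truth$true_diameter_px) <= 0)) # monotone decay
  expect_equal(seqd$truth$true_diameter_px[1], 90)

  const <- generate_eye_sequence(n = 5, scene = eye_scene(mode = "outdoor"),
                                 profile = rep(60, 5), seed = 1)
  expect_true(all(const$truth$true_diameter_px == 60))

  # determinism of the whole sequence under the master seed
  again <- generate_eye_sequence(n = 5, scene = eye_scene(mode = "outdoor"),
                                 profile = rep(60, 5), seed = 1)
  expect_identical(const$frames, again$frames)

  expect_error(generate_eye_sequence(n = 3, profile = c(90, 90, 150), seed = 1),
               "diameters")
  expect_error(generate_eye_sequence(n = 0), "n >= 1")
})

test_that("sequences write numbered frames, truth CSV, and a params sidecar", {
  dir <- withr::local_tempdir()
  seqd <- generate_eye_sequence(n = 3, scene = eye_scene(mode = "indoor"),
                                profile = rep(50, 3), seed = 2)
  write_eye_sequence(seqd, dir)
  expect_true(all(file.exists(file.path(dir,
    c("frame_000.png", "frame_001.png", "frame_002.png",
      "truth.csv", "params.yaml")))))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$true_diameter_px, rep(50, 3))
  params <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expect_equal(params$mode, "indoor")
  expect_equal(params$sequence_seed, 2)

  frames <- read_eye_frames(dir)
  expect_length(frames, 3)
  expect_equal(frames[[1]]$r, seqd$frames[[1]]$r)
})

test_that("read_eye_frames sorts numerically, not lexically", {
  dir <- withr::local_tempdir()
  vals <- c(10, 40, 70)
  names <- c("frame_2.png", "frame_10.png", "frame_1.png")
  order_vals <- c(40, 70, 10) # written per file name above
  for (i in seq_along(names)) {
    img <- rgb_image(matrix(order_vals[i], 20, 20),
                     matrix(0, 20, 20), matrix(0, 20, 20))
    write_eye_image(img, file.path(dir, names[i]))
  }
  frames <- read_eye_frames(dir, width = 20, height = 20)
  got <- vapply(frames, function(f) f$r[1, 1], numeric(1))
  expect_equal(got, c(10, 40, 70)) # frame_1, frame_2, frame_10
  expect_error(read_eye_frames(withr::local_tempdir()), "no image frames")
})
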