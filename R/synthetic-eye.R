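# Seeded generator of synthetic eye images and constriction sequences with
# ground-truth diameters. Scenes are concentric sclera/iris/pupil disks with
# anti-aliased boundaries, an optional specular highlight inside the pupil,
# a multiplicative radial shading of the pupil, additive Gaussian pixel
# noise, and an acquisition blur emulating smartphone optics + in-camera
# denoising. Two palettes emulate the two imaging regimes: indoor flash
# photography (bright red-eye pupil, the unique high-saturation region) and
# outdoor sunlight (pupil darkest in the red channel, low iris contrast).

saturation8 <- function(rgb) {
  mx <- max(rgb)
  if (mx == 0) return(0)
  255 * (1 - min(rgb) / mx)
}

default_palette <- function(mode) {
  if (mode == "indoor") {
    # flash red-eye pupil: bright and strongly saturated, so its saturation
    # is both high and insensitive to pixel noise; warm saturated brown iris
    list(sclera = c(225, 222, 218), iris = c(95, 60, 35), pupil = c(80, 28, 18))
  } else {
    list(sclera = c(210, 200, 195), iris = c(70, 55, 45), pupil = c(52, 40, 35))
  }
}

#' Synthetic eye scene parameters
#'
#' Bundles and validates the full description of a rendered eye scene. The
#' two modes encode the imaging regimes the pipelines target: in `indoor`
#' mode the pupil must be the most saturated region (saturation ordering
#' pupil > iris > sclera with margins of at least 30 8-bit units — the
#' red-eye appearance of flash photographs); in `outdoor` mode the pupil
#' must be the darkest red-channel region with low pupil/iris contrast
#' (red(pupil) < red(iris) < red(sclera), pupil-iris gap at most 25).
#'
#' @param width,height Image size in pixels (default 333 x 250).
#' @param mode `"indoor"` or `"outdoor"`.
#' @param center Pupil/iris center as `c(x, y)` in 0-based pixel
#'   coordinates; default is the image center.
#' @param pupil_radius,iris_radius Disk radii in pixels (pupil < iris).
#' @param sclera,iris,pupil RGB triples in \[0, 255\]; defaults depend on
#'   `mode`.
#' @param highlight Render a specular highlight inside the pupil?
#' @param highlight_radius,highlight_offset Highlight geometry (default
#'   radius 3 px at offset (4, -4) from the pupil center — small enough that
#'   the 10x10 opening suppresses its artifacts).
#' @param noise_sd Additive Gaussian noise standard deviation per channel
#'   (default 5).
#' @param shading Relative depth of the multiplicative radial luminance
#'   falloff toward the pupil rim (darkest at the center; default 0.3 indoor,
#'   0 outdoor). The factor is
#'   `1 - shading * (1 - (rho / pupil_radius)^shading_power)`, scaling all
#'   three channels equally so HSV saturation is unaffected.
#' @param shading_power Exponent of the radial profile (default 6: a flat
#'   dark core with the rise concentrated near the rim).
#' @param band_depth Relative depth of the horizontal shadow band across the
#'   pupil (default 0.29 outdoor, 0 indoor) — the soft shadow that lids and
#'   brow cast across the pupil under high-angle sunlight. Multiplicative,
#'   so saturation is unaffected.
#' @param band_sigma Vertical Gaussian scale of the band profile in pixels
#'   (default 8).
#' @param band_offset Vertical offset of the band center below the pupil
#'   center in pixels (default 6, placing the shadow under the specular
#'   highlight).
#' @param blur_sigma Acquisition Gaussian blur in pixels, applied after the
#'   noise, emulating optics plus in-camera denoising (default 2;
#'   0 disables).
#' @param seed Optional RNG seed making the rendered image reproducible.
#' @return An `eye_scene` parameter object.
#' @export
eye_scene <- function(width = 333, height = 250,
                      mode = c("indoor", "outdoor"),
                      center = NULL, pupil_radius = 30, iris_radius = 70,
                      sclera = NULL, iris = NULL, pupil = NULL,
                      highlight = TRUE, highlight_radius = 3,
                      highlight_offset = c(4, -4),
                      noise_sd = 5, shading = NULL, shading_power = 6,
                      band_depth = NULL, band_sigma = 8, band_offset = 6,
                      blur_sigma = 2, seed = NULL) {
  mode <- match.arg(mode)
  pal <- default_palette(mode)
  if (is.null(shading)) shading <- if (mode == "indoor") 0.3 else 0
  if (is.null(band_depth)) band_depth <- if (mode == "outdoor") 0.29 else 0
  if (is.null(sclera)) sclera <- pal$sclera
  if (is.null(iris)) iris <- pal$iris
  if (is.null(pupil)) pupil <- pal$pupil
  if (is.null(center)) center <- c((width - 1) / 2, (height - 1) / 2)
  if (pupil_radius >= iris_radius) {
    stop("eye_scene: pupil radius must be smaller than iris radius",
         call. = FALSE)
  }
  if (mode == "indoor") {
    s <- vapply(list(pupil, iris, sclera), saturation8, numeric(1))
    if (!(s[1] >= s[2] + 30 && s[2] >= s[3] + 30)) {
      stop(sprintf(paste0(
        "eye_scene: indoor mode needs saturation(pupil) > saturation(iris) > ",
        "saturation(sclera) with margins >= 30; got %.1f / %.1f / %.1f"),
        s[1], s[2], s[3]), call. = FALSE)
    }
  } else {
    r <- c(pupil[1], iris[1], sclera[1])
    if (!(r[1] < r[2] && r[2] < r[3])) {
      stop(sprintf(paste0(
        "eye_scene: outdoor mode needs red(pupil) < red(iris) < red(sclera); ",
        "got %g / %g / %g"), r[1], r[2], r[3]), call. = FALSE)
    }
    if (r[2] - r[1] > 25) {
      stop(sprintf(paste0(
        "eye_scene: outdoor mode is the low-contrast regime; pupil-iris red ",
        "gap must be <= 25, got %g"), r[2] - r[1]), call. = FALSE)
    }
  }
  structure(list(width = width, height = height, mode = mode,
                 center = center, pupil_radius = pupil_radius,
                 iris_radius = iris_radius,
                 sclera = sclera, iris = iris, pupil = pupil,
                 highlight = highlight, highlight_radius = highlight_radius,
                 highlight_offset = highlight_offset,
                 noise_sd = noise_sd, shading = shading,
                 shading_power = shading_power, band_depth = band_depth,
                 band_sigma = band_sigma, band_offset = band_offset,
                 blur_sigma = blur_sigma, seed = seed),
            class = "eye_scene")
}

#' @export
print.eye_scene <- function(x, ...) {
  cat(sprintf("<eye_scene> %s, %d x %d px, pupil r=%.1f, iris r=%.1f\n",
              x$mode, x$width, x$height, x$pupil_radius, x$iris_radius))
  invisible(x)
}

with_scene_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a synthetic eye image
#'
#' Draws the sclera field, iris disk, and pupil disk with 1-pixel
#' anti-aliased boundaries, applies the pupil shading, the specular
#' highlight, per-pixel Gaussian noise, the acquisition blur, and quantizes
#' to 8 bits. Fully deterministic given the scene's seed.
#'
#' @param scene An [eye_scene].
#' @return A list with `image` (an [rgb_image]) and `true_diameter`
#'   (2 x pupil radius, pixels).
#' @export
render_eye <- function(scene) {
  stopifnot(inherits(scene, "eye_scene"))
  with_scene_seed(scene$seed, {
    w <- scene$width; h <- scene$height
    xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    ys <- matrix(seq_len(h) - 1, h, w)
    d <- sqrt((xs - scene$center[1])^2 + (ys - scene$center[2])^2)
    cov <- function(radius) pmin(pmax(radius + 0.5 - d, 0), 1)
    a_iris <- cov(scene$iris_radius)
    a_pupil <- cov(scene$pupil_radius)
    shade <- 1 - scene$shading *
      pmax(0, 1 - (pmin(d / scene$pupil_radius, 1))^scene$shading_power)
    if (scene$band_depth > 0) {
      dy <- ys - (scene$center[2] + scene$band_offset)
      shade <- shade *
        (1 - scene$band_depth * exp(-dy^2 / (2 * scene$band_sigma^2)))
    }
    chans <- lapply(1:3, function(k) {
      base <- scene$sclera[k] * (1 - a_iris) +
              scene$iris[k] * (a_iris - a_pupil) +
              scene$pupil[k] * shade * a_pupil
      base
    })
    if (scene$highlight) {
      hx <- scene$center[1] + scene$highlight_offset[1]
      hy <- scene$center[2] + scene$highlight_offset[2]
      dh <- sqrt((xs - hx)^2 + (ys - hy)^2)
      a_h <- pmin(pmax(scene$highlight_radius + 0.5 - dh, 0), 1)
      chans <- lapply(chans, function(m) m * (1 - a_h) + 255 * a_h)
    }
    if (scene$noise_sd > 0) {
      chans <- lapply(chans, function(m) {
        m + matrix(stats::rnorm(length(m), sd = scene$noise_sd), nrow(m))
      })
    }
    if (scene$blur_sigma > 0) {
      chans <- lapply(chans, blur_matrix, sigma = scene$blur_sigma)
    }
    chans <- lapply(chans, function(m) clip8(round_half_up(m)))
    list(image = rgb_image(chans[[1]], chans[[2]], chans[[3]]),
         true_diameter = 2 * scene$pupil_radius)
  })
}

#' Geometric ground-truth pupil mask of a scene
#'
#' The set of pixels whose centers fall inside the pupil disk, straight from
#' the scene parameters (no rendering, noise, or shading involved). This is
#' the generator's self-consistency oracle: measuring this mask must recover
#' the requested diameter.
#'
#' @param scene An [eye_scene].
#' @return A [binary_mask].
#' @export
pupil_truth_mask <- function(scene) {
  stopifnot(inherits(scene, "eye_scene"))
  xs <- matrix(seq_len(scene$width) - 1, scene$height, scene$width, byrow = TRUE)
  ys <- matrix(seq_len(scene$height) - 1, scene$height, scene$width)
  d <- sqrt((xs - scene$center[1])^2 + (ys - scene$center[2])^2)
  binary_mask(d <= scene$pupil_radius)
}

#' Generate a synthetic constriction sequence with ground truth
#'
#' Renders `n` frames whose true pupil diameter follows a constriction
#' profile (default: exponential decay from 90 px to 45 px, the camera-flash
#' response), with integer center jitter of at most `jitter` pixels per
#' frame and fresh noise per frame. All randomness derives from `seed`.
#'
#' @param n Number of frames (default 80).
#' @param scene An [eye_scene] providing everything except the per-frame
#'   pupil radius and jitter.
#' @param d_start,d_end Initial and final true diameters in pixels (defaults
#'   90 and 45).
#' @param rate Decay rate of the exponential profile over the sequence
#'   (default 3; `d_i = d_end + (d_start - d_end) exp(-rate (i-1)/(n-1))`).
#' @param profile Optional explicit vector of `n` true diameters overriding
#'   the exponential profile.
#' @param jitter Maximum absolute per-frame center shift in pixels
#'   (default 2).
#' @param seed RNG seed for the whole sequence (default 7).
#' @return A list with `frames` (list of [rgb_image]), `truth` (tibble with
#'   `frame_index`, `true_diameter_px`), `scene`, and `seed`.
#' @export
generate_eye_sequence <- function(n = 80, scene = eye_scene(),
                                  d_start = 90, d_end = 45, rate = 3,
                                  profile = NULL, jitter = 2, seed = 7) {
  if (!is.numeric(n) || n < 1) stop("generate_eye_sequence: need n >= 1",
                                    call. = FALSE)
  n <- as.integer(n)
  if (is.null(profile)) {
    tt <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
    profile <- d_end + (d_start - d_end) * exp(-rate * tt)
  }
  if (length(profile) != n) {
    stop("generate_eye_sequence: profile length must equal n", call. = FALSE)
  }
  if (any(profile / 2 >= scene$iris_radius - 2) || any(profile < 2 * 10)) {
    stop(sprintf(paste0(
      "generate_eye_sequence: true diameters must lie in [%g, %g] px for ",
      "this scene"), 20, 2 * (scene$iris_radius - 2)), call. = FALSE)
  }
  with_scene_seed(seed, {
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- scene
      sc$seed <- NULL
      sc$pupil_radius <- profile[i] / 2
      if (jitter > 0) {
        sc$center <- scene$center + sample(seq(-jitter, jitter), 2, replace = TRUE)
      }
      frames[[i]] <- render_eye(sc)$image
    }
    list(frames = frames,
         truth = tibble::tibble(frame_index = seq_len(n) - 1L,
                                true_diameter_px = profile),
         scene = scene, seed = seed)
  })
}

#' Write an eye sequence to disk
#'
#' Writes numbered PNG frames (`frame_000.png`, ...), a `truth.csv`
#' (`frame_index`, `true_diameter_px`), and a `params.yaml` sidecar holding
#' the full scene specification and seed.
#'
#' @param seq_data Result of [generate_eye_sequence()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eye_sequence <- function(seq_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq_data$frames)) {
    write_eye_image(seq_data$frames[[i]],
                    file.path(dir, sprintf("frame_%03d.png", i - 1)))
  }
  utils::write.csv(as.data.frame(seq_data$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  scene <- seq_data$scene
  params <- c(unclass(scene), list(n_frames = length(seq_data$frames),
                                   sequence_seed = seq_data$seed))
  yaml::write_yaml(params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Write an RGB image as PNG
#'
#' @param img An [rgb_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eye_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- array(0, c(nrow(img$r), ncol(img$r), 3))
  arr[, , 1] <- img$r / 255
  arr[, , 2] <- img$g / 255
  arr[, , 3] <- img$b / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a directory of numbered frames
#'
#' Loads every PNG/JPEG/TIFF in `dir`, ordered by the first number in each
#' filename (numeric-aware, so `frame_2` sorts before `frame_10`).
#'
#' @param dir Directory of image frames.
#' @param width,height Working resolution passed to [read_eye_image()].
#' @return A list of [rgb_image] frames.
#' @export
read_eye_frames <- function(dir, width = 333, height = 250) {
  files <- list.files(dir, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) {
    stop(sprintf("no image frames found in '%s'", dir), call. = FALSE)
  }
  nums <- suppressWarnings(
    as.numeric(sub(".*?(\\d+)\\D*$", "\\1", basename(files))))
  ord <- order(is.na(nums), nums, basename(files))
  lapply(files[ord], read_eye_image, width = width, height = height)
}
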