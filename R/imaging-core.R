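# Image I/O, exposure enhancement, color conversions, windowed means, and the
# preprocessing primitives shared by all three pipelines.

#' Read an eye image and resize it to the working resolution
#'
#' Loads a PNG, JPEG, or TIFF raster and resizes it (bilinear) to the target
#' dimensions. Images already at the target size pass through unchanged.
#'
#' @param path Path to an image file.
#' @param width,height Target dimensions in pixels (default 333 x 250, the
#'   working resolution of both pipelines).
#' @return An [rgb_image]. Grayscale sources are replicated across channels.
#' @export
read_eye_image <- function(path, width = 333, height = 250) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) {
      stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  arr <- EBImage::imageData(img) # [x, y] or [x, y, channel], in [0, 1]
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  chans <- lapply(1:3, function(k) {
    m <- t(arr[, , k]) # -> [y, x]
    clip8(round_half_up(m * 255))
  })
  out <- rgb_image(chans[[1]], chans[[2]], chans[[3]])
  resize_eye_image(out, width = width, height = height)
}

#' Resize an RGB image (bilinear)
#'
#' @param img An [rgb_image].
#' @param width,height Target dimensions in pixels.
#' @return An [rgb_image] of exactly `height` x `width`; an already-correct
#'   image is returned unchanged.
#' @export
resize_eye_image <- function(img, width = 333, height = 250) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  if (d[1] == height && d[2] == width) return(img)
  ch <- lapply(img[c("r", "g", "b")], function(m) {
    # EBImage's first margin maps to our rows
    res <- EBImage::resize(m / 255, w = height, h = width, filter = "bilinear")
    clip8(round_half_up(res * 255))
  })
  rgb_image(ch$r, ch$g, ch$b)
}

#' Multiply image brightness with clipping
#'
#' Per-pixel exposure enhancement: every channel intensity v becomes
#' round(v * factor), clipped to \[0, 255\]. The pipelines' default factor is
#' 3, which drives bright sclera regions into saturation and stretches the
#' dark pupil/iris band apart.
#'
#' @param img An [rgb_image].
#' @param factor Positive multiplier (default 3).
#' @return An [rgb_image].
#' @examples
#' img <- rgb_image(matrix(50, 2, 2), matrix(100, 2, 2), matrix(0, 2, 2))
#' enhance_exposure(img, 3)$r[1, 1] # 150
#' @export
enhance_exposure <- function(img, factor = 3) {
  stopifnot(inherits(img, "rgb_image"))
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor <= 0) {
    stop("enhance_exposure: 'factor' must be a positive number", call. = FALSE)
  }
  rgb_image(clip8(round_half_up(img$r * factor)),
            clip8(round_half_up(img$g * factor)),
            clip8(round_half_up(img$b * factor)))
}

#' 3x3 sliding-window channel means
#'
#' Computes the arithmetic mean of every fully interior 3x3 window of one
#' color channel at unit stride. For an H x W image the result is
#' (H - 2) x (W - 2); at the working resolution 333 x 250 that is
#' 331 x 248 = 82,088 window means. Entries are real-valued (no integer
#' truncation), since the CCLPF threshold comparisons operate on reals.
#'
#' @param img An [rgb_image].
#' @param channel One of "red", "green", "blue".
#' @return A `mean_matrix`: a numeric matrix with attributes `channel` and
#'   `src_dim` (dimensions of the source image).
#' @export
sliding_mean_3x3 <- function(img, channel = c("red", "green", "blue")) {
  stopifnot(inherits(img, "rgb_image"))
  channel <- match.arg(channel)
  m <- img[[substr(channel, 1, 1)]]
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) {
    stop("sliding_mean_3x3: image must be at least 3x3", call. = FALSE)
  }
  rs <- m[1:(h - 2), , drop = FALSE] +
        m[2:(h - 1), , drop = FALSE] +
        m[3:h,       , drop = FALSE]
  sums <- rs[, 1:(w - 2), drop = FALSE] +
          rs[, 2:(w - 1), drop = FALSE] +
          rs[, 3:w,       drop = FALSE]
  structure(sums / 9,
            channel = channel, src_dim = c(h, w),
            class = c("mean_matrix", "matrix", "array"))
}

#' @export
print.mean_matrix <- function(x, ...) {
  cat(sprintf("<mean_matrix> %s channel, %d x %d (%d window means)\n",
              attr(x, "channel"), nrow(x), ncol(x), length(x)))
  invisible(x)
}

#' Convert RGB to 8-bit HSV
#'
#' Standard hexcone conversion, reported in the 8-bit half-degree convention:
#' hue in \[0, 180\] (degrees halved), saturation `255 * (1 - min/max)` and
#' value `max(R, G, B)` in \[0, 255\]. Gray pixels (all channels equal) have
#' saturation 0.
#'
#' @param img An [rgb_image].
#' @return An [hsv_image].
#' @examples
#' img <- rgb_image(matrix(0, 1, 1), matrix(0, 1, 1), matrix(255, 1, 1))
#' rgb_to_hsv(img)$h # 120 (240 degrees halved)
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(r = as.vector(img$r), g = as.vector(img$g),
                            b = as.vector(img$b), maxColorValue = 255)
  h8 <- round_half_up(hsv[1, ] * 360 / 2)
  s8 <- round_half_up(hsv[2, ] * 255)
  v8 <- pmax(img$r, img$g, img$b)
  hsv_image(matrix(h8, d[1], d[2]),
            matrix(s8, d[1], d[2]),
            v8)
}

#' Standard luma grayscale
#'
#' Gray = 0.299 R + 0.587 G + 0.114 B, rounded to the nearest integer.
#'
#' @param img An [rgb_image].
#' @return A [gray_image].
#' @examples
#' img <- rgb_image(matrix(100, 1, 1), matrix(50, 1, 1), matrix(200, 1, 1))
#' grayscale_standard(img)[1, 1] # 82
#' @export
grayscale_standard <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  gray_image(clip8(round_half_up(img$r * 0.299 + img$g * 0.587 + img$b * 0.114)))
}

#' Blue-weighted grayscale
#'
#' A grayscale variant in which the green weight is reassigned to blue:
#' Gray = 0.299 R + (0.587 + 0.114) B. Green contributes nothing. The
#' comparison baseline uses this formula by default because it sharpens the
#' iris boundary in eye images.
#'
#' @param img An [rgb_image].
#' @return A [gray_image].
#' @export
grayscale_blue_weighted <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  gray_image(clip8(round_half_up(img$r * 0.299 + img$b * 0.587 + img$b * 0.114)))
}

#' Histogram equalization
#'
#' Cumulative-histogram equalization of an 8-bit grayscale image over 256
#' levels. Single-valued images are returned unchanged.
#'
#' @param img A [gray_image].
#' @return A [gray_image] with values in \[0, 255\].
#' @export
equalize_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  m <- as_plain_matrix(img)
  lv <- floor(m)
  counts <- tabulate(lv + 1L, nbins = 256L)
  if (sum(counts > 0) <= 1) return(img)
  cdf <- cumsum(counts) / length(m)
  gray_image(matrix(clip8(round_half_up(cdf[lv + 1L] * 255)), nrow(m), ncol(m)))
}

#' Gaussian blur
#'
#' Convolution with a normalized odd-sized Gaussian kernel, replicating edge
#' pixels at the border. With the default `sigma = NULL` the bandwidth is
#' derived from the kernel size as `0.3 * ((size - 1) / 2 - 1) + 0.8`, the
#' conventional size-to-sigma rule for 8-bit image kernels.
#'
#' @param img A [gray_image].
#' @param size Odd kernel size (default 5). Size 1 is the identity.
#' @param sigma Gaussian standard deviation in pixels, or `NULL` to derive it
#'   from `size`.
#' @return A [gray_image].
#' @export
gaussian_blur <- function(img, size = 5, sigma = NULL) {
  stopifnot(inherits(img, "gray_image"))
  if (size < 1 || size %% 2 == 0) {
    stop("gaussian_blur: kernel size must be odd and >= 1", call. = FALSE)
  }
  if (size == 1) return(img)
  if (is.null(sigma)) sigma <- 0.3 * ((size - 1) / 2 - 1) + 0.8
  half <- (size - 1) / 2
  g1 <- exp(-(-half:half)^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  out <- EBImage::filter2(as_plain_matrix(img), kern, boundary = "replicate")
  gray_image(clip8(round_half_up(out)))
}

# Internal: blur an arbitrary numeric matrix (no rounding), replicate borders.
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2 * ceiling(3 * sigma) + 1
  half <- (size - 1) / 2
  g1 <- exp(-(-half:half)^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  EBImage::filter2(m, kern / sum(kern), boundary = "replicate")
}
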