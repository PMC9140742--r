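# All raster grids are numeric matrices with dim = c(height, width): rows are
# image rows (y, top to bottom), columns are x. Pixel (x, y) in 0-based image
# coordinates lives at mat[y + 1, x + 1].

round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' RGB eye image
#'
#' An 8-bit RGB raster held as three height-by-width intensity matrices with
#' values in \[0, 255\]. This is the working representation for all pipelines;
#' images are conventionally 333 x 250 pixels (width x height).
#'
#' @param r,g,b Numeric matrices of identical dimensions with values in
#'   \[0, 255\]; rows are image rows (y), columns are x.
#' @return An object of class `rgb_image` with elements `r`, `g`, `b`.
#' @examples
#' img <- rgb_image(matrix(255, 4, 4), matrix(0, 4, 4), matrix(0, 4, 4))
#' dim(img)
#' @export
rgb_image <- function(r, g, b) {
  r <- as.matrix(r); g <- as.matrix(g); b <- as.matrix(b)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b))) {
    stop("rgb_image: channel dimensions differ", call. = FALSE)
  }
  for (ch in list(r, g, b)) {
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 255) {
      stop("rgb_image: intensities must be in [0, 255]", call. = FALSE)
    }
  }
  structure(list(r = r, g = g, b = b), class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$r)

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px (width x height)\n", d[2], d[1]))
  invisible(x)
}

#' HSV eye image
#'
#' 8-bit HSV raster in the half-degree convention: hue in \[0, 180\]
#' (degrees / 2), saturation and value in \[0, 255\].
#'
#' @param h,s,v Numeric matrices of identical dimensions.
#' @return An object of class `hsv_image` with elements `h`, `s`, `v`.
#' @export
hsv_image <- function(h, s, v) {
  h <- as.matrix(h); s <- as.matrix(s); v <- as.matrix(v)
  if (!identical(dim(h), dim(s)) || !identical(dim(h), dim(v))) {
    stop("hsv_image: channel dimensions differ", call. = FALSE)
  }
  if (min(h) < 0 || max(h) > 180) stop("hsv_image: hue outside [0, 180]", call. = FALSE)
  if (min(s) < 0 || max(s) > 255 || min(v) < 0 || max(v) > 255) {
    stop("hsv_image: saturation/value outside [0, 255]", call. = FALSE)
  }
  structure(list(h = h, s = s, v = v), class = "hsv_image")
}

#' @export
dim.hsv_image <- function(x) dim(x$h)

#' @export
print.hsv_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hsv_image> %d x %d px (width x height)\n", d[2], d[1]))
  invisible(x)
}

#' Grayscale image
#'
#' Single-channel 8-bit raster.
#'
#' @param x Numeric matrix with values in \[0, 255\].
#' @return An object of class `gray_image` (a classed matrix).
#' @export
gray_image <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop("gray_image: intensities must be in [0, 255]", call. = FALSE)
  }
  structure(x, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px (width x height)\n", ncol(x), nrow(x)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param x Logical (or 0/1 numeric) matrix; `TRUE` marks foreground.
#' @return An object of class `binary_mask` (a classed logical matrix).
#' @export
binary_mask <- function(x) {
  x <- as.matrix(x)
  mode(x) <- "logical"
  if (anyNA(x)) stop("binary_mask: NA entries not allowed", call. = FALSE)
  structure(x, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground\n",
              ncol(x), nrow(x), sum(x)))
  invisible(x)
}

as_plain_matrix <- function(x) {
  attr(x, "class") <- NULL
  x
}
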