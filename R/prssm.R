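# PRSSM: the indoor-artificial-light pipeline. Under flash illumination the
# pupil is the unique high-saturation region of the HSV image; the saturation
# cut separating it from the rest of the eye is found adaptively by sweeping
# the cut downward from 255 and stopping at the first decline of the pixel
# growth ratio.

#' Pixel growth ratio
#'
#' The fractional gain in mask pixels between two sweep stages:
#' `(p_now - p_prev) / total`.
#'
#' @param p_now,p_prev Pixel counts at the current and previous stage.
#' @param total Total pixel count of the image (must be positive).
#' @return A single number.
#' @examples
#' growth_ratio(1500, 1000, 83250)
#' @export
growth_ratio <- function(p_now, p_prev, total) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) || total <= 0) {
    stop("growth_ratio: 'total' must be positive", call. = FALSE)
  }
  (p_now - p_prev) / total
}

#' High-saturation HSV band mask
#'
#' Marks pixels whose hue and value lie inside the band limits and whose
#' saturation is at least `t`. The hue and value limits default to the full
#' 8-bit ranges (180 and 255), so by default the band is a pure saturation
#' cut.
#'
#' @param hsv An [hsv_image].
#' @param t Saturation cut in \[0, 255\] (256 is an explicit empty-band
#'   sentinel).
#' @param hue_max,value_max Upper band limits (defaults 180 and 255).
#' @return A [binary_mask].
#' @export
saturation_mask <- function(hsv, t, hue_max = 180, value_max = 255) {
  stopifnot(inherits(hsv, "hsv_image"))
  binary_mask(hsv$h <= hue_max & hsv$v <= value_max & hsv$s >= t)
}

#' Adaptive saturation threshold by pixel-growth-ratio decline
#'
#' Sweeps the saturation cut downward from 255 in steps of `step` (default
#' 5). At each stage n the foreground count P_n of the saturation band mask
#' and the growth ratio G_n = (P_n - P_{n-1}) / S are recorded. The sweep
#' stops at the first stage (n >= 2) where the growth ratio falls below the
#' previous one — the point where the high-saturation pupil cluster has just
#' been swallowed — and returns that stage's cut. If no decline occurs by
#' cut 0, the cut with maximal growth ratio is returned and the trace is
#' flagged.
#'
#' @param hsv An [hsv_image].
#' @param step Sweep decrement (default 5).
#' @return A list with `threshold` (integer cut), `declined` (logical:
#'   `FALSE` when the fallback was used), and `trace`, a tibble with columns
#'   `step`, `threshold`, `pixels`, `growth`.
#' @export
adaptive_saturation_threshold <- function(hsv, step = 5) {
  stopifnot(inherits(hsv, "hsv_image"))
  if (!is.numeric(step) || length(step) != 1 || is.na(step) || step < 1) {
    stop("adaptive_saturation_threshold: 'step' must be >= 1", call. = FALSE)
  }
  step <- as.integer(step)
  s <- hsv$s
  total <- length(s)
  thresholds <- seq(255L, 0L, by = -step)
  # P(t) = #{saturation >= t}, from a single histogram pass
  counts <- tabulate(floor(s) + 1L, nbins = 256L)
  above <- rev(cumsum(rev(counts))) # above[k] = #{s >= k - 1}
  pixels <- above[thresholds + 1L]
  growth <- c(NA_real_, diff(pixels) / total)
  n <- length(thresholds)
  trace <- tibble::tibble(step = seq_len(n) - 1L,
                          threshold = thresholds,
                          pixels = pixels,
                          growth = growth)
  stop_at <- NA_integer_
  if (n >= 3) {
    decl <- which(growth[3:n] < growth[2:(n - 1)])
    if (length(decl) > 0) stop_at <- decl[1] + 2L
  }
  if (!is.na(stop_at)) {
    list(threshold = thresholds[stop_at], declined = TRUE, trace = trace)
  } else {
    best <- which.max(growth[-1]) + 1L
    list(threshold = thresholds[best], declined = FALSE, trace = trace)
  }
}

#' Full-resolution PRSSM pupil mask
#'
#' Draws the accepted saturation band of the final decision on a fresh blank
#' canvas: foreground pixels are those with saturation at or above the cut
#' `t` (the sentinel `t = 256` yields an empty mask, `t = 0` a full one).
#'
#' @param hsv An [hsv_image].
#' @param t Saturation cut.
#' @return A [binary_mask] with the dimensions of `hsv`.
#' @export
prssm_mask <- function(hsv, t) {
  saturation_mask(hsv, t)
}

#' Run the PRSSM pipeline over an image sequence
#'
#' Per frame: resize to the working resolution, convert to HSV, find the
#' adaptive saturation threshold (sweep step 5), draw the saturation mask,
#' open with a 10x10 element, and measure the largest contour's bounding-box
#' diameter. The per-frame series is then passed through
#' [temporal_correction()] with a 5-pixel tolerance (the indoor pipeline is
#' more stable than the outdoor one, so its permissible jump is smaller).
#'
#' @param frames List of [rgb_image] frames, in temporal order.
#' @param step Saturation sweep decrement (default 5).
#' @param opening Structuring element size for the opening (default 10x10).
#' @param temporal_tol Rule-of-thumb tolerance in pixels (default 5).
#' @param width,height Working resolution (default 333 x 250).
#' @return A [diameter_series].
#' @export
run_prssm <- function(frames, step = 5, opening = c(10, 10), temporal_tol = 5,
                      width = 333, height = 250) {
  check_frames(frames)
  per_frame <- lapply(frames, function(fr) {
    tryCatch({
      fr <- resize_eye_image(fr, width = width, height = height)
      hsv <- rgb_to_hsv(fr)
      at <- adaptive_saturation_threshold(hsv, step)
      mask <- prssm_mask(hsv, at$threshold)
      mask_to_diameter(mask, opening)
    }, error = function(e) list(diameter = 0, flagged = TRUE))
  })
  assemble_series(per_frame, temporal_tol, algorithm = "prssm")
}
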