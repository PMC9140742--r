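# CCLPF: the outdoor-sunlight pipeline. The pupil is located as the darkest
# band of the red-channel 3x3 window means: a 5000-entry interval is read
# forward from the global minimum, clamped with a running-minimum filter, and
# scanned upward for the first jump above the criterion to fix the
# component threshold.

#' Running-minimum low-pass filter
#'
#' Clamps a sequence with a descending cutoff: the cutoff starts at the first
#' element, values above the cutoff are replaced by it, and values below it
#' lower the cutoff. The output is exactly the prefix minimum of the input:
#' `out[i] = min(x[1..i])`.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector of the same length, non-increasing.
#' @examples
#' running_min_filter(c(5, 7, 3, 4, 2)) # 5 5 3 3 2
#' @export
running_min_filter <- function(x) {
  if (length(x) == 0) stop("running_min_filter: empty sequence", call. = FALSE)
  cummin(x)
}

#' Extract the dark interval of a mean matrix
#'
#' Flattens the mean matrix in raster (row-major) order, finds the global
#' minimum (first occurrence on ties), and reads `n` consecutive entries
#' forward from it. If fewer than `n` entries remain the interval is
#' truncated and flagged. This window is the candidate pupil-color band: the
#' deepest window mean must be a pupil pixel neighborhood, and the entries
#' after it sample the surrounding dark band.
#'
#' @param m A `mean_matrix` from [sliding_mean_3x3()].
#' @param n Window length (default 5000).
#' @return A `dark_interval`: list with `values`, `start_index` (1-based
#'   position of the minimum in the flattened matrix), `indices`, `target`,
#'   and `truncated`.
#' @export
extract_dark_interval <- function(m, n = 5000) {
  stopifnot(inherits(m, "mean_matrix") || is.matrix(m))
  if (length(m) == 0) stop("extract_dark_interval: empty matrix", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2) {
    stop("extract_dark_interval: 'n' must be >= 2", call. = FALSE)
  }
  flat <- as.vector(t(as_plain_matrix(m))) # raster order
  start <- which.min(flat)
  end <- min(start + n - 1, length(flat))
  truncated <- (end - start + 1) < n
  if (truncated) {
    warning(sprintf("dark interval truncated to %d of %d entries",
                    end - start + 1, n), call. = FALSE)
  }
  structure(list(values = flat[start:end],
                 start_index = start,
                 indices = start:end,
                 target = n,
                 truncated = truncated),
            class = "dark_interval")
}

#' @export
print.dark_interval <- function(x, ...) {
  cat(sprintf("<dark_interval> %d entries from flat index %d (min %.2f)%s\n",
              length(x$values), x$start_index, x$values[1],
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Smooth a dark interval into a non-decreasing envelope
#'
#' Reverses the interval, applies the running-minimum filter, and reverses
#' back. The result is the suffix minimum of the window: a non-decreasing
#' curve that starts at the global minimum and clamps upward noise spikes,
#' leaving a flat, scannable band profile.
#'
#' @param d A `dark_interval`, or a plain numeric vector.
#' @return Numeric vector, non-decreasing, first element equal to the
#'   interval minimum.
#' @examples
#' smooth_dark_interval(c(2, 7, 5, 8)) # 2 5 5 8
#' @export
smooth_dark_interval <- function(d) {
  x <- if (inherits(d, "dark_interval")) d$values else d
  rev(running_min_filter(rev(x)))
}

#' Decide the component extraction threshold
#'
#' Scans a smoothed (non-decreasing) band profile from its lowest value
#' upward. The first consecutive difference greater than `jump` marks the top
#' of the pupil-color band: the value before the jump becomes the upper
#' component limit, the first element is the lower limit, and the final
#' threshold is the mean of lower, upper, and their midpoint (algebraically
#' the midpoint itself). If no difference exceeds `jump`, the last element is
#' the upper limit.
#'
#' @param smoothed Non-decreasing numeric vector of length >= 2.
#' @param jump Jump criterion (default 5).
#' @return A `component_threshold`: list with `lower`, `upper`, `final`,
#'   `jump`, and `jump_index` (NA when the fallback was used).
#' @examples
#' decide_component_threshold(c(10, 11, 12, 20, 21))$final # 11
#' @export
decide_component_threshold <- function(smoothed, jump = 5) {
  if (length(smoothed) < 2) {
    stop("decide_component_threshold: need at least 2 values", call. = FALSE)
  }
  if (!is.numeric(jump) || length(jump) != 1 || is.na(jump) || jump <= 0) {
    stop("decide_component_threshold: 'jump' must be positive", call. = FALSE)
  }
  if (is.unsorted(smoothed)) {
    stop("decide_component_threshold: sequence must be non-decreasing",
         call. = FALSE)
  }
  d <- diff(smoothed)
  j <- which(d > jump)
  if (length(j) == 0) {
    upper <- smoothed[length(smoothed)]
    jump_index <- NA_integer_
  } else {
    upper <- smoothed[j[1]]
    jump_index <- j[1]
  }
  lower <- smoothed[1]
  final <- mean(c(lower, upper, (lower + upper) / 2))
  structure(list(lower = lower, upper = upper, final = final,
                 jump = jump, jump_index = jump_index),
            class = "component_threshold")
}

#' @export
print.component_threshold <- function(x, ...) {
  cat(sprintf("<component_threshold> lower %.3f, upper %.3f, final %.3f (jump > %g%s)\n",
              x$lower, x$upper, x$final, x$jump,
              if (is.na(x$jump_index)) ", fallback: no jump found" else ""))
  invisible(x)
}

#' Threshold a mean matrix into a full-resolution pupil mask
#'
#' Marks image pixels whose 3x3 window mean falls strictly below the final
#' component threshold. Mean-matrix cell (i, j) corresponds to its window
#' center, image pixel (i + 1, j + 1) in 0-based coordinates; the one-pixel
#' image border is always background.
#'
#' @param m A `mean_matrix`.
#' @param t A `component_threshold` (or a single numeric threshold).
#' @return A [binary_mask] at the source image resolution.
#' @export
cclpf_mask <- function(m, t) {
  stopifnot(inherits(m, "mean_matrix"))
  thr <- if (inherits(t, "component_threshold")) t$final else t
  src <- attr(m, "src_dim")
  mask <- matrix(FALSE, src[1], src[2])
  mask[2:(src[1] - 1), 2:(src[2] - 1)] <- as_plain_matrix(m) < thr
  binary_mask(mask)
}

#' Run the CCLPF pipeline over an image sequence
#'
#' Per frame: resize to the working resolution, multiply exposure (default
#' x3), compute the red-channel 3x3 mean matrix, extract and smooth the
#' 5000-entry dark interval, decide the component threshold (jump criterion
#' 5), threshold into a mask, open with a 10x10 element, and measure the
#' largest contour's bounding-box diameter. The per-frame series is then
#' passed through [temporal_correction()] with a 10-pixel tolerance.
#'
#' A frame whose processing fails (or yields no contour) contributes raw
#' diameter 0 and is flagged; the sequence is never aborted.
#'
#' @param frames List of [rgb_image] frames, in temporal order.
#' @param enhance_factor Exposure multiplier (default 3).
#' @param window Dark-interval length (default 5000).
#' @param jump Component-threshold jump criterion (default 5).
#' @param opening Structuring element size for the opening (default 10x10).
#' @param temporal_tol Rule-of-thumb tolerance in pixels (default 10).
#' @param width,height Working resolution (default 333 x 250).
#' @return A [diameter_series].
#' @export
run_cclpf <- function(frames, enhance_factor = 3, window = 5000, jump = 5,
                      opening = c(10, 10), temporal_tol = 10,
                      width = 333, height = 250) {
  check_frames(frames)
  per_frame <- lapply(frames, function(fr) {
    tryCatch({
      fr <- resize_eye_image(fr, width = width, height = height)
      fr <- enhance_exposure(fr, enhance_factor)
      m <- sliding_mean_3x3(fr, "red")
      di <- suppressWarnings(extract_dark_interval(m, window))
      thr <- decide_component_threshold(smooth_dark_interval(di), jump)
      mask <- cclpf_mask(m, thr)
      mask_to_diameter(mask, opening)
    }, error = function(e) list(diameter = 0, flagged = TRUE))
  })
  assemble_series(per_frame, temporal_tol, algorithm = "cclpf")
}

check_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("need a non-empty list of rgb_image frames", call. = FALSE)
  }
  ok <- vapply(frames, inherits, logical(1), "rgb_image")
  if (!all(ok)) stop("all frames must be rgb_image objects", call. = FALSE)
  invisible(frames)
}
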