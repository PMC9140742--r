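# Comparison baseline: per-channel grayscale / histogram equalization /
# Gaussian blur preprocessing, Canny edge detection, and gradient-based
# circular Hough voting, plus the per-channel Canny lower-threshold sweep.
# No installed R package provides Canny or a circular Hough transform, so
# both are implemented here against their textbook definitions.

sobel_gradients <- function(m) {
  # x = columns, y = rows (downward)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(m, kx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(kx), boundary = "replicate")
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, and two-threshold hysteresis: pixels with gradient magnitude at
#' or above `upper` seed edges, and pixels at or above `lower` are kept only
#' when 8-connected (through other weak pixels) to a seed.
#'
#' @param img A [gray_image].
#' @param lower,upper Hysteresis thresholds on the gradient magnitude
#'   (defaults 50 and 150); `lower` must not exceed `upper`.
#' @return A [binary_mask] of edge pixels.
#' @export
canny_edges <- function(img, lower = 50, upper = 150) {
  stopifnot(inherits(img, "gray_image"))
  if (lower < 0 || lower > upper) {
    stop("canny_edges: need 0 <= lower <= upper", call. = FALSE)
  }
  m <- as_plain_matrix(img)
  h <- nrow(m); w <- ncol(m)
  g <- sobel_gradients(m)
  mag <- g$mag
  # quantize direction into 4 sectors: 0 = horizontal gradient (vertical
  # edge), 1 = 45 deg, 2 = vertical gradient, 3 = 135 deg
  ang <- atan2(g$gy, g$gx)
  sector <- floor(((ang + pi) / (pi / 4)) + 0.5) %% 4
  shift <- function(mm, dr, dc) {
    out <- matrix(0, h, w)
    rs <- (1 + max(0, dr)):(h + min(0, dr))
    cs <- (1 + max(0, dc)):(w + min(0, dc))
    out[rs, cs] <- mm[rs - dr, cs - dc]
    out
  }
  keep <- matrix(FALSE, h, w)
  nbrs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- nbrs[[as.character(s)]]
    sel <- sector == s
    ge <- mag >= shift(mag, d[1], d[2]) & mag >= shift(mag, -d[1], -d[2])
    keep <- keep | (sel & ge)
  }
  nms <- keep & mag > 0
  strong <- nms & mag >= upper
  weak <- nms & mag >= lower
  if (!any(strong)) return(binary_mask(matrix(FALSE, h, w)))
  # hysteresis: grow strong seeds through weak pixels (8-connected)
  labels <- label_components_8(binary_mask(weak))
  keep_ids <- unique(labels[strong])
  binary_mask(matrix(labels %in% keep_ids & labels > 0, h, w))
}

#' Circular Hough transform
#'
#' Gradient-based circular Hough voting: every edge pixel votes for candidate
#' centers along its gradient line at each radius in `radius_range`; center
#' peaks separated by at least `min_dist` are then assigned radii by peaks in
#' the histogram of edge-pixel distances, requiring that at least
#' `min_support` of the circle's circumference is covered by edge pixels.
#'
#' @param img A [gray_image] (used for gradient directions).
#' @param radius_range Circle radii to consider, `c(min, max)` in pixels
#'   (default 10 to 120).
#' @param edges Optional [binary_mask] of edge pixels; when `NULL`, Canny
#'   with thresholds `canny` is run internally.
#' @param canny Canny thresholds used when `edges` is `NULL`.
#' @param min_dist Minimum distance between detected centers (default half
#'   the image height).
#' @param vote_step Radius stride used during center voting (default 1;
#'   radius estimation is always at unit resolution).
#' @param min_support Minimum fraction of circumference covered (default 0.3).
#' @param max_circles Maximum number of detections returned.
#' @return A tibble with columns `x`, `y`, `r`, `votes` (circumference
#'   support count), sorted by decreasing support; zero rows when nothing is
#'   detected.
#' @export
hough_circles <- function(img, radius_range = c(10, 120), edges = NULL,
                          canny = c(50, 150), min_dist = NULL, vote_step = 1,
                          min_support = 0.3, max_circles = 4) {
  stopifnot(inherits(img, "gray_image"))
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2]) {
    stop("hough_circles: invalid radius range", call. = FALSE)
  }
  m <- as_plain_matrix(img)
  h <- nrow(m); w <- ncol(m)
  if (is.null(min_dist)) min_dist <- h / 2
  if (is.null(edges)) edges <- canny_edges(img, canny[1], canny[2])
  idx <- which(as_plain_matrix(edges))
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), r = numeric(0),
                          votes = numeric(0))
  if (length(idx) < 8) return(empty)
  g <- sobel_gradients(m)
  ey <- ((idx - 1) %% h) + 1
  ex <- ((idx - 1) %/% h) + 1
  gx <- g$gx[idx]; gy <- g$gy[idx]
  mag <- sqrt(gx^2 + gy^2)
  ok <- mag > 1e-9
  ex <- ex[ok]; ey <- ey[ok]; ux <- gx[ok] / mag[ok]; uy <- gy[ok] / mag[ok]
  # cap the voting set for speed; radius estimation uses all edge pixels
  if (length(ex) > 6000) {
    pick <- seq(1, length(ex), length.out = 6000)
    vx <- ex[pick]; vy <- ey[pick]; vux <- ux[pick]; vuy <- uy[pick]
  } else {
    vx <- ex; vy <- ey; vux <- ux; vuy <- uy
  }
  radii <- seq(radius_range[1], radius_range[2], by = vote_step)
  cx <- round(c(outer(vx, radii, function(p, r) p) + outer(vux, radii, `*`),
                outer(vx, radii, function(p, r) p) - outer(vux, radii, `*`)))
  cy <- round(c(outer(vy, radii, function(p, r) p) + outer(vuy, radii, `*`),
                outer(vy, radii, function(p, r) p) - outer(vuy, radii, `*`)))
  keep <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
  if (!any(keep)) return(empty)
  acc_idx <- (cx[keep] - 1) * h + cy[keep]
  acc <- tabulate(acc_idx, nbins = h * w)
  accm <- matrix(acc, h, w)
  # greedy peak picking with min_dist separation
  centers <- list()
  tmp <- accm
  for (k in seq_len(max_circles)) {
    p <- which.max(tmp)
    if (tmp[p] <= 0) break
    py <- ((p - 1) %% h) + 1
    px <- ((p - 1) %/% h) + 1
    centers[[length(centers) + 1]] <- c(px, py, accm[p])
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    tmp[(xx - px)^2 + (yy - py)^2 < min_dist^2] <- 0
  }
  res <- list()
  for (ct in centers) {
    # centroid refinement of the accumulator peak (vote quantization can
    # put the raw argmax a pixel off)
    win <- 2
    rr <- max(1, ct[2] - win):min(h, ct[2] + win)
    cc <- max(1, ct[1] - win):min(w, ct[1] + win)
    wts <- accm[rr, cc]^2
    cy0 <- sum(rr * rowSums(wts)) / sum(wts)
    cx0 <- sum(cc * colSums(wts)) / sum(wts)
    dists <- sqrt((ex - cx0)^2 + (ey - cy0)^2)
    dcount <- tabulate(pmax(1, round(dists)),
                       nbins = ceiling(radius_range[2]) + 3)
    rs <- radius_range[1]:radius_range[2]
    # support over a +-1 px annulus, as a fraction of circumference,
    # lightly smoothed
    supp <- vapply(rs, function(r) sum(dcount[max(1, r - 1):(r + 1)]),
                   numeric(1))
    frac <- supp / (2 * pi * rs)
    # a genuine circle must stand out against the diffuse edge background
    background <- stats::median(frac)
    good <- which(frac >= min_support & frac >= 2 * background)
    if (length(good) == 0) next
    # merge qualifying radii into contiguous bands (gap <= 3) and keep the
    # peak of each
    runs <- split(good, cumsum(c(1, diff(good) > 3)))
    for (run in runs) {
      r_best <- rs[run[which.max(supp[run])]]
      res[[length(res) + 1]] <- tibble::tibble(
        x = cx0 - 1, y = cy0 - 1, r = r_best,
        votes = supp[match(r_best, rs)])
    }
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  out[order(out$votes, decreasing = TRUE), ]
}

baseline_channels <- c("red", "green", "blue", "hue", "saturation", "value")

channel_gray <- function(img, channel) {
  switch(channel,
    red = gray_image(img$r),
    green = gray_image(img$g),
    blue = gray_image(img$b),
    hue = gray_image(rgb_to_hsv(img)$h),
    saturation = gray_image(rgb_to_hsv(img)$s),
    value = gray_image(rgb_to_hsv(img)$v),
    stop(sprintf("unknown channel '%s' (use one of %s)", channel,
                 paste(baseline_channels, collapse = ", ")), call. = FALSE)
  )
}

preprocess_channel <- function(img, channel, blur_size = 5) {
  gaussian_blur(equalize_histogram(channel_gray(img, channel)), blur_size)
}

#' Canny lower-threshold sweep across color channels
#'
#' For each of the six channels (R, G, B and H, S, V): grayscale the channel,
#' equalize its histogram, Gaussian-blur it, then sweep the Canny lower
#' threshold over `lowers` (default 10 to 70 in steps of 5, upper always
#' twice the lower) and record the first parameterization at which the Hough
#' transform yields a detection, together with that detection.
#'
#' @param img An [rgb_image].
#' @param lowers Candidate Canny lower thresholds.
#' @param radius_range Hough radius range.
#' @param channels Channels to sweep (default all six).
#' @return A tibble with one row per channel: `channel`, `detected`,
#'   `lower`, `upper`, `x`, `y`, `r`, `votes` (NA where no parameterization
#'   yielded a detection).
#' @export
channel_threshold_sweep <- function(img, lowers = seq(10, 70, by = 5),
                                    radius_range = c(10, 120),
                                    channels = baseline_channels) {
  stopifnot(inherits(img, "rgb_image"))
  rows <- lapply(channels, function(ch) {
    pre <- preprocess_channel(img, ch)
    for (lo in lowers) {
      det <- hough_circles(pre, radius_range, canny = c(lo, 2 * lo))
      if (nrow(det) > 0) {
        return(tibble::tibble(channel = ch, detected = TRUE,
                              lower = lo, upper = 2 * lo,
                              x = det$x[1], y = det$y[1], r = det$r[1],
                              votes = det$votes[1]))
      }
    }
    tibble::tibble(channel = ch, detected = FALSE,
                   lower = NA_real_, upper = NA_real_,
                   x = NA_real_, y = NA_real_, r = NA_real_,
                   votes = NA_real_)
  })
  do.call(rbind, rows)
}

#' Run the Hough-circle baseline over an image sequence
#'
#' Per frame and configured channel: grayscale, equalize, Gaussian-blur,
#' Canny with the given thresholds, circular Hough detection. The strongest
#' detection across the configured channels gives the frame's diameter
#' (2 x radius); frames with no detection on any channel are flagged with
#' diameter 0. No temporal correction is applied (the corrected series
#' equals the raw one): the rule-of-thumb filter belongs to the two color
#' pipelines.
#'
#' @param frames List of [rgb_image] frames.
#' @param channels Channel labels among red, green, blue, hue, saturation,
#'   value (default green + hue, the indoor comparison configuration).
#' @param canny_lower,canny_upper Canny thresholds (default 40 / 50).
#' @param radius_range Hough radius range (default 10 to 120 px).
#' @param width,height Working resolution.
#' @return A [diameter_series].
#' @export
run_baseline <- function(frames, channels = c("green", "hue"),
                         canny_lower = 40, canny_upper = 50,
                         radius_range = c(10, 120),
                         width = 333, height = 250) {
  check_frames(frames)
  bad <- setdiff(channels, baseline_channels)
  if (length(bad) > 0) {
    stop(sprintf("unknown channel '%s' (use one of %s)", bad[1],
                 paste(baseline_channels, collapse = ", ")), call. = FALSE)
  }
  per_frame <- lapply(frames, function(fr) {
    tryCatch({
      fr <- resize_eye_image(fr, width = width, height = height)
      best <- NULL
      for (ch in channels) {
        pre <- preprocess_channel(fr, ch)
        det <- hough_circles(pre, radius_range,
                             canny = c(canny_lower, canny_upper))
        if (nrow(det) > 0 && (is.null(best) || det$votes[1] > best$votes)) {
          best <- list(r = det$r[1], votes = det$votes[1])
        }
      }
      if (is.null(best)) list(diameter = 0, flagged = TRUE)
      else list(diameter = 2 * best$r, flagged = FALSE)
    }, error = function(e) list(diameter = 0, flagged = TRUE))
  })
  assemble_series(per_frame, temporal_tol = NULL, algorithm = "baseline")
}
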