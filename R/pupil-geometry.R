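# Shared back half of both pipelines: morphological cleanup of the binary
# pupil mask, contour extraction, bounding-box diameter, and the
# rule-of-thumb temporal correction of the per-frame series.

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a solid rectangular structuring element
#' (default 10 x 10). Foreground components too small to contain the element
#' anywhere — specular highlights, threshold speckle — are removed; larger
#' components keep their extent.
#'
#' @param mask A [binary_mask].
#' @param se Structuring element size as `c(rows, cols)` or a single number
#'   for a square element (default 10).
#' @return A [binary_mask].
#' @export
morphological_opening <- function(mask, se = c(10, 10)) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(se) == 1) se <- c(se, se)
  se <- as.integer(se)
  if (any(se < 1)) stop("morphological_opening: structuring element must be >= 1x1",
                        call. = FALSE)
  if (!any(mask)) return(mask)
  # Even-sized elements need care: embed the element in an odd frame for
  # erosion and use its point reflection for dilation, so the pair is a true
  # adjunction and the opening is anti-extensive and idempotent. The element
  # anchor sits at cell (floor(h/2), floor(w/2)), 0-based.
  oh <- se[1] + (1L - se[1] %% 2L)
  ow <- se[2] + (1L - se[2] %% 2L)
  k_er <- matrix(0, oh, ow)
  k_er[seq_len(se[1]), seq_len(se[2])] <- 1
  k_di <- matrix(0, oh, ow)
  k_di[oh - se[1] + seq_len(se[1]), ow - se[2] + seq_len(se[2])] <- 1
  m <- as_plain_matrix(mask) * 1
  opened <- EBImage::dilate(EBImage::erode(m, k_er), k_di)
  binary_mask(opened > 0.5)
}

# 8-connected component labels of a binary mask; 0 = background.
# EBImage::bwlabel is 4-connected, so diagonal adjacency is resolved on a
# pixel graph instead.
label_components_8 <- function(mask) {
  m <- as_plain_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  labels <- matrix(0L, h, w)
  if (length(idx) == 0) return(labels)
  fg <- logical(h * w)
  fg[idx] <- TRUE
  edge_pairs <- function(offset, valid) {
    from <- idx[valid[idx]]
    from <- from[fg[from + offset]]
    cbind(from, from + offset)
  }
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  not_last_row <- logical(h * w); not_last_row[idx] <- rows < h
  not_first_row <- logical(h * w); not_first_row[idx] <- rows > 1L
  not_last_col <- logical(h * w); not_last_col[idx] <- cols < w
  e <- rbind(
    edge_pairs(1L, not_last_row),                      # down
    edge_pairs(h, not_last_col),                       # right
    edge_pairs(h + 1L, not_last_row & not_last_col),   # down-right
    edge_pairs(h - 1L, not_first_row & not_last_col)   # up-right
  )
  vert_id <- match(idx, idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0) {
    g <- igraph::add_edges(g, rbind(match(e[, 1], idx), match(e[, 2], idx)))
  }
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

# Moore-neighbor boundary trace of one labeled component, clockwise from its
# topmost-leftmost pixel. Returns an n x 2 matrix of 0-based (x, y).
trace_boundary <- function(labels, id) {
  h <- nrow(labels); w <- ncol(labels)
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && labels[r, c] == id
  idx <- which(labels == id)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  start_c <- min(cols)
  start_r <- min(rows[cols == start_c])
  # neighbors clockwise starting from "west": (dr, dc)
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
               ncol = 2, byrow = TRUE)
  if (length(idx) == 1) {
    return(matrix(c(start_c - 1L, start_r - 1L), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  path_r <- integer(0); path_c <- integer(0)
  cur_r <- start_r; cur_c <- start_c
  entry <- 1L # came from the west
  repeat {
    path_r <- c(path_r, cur_r); path_c <- c(path_c, cur_c)
    found <- FALSE
    for (k in 0:7) {
      j <- ((entry - 1L + k) %% 8L) + 1L
      nr <- cur_r + nb[j, 1]; nc <- cur_c + nb[j, 2]
      if (inside(nr, nc)) {
        # re-enter search from the neighbor opposite the move direction
        entry <- ((j - 1L + 5L) %% 8L) + 1L
        cur_r <- nr; cur_c <- nc
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel (cannot happen for size > 1)
    if (cur_r == start_r && cur_c == start_c && length(path_r) > 1) break
    if (length(path_r) > 4L * length(idx) + 8L) break # safety
  }
  cbind(x = path_c - 1L, y = path_r - 1L)
}

#' Extract outer contours of foreground components
#'
#' Labels 8-connected foreground components and traces the outer boundary of
#' each (Moore neighborhood, clockwise). Interior hole boundaries are not
#' reported. Boundary pixels are foreground pixels, in 0-based (x, y)
#' coordinates with the origin at the top-left.
#'
#' @param mask A [binary_mask].
#' @return A list of `contour` objects, sorted by decreasing enclosed area.
#'   Each has elements `coords` (n x 2 matrix of boundary x, y), `bbox`
#'   (named vector xmin/xmax/ymin/ymax), and `area` (component pixel count).
#' @export
extract_contours <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  labels <- label_components_8(mask)
  n <- max(labels)
  if (n == 0) return(list())
  h <- nrow(labels)
  idx <- which(labels > 0)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  lab <- labels[idx]
  out <- lapply(seq_len(n), function(id) {
    sel <- lab == id
    r <- rows[sel]; c <- cols[sel]
    coords <- trace_boundary(labels, id)
    structure(list(
      coords = coords,
      bbox = c(xmin = min(c) - 1L, xmax = max(c) - 1L,
               ymin = min(r) - 1L, ymax = max(r) - 1L),
      area = sum(sel)
    ), class = "contour")
  })
  out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> area %d px, bbox x[%d, %d] y[%d, %d]\n",
              x$area, x$bbox["xmin"], x$bbox["xmax"],
              x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Pupil diameter from contours
#'
#' Selects the largest-area contour (taken to be the pupil among any residual
#' components) and reports the larger of its bounding-box width and height,
#' in whole pixels. Using the box extent rather than a fitted circle is
#' robust to locally imperfect pupil contours. An empty contour list yields
#' diameter 0 with `flagged = TRUE`.
#'
#' @param contours A list of contours from [extract_contours()].
#' @return A list with elements `diameter` (pixels) and `flagged` (logical).
#' @export
measure_diameter <- function(contours) {
  if (length(contours) == 0) {
    return(list(diameter = 0, flagged = TRUE))
  }
  areas <- vapply(contours, `[[`, numeric(1), "area")
  bb <- contours[[which.max(areas)]]$bbox
  d <- max(bb["xmax"] - bb["xmin"] + 1, bb["ymax"] - bb["ymin"] + 1)
  list(diameter = as.numeric(d), flagged = FALSE)
}

#' Rule-of-thumb temporal correction of a diameter series
#'
#' Compares each frame's raw diameter against the previous accepted value; a
#' jump larger than `tol` pixels is treated as a misdetection and the
#' previous accepted value is carried forward. The first frame is always
#' accepted. Comparisons chain off the corrected value, so a single bad frame
#' cannot drag the series away.
#'
#' @param raw Numeric vector of per-frame raw diameters (pixels).
#' @param tol Positive jump tolerance in pixels (10 for the outdoor pipeline,
#'   5 for the indoor pipeline).
#' @return A list with `corrected` (numeric vector) and `substituted`
#'   (logical vector marking frames where the previous value was used).
#' @examples
#' temporal_correction(c(50, 75, 52), tol = 10)$corrected # 50 50 52
#' @export
temporal_correction <- function(raw, tol) {
  if (length(raw) == 0) {
    stop("temporal_correction: empty diameter sequence", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1 || is.na(tol) || tol <= 0) {
    stop("temporal_correction: 'tol' must be a positive number", call. = FALSE)
  }
  corrected <- raw
  substituted <- logical(length(raw))
  for (t in seq_along(raw)[-1]) {
    if (abs(raw[t] - corrected[t - 1]) > tol) {
      corrected[t] <- corrected[t - 1]
      substituted[t] <- TRUE
    }
  }
  list(corrected = corrected, substituted = substituted)
}

# Mask -> diameter convenience used by all pipelines.
mask_to_diameter <- function(mask, se = c(10, 10)) {
  opened <- morphological_opening(mask, se)
  measure_diameter(extract_contours(opened))
}
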