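# Per-frame diameter series: the common output container of the three
# pipelines, plus CSV I/O, evaluation against a reference, and plot/tidier
# methods for the tabular results.

assemble_series <- function(per_frame, temporal_tol, algorithm) {
  raw <- vapply(per_frame, function(p) p$diameter, numeric(1))
  flagged <- vapply(per_frame, function(p) isTRUE(p$flagged), logical(1))
  if (is.null(temporal_tol)) {
    corrected <- raw
    substituted <- logical(length(raw))
  } else {
    tc <- temporal_correction(raw, temporal_tol)
    corrected <- tc$corrected
    substituted <- tc$substituted
  }
  new_diameter_series(raw, corrected, flagged, substituted,
                      algorithm = algorithm, temporal_tol = temporal_tol)
}

#' Construct a diameter series
#'
#' A tibble subclass with one row per frame: `frame_index` (0-based),
#' `raw_px`, `corrected_px`, and `flagged` (no contour found, or frame-level
#' failure). A `substituted` column marks frames where the temporal
#' correction carried the previous value forward.
#'
#' @param raw,corrected Numeric per-frame diameters in pixels.
#' @param flagged,substituted Logical per-frame markers.
#' @param algorithm,temporal_tol Provenance attributes.
#' @return A `diameter_series` tibble.
#' @export
new_diameter_series <- function(raw, corrected, flagged,
                                substituted = logical(length(raw)),
                                algorithm = NA_character_,
                                temporal_tol = NA_real_) {
  out <- tibble::tibble(
    frame_index = seq_along(raw) - 1L,
    raw_px = as.numeric(raw),
    corrected_px = as.numeric(corrected),
    flagged = as.logical(flagged),
    substituted = as.logical(substituted)
  )
  class(out) <- c("diameter_series", class(out))
  attr(out, "algorithm") <- algorithm
  attr(out, "temporal_tol") <- temporal_tol
  out
}

#' Write / read a diameter series as CSV
#'
#' Columns: `frame_index`, `raw_px`, `corrected_px`, `flagged`,
#' `substituted`.
#'
#' @param x A `diameter_series`.
#' @param path Output CSV path.
#' @return `write_diameter_series()` returns `path` invisibly;
#'   `read_diameter_series()` returns a `diameter_series`.
#' @export
write_diameter_series <- function(x, path) {
  stopifnot(inherits(x, "diameter_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diameter_series
#' @export
read_diameter_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "raw_px", "corrected_px", "flagged")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' is not a diameter series CSV (need columns %s)",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$substituted)) df$substituted <- FALSE
  out <- new_diameter_series(df$raw_px, df$corrected_px, df$flagged,
                             df$substituted)
  out$frame_index <- as.integer(df$frame_index)
  out
}

#' Evaluate a diameter series against reference diameters
#'
#' Joins predictions and reference by `frame_index` and computes per-frame
#' absolute errors of the corrected diameters, mirroring the comparison of
#' algorithm output against ruler-measured reference diameters.
#'
#' @param pred A `diameter_series` (or data frame with `frame_index` and
#'   `corrected_px`).
#' @param truth A data frame with `frame_index` and `true_diameter_px`
#'   (e.g. the ground truth of [generate_eye_sequence()]).
#' @return A `diameter_eval` tibble with columns `frame_index`, `true_px`,
#'   `pred_px`, `abs_error_px`, and attributes `max_error`, `mean_error`.
#' @export
evaluate_diameters <- function(pred, truth) {
  stopifnot(is.data.frame(pred), is.data.frame(truth))
  if (is.null(truth[["true_diameter_px"]])) {
    stop("evaluate_diameters: 'truth' needs a true_diameter_px column",
         call. = FALSE)
  }
  missing_in_pred <- setdiff(truth$frame_index, pred$frame_index)
  missing_in_truth <- setdiff(pred$frame_index, truth$frame_index)
  if (length(missing_in_pred) || length(missing_in_truth)) {
    stop(sprintf(
      "frame index mismatch: missing in predictions [%s], missing in reference [%s]",
      paste(missing_in_pred, collapse = ", "),
      paste(missing_in_truth, collapse = ", ")), call. = FALSE)
  }
  ord <- order(truth$frame_index)
  truth <- truth[ord, ]
  pred <- pred[match(truth$frame_index, pred$frame_index), ]
  out <- tibble::tibble(
    frame_index = as.integer(truth$frame_index),
    true_px = as.numeric(truth$true_diameter_px),
    pred_px = as.numeric(pred$corrected_px),
    abs_error_px = abs(as.numeric(pred$corrected_px) -
                       as.numeric(truth$true_diameter_px))
  )
  class(out) <- c("diameter_eval", class(out))
  attr(out, "max_error") <- max(out$abs_error_px)
  attr(out, "mean_error") <- mean(out$abs_error_px)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diameter evaluation
#'
#' @param x A `diameter_eval` from [evaluate_diameters()].
#' @param ... Unused.
#' @return Per-frame tibble (`tidy`) or a one-row summary with `n_frames`,
#'   `max_error_px`, `mean_error_px` (`glance`).
#' @export
tidy.diameter_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("frame_index", "true_px", "pred_px",
                                 "abs_error_px")])
}

#' @rdname tidy.diameter_eval
#' @export
glance.diameter_eval <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x),
                 max_error_px = attr(x, "max_error"),
                 mean_error_px = attr(x, "mean_error"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diameter series
#'
#' Raw and corrected per-frame diameters against frame index.
#'
#' @param object A `diameter_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diameter_series <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)[c("frame_index", "raw_px",
                                            "corrected_px")])
  long <- rbind(
    data.frame(frame_index = df$frame_index, diameter_px = df$raw_px,
               series = "raw"),
    data.frame(frame_index = df$frame_index, diameter_px = df$corrected_px,
               series = "corrected")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame_index,
                                     y = .data$diameter_px,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame index", y = "pupil diameter (px)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-frame error curve
#'
#' @param object A `diameter_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diameter_eval <- function(object, ...) {
  df <- tidy.diameter_eval(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_index,
                                   y = .data$abs_error_px)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame index", y = "absolute error (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
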