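#' Average nearest-neighbour (ANN) clustering ratio
#'
#' Clark-Evans index of spatial aggregation for a point pattern: the mean
#' distance from each point to its nearest neighbour, divided by the
#' expectation under complete spatial randomness, `0.5 / sqrt(n / A)` for
#' `n` points in a window of area `A`.  Ratios below 1 indicate clustering,
#' above 1 dispersion (over-regularity).
#'
#' @param pattern A [point_pattern()] with at least two points, or a
#'   data frame with columns `x_cm`, `y_cm` (then `window` is required).
#' @param window Optional numeric length-2 (width, height in cm) overriding
#'   the pattern's own window; required for data-frame input.
#' @param edge_correction `"none"` (plain Clark-Evans ratio, the default)
#'   or `"donnelly"` (Donnelly's boundary adjustment of the CSR
#'   expectation, provided for sensitivity analysis).
#' @return An `ann_result` list: `n_points`, `mean_nn_distance`,
#'   `expected_nn_distance` (cm), `ratio` and a descriptive
#'   `classification` (`"clustered"`, `"random"`, `"scattered"`).
#' @examples
#' p <- point_pattern(c(0.25, 0.75), c(0.5, 0.5), 1, 1)
#' ann_ratio(p)$ratio  # sqrt(2)
#' @export
ann_ratio <- function(pattern, window = NULL,
                      edge_correction = c("none", "donnelly")) {
  edge_correction <- match.arg(edge_correction)
  if (is.data.frame(pattern)) {
    if (is.null(window)) stop("window is required for data-frame input")
    pattern <- point_pattern(pattern$x_cm, pattern$y_cm, window[1], window[2])
  }
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.null(window)) {
    if (length(window) != 2 || any(window <= 0)) stop("invalid window")
    pattern$window <- c(width = window[1], height = window[2])
  }
  n <- n_points(pattern)
  if (n < 2) stop("ANN requires at least 2 points")
  A <- window_area(pattern)
  if (A <= 0) stop("window area must be positive")
  d <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  diag(d) <- Inf
  mean_nn <- mean(apply(d, 1, min))
  expected <- 0.5 / sqrt(n / A)
  if (edge_correction == "donnelly") {
    # Donnelly (1978) small-sample boundary adjustment of the CSR mean
    per <- 2 * sum(pattern$window)
    expected <- expected + (0.0514 + 0.041 / sqrt(n)) * per / n
  }
  ratio <- mean_nn / expected
  structure(list(n_points = n, mean_nn_distance = mean_nn,
                 expected_nn_distance = expected, ratio = ratio,
                 edge_correction = edge_correction,
                 classification = if (ratio < 1) "clustered"
                                  else if (ratio > 1) "scattered"
                                  else "random"),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  cat(sprintf("ANN ratio %.4f (%s): n = %d, mean NN %.4g cm, CSR %.4g cm\n",
              x$ratio, x$classification, x$n_points,
              x$mean_nn_distance, x$expected_nn_distance))
  invisible(x)
}

#' Per-fish ANN ratios from a per-spot table
#'
#' Computes the ANN ratio for every image in a per-spot table (as written
#' by [detect_spots()] pipelines), applying the minimum-spot-count rule:
#' patterns with fewer than `min_points` spots are not scored (NA), since
#' aggregation is not meaningful at low counts.
#'
#' @param spots Data frame with columns `image_id`, `x_cm`, `y_cm`.
#' @param windows Data frame with columns `image_id`, `width_cm`,
#'   `height_cm` giving each image's ROI geometry.
#' @param min_points Minimum spots required to score a pattern (default 10).
#' @param edge_correction Passed to [ann_ratio()].
#' @return A tibble with `image_id`, `n_spots`, `ann_ratio`.
#' @export
ann_table <- function(spots, windows, min_points = 10,
                      edge_correction = "none") {
  stopifnot(all(c("image_id", "x_cm", "y_cm") %in% names(spots)),
            all(c("image_id", "width_cm", "height_cm") %in% names(windows)))
  ids <- windows$image_id
  res <- lapply(seq_along(ids), function(i) {
    sp <- spots[spots$image_id == ids[i], ]
    n <- nrow(sp)
    r <- if (n >= max(min_points, 2)) {
      ann_ratio(point_pattern(sp$x_cm, sp$y_cm,
                              windows$width_cm[i], windows$height_cm[i]),
                edge_correction = edge_correction)$ratio
    } else NA_real_
    tibble::tibble(image_id = ids[i], n_spots = n, ann_ratio = r)
  })
  do.call(rbind, res)
}
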