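#' Planar point pattern in a rectangular window
#'
#' Container for spot centroids observed in a rectangular window with
#' physical units (cm).  The window always has its origin at (0, 0).
#'
#' @param x,y Numeric vectors of point coordinates (cm).
#' @param width,height Window dimensions (cm), both > 0.
#' @return An object of class `point_pattern`: a list with elements `x`,
#'   `y` and `window = c(width, height)`.
#' @export
point_pattern <- function(x, y, width, height) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("window dimensions must be positive")
  if (length(x) && (any(x < 0 | x > width) || any(y < 0 | y > height)))
    stop("all points must lie inside the window")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 window = c(width = width, height = height)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in %.3g x %.3g cm window\n",
              length(x$x), x$window[1], x$window[2]))
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern A `point_pattern`.
#' @return Integer count.
#' @export
n_points <- function(pattern) length(pattern$x)

#' Window area of a pattern (cm^2)
#' @param pattern A `point_pattern`.
#' @export
window_area <- function(pattern) unname(pattern$window[1] * pattern$window[2])

#' Specify a synthetic spot point process
#'
#' Defines one of three planar point processes used to emulate the two spot
#' regimes seen on salmon flanks: homogeneous Poisson (random, the
#' high-density hatchery-like regime), Thomas cluster (aggregated, the
#' low-density river-like regime) and hard-core (inhibited/over-dispersed).
#'
#' @param process One of `"poisson"`, `"thomas"`, `"hardcore"`.
#' @param window Numeric length-2, window width and height in cm.
#' @param intensity Expected points per cm^2 of the final pattern.
#' @param cluster_sd Thomas only: isotropic Gaussian dispersal sd of
#'   offspring points around their cluster parent (cm).
#' @param mean_per_cluster Thomas only: expected offspring per parent; the
#'   parent intensity is `intensity / mean_per_cluster`.
#' @param min_dist Hard-core only: minimum permitted inter-point distance (cm).
#' @param seed Optional integer seed; generation is reproducible given it.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(process = c("poisson", "thomas", "hardcore"),
                         window = c(8, 5), intensity = 1.5,
                         cluster_sd = NULL, mean_per_cluster = NULL,
                         min_dist = 0, seed = NULL) {
  process <- match.arg(process)
  if (length(window) != 2 || any(!is.finite(window)) || any(window <= 0))
    stop("window must be two positive dimensions (cm)")
  if (!is.finite(intensity) || intensity <= 0)
    stop("intensity must be positive")
  if (process == "thomas") {
    if (is.null(cluster_sd) || cluster_sd <= 0)
      stop("thomas process requires cluster_sd > 0")
    if (is.null(mean_per_cluster) || mean_per_cluster <= 0)
      stop("thomas process requires mean_per_cluster > 0")
  }
  if (process == "hardcore" && min_dist < 0)
    stop("min_dist must be >= 0")
  structure(list(process = process, window = as.numeric(window),
                 intensity = intensity, cluster_sd = cluster_sd,
                 mean_per_cluster = mean_per_cluster, min_dist = min_dist,
                 seed = seed),
            class = "pattern_spec")
}

#' Generate a point pattern from a process specification
#'
#' @param spec A [pattern_spec()].
#' @return A [point_pattern()] with all points inside the window.
#' @details Thomas parents are simulated in a window dilated by `4 *
#'   cluster_sd` so the pattern has no artificial thinning near the edges;
#'   offspring falling outside the window are dropped.  Hard-core patterns
#'   use random sequential adsorption: a Poisson number of points is
#'   proposed and placed one at a time, rejecting proposals closer than
#'   `min_dist` to an accepted point (up to 100 attempts each), so at very
#'   high packing the realized count can fall below the nominal intensity.
#' @export
gen_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  run <- function() {
    w <- spec$window[1]; h <- spec$window[2]; area <- w * h
    switch(spec$process,
      poisson = {
        n <- stats::rpois(1, spec$intensity * area)
        point_pattern(stats::runif(n, 0, w), stats::runif(n, 0, h), w, h)
      },
      thomas = {
        kappa <- spec$intensity / spec$mean_per_cluster
        pad <- 4 * spec$cluster_sd
        npar <- stats::rpois(1, kappa * (w + 2 * pad) * (h + 2 * pad))
        px <- stats::runif(npar, -pad, w + pad)
        py <- stats::runif(npar, -pad, h + pad)
        noff <- stats::rpois(npar, spec$mean_per_cluster)
        cx <- rep(px, noff) + stats::rnorm(sum(noff), 0, spec$cluster_sd)
        cy <- rep(py, noff) + stats::rnorm(sum(noff), 0, spec$cluster_sd)
        keep <- cx >= 0 & cx <= w & cy >= 0 & cy <= h
        point_pattern(cx[keep], cy[keep], w, h)
      },
      hardcore = {
        n <- stats::rpois(1, spec$intensity * area)
        xs <- numeric(0); ys <- numeric(0)
        d2 <- spec$min_dist^2
        for (i in seq_len(n)) {
          for (try in seq_len(100L)) {
            cx <- stats::runif(1, 0, w); cy <- stats::runif(1, 0, h)
            if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 >= d2)) {
              xs <- c(xs, cx); ys <- c(ys, cy)
              break
            }
          }
        }
        point_pattern(xs, ys, w, h)
      })
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}
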