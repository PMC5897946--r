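#' Render a point pattern as a synthetic flank photograph
#'
#' Draws dark disks on a light background at the pattern's coordinates and
#' embeds anatomical landmark coordinates (gill crease, dorsal-fin front,
#' lateral line, pectoral-fin top) positioned so that the standardized ROI
#' constructed by [construct_roi()] covers the pattern window exactly.
#' Pixel (x, y) is 0-based and covers the half-open square
#' `[x, x+1) x [y, y+1)`; a pixel is painted dark when its centre lies
#' within `radius_mean` of a spot centre.
#'
#' @param pattern A [point_pattern()].
#' @param scale Physical pixel size, cm per pixel (> 0).
#' @param radius_mean Spot radius in cm (> 0).
#' @param noise_sd Gaussian pixel noise sd in intensity units (image values
#'   are clamped to `[0, 1]`); 0 gives a binary image that round-trips
#'   through PNG losslessly.
#' @param margin_px Light margin around the pattern window, in pixels.
#' @param seed Optional integer seed for the noise.
#' @return A `spot_image`: list with `pixels` (numeric matrix, rows = y),
#'   `scale`, `landmarks` (list: `gill_crease_x`, `dorsal_fin_front_x`,
#'   `lateral_line_y`, `pectoral_fin_top = c(x, y)`), and
#'   `window_origin_px` (0-based pixel of the pattern window's corner).
#' @export
render_spot_image <- function(pattern, scale = 0.02, radius_mean = 0.1,
                              noise_sd = 0, margin_px = 20, seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (scale <= 0) stop("scale must be positive (cm per pixel)")
  if (radius_mean <= 0) stop("radius_mean must be positive")
  w_px <- 2L * as.integer(round(pattern$window[1] / scale / 2))
  h_px <- 2L * as.integer(round(pattern$window[2] / scale / 2))
  if (w_px <= 0 || h_px <= 0) stop("pattern window too small at this scale")
  x0 <- as.integer(margin_px); y0 <- as.integer(margin_px)
  nc <- w_px + 2L * margin_px
  # room below the window for the pectoral-fin-top landmark (see landmarks)
  nr <- y0 + h_px + h_px %/% 2L + margin_px
  px <- matrix(1, nr, nc)
  r_px <- radius_mean / scale
  cx <- x0 + pattern$x / scale
  cy <- y0 + pattern$y / scale
  for (k in seq_along(cx)) {
    js <- max(0, floor(cx[k] - r_px)):min(nc - 1, ceiling(cx[k] + r_px))
    is <- max(0, floor(cy[k] - r_px)):min(nr - 1, ceiling(cy[k] + r_px))
    if (!length(js) || !length(is)) next
    dj <- (js + 0.5 - cx[k])^2
    di <- (is + 0.5 - cy[k])^2
    hit <- outer(di, dj, `+`) <= r_px^2
    px[is + 1, js + 1][hit] <- 0
  }
  if (noise_sd > 0) {
    add <- function() px + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    px <- if (is.null(seed)) add() else withr::with_seed(seed, add())
    px <- pmin(pmax(px, 0), 1)
  }
  lateral <- y0 + h_px %/% 2L
  structure(list(
    pixels = px, scale = scale,
    landmarks = list(gill_crease_x = x0,
                     dorsal_fin_front_x = x0 + w_px,
                     lateral_line_y = lateral,
                     pectoral_fin_top = c(x = x0, y = lateral + h_px)),
    window_origin_px = c(x = x0, y = y0),
    window_px = c(width = w_px, height = h_px)),
    class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  cat(sprintf("spot_image: %d x %d px, %.4g cm/px\n",
              ncol(x$pixels), nrow(x$pixels), x$scale))
  invisible(x)
}

#' Write / read a spot image with its landmark sidecar
#'
#' The raster goes to an 8-bit grayscale PNG; scale and landmarks go to a
#' CSV sidecar (`<path>.landmarks.csv`, columns `landmark`, `x`, `y`) so a
#' directory of images remains plain text + standard formats.
#'
#' @param image A `spot_image`.
#' @param path PNG file path.
#' @return `write_spot_image` returns `path` invisibly; `read_spot_image`
#'   returns a `spot_image`.
#' @export
write_spot_image <- function(image, path) {
  stopifnot(inherits(image, "spot_image"))
  png::writePNG(image$pixels, path)
  lm <- image$landmarks
  side <- data.frame(
    landmark = c("gill_crease_x", "dorsal_fin_front_x", "lateral_line_y",
                 "pectoral_fin_top", "window_origin", "window_size", "scale"),
    x = c(lm$gill_crease_x, lm$dorsal_fin_front_x, NA,
          lm$pectoral_fin_top["x"], image$window_origin_px["x"],
          image$window_px["width"], image$scale),
    y = c(NA, NA, lm$lateral_line_y, lm$pectoral_fin_top["y"],
          image$window_origin_px["y"], image$window_px["height"], NA))
  utils::write.csv(side, paste0(path, ".landmarks.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_image
#' @export
read_spot_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  side <- utils::read.csv(paste0(path, ".landmarks.csv"))
  val <- function(nm, col) side[side$landmark == nm, col]
  structure(list(
    pixels = px, scale = val("scale", "x"),
    landmarks = list(
      gill_crease_x = val("gill_crease_x", "x"),
      dorsal_fin_front_x = val("dorsal_fin_front_x", "x"),
      lateral_line_y = val("lateral_line_y", "y"),
      pectoral_fin_top = c(x = val("pectoral_fin_top", "x"),
                           y = val("pectoral_fin_top", "y"))),
    window_origin_px = c(x = val("window_origin", "x"),
                         y = val("window_origin", "y")),
    window_px = c(width = val("window_size", "x"),
                  height = val("window_size", "y"))),
    class = "spot_image")
}
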