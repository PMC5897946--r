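#' Construct the standardized flank ROI from anatomical landmarks
#'
#' Reproduces the standardized measurement rectangle: an initial rectangle
#' spans horizontally from the gill crease to the front of the dorsal fin
#' and vertically from the lateral line down to the top of the pectoral
#' fin; the final ROI keeps that width and height but is translated
#' vertically so that its vertical midline sits on the lateral line.
#' Pixel coordinates are 0-based with half-open rectangles
#' `[x0, x0 + width) x [y0, y0 + height)`; rows increase downwards.
#'
#' @param landmarks List with `gill_crease_x`, `dorsal_fin_front_x`,
#'   `lateral_line_y` (all scalars, pixels) and `pectoral_fin_top`
#'   (named numeric `c(x, y)`).
#' @param image_dim Integer length-2 `c(n_rows, n_cols)` of the image.
#' @param scale Physical pixel size, cm per pixel (> 0).
#' @return An object of class `roi`: `origin` (0-based `c(x, y)`),
#'   `width`, `height` (pixels), `area_cm2`, `scale`.
#' @export
construct_roi <- function(landmarks, image_dim, scale) {
  if (scale <= 0) stop("scale must be positive")
  gx <- landmarks$gill_crease_x
  dx <- landmarks$dorsal_fin_front_x
  ly <- landmarks$lateral_line_y
  py <- landmarks$pectoral_fin_top["y"]
  if (any(!is.finite(c(gx, dx, ly, py)))) stop("incomplete landmarks")
  if (gx >= dx) stop("gill crease must lie left of the dorsal-fin front")
  if (ly >= py) stop("lateral line must lie above the pectoral-fin top")
  width <- unname(dx - gx)
  height <- unname(py - ly)
  if (width <= 0 || height <= 0) stop("degenerate ROI")
  y0 <- round(ly - height / 2)
  roi <- structure(list(origin = c(x = as.numeric(gx), y = as.numeric(y0)),
                        width = as.numeric(width),
                        height = as.numeric(height),
                        area_cm2 = width * height * scale^2,
                        scale = scale),
                   class = "roi")
  if (roi$origin["x"] < 0 || roi$origin["y"] < 0 ||
      roi$origin["x"] + width > image_dim[2] ||
      roi$origin["y"] + height > image_dim[1])
    stop("ROI exceeds image bounds; check landmarks")
  roi
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi: origin (%g, %g), %g x %g px, %.4g cm^2\n",
              x$origin["x"], x$origin["y"], x$width, x$height, x$area_cm2))
  invisible(x)
}

#' Detect spots inside an ROI by thresholding and connected components
#'
#' Converts the ROI to grayscale, binarizes (spots are the dark
#' foreground) using either Otsu's threshold on the ROI histogram or a
#' fixed cutoff, labels 8-connected components, discards components
#' smaller than `min_area_cm2`, and reports per-spot areas and centroids
#' in ROI-local physical coordinates.
#'
#' @param image A `spot_image`, or a numeric matrix / 3-channel array of
#'   intensities in `[0, 1]`.
#' @param roi An `roi` from [construct_roi()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Cutoff in `[0, 1]` when `method = "fixed"`.
#' @param min_area_cm2 Minimum spot area retained (default 0.005 cm^2).
#' @return A `detected_spots` list: `count`, `spots` (tibble `spot`,
#'   `x_cm`, `y_cm`, `area_cm2`), `threshold`.
#' @export
detect_spots <- function(image, roi, method = c("otsu", "fixed"),
                         fixed_threshold = NULL, min_area_cm2 = 0.005) {
  method <- match.arg(method)
  if (min_area_cm2 < 0) stop("min_area_cm2 must be >= 0")
  px <- if (inherits(image, "spot_image")) image$pixels else image
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  stopifnot(inherits(roi, "roi"))
  if (roi$width < 1 || roi$height < 1) stop("empty ROI")
  rows <- (roi$origin["y"] + 1):(roi$origin["y"] + roi$height)
  cols <- (roi$origin["x"] + 1):(roi$origin["x"] + roi$width)
  if (max(rows) > nrow(px) || max(cols) > ncol(px) || min(rows) < 1 ||
      min(cols) < 1)
    stop("ROI outside image")
  crop <- px[rows, cols, drop = FALSE]
  thr <- if (method == "otsu") {
    if (stats::sd(crop) == 0) -Inf else EBImage::otsu(crop, range = c(0, 1))
  } else {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1)
      stop("fixed_threshold must lie in [0, 1]")
    fixed_threshold
  }
  mask <- crop < thr
  lab <- .label_components8(mask)
  scale <- roi$scale
  if (max(lab) == 0) {
    return(structure(list(count = 0L,
                          spots = tibble::tibble(spot = integer(),
                                                 x_cm = numeric(),
                                                 y_cm = numeric(),
                                                 area_cm2 = numeric()),
                          threshold = as.numeric(thr)),
                     class = "detected_spots"))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  # 0-based pixel centres, ROI-local
  yc <- (idx - 1) %% nrow(lab) + 0.5
  xc <- (idx - 1) %/% nrow(lab) + 0.5
  npix <- tabulate(comp)
  area <- npix * scale^2
  sx <- tapply(xc, comp, mean) * scale
  sy <- tapply(yc, comp, mean) * scale
  keep <- area >= min_area_cm2
  spots <- tibble::tibble(spot = seq_len(sum(keep)),
                          x_cm = as.numeric(sx[keep]),
                          y_cm = as.numeric(sy[keep]),
                          area_cm2 = area[keep])
  structure(list(count = nrow(spots), spots = spots,
                 threshold = as.numeric(thr)),
            class = "detected_spots")
}

#' @export
print.detected_spots <- function(x, ...) {
  cat(sprintf("detected_spots: %d spots (threshold %.4g)\n",
              x$count, x$threshold))
  invisible(x)
}

#' Spot density: automatic count adjusted by ROI area
#'
#' Spot counts scale with fish size (ROI area tracks weight closely), so
#' counts are normalized to spots per cm^2.  Fish with zero spots are
#' excluded rather than assigned density 0, because ROI size — and hence
#' density — is only defined through the presence of spots; they come back
#' as `NA` and are dropped by [apply_exclusions()] with purpose
#' `"density"`.
#'
#' @param count Integer vector of spot counts.
#' @param roi_area_cm2 ROI areas in cm^2 (> 0).
#' @return Numeric vector of spots/cm^2, `NA` where `count == 0`.
#' @export
spot_density <- function(count, roi_area_cm2) {
  if (any(roi_area_cm2 <= 0, na.rm = TRUE)) stop("ROI area must be positive")
  d <- count / roi_area_cm2
  d[!is.na(count) & count == 0] <- NA_real_
  d
}

#' Head-spot density: manual head count adjusted by body weight
#'
#' @param head_count Manual head-spot counts (may be `NA`: heads are not
#'   always fully visible in the photographs; missingness propagates).
#' @param weight_g Body weight in grams (> 0).
#' @return head_count / weight_g, per gram.
#' @export
head_density <- function(head_count, weight_g) {
  if (any(weight_g <= 0, na.rm = TRUE)) stop("weight must be positive")
  head_count / weight_g
}

#' Apply the cohort exclusion rules
#'
#' Three rules, each tied to an analysis purpose: `"density"` drops fish
#' with zero spots (density undefined); `"ann"` drops fish with fewer than
#' 10 spots (aggregation is noise-dominated at low counts; 10 is the
#' declared threshold, and a fish with exactly 10 is retained);
#' `"family_model"` drops families with a single member (no within-family
#' information).  Dropped ids and reasons are recorded in the
#' `exclusion_log` attribute.
#'
#' @param table Cohort data frame; needs `spot_count` for `"density"` and
#'   `"ann"`, `family` for `"family_model"`, and `id` always.
#' @param purpose One of `"density"`, `"ann"`, `"family_model"`.
#' @return The filtered table, with attribute `exclusion_log` (tibble
#'   `id`, `reason`).
#' @export
apply_exclusions <- function(table,
                             purpose = c("density", "ann", "family_model")) {
  purpose <- match.arg(purpose)
  if (!"id" %in% names(table)) stop("missing required column: id")
  need <- switch(purpose, density = "spot_count", ann = "spot_count",
                 family_model = "family")
  if (!need %in% names(table))
    stop("missing required column: ", need)
  drop <- switch(purpose,
    density = !is.na(table$spot_count) & table$spot_count == 0,
    ann = !is.na(table$spot_count) & table$spot_count < 10,
    family_model = {
      sizes <- table(table$family)
      table$family %in% names(sizes)[sizes < 2]
    })
  drop[is.na(drop)] <- FALSE
  log <- tibble::tibble(
    id = table$id[drop],
    reason = switch(purpose,
                    density = "zero spots",
                    ann = "fewer than 10 spots",
                    family_model = "single-member family"))
  out <- table[!drop, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Quantify one synthetic or photographed image end to end
#'
#' Convenience wrapper: build the ROI from the image's landmarks, detect
#' spots, and return the per-image record pieces.
#'
#' @param image A `spot_image` (landmarks embedded).
#' @param method,fixed_threshold,min_area_cm2 Passed to [detect_spots()].
#' @return List: `roi`, `detection`, `spot_count`, `roi_area_cm2`,
#'   `spot_density`.
#' @export
quantify_image <- function(image, method = "otsu", fixed_threshold = NULL,
                           min_area_cm2 = 0.005) {
  roi <- construct_roi(image$landmarks, dim(image$pixels), image$scale)
  det <- detect_spots(image, roi, method = method,
                      fixed_threshold = fixed_threshold,
                      min_area_cm2 = min_area_cm2)
  list(roi = roi, detection = det, spot_count = det$count,
       roi_area_cm2 = roi$area_cm2,
       spot_density = spot_density(det$count, roi$area_cm2))
}
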