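#' Region area as a percentage of a reference mask
#'
#' The section-level area ratio (e.g. Arc area divided by total brain area
#' on the same slide), reported as a percent. The physical pixel area
#' cancels in the ratio and is used only for the absolute areas attached
#' as attributes.
#'
#' @param region_mask Logical/0-1 matrix (or labeled matrix; any non-zero
#'   pixel counts) of the region.
#' @param brain_mask Non-empty reference mask of the whole section.
#' @param pixel_area Physical area per pixel (mm^2), default 1.
#' @return Percent in \[0, 100\] (may exceed 100 if the region is not a
#'   subset of the reference, which triggers a warning). Attributes
#'   `region_area` and `brain_area` hold absolute areas in
#'   `pixel_area` units.
#' @export
area_ratio <- function(region_mask, brain_mask, pixel_area = 1) {
  n_region <- sum(region_mask != 0)
  n_brain <- sum(brain_mask != 0)
  if (n_brain == 0L) stop("empty brain mask", call. = FALSE)
  if (identical(dim(region_mask), dim(brain_mask)) &&
      any(region_mask != 0 & brain_mask == 0)) {
    warning("region mask extends outside the reference mask")
  }
  out <- 100 * n_region / n_brain
  attr(out, "region_area") <- n_region * pixel_area
  attr(out, "brain_area") <- n_brain * pixel_area
  out
}

#' Split a region's area into tier 1 and tiers 2-3
#'
#' Tier 1 is the cell-dense layer against the ventricular wall; tiers 2-3
#' are defined by subtraction as the remaining region area.
#'
#' @param arc_mask Mask of the whole region (any non-zero pixel counts).
#' @param tier1_mask Mask of tier 1; must be a subset of `arc_mask`.
#' @param pixel_area Physical area per pixel, default 1.
#' @return Named numeric vector `c(tier1 = ..., tiers2_3 = ...)` in
#'   `pixel_area` units.
#' @export
tier_areas <- function(arc_mask, tier1_mask, pixel_area = 1) {
  if (!identical(dim(arc_mask), dim(tier1_mask))) {
    stop("masks must have identical dimensions", call. = FALSE)
  }
  if (any(tier1_mask != 0 & arc_mask == 0)) {
    stop("tier 1 mask is not contained in the region mask", call. = FALSE)
  }
  a <- sum(arc_mask != 0) * pixel_area
  t1 <- sum(tier1_mask != 0) * pixel_area
  c(tier1 = t1, tiers2_3 = a - t1)
}

#' Gyrification index of a cortical contour
#'
#' The ratio of the length of the full cortical contour (following every
#' sulcus and gyrus) to the length of the outer envelope connecting the
#' cortical surface. A smooth (lissencephalic) outline gives 1; folding
#' increases the index. When the contour set carries no outer contour, the
#' convex hull of the full contour is used as a reproducible envelope.
#'
#' @param contours A [contour_set()], or an n x 2 matrix taken as the full
#'   contour (envelope by convex hull).
#' @return Numeric scalar >= ~1, invariant to rigid motion and uniform
#'   scaling. Attributes `full_length` and `outer_length` hold the two
#'   lengths.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 257)[-257]
#' circle <- cbind(cos(theta), sin(theta))
#' gyrification_index(contour_set(circle))
#' @export
gyrification_index <- function(contours) {
  if (!inherits(contours, "contour_set")) {
    contours <- contour_set(as.matrix(contours))
  }
  full <- contours$full
  outer <- contours$outer
  if (is.null(outer)) {
    hull <- grDevices::chull(full[, 1], full[, 2])
    outer <- close_polyline(full[hull, , drop = FALSE])
  }
  lf <- polyline_length(full)
  lo <- polyline_length(outer)
  if (lo <= 0) stop("outer contour has zero length", call. = FALSE)
  out <- lf / lo
  attr(out, "full_length") <- lf
  attr(out, "outer_length") <- lo
  out
}

#' Percent of a region above an intensity threshold
#'
#' Positive-area fraction of a fluorescence channel within a region mask
#' (e.g. the vascular area labeled by a smooth-muscle marker relative to
#' the whole region), as a percent of region pixels strictly above the
#' threshold. The threshold is either supplied or chosen automatically
#' with [renyi_threshold()] from the intensities inside the region.
#'
#' @param channel_image Numeric intensity matrix.
#' @param region_mask Non-empty mask delimiting the region.
#' @param threshold Intensity threshold; `NULL` (default) selects it by
#'   Renyi-entropy thresholding of the region's intensities.
#' @return Percent in \[0, 100\], with the threshold used in attribute
#'   `threshold`.
#' @export
positive_area_fraction <- function(channel_image, region_mask,
                                   threshold = NULL) {
  if (!identical(dim(channel_image), dim(region_mask))) {
    stop("image and mask must have identical dimensions", call. = FALSE)
  }
  inside <- region_mask != 0
  n <- sum(inside)
  if (n == 0L) stop("empty region mask", call. = FALSE)
  if (is.null(threshold)) {
    threshold <- renyi_threshold(channel_image[inside])
  }
  out <- 100 * sum(channel_image[inside] > threshold) / n
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Tier specification for intensity profiles
#'
#' A rectangular box anchored at the ventricular wall, subdivided into
#' ordered tier bands by offsets measured from the wall-side edge.
#'
#' @param x0,y0 Top-left corner of the box, 0-based pixel indices; the
#'   wall-side edge is the top edge (`y = y0`) and tiers extend downward.
#' @param width Box width in pixels.
#' @param boundaries Strictly increasing offsets (pixels from the wall
#'   edge) ending each tier; the last value is the box depth. With
#'   `boundaries = c(b1, b2, b3)` tier 1 spans rows `[0, b1)`, tier 2
#'   `[b1, b2)`, tier 3 `[b2, b3)`.
#' @return Object of class `tier_spec`.
#' @export
tier_spec <- function(x0, y0, width, boundaries) {
  if (any(diff(boundaries) <= 0) || boundaries[1] <= 0) {
    stop("`boundaries` must be strictly increasing and positive",
         call. = FALSE)
  }
  structure(
    list(x0 = x0, y0 = y0, width = width, boundaries = boundaries),
    class = "tier_spec"
  )
}

#' Mean positive signal intensity per tier band
#'
#' Within a rectangular box spanning from the ventricular wall across the
#' tier bands, computes the mean intensity of positive pixels (strictly
#' above `threshold`) separately for each tier. A band containing no
#' positive pixel yields `NA` rather than an error.
#'
#' @param channel_image Numeric intensity matrix (rows = y, columns = x).
#' @param tiers A [tier_spec()]; the box must lie inside the image.
#' @param threshold Positivity threshold; `NULL` selects it with
#'   [renyi_threshold()] from the box intensities.
#' @return Numeric vector of per-tier mean positive intensities (length =
#'   number of tiers), `NA` where a band has no positive pixel.
#' @export
tier_intensity_profile <- function(channel_image, tiers, threshold = NULL) {
  stopifnot(inherits(tiers, "tier_spec"))
  depth <- tiers$boundaries[length(tiers$boundaries)]
  rows <- tiers$y0 + seq_len(depth)          # 1-based rows of the box
  cols <- tiers$x0 + seq_len(tiers$width)
  if (min(rows) < 1 || max(rows) > nrow(channel_image) ||
      min(cols) < 1 || max(cols) > ncol(channel_image)) {
    stop("tier box does not lie inside the image", call. = FALSE)
  }
  box <- channel_image[rows, cols, drop = FALSE]
  if (is.null(threshold)) threshold <- renyi_threshold(box)
  starts <- c(0, tiers$boundaries[-length(tiers$boundaries)])
  ends <- tiers$boundaries
  vapply(seq_along(ends), function(i) {
    band <- box[(starts[i] + 1):ends[i], , drop = FALSE]
    pos <- band[band > threshold]
    if (length(pos) == 0L) NA_real_ else mean(pos)
  }, numeric(1))
}

#' Serial-section volume by the conical-frustum estimator
#'
#' Estimates a region's volume from ordered serial-section areas spaced
#' `h` apart by summing the volume of the conical frustum between each
#' consecutive pair of sections:
#' \deqn{V = \sum_{k=2}^{n} \left(A_{k-1} + A_k +
#'       \sqrt{A_{k-1} A_k}\right) \frac{h}{3}.}
#' The estimator is exact for any solid whose cross-section radius varies
#' linearly between sections (cylinders, cones, frustum stacks) and
#' converges to the true volume for smooth solids as sections are refined.
#'
#' @param series A [section_series()] (per-gap spacing supported), or a
#'   numeric vector of areas combined with `spacing`.
#' @param spacing Used only when `series` is a bare numeric vector.
#' @return Volume in units of area x spacing (mm^3 for mm^2 areas and mm
#'   spacing).
#' @examples
#' estimate_volume(section_series(c(0, 0.25 * pi, pi), spacing = 0.75))
#' @export
estimate_volume <- function(series, spacing = NULL) {
  if (!inherits(series, "section_series")) {
    series <- section_series(series, spacing = spacing)
  }
  a <- series$area
  n <- length(a)
  h <- attr(series, "spacing")
  if (length(h) == 1L) h <- rep(h, n - 1L)
  a0 <- a[-n]; a1 <- a[-1]
  sum((a0 + a1 + sqrt(a0 * a1)) * h / 3)
}

#' Pearson correlation between two morphometric series
#'
#' Product-moment correlation with the two-sided t-test, as used to relate
#' the gyrification index to the region area ratio across specimens.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Data frame with `r`, `p_value`, `n`, and the 95% confidence
#'   interval bounds `conf_low`, `conf_high` (NA when n == 3).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_
  )
}
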