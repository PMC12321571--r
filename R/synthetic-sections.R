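#' Section-area series
#'
#' Container for an ordered series of serial-section cross-sectional areas
#' together with the inter-section spacing, the input of
#' [estimate_volume()]. Spacing may be a single value (uniform sectioning,
#' e.g. 0.75 mm serial Nissl sections) or one value per gap.
#'
#' @param areas Numeric vector of section areas (mm^2), length >= 2, all
#'   >= 0.
#' @param spacing Inter-section distance(s) (mm): a single positive number
#'   or a vector of length `length(areas) - 1`.
#' @return An object of class `section_series`: a data frame with columns
#'   `section` and `area`, with the spacing stored in attribute `spacing`.
#' @examples
#' s <- section_series(c(1, 1, 1), spacing = 0.75)
#' estimate_volume(s)
#' @export
section_series <- function(areas, spacing) {
  areas <- as.numeric(areas)
  n <- length(areas)
  if (n < 2L) stop("a section series needs at least 2 sections", call. = FALSE)
  if (anyNA(areas) || any(areas < 0)) {
    stop("section areas must be non-negative and non-missing", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (!length(spacing) %in% c(1L, n - 1L)) {
    stop("`spacing` must have length 1 or length(areas) - 1", call. = FALSE)
  }
  if (anyNA(spacing) || any(spacing <= 0)) {
    stop("`spacing` must be positive", call. = FALSE)
  }
  out <- data.frame(section = seq_len(n), area = areas)
  attr(out, "spacing") <- spacing
  class(out) <- c("section_series", "data.frame")
  out
}

#' Specify an analytic solid for synthetic serial sectioning
#'
#' Describes a solid of revolution whose planar cross-sections have a
#' closed-form area, used by [generate_section_profile()] to emulate
#' serial coronal sectioning of a brain region at fixed intervals.
#'
#' Shapes:
#' \describe{
#'   \item{`cylinder`}{`dimensions = c(radius, height)`; constant
#'     cross-section.}
#'   \item{`cone`}{`dimensions = c(radius, height)`; sectioned from apex
#'     (area 0) towards the base.}
#'   \item{`sphere`}{`dimensions = radius`; sectioned along a diameter.}
#'   \item{`frustum_stack`}{`dimensions` is the vector of radii at each
#'     section plane (length `n_sections`); the solid is the stack of
#'     conical frusta linearly interpolating those radii.}
#' }
#'
#' @param shape One of `"cylinder"`, `"cone"`, `"sphere"`,
#'   `"frustum_stack"`.
#' @param dimensions Numeric vector of lengths in mm (see Details).
#' @param n_sections Number of sections (>= 2).
#' @param spacing Distance between consecutive section planes (mm).
#' @return An object of class `solid_spec`.
#' @export
solid_spec <- function(shape = c("cylinder", "cone", "sphere", "frustum_stack"),
                       dimensions, n_sections, spacing) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  if (anyNA(dimensions) || any(dimensions <= 0)) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (!is.numeric(n_sections) || length(n_sections) != 1L || n_sections < 2) {
    stop("`n_sections` must be a single count >= 2", call. = FALSE)
  }
  n_sections <- as.integer(n_sections)
  stop_if_not_scalar_number(spacing, "spacing", positive = TRUE)
  n_dim <- switch(shape,
    cylinder = 2L, cone = 2L, sphere = 1L, frustum_stack = n_sections
  )
  if (length(dimensions) != n_dim) {
    stop(sprintf("shape '%s' needs %d dimension(s), got %d",
                 shape, n_dim, length(dimensions)), call. = FALSE)
  }
  structure(
    list(shape = shape, dimensions = dimensions,
         n_sections = n_sections, spacing = spacing),
    class = "solid_spec"
  )
}

#' Analytic serial-section area profile of a solid
#'
#' Computes the exact cross-sectional areas of a [solid_spec()] at
#' `n_sections` evenly spaced parallel planes, the synthetic analogue of
#' measuring a region's area on serial coronal sections. The resulting
#' [section_series()] carries planted ground truth: the solid's true
#' volume is known in closed form, so the frustum estimator
#' ([estimate_volume()]) can be validated against it.
#'
#' For cone and sphere the sectioned span `spacing * (n_sections - 1)`
#' must not exceed the solid's extent (height, respectively diameter);
#' planes are anchored at the apex (cone) or at one pole (sphere).
#'
#' @param solid A [solid_spec()].
#' @return A [section_series()] whose attribute `true_volume` holds the
#'   solid's analytic volume (for the cone and sphere this is the volume
#'   of the sectioned span, which equals the full solid when the span
#'   covers it).
#' @examples
#' sp <- solid_spec("sphere", dimensions = 1, n_sections = 11, spacing = 0.2)
#' generate_section_profile(sp)
#' @export
generate_section_profile <- function(solid) {
  stopifnot(inherits(solid, "solid_spec"))
  n <- solid$n_sections
  h <- solid$spacing
  span <- h * (n - 1)
  z <- h * (seq_len(n) - 1)

  if (solid$shape == "cylinder") {
    r <- solid$dimensions[1]
    areas <- rep(pi * r^2, n)
    true_volume <- pi * r^2 * span
  } else if (solid$shape == "cone") {
    r <- solid$dimensions[1]
    height <- solid$dimensions[2]
    if (span > height + 1e-12) {
      stop("sectioned span exceeds cone height", call. = FALSE)
    }
    # z measured from the apex; radius grows linearly towards the base
    areas <- pi * (r * z / height)^2
    true_volume <- pi * r^2 * span^3 / (3 * height^2)
  } else if (solid$shape == "sphere") {
    r <- solid$dimensions[1]
    if (span > 2 * r + 1e-12) {
      stop("sectioned span exceeds sphere diameter", call. = FALSE)
    }
    zc <- z - r                        # signed distance from the equator
    areas <- pi * pmax(r^2 - zc^2, 0)
    # volume of the spherical segment between the first and last plane
    a <- -r; b <- span - r
    true_volume <- pi * ((r^2 * b - b^3 / 3) - (r^2 * a - a^3 / 3))
  } else { # frustum_stack
    radii <- solid$dimensions
    areas <- pi * radii^2
    rk <- radii[-n]; rk1 <- radii[-1]
    true_volume <- sum(pi * h / 3 * (rk^2 + rk * rk1 + rk1^2))
  }

  out <- section_series(areas, spacing = h)
  attr(out, "true_volume") <- true_volume
  out
}
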