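#' Contour pair for gyrification measurements
#'
#' Bundles the full (folded) cortical contour with its outer envelope.
#' [gyrification_index()] takes the ratio of their lengths; when the outer
#' contour is `NULL` it is constructed as the convex hull of the full
#' contour.
#'
#' @param full Closed polyline, an n x 2 numeric matrix (columns x, y).
#' @param outer Closed polyline for the outer envelope, or `NULL`.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(full, outer = NULL) {
  full <- as.matrix(full)
  if (ncol(full) != 2L || nrow(full) < 3L) {
    stop("`full` must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  full <- close_polyline(full)
  if (!is.null(outer)) {
    outer <- as.matrix(outer)
    if (ncol(outer) != 2L || nrow(outer) < 3L) {
      stop("`outer` must be an n x 2 matrix with n >= 3", call. = FALSE)
    }
    outer <- close_polyline(outer)
  }
  structure(list(full = full, outer = outer), class = "contour_set")
}

#' Synthetic folded cortical contour with ground-truth lengths
#'
#' Generates a closed contour in polar form `r(theta) = R + a * sin(k *
#' theta)`, a controllable stand-in for a folded (gyrencephalic) cortical
#' outline, together with its outer envelope (the circumscribing circle of
#' radius `R + a` that touches every fold crest). Ground-truth arc lengths
#' of both curves, computed by dense numeric quadrature of
#' `sqrt(r^2 + r'^2)`, are attached so downstream gyrification estimates
#' can be checked against an analytic reference. With `fold_amplitude =
#' 0` the contour is a circle, the envelope coincides with it, and the
#' ground-truth gyrification index is exactly 1.
#'
#' @param base_radius Mean radius R (length units; > 0).
#' @param fold_amplitude Fold amplitude a, with `0 <= a < R` (an amplitude
#'   reaching or exceeding the base radius would drive the radius to zero
#'   or negative values and the curve would self-intersect; such
#'   combinations are rejected).
#' @param fold_frequency Integer number of folds k (>= 0).
#' @param n_points Number of contour vertices (>= 64).
#' @param quadrature_points Number of abscissae used for the ground-truth
#'   arc-length quadrature.
#' @return A [contour_set()] with attributes `true_full_length`,
#'   `true_outer_length` and `true_gi` (their ratio).
#' @examples
#' cs <- generate_contour(10, 2, fold_frequency = 8, n_points = 512)
#' attr(cs, "true_gi")
#' gyrification_index(cs)
#' @export
generate_contour <- function(base_radius, fold_amplitude, fold_frequency,
                             n_points = 512L, quadrature_points = 20000L) {
  stop_if_not_scalar_number(base_radius, "base_radius", positive = TRUE)
  stop_if_not_scalar_number(fold_amplitude, "fold_amplitude")
  if (fold_amplitude < 0 || fold_amplitude >= base_radius) {
    stop("`fold_amplitude` must satisfy 0 <= a < base_radius ",
         "(otherwise the contour self-intersects)", call. = FALSE)
  }
  if (!is.numeric(fold_frequency) || fold_frequency < 0 ||
      fold_frequency != round(fold_frequency)) {
    stop("`fold_frequency` must be a non-negative integer", call. = FALSE)
  }
  if (n_points < 64L) stop("`n_points` must be >= 64", call. = FALSE)

  R <- base_radius; a <- fold_amplitude; k <- fold_frequency
  # with no folds the curve is the circle of radius R and is its own envelope
  r_out <- if (k == 0) R else R + a

  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  r <- R + a * sin(k * theta)
  full <- cbind(x = r * cos(theta), y = r * sin(theta))
  outer <- cbind(x = r_out * cos(theta), y = r_out * sin(theta))

  # dense trapezoidal quadrature of the exact arc-length integrand
  tq <- seq(0, 2 * pi, length.out = quadrature_points + 1L)
  rq <- R + a * sin(k * tq)
  drq <- a * k * cos(k * tq)
  integrand <- sqrt(rq^2 + drq^2)
  w <- rep(2 * pi / quadrature_points, quadrature_points + 1L)
  w[c(1L, quadrature_points + 1L)] <- w[1L] / 2
  true_full <- sum(integrand * w)
  true_outer <- 2 * pi * r_out

  out <- contour_set(full, outer)
  attr(out, "true_full_length") <- true_full
  attr(out, "true_outer_length") <- true_outer
  attr(out, "true_gi") <- true_full / true_outer
  out
}
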