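#' Per-type, per-gene probe expression model
#'
#' Describes how synthetic multiplexed-FISH probe channels are generated:
#' inside a cell's region of interest (ROI, a disk around the centroid)
#' each pixel is probe-positive independently with the probability given
#' for that cell's type and the gene; pixels outside every ROI are
#' positive at the background speckle rate. This emulates area-based smFISH
#' signal where a cell's expression is read out as the fraction of its ROI
#' covered by probe signal.
#'
#' @param prob Numeric matrix of probe-pixel probabilities in \[0, 1\],
#'   rows = cell types, columns = genes, with dimnames.
#' @param speckle_rate Background positive-pixel rate in \[0, 1\].
#' @param roi_radius ROI disk radius in pixels (> 0).
#' @param intensity Pixel value written for positive pixels (default 255,
#'   an 8-bit-style image; negative pixels are 0).
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(prob, speckle_rate = 0, roi_radius = 4,
                             intensity = 255) {
  prob <- as.matrix(prob)
  if (is.null(rownames(prob)) || is.null(colnames(prob))) {
    stop("`prob` needs type rownames and gene colnames", call. = FALSE)
  }
  if (any(prob < 0 | prob > 1)) {
    stop("probe probabilities must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(speckle_rate, "speckle_rate")
  if (speckle_rate < 0 || speckle_rate > 1) {
    stop("`speckle_rate` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(roi_radius, "roi_radius", positive = TRUE)
  structure(
    list(prob = prob, speckle_rate = speckle_rate,
         roi_radius = roi_radius, intensity = intensity),
    class = "expression_model"
  )
}

# Pixel indices (0-based x, y) of the disk of radius r around (cx, cy).
# Pixel centers sit at integer coordinates.
disk_pixels <- function(cx, cy, r) {
  ix <- seq.int(floor(cx - r), ceiling(cx + r))
  iy <- seq.int(floor(cy - r), ceiling(cy + r))
  g <- expand.grid(x = ix, y = iy)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  g[keep, , drop = FALSE]
}

# Partition image pixels into cell ROIs: disk of `radius` per centroid,
# overlaps resolved by nearest centroid (ties to the lower cell id).
# Returns an integer label matrix (rows = y, cols = x, 0 = background).
roi_label_image <- function(cells, radius, image_size) {
  w <- image_size[1]; h <- image_size[2]
  px <- integer(0); py <- integer(0); owner <- integer(0); d2 <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    d <- disk_pixels(cells$x[i], cells$y[i], radius)
    if (any(d$x < 0 | d$x >= w | d$y < 0 | d$y >= h)) {
      stop(sprintf("ROI of cell %s does not fit inside the %g x %g image",
                   cells$cell_id[i], w, h), call. = FALSE)
    }
    px <- c(px, d$x); py <- c(py, d$y)
    owner <- c(owner, rep(i, nrow(d)))
    d2 <- c(d2, (d$x - cells$x[i])^2 + (d$y - cells$y[i])^2)
  }
  lin <- py * w + px
  ord <- order(lin, d2, owner)
  first <- !duplicated(lin[ord])
  lab <- matrix(0L, nrow = h, ncol = w)
  lab[cbind(py[ord][first] + 1L, px[ord][first] + 1L)] <-
    cells$cell_id[owner[ord][first]]
  lab
}

#' Generate synthetic probe channel images with planted expression
#'
#' Builds, for every gene in the model, a probe channel image over the
#' cell map: cell ROIs are disks of `roi_radius` around the centroids
#' (overlapping disks are split by nearest centroid so the ROIs partition
#' their union), each ROI pixel is positive with the (cell type, gene)
#' probability, and background pixels are positive at the speckle rate.
#' The returned ground-truth table records each cell's realized
#' positive-pixel percentage per gene, which the quantification pipeline
#' must reproduce exactly when speckle and the component-size filter are
#' off.
#'
#' @param cells A `cell_map` (see [generate_cell_map()]); all cell types
#'   must appear in the model's probability matrix.
#' @param model An [expression_model()].
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return An object of class `probe_set`: a list with elements
#'   \describe{
#'     \item{`probes`}{named list of gene channel matrices (rows = y,
#'       columns = x; positive pixels at `model$intensity`, others 0).}
#'     \item{`roi`}{integer ROI label matrix (0 = background, otherwise
#'       `cell_id`).}
#'     \item{`truth`}{cells x genes matrix of realized positive-pixel
#'       percentages in \[0, 100\], rownames = cell ids.}
#'     \item{`cells`}{the input cell map.}
#'   }
#' @export
generate_probe_images <- function(cells, model, seed) {
  stopifnot(inherits(cells, "cell_map"), inherits(model, "expression_model"))
  genes <- colnames(model$prob)
  missing_types <- setdiff(unique(cells$type), rownames(model$prob))
  if (length(missing_types) > 0L) {
    stop("cell types absent from the expression model: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  sz <- attr(cells, "image_size")
  w <- sz[1]; h <- sz[2]

  roi <- roi_label_image(cells, model$roi_radius, c(w, h))
  roi_idx <- lapply(cells$cell_id, function(id) which(roi == id))
  roi_size <- lengths(roi_idx)
  if (any(roi_size == 0L)) {
    stop("a cell ROI was completely covered by its neighbors; ",
         "reduce density or roi_radius", call. = FALSE)
  }
  bg_idx <- which(roi == 0L)

  n_cells <- nrow(cells)
  truth <- matrix(
    0, n_cells, length(genes),
    dimnames = list(as.character(cells$cell_id), genes)
  )
  probes <- with_seed(seed, {
    lapply(stats::setNames(genes, genes), function(g) {
      img <- matrix(0, nrow = h, ncol = w)
      for (i in seq_len(n_cells)) {
        p <- model$prob[cells$type[i], g]
        pos <- stats::runif(roi_size[i]) < p
        img[roi_idx[[i]][pos]] <- model$intensity
        truth[i, g] <<- 100 * sum(pos) / roi_size[i]
      }
      if (model$speckle_rate > 0 && length(bg_idx) > 0L) {
        sp <- stats::runif(length(bg_idx)) < model$speckle_rate
        img[bg_idx[sp]] <- model$intensity
      }
      img
    })
  })
  structure(
    list(probes = probes, roi = roi, truth = truth, cells = cells),
    class = "probe_set"
  )
}

#' Labeled rectangular region masks with exact pixel counts
#'
#' Packs non-overlapping labeled regions with exactly the requested pixel
#' counts into an image, for testing area-ratio and tier computations
#' against known ground truth. Regions are laid out as contiguous
#' row-major runs (a full-width rectangle plus a partial final row when
#' the count is not a multiple of the width).
#'
#' @param areas Integer vector of requested pixel counts (> 0), one per
#'   region; region `i` receives label `i`.
#' @param image_size Integer vector `c(width, height)`.
#' @return Integer label matrix (rows = y, columns = x; 0 = unassigned).
#' @examples
#' m <- generate_region_masks(c(500, 9500), c(100, 100))
#' table(m)
#' @export
generate_region_masks <- function(areas, image_size) {
  areas <- as.integer(areas)
  if (length(areas) == 0L || any(areas <= 0)) {
    stop("`areas` must be positive pixel counts", call. = FALSE)
  }
  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  if (sum(areas) > w * h) {
    stop("requested areas exceed the image area; packing infeasible",
         call. = FALSE)
  }
  # row-major fill: matrix is indexed [y, x], transpose trick keeps runs
  # contiguous in reading order
  flat <- integer(w * h)
  pos <- 1L
  for (i in seq_along(areas)) {
    flat[pos:(pos + areas[i] - 1L)] <- i
    pos <- pos + areas[i]
  }
  t(matrix(flat, nrow = w, ncol = h))
}
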