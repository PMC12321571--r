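#' Construct a cell-by-gene expression matrix object
#'
#' Thin wrapper around a numeric cells x genes matrix that records the
#' processing stage of pixel-percentage expression values: `raw`
#' (straight from quantification, values in \[0, 100\]), `median_zeroed`
#' (per-gene background zeroing applied) or `normalized`.
#'
#' @param values Numeric matrix, rows = cells, columns = genes, with
#'   dimnames.
#' @param stage One of `"raw"`, `"median_zeroed"`, `"normalized"`.
#' @return The matrix with class `expr_matrix` and attribute `stage`.
#' @export
expression_matrix <- function(values,
                              stage = c("raw", "median_zeroed", "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs cell rownames and gene colnames",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated gene names", call. = FALSE)
  }
  if (stage != "normalized" && (any(values < 0) || any(values > 100))) {
    stop("pixel-percentage values must lie in [0, 100]", call. = FALSE)
  }
  attr(values, "stage") <- stage
  class(values) <- c("expr_matrix", class(values))
  values
}

expr_stage <- function(x) attr(x, "stage") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel-percentage expression of one cell
#'
#' The per-cell expression readout for area-based multiplexed FISH: the
#' percentage of the cell's ROI pixels covered by thresholded probe
#' signal,
#' `100 * |probe AND roi| / |roi|`.
#'
#' @param probe_mask Logical (or 0/1) matrix of probe-positive pixels.
#' @param roi_mask Logical (or 0/1) matrix marking the cell's ROI; must be
#'   non-empty and the same size as `probe_mask`.
#' @return Numeric scalar in \[0, 100\].
#' @examples
#' roi <- matrix(FALSE, 10, 10); roi[1:10, 1:10] <- TRUE
#' probe <- matrix(FALSE, 10, 10); probe[1:3, 1:10] <- TRUE
#' quantify_cell(probe, roi)  # 30
#' @export
quantify_cell <- function(probe_mask, roi_mask) {
  if (!identical(dim(probe_mask), dim(roi_mask))) {
    stop("`probe_mask` and `roi_mask` must have identical dimensions",
         call. = FALSE)
  }
  roi <- roi_mask != 0
  n_roi <- sum(roi)
  if (n_roi == 0L) stop("empty ROI", call. = FALSE)
  100 * sum(probe_mask != 0 & roi) / n_roi
}

#' Build a raw cell-by-gene expression matrix from probe channels
#'
#' Runs the per-channel quantification pipeline: each gene's probe image
#' is binarized with [renyi_threshold()], connected foreground components
#' smaller than `min_object_px` pixels are removed (an automated stand-in
#' for manual curation of spurious speckle), and each cell's
#' pixel-percentage expression is computed over its ROI with
#' [quantify_cell()].
#'
#' A channel with a single constant intensity carries no separable signal
#' and quantifies to 0 for every cell.
#'
#' @param probes A `probe_set` from [generate_probe_images()], or a named
#'   list of gene channel matrices.
#' @param roi Integer ROI label matrix (0 = background, positive labels =
#'   cell ids); taken from `probes` when a `probe_set` is given.
#' @param min_object_px Minimum connected-component size (4-connectivity)
#'   kept as foreground, in pixels; 0 disables the filter.
#' @param alpha_set Entropy orders passed to [renyi_threshold()].
#' @return An [expression_matrix()] at stage `"raw"`, one row per ROI
#'   label (rownames = labels), one column per gene.
#' @export
build_expression_matrix <- function(probes, roi = NULL, min_object_px = 0,
                                    alpha_set = c(0.5, 1, 2)) {
  if (inherits(probes, "probe_set")) {
    if (is.null(roi)) roi <- probes$roi
    probes <- probes$probes
  }
  if (is.null(roi)) stop("`roi` label image is required", call. = FALSE)
  genes <- names(probes)
  if (is.null(genes) || any(!nzchar(genes))) {
    stop("probe channels must be named by gene", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicated gene names", call. = FALSE)
  labels <- sort(unique(roi[roi > 0]))
  if (length(labels) == 0L) {
    stop("ROI label image contains no positive labels", call. = FALSE)
  }
  roi_idx <- lapply(labels, function(id) which(roi == id))
  roi_size <- lengths(roi_idx)

  values <- matrix(
    0, length(labels), length(genes),
    dimnames = list(as.character(labels), genes)
  )
  for (g in genes) {
    img <- probes[[g]]
    if (!identical(dim(img), dim(roi))) {
      stop("channel '", g, "' and ROI image differ in size", call. = FALSE)
    }
    if (length(unique(as.numeric(img))) < 2L) next  # constant: no signal
    thr <- renyi_threshold(img, alpha_set = alpha_set)
    mask <- img > thr
    if (min_object_px > 0) {
      mask <- drop_small_components(mask, min_object_px)
    }
    for (i in seq_along(labels)) {
      values[i, g] <- 100 * sum(mask[roi_idx[[i]]]) / roi_size[i]
    }
  }
  expression_matrix(values, stage = "raw")
}

# Remove 4-connected foreground components smaller than min_px pixels.
drop_small_components <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.integer(round(as.numeric(lab)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep & lab > 0, nrow = nrow(mask))
  out
}

#' Zero per-gene background expression at the median
#'
#' Applies the background rule used for area-based FISH matrices: for each
#' gene, only cells whose raw pixel-percentage value is strictly greater
#' than that gene's median (computed over all cells, zeros included) are
#' considered to truly express it; all other entries are set to 0. An
#' all-zero gene passes through unchanged (its median is 0 and nothing
#' exceeds it).
#'
#' Note this is a single-pass rule: re-applying it to its own output can
#' zero further entries because the medians change.
#'
#' @param matrix An [expression_matrix()] at stage `"raw"`.
#' @return The matrix with sub-median entries zeroed, at stage
#'   `"median_zeroed"`.
#' @examples
#' m <- expression_matrix(matrix(c(0, 10, 20, 30, 40), 5, 1,
#'   dimnames = list(1:5, "G")))
#' median_zero(m)[, 1]  # 0 0 0 30 40
#' @export
median_zero <- function(matrix) {
  if (expr_stage(matrix) != "raw") {
    stop("`median_zero()` expects a raw expression matrix", call. = FALSE)
  }
  med <- apply(matrix, 2L, stats::median)
  out <- unclass(matrix)
  out[sweep(out, 2L, med, `<=`)] <- 0
  expression_matrix(out, stage = "median_zeroed")
}
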