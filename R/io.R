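# Plain-text and TIFF interchange for the pipeline's containers.

#' Read or write a cell map as CSV
#'
#' The on-disk cell map is a CSV with columns `cell_id`, `image_id`, `x`,
#' `y`, `type` (pixel coordinates, 0-based, origin top-left).
#'
#' @param cells A `cell_map` or compatible data frame.
#' @param path File path.
#' @param image_size Optional `c(width, height)` restored as the map
#'   attribute when reading.
#' @return `read_cell_map()` returns a `cell_map`; `write_cell_map()`
#'   returns `path` invisibly.
#' @export
write_cell_map <- function(cells, path) {
  utils::write.csv(
    as.data.frame(cells)[, c("cell_id", "image_id", "x", "y", "type")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_cell_map
#' @export
read_cell_map <- function(path, image_size = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "image_id", "x", "y", "type")
  if (!all(need %in% names(df))) {
    stop("cell map CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(image_size)) attr(df, "image_size") <- image_size
  class(df) <- c("cell_map", "data.frame")
  df
}

#' Read or write a section-area series as CSV
#'
#' Columns: `section`, `area`, `spacing` (spacing repeated per row; the
#' last row's spacing is ignored when per-gap spacings are used).
#'
#' @param series A [section_series()].
#' @param path File path.
#' @return `read_section_series()` returns a [section_series()];
#'   `write_section_series()` returns `path` invisibly.
#' @export
write_section_series <- function(series, path) {
  h <- attr(series, "spacing")
  n <- nrow(series)
  if (length(h) == 1L) h <- rep(h, n - 1L)
  utils::write.csv(
    data.frame(section = series$section, area = series$area,
               spacing = c(h, NA)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_section_series
#' @export
read_section_series <- function(path) {
  df <- utils::read.csv(path)
  h <- df$spacing[-nrow(df)]
  if (length(unique(h)) == 1L) h <- h[1]
  section_series(df$area, spacing = h)
}

#' Read or write a contour set as CSV
#'
#' Long format with columns `contour` (`"full"` or `"outer"`), `x`, `y`,
#' vertices in drawing order.
#'
#' @param contours A [contour_set()].
#' @param path File path.
#' @return `read_contour_set()` returns a [contour_set()];
#'   `write_contour_set()` returns `path` invisibly.
#' @export
write_contour_set <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  rows <- data.frame(contour = "full",
                     x = contours$full[, 1], y = contours$full[, 2])
  if (!is.null(contours$outer)) {
    rows <- rbind(rows, data.frame(contour = "outer",
                                   x = contours$outer[, 1],
                                   y = contours$outer[, 2]))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_set
#' @export
read_contour_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  full <- as.matrix(df[df$contour == "full", c("x", "y")])
  outer <- if (any(df$contour == "outer")) {
    as.matrix(df[df$contour == "outer", c("x", "y")])
  }
  contour_set(full, outer)
}

#' Write or read a probe set as multi-page TIFF
#'
#' The probe channels are written as one multi-page TIFF (one page per
#' gene, in manifest order, intensities rescaled to \[0, 1\] as the TIFF
#' format requires) and the ROI labels as a separate single-page TIFF.
#' A gene manifest CSV (`gene`, `page`) accompanies the stack.
#'
#' @param probes A `probe_set` from [generate_probe_images()].
#' @param stack_path,roi_path,manifest_path Output file paths.
#' @param max_intensity Intensity mapped to TIFF white (default 255).
#' @return `read_probe_stack()` returns a list with `probes` (named list
#'   of matrices on the original intensity scale) and `roi`.
#' @export
write_probe_stack <- function(probes, stack_path, roi_path, manifest_path,
                              max_intensity = 255) {
  stopifnot(inherits(probes, "probe_set"))
  pages <- lapply(probes$probes, function(m) m / max_intensity)
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 8L)
  # labels stored in a 16-bit page to keep integer ids exact
  tiff::writeTIFF(probes$roi / 65535, roi_path, bits.per.sample = 16L)
  utils::write.csv(
    data.frame(gene = names(probes$probes),
               page = seq_along(probes$probes)),
    manifest_path, row.names = FALSE
  )
  invisible(stack_path)
}

#' @rdname write_probe_stack
#' @export
read_probe_stack <- function(stack_path, roi_path, manifest_path,
                             max_intensity = 255) {
  pages <- tiff::readTIFF(stack_path, all = TRUE)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (length(pages) != nrow(manifest)) {
    stop("manifest and TIFF stack disagree on the number of pages",
         call. = FALSE)
  }
  probes <- stats::setNames(
    lapply(pages[manifest$page], function(m) round(m * max_intensity)),
    manifest$gene
  )
  roi <- round(tiff::readTIFF(roi_path) * 65535)
  list(probes = probes, roi = roi)
}
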