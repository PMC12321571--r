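#' Spatial interaction specification for synthetic cell maps
#'
#' Declares, for a synthetic image, how cell positions relate to cell-type
#' labels: complete spatial randomness (`csr`, the calibration null of the
#' neighborhood permutation test) or planted homotypic attraction
#' (`attract`), in which the cells of one or more types are placed by a
#' Neyman-Scott (Thomas) parent-offspring process so that they clump.
#'
#' @param mode `"csr"` or `"attract"`.
#' @param attract_types Character vector of type names placed by the
#'   clustered process (required when `mode = "attract"`).
#' @param cluster_sd Gaussian dispersion of offspring around their parent,
#'   in pixels (> 0).
#' @param mean_offspring Expected number of cells per parent cluster
#'   (> 0); the number of parents is the type's cell count divided by
#'   this, rounded up.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(mode = c("csr", "attract"),
                             attract_types = character(),
                             cluster_sd = 2,
                             mean_offspring = 8) {
  mode <- match.arg(mode)
  if (mode == "attract") {
    if (length(attract_types) == 0L) {
      stop("`attract` mode requires at least one entry in `attract_types`",
           call. = FALSE)
    }
    stop_if_not_scalar_number(cluster_sd, "cluster_sd", positive = TRUE)
    stop_if_not_scalar_number(mean_offspring, "mean_offspring", positive = TRUE)
  }
  structure(
    list(mode = mode, attract_types = attract_types,
         cluster_sd = cluster_sd, mean_offspring = mean_offspring),
    class = "interaction_spec"
  )
}

#' Generate a synthetic 2-D cell map
#'
#' Places `n_cells` cell centroids in an image and assigns each a type
#' label, providing ground truth for the neighborhood interaction
#' analysis. Under `csr` all cells are placed uniformly at random and
#' labels are drawn independently from `type_proportions` (so labels are
#' exchangeable over positions, the null of the permutation test). Under
#' `attract`, the cells of each attracted type are instead placed around
#' uniformly scattered parent points with isotropic Gaussian dispersion
#' `cluster_sd`, planting homotypic spatial attraction; all other cells
#' remain uniform. In both modes each cell's label is drawn independently
#' from `type_proportions` (multinomial composition), so type counts vary
#' binomially around their expectations.
#'
#' Coordinates are continuous, 0-based pixel units with the origin at the
#' top-left corner and y increasing downward; generated positions lie in
#' `[0, width) x [0, height)`.
#'
#' @param n_cells Number of cells (> 0).
#' @param type_proportions Named numeric vector of type proportions
#'   summing to 1; names are the type labels.
#' @param interaction An [interaction_spec()].
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param seed Integer seed; the map is a pure function of the arguments.
#' @param image_id Identifier stored in the `image_id` column.
#' @param margin Keep all centroids at least this many pixels away from
#'   every image border (so that cell ROIs of that radius fit inside the
#'   image); default 0.
#' @return A `cell_map`: a data frame with columns `cell_id`, `image_id`,
#'   `x`, `y`, `type`, with `image_size` and the interaction mode stored
#'   as attributes.
#' @examples
#' cm <- generate_cell_map(100, c(A = 0.5, B = 0.5),
#'                         interaction_spec("csr"),
#'                         image_size = c(64, 64), seed = 1)
#' table(cm$type)
#' @export
generate_cell_map <- function(n_cells, type_proportions, interaction,
                              image_size = c(64L, 64L), seed,
                              image_id = "img1", margin = 0) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop("`n_cells` must be a positive count", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (is.null(names(type_proportions)) ||
      any(!nzchar(names(type_proportions)))) {
    stop("`type_proportions` must be a named vector", call. = FALSE)
  }
  if (abs(sum(type_proportions) - 1) > 1e-8 || any(type_proportions < 0)) {
    stop("`type_proportions` must be non-negative and sum to 1",
         call. = FALSE)
  }
  stopifnot(inherits(interaction, "interaction_spec"))
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(image_size <= 0)) {
    stop("`image_size` must be positive c(width, height)", call. = FALSE)
  }
  w <- image_size[1]; h <- image_size[2]
  stop_if_not_scalar_number(margin, "margin")
  if (margin < 0 || 2 * margin >= min(w, h)) {
    stop("`margin` must be non-negative and leave room inside the image",
         call. = FALSE)
  }
  lo_x <- margin; hi_x <- w - margin
  lo_y <- margin; hi_y <- h - margin

  with_seed(seed, {
    types <- sample(names(type_proportions), n_cells, replace = TRUE,
                    prob = type_proportions)
    if (interaction$mode == "csr") {
      # uniform positions; labels independent of positions
      x <- runif(n_cells, lo_x, hi_x)
      y <- runif(n_cells, lo_y, hi_y)
    } else {
      x <- numeric(n_cells); y <- numeric(n_cells)
      clustered <- types %in% interaction$attract_types
      n_free <- sum(!clustered)
      x[!clustered] <- runif(n_free, lo_x, hi_x)
      y[!clustered] <- runif(n_free, lo_y, hi_y)
      for (tp in intersect(unique(types), interaction$attract_types)) {
        idx <- which(types == tp)
        nt <- length(idx)
        n_parents <- max(1L, ceiling(nt / interaction$mean_offspring))
        px <- runif(n_parents, lo_x, hi_x)
        py <- runif(n_parents, lo_y, hi_y)
        parent <- sample.int(n_parents, nt, replace = TRUE)
        ox <- px[parent] + rnorm(nt, 0, interaction$cluster_sd)
        oy <- py[parent] + rnorm(nt, 0, interaction$cluster_sd)
        # reflect stray offspring back into the allowed region
        x[idx] <- lo_x + reflect_into(ox - lo_x, hi_x - lo_x)
        y[idx] <- lo_y + reflect_into(oy - lo_y, hi_y - lo_y)
      }
      # shuffle storage order so cell_id carries no type information
      ord <- sample.int(n_cells)
      x <- x[ord]; y <- y[ord]; types <- types[ord]
    }
    out <- data.frame(
      cell_id = seq_len(n_cells),
      image_id = image_id,
      x = x, y = y,
      type = types,
      stringsAsFactors = FALSE
    )
    attr(out, "image_size") <- c(width = w, height = h)
    attr(out, "interaction_mode") <- interaction$mode
    class(out) <- c("cell_map", "data.frame")
    out
  })
}

# Reflect coordinates into [0, limit) (mirror at the borders).
reflect_into <- function(v, limit) {
  v <- v %% (2 * limit)
  v <- ifelse(v < 0, v + 2 * limit, v)
  ifelse(v >= limit, 2 * limit - v - 1e-9, v)
}

#' @export
print.cell_map <- function(x, ...) {
  sz <- attr(x, "image_size")
  cat(sprintf("cell_map: %d cells, %d type(s), image %g x %g px\n",
              nrow(x), length(unique(x$type)), sz[1], sz[2]))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
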