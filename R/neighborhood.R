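#' Build the within-image cell neighbor graph
#'
#' Two cells are neighbors when the Euclidean distance between their
#' centroids is strictly less than `distance_threshold` pixels (default 4,
#' the conventional contact distance for confocal cell maps). The graph is
#' undirected, simple, and has a node for every cell including isolated
#' ones.
#'
#' @param cells A `cell_map` (or data frame with columns `cell_id`,
#'   `image_id`, `x`, `y`); all rows must share one `image_id`.
#' @param distance_threshold Neighbor distance in pixels (> 0).
#' @return An object of class `neighbor_graph`: list with `cell_id`,
#'   `edges` (two-column matrix of cell indices, i < j), `image_id`,
#'   `distance_threshold` and `n`.
#' @export
build_neighbor_graph <- function(cells, distance_threshold = 4) {
  stop_if_not_scalar_number(distance_threshold, "distance_threshold",
                            positive = TRUE)
  if (length(unique(cells$image_id)) != 1L) {
    stop("all cells must come from one image; split by image_id first",
         call. = FALSE)
  }
  n <- nrow(cells)
  edges <- base::matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
    hit <- which(upper.tri(d) & d < distance_threshold, arr.ind = TRUE)
    edges <- unname(hit[, c("row", "col"), drop = FALSE])
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(
    list(
      cell_id = cells$cell_id,
      edges = edges,
      image_id = cells$image_id[1],
      distance_threshold = distance_threshold,
      n = n
    ),
    class = "neighbor_graph"
  )
}

# Directed endpoint vectors (both orientations of each undirected edge),
# used for fast neighbor tallies.
directed_edges <- function(graph) {
  e <- graph$edges
  list(from = c(e[, 1], e[, 2]), to = c(e[, 2], e[, 1]))
}

#' Observed neighborhood interaction statistic
#'
#' For an ordered type pair (A, B), the statistic is the mean number of
#' B-type neighbors per A-type cell (isolated A cells contribute 0;
#' A = B counts homotypic contacts). When no A cell is present the pair is
#' not testable in this image and `NA` is returned.
#'
#' @param graph A [build_neighbor_graph()] result.
#' @param labels Character vector of cell types, one per graph node.
#' @param pair Length-2 character vector `c(A, B)`; both names must be
#'   known types (i.e. occur somewhere in the study's type set given by
#'   `types`).
#' @param types Optional character vector of valid type names; defaults to
#'   the types present in `labels`.
#' @return Numeric scalar, or `NA_real_` when type A is absent.
#' @export
interaction_statistic <- function(graph, labels, pair, types = unique(labels)) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (length(labels) != graph$n) {
    stop("`labels` must have one entry per graph node", call. = FALSE)
  }
  if (length(pair) != 2L || !all(pair %in% types)) {
    stop("`pair` must name two known cell types", call. = FALSE)
  }
  n_a <- sum(labels == pair[1])
  if (n_a == 0L) return(NA_real_)
  de <- directed_edges(graph)
  contacts <- sum(labels[de$from] == pair[1] & labels[de$to] == pair[2])
  contacts / n_a
}

#' Permutation test for neighborhood enrichment of a type pair
#'
#' Tests whether cells of type A have more type-B neighbors than expected
#' if type labels were assigned at random within the image. The neighbor
#' graph stays fixed; the observed label vector is permuted over node
#' positions `n_permutations` times (fixed label composition, the
#' exchangeable null) and the statistic recomputed each time. The
#' one-tailed p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)` for
#' enrichment (`<=` for the avoidance tail), so p is never 0 and is valid
#' under exchangeability.
#'
#' If either type of the pair is absent from the image the pair is marked
#' not present and no test is run.
#'
#' @inheritParams interaction_statistic
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @param tail `"enrichment"` (default) or `"avoidance"`.
#' @return A one-row data frame of class `interaction_result`: `image_id`,
#'   `type_a`, `type_b`, `present`, `observed`, `null_mean`, `null_sd`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_test <- function(graph, labels, pair, n_permutations = 1000,
                             seed, tail = c("enrichment", "avoidance"),
                             types = unique(labels)) {
  tail <- match.arg(tail)
  if (n_permutations < 1) {
    stop("`n_permutations` must be at least 1", call. = FALSE)
  }
  res <- data.frame(
    image_id = graph$image_id,
    type_a = pair[1], type_b = pair[2],
    present = all(pair %in% labels),
    observed = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
    p_value = NA_real_, n_permutations = as.integer(n_permutations),
    stringsAsFactors = FALSE
  )
  class(res) <- c("interaction_result", "data.frame")
  if (!res$present) return(res)

  de <- directed_edges(graph)
  # integer-coded labels for a fast permutation loop
  lev <- unique(c(pair, labels))
  code <- match(labels, lev)
  a <- match(pair[1], lev); b <- match(pair[2], lev)
  n_a <- sum(code == a)
  stat_of <- function(cd) {
    sum(cd[de$from] == a & cd[de$to] == b) / n_a
  }
  observed <- stat_of(code)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat_of(code[sample.int(length(code))]),
           numeric(1))
  })
  extreme <- if (tail == "enrichment") sum(null >= observed)
             else sum(null <= observed)
  res$observed <- observed
  res$null_mean <- mean(null)
  res$null_sd <- stats::sd(null)
  res$p_value <- (1 + extreme) / (1 + n_permutations)
  res
}

#' Test all ordered type pairs in every image
#'
#' Convenience driver: splits a multi-image cell map by `image_id`, builds
#' each image's neighbor graph, and runs [permutation_test()] for every
#' ordered pair of the study's types.
#'
#' @param cells A `cell_map` possibly spanning several images.
#' @param types Character vector of the type set to test; defaults to all
#'   types observed anywhere in `cells`.
#' @param distance_threshold Neighbor distance in pixels.
#' @param n_permutations Permutations per test.
#' @param seed Integer seed; each image/pair test gets a sub-seed derived
#'   from it.
#' @param tail Passed to [permutation_test()].
#' @return Data frame of stacked [permutation_test()] rows.
#' @export
test_all_pairs <- function(cells, types = sort(unique(cells$type)),
                           distance_threshold = 4, n_permutations = 1000,
                           seed, tail = "enrichment") {
  pieces <- split(as.data.frame(cells), cells$image_id)
  pairs <- expand.grid(a = types, b = types, stringsAsFactors = FALSE)
  out <- vector("list", length(pieces) * nrow(pairs))
  idx <- 1L
  for (i in seq_along(pieces)) {
    img <- pieces[[i]]
    graph <- build_neighbor_graph(img, distance_threshold)
    for (j in seq_len(nrow(pairs))) {
      out[[idx]] <- permutation_test(
        graph, img$type, c(pairs$a[j], pairs$b[j]),
        n_permutations = n_permutations,
        seed = (seed + 7919L * i + j) %% .Machine$integer.max,
        tail = tail, types = types
      )
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Aggregate per-image interaction tests across images
#'
#' Applies the cross-image visualization rule: an ordered type pair is
#' kept when it is significant (p < `alpha`) in at least `sig_frac` of all
#' images and simultaneously present in at least `presence_frac` of all
#' images. Both fractions are computed over all images and compared with
#' `>=`.
#'
#' @param results Data frame of [permutation_test()] rows covering one or
#'   more images (all images must appear for every pair).
#' @param alpha Per-image significance level (default 0.05).
#' @param sig_frac Minimum fraction of images significant (default 0.30).
#' @param presence_frac Minimum fraction of images where the pair is
#'   present (default 0.90).
#' @return Data frame with one row per ordered pair: `type_a`, `type_b`,
#'   `n_images`, `frac_significant`, `frac_present`, `mean_observed`,
#'   `keep`.
#' @export
aggregate_images <- function(results, alpha = 0.05, sig_frac = 0.30,
                             presence_frac = 0.90) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("`results` must contain at least one image", call. = FALSE)
  }
  key <- interaction(results$type_a, results$type_b, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(r) {
    n_img <- length(unique(r$image_id))
    sig <- !is.na(r$p_value) & r$p_value < alpha
    data.frame(
      type_a = r$type_a[1], type_b = r$type_b[1],
      n_images = n_img,
      frac_significant = sum(sig) / n_img,
      frac_present = sum(r$present) / n_img,
      mean_observed = mean(r$observed[r$present], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  out$keep <- out$frac_significant >= sig_frac &
    out$frac_present >= presence_frac
  rownames(out) <- NULL
  out
}
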