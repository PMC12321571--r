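#' Normalize, cluster and embed an expression matrix
#'
#' The standard downstream of the pixel-percentage matrix: `log(1 + x)`
#' transform, per-gene standardization, principal component analysis with
#' all components retained, a k-nearest-neighbor graph on the full PC
#' space, Leiden community detection at the given resolution, and a 2-D
#' embedding for visualization.
#'
#' The default embedding is the first two principal components, which is
#' fully deterministic; `embedding = "umap"` computes a UMAP layout via
#' the \pkg{uwot} package when it is installed. Cluster labels do not
#' depend on the embedding choice.
#'
#' @param matrix An [expression_matrix()], normally at stage
#'   `"median_zeroed"`.
#' @param resolution Leiden resolution parameter (modularity objective);
#'   default 1.
#' @param k Number of nearest neighbors for the graph; default 20.
#' @param seed Integer seed; labels and embedding are reproducible.
#' @param embedding `"pca"` (default) or `"umap"`.
#' @return An object of class `cluster_result`: list with `cluster`
#'   (integer vector named by cell), `embedding` (cells x 2 matrix),
#'   `pcs` (all principal component scores), `resolution`, `k`, `seed`.
#' @export
normalize_cluster_embed <- function(matrix, resolution = 1, k = 20, seed,
                                    embedding = c("pca", "umap")) {
  embedding <- match.arg(embedding)
  if (expr_stage(matrix) == "raw") {
    warning("clustering a raw matrix; median_zero() is normally applied first")
  }
  x <- unclass(matrix)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 cells to cluster", call. = FALSE)
  if (k >= n) {
    stop(sprintf(
      "k = %d nearest neighbors requires more than %d cells; reduce `k`",
      k, n), call. = FALSE)
  }

  z <- scale_log_expression(x)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pcs <- pca$x                       # all components retained

  # union-symmetrized unweighted kNN graph on the full PC space
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)

  cl <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 10
  ))
  membership <- as.integer(igraph::membership(cl))

  emb <- if (embedding == "pca") {
    if (ncol(pcs) >= 2L) pcs[, 1:2, drop = FALSE] else cbind(pcs[, 1], 0)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("embedding = \"umap\" requires the 'uwot' package; ",
           "use embedding = \"pca\" instead", call. = FALSE)
    }
    with_seed(seed, uwot::umap(pcs, n_neighbors = min(k, n - 1)))
  }
  dimnames(emb) <- list(rownames(x), c("dim1", "dim2"))

  structure(
    list(
      cluster = stats::setNames(membership, rownames(x)),
      embedding = emb, pcs = pcs,
      resolution = resolution, k = k, seed = seed
    ),
    class = "cluster_result"
  )
}

# log(1 + x) then per-gene z-scoring; genes with zero variance map to 0.
scale_log_expression <- function(x) {
  lx <- log1p(x)
  mu <- colMeans(lx)
  sd <- apply(lx, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf
  sweep(sweep(lx, 2L, mu, `-`), 2L, sd, `/`)
}

#' Marker rules for perinatal interneuron subtypes
#'
#' The default marker-gene rules used by [assign_subtypes()]: the six
#' inhibitory subtypes of migratory young neurons described for the
#' perinatal subventricular Arc and its cortical streams (MGE-derived
#' NKX2.1+MAF1+ and SST+LHX6+; CGE-derived COUP-TFII+ combinations and
#' VIP+GAD1+) plus the SATB2+ excitatory class.
#'
#' @return Named list mapping subtype name to required marker genes.
#' @export
default_subtype_rules <- function() {
  list(
    "NKX2.1+MAF1+"     = c("NKX2.1", "MAF1"),
    "SST+LHX6+"        = c("SST", "LHX6"),
    "COUP-TFII+SP8+"   = c("COUP-TFII", "SP8"),
    "COUP-TFII+TBR1+"  = c("COUP-TFII", "TBR1"),
    "COUP-TFII+CALB2+" = c("COUP-TFII", "CALB2"),
    "VIP+GAD1+"        = c("VIP", "GAD1"),
    "SATB2+ EN"        = "SATB2"
  )
}

#' Assign marker-based subtype labels to clusters
#'
#' Scores every cluster against each subtype rule as the mean, over the
#' rule's required marker genes, of the cluster's average standardized
#' log expression. A cluster receives the top-scoring subtype if that
#' score exceeds the runner-up by at least `margin`; otherwise it is
#' labeled `"unassigned"`. Every cell inherits its cluster's label.
#'
#' @param clusters A `cluster_result` from [normalize_cluster_embed()].
#' @param matrix The [expression_matrix()] the clusters were computed
#'   from.
#' @param rules Named list of subtype -> required marker genes; defaults
#'   to [default_subtype_rules()]. All marker genes must be present.
#' @param margin Minimum lead of the best score over the second best (in
#'   z-score units) required for assignment; default 0.25.
#' @return Character vector of per-cell subtype labels (named by cell),
#'   with the per-cluster label table in attribute `cluster_labels` and
#'   the cluster x subtype score matrix in attribute `scores`.
#' @export
assign_subtypes <- function(clusters, matrix, rules = default_subtype_rules(),
                            margin = 0.25) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (length(rules) == 0L) stop("`rules` must be non-empty", call. = FALSE)
  markers <- unique(unlist(rules))
  missing <- setdiff(markers, colnames(matrix))
  if (length(missing) > 0L) {
    stop("marker genes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- scale_log_expression(unclass(matrix))
  cl <- clusters$cluster
  ids <- sort(unique(cl))
  # `matrix` is shadowed by the argument; use array() for construction
  scores <- array(
    NA_real_, dim = c(length(ids), length(rules)),
    dimnames = list(as.character(ids), names(rules))
  )
  for (i in seq_along(ids)) {
    zbar <- colMeans(z[cl == ids[i], , drop = FALSE])
    scores[i, ] <- vapply(rules, function(mk) mean(zbar[mk]), numeric(1))
  }
  cluster_label <- apply(scores, 1L, function(s) {
    o <- order(s, decreasing = TRUE)
    if (length(s) == 1L || s[o[1]] - s[o[2]] >= margin) {
      names(s)[o[1]]
    } else {
      "unassigned"
    }
  })
  labels <- stats::setNames(
    cluster_label[match(cl, ids)],
    names(cl)
  )
  attr(labels, "cluster_labels") <-
    stats::setNames(cluster_label, as.character(ids))
  attr(labels, "scores") <- scores
  labels
}
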