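#' Planted expression model for the perinatal interneuron subtypes
#'
#' Builds the [expression_model()] used to simulate multiplexed-FISH
#' probe channels over the seven default subtypes of
#' [default_subtype_rules()]. Each subtype expresses its rule's marker
#' genes at `marker_prob`, all other genes at `off_prob`; the
#' pan-inhibitory marker GAD1 is additionally expressed at `gad1_shared`
#' by the inhibitory subtypes whose rule does not already require it, and
#' DCX (which defines the migratory population itself) is expressed by
#' every type at `marker_prob`.
#'
#' The defaults emulate a clean but realistic area-based readout: a probe
#' covering about half of a truly expressing cell's ROI, a few percent of
#' nonspecific coverage elsewhere, and sparse background speckle.
#'
#' @param rules Subtype marker rules; default [default_subtype_rules()].
#' @param marker_prob Probe-pixel probability for a subtype's own markers
#'   (default 0.5).
#' @param off_prob Nonspecific probe-pixel probability (default 0.03).
#' @param gad1_shared GAD1 probability in non-VIP inhibitory subtypes
#'   (default 0.2).
#' @param speckle_rate Background positive-pixel rate (default 0.002).
#' @param roi_radius ROI disk radius in pixels (default 4).
#' @return An [expression_model()] over the seven types and the marker
#'   genes plus DCX.
#' @export
arc_subtype_model <- function(rules = default_subtype_rules(),
                              marker_prob = 0.5, off_prob = 0.03,
                              gad1_shared = 0.2, speckle_rate = 0.002,
                              roi_radius = 4) {
  types <- names(rules)
  genes <- c(unique(unlist(rules)), "DCX")
  prob <- base::matrix(off_prob, length(types), length(genes),
                       dimnames = list(types, genes))
  for (tp in types) prob[tp, rules[[tp]]] <- marker_prob
  if ("GAD1" %in% genes) {
    inhibitory <- types[vapply(rules, function(mk) !"SATB2" %in% mk,
                               logical(1))]
    share <- setdiff(inhibitory, types[vapply(rules, function(mk)
      "GAD1" %in% mk, logical(1))])
    prob[share, "GAD1"] <- gad1_shared
  }
  prob[, "DCX"] <- marker_prob
  expression_model(prob, speckle_rate = speckle_rate,
                   roi_radius = roi_radius)
}

#' Simulate a full multiplexed-FISH experiment with planted subtypes
#'
#' One-call driver for the end-to-end simulation: places
#' `n_cells_per_type` cells of each subtype uniformly in the image
#' (complete spatial randomness), then renders all probe channels under
#' [arc_subtype_model()].
#'
#' @param n_cells_per_type Cells per subtype (default 100).
#' @param model An [expression_model()]; default [arc_subtype_model()].
#' @param image_size `c(width, height)` in pixels; default 300 x 300.
#' @param seed Integer seed (the cell map and probe noise derive
#'   sub-seeds from it).
#' @return The `probe_set` from [generate_probe_images()] (its `cells`
#'   element carries the true type labels).
#' @export
simulate_arc_fish <- function(n_cells_per_type = 100,
                              model = arc_subtype_model(),
                              image_size = c(300, 300), seed) {
  types <- rownames(model$prob)
  props <- stats::setNames(rep(1 / length(types), length(types)), types)
  cells <- generate_cell_map(
    n_cells_per_type * length(types), props, interaction_spec("csr"),
    image_size = image_size, seed = seed,
    margin = ceiling(model$roi_radius) + 1
  )
  generate_probe_images(cells, model, seed = seed + 1L)
}
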