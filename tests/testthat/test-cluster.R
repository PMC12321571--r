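planted_blocks <- function(n_per = 40, seed = fixture_seed) {
  set.seed(seed)
  active <- function() pmin(pmax(70 + rnorm(n_per * 5, 0, 3), 0), 100)
  v <- rbind(
    cbind(matrix(active(), n_per), matrix(0, n_per, 5)),
    cbind(matrix(0, n_per, 5), matrix(active(), n_per))
  )
  dimnames(v) <- list(seq_len(2 * n_per), paste0("g", 1:10))
  expression_matrix(v, stage = "median_zeroed")
}

test_that("two orthogonal planted blocks are recovered perfectly", {
  m <- planted_blocks()
  cl <- normalize_cluster_embed(m, resolution = 1, k = 20, seed = 1)
  expect_length(unique(cl$cluster), 2L)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1.0)
  expect_equal(dim(cl$embedding), c(80L, 2L))
})

test_that("identical cells collapse to one cluster", {
  v <- matrix(rep(c(5, 40, 80, 0, 12), each = 30), 30, 5,
              dimnames = list(1:30, paste0("g", 1:5)))
  cl <- normalize_cluster_embed(expression_matrix(v, "median_zeroed"),
                                k = 5, seed = 2)
  expect_length(unique(cl$cluster), 1L)
})

test_that("clustering is deterministic given the seed", {
  m <- planted_blocks()
  a <- normalize_cluster_embed(m, k = 10, seed = 11)
  b <- normalize_cluster_embed(m, k = 10, seed = 11)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$embedding, b$embedding)
})

test_that("too few cells for the neighbor count gives guidance", {
  m <- planted_blocks(n_per = 5)
  expect_error(normalize_cluster_embed(m, k = 20, seed = 1), "reduce `k`")
})

test_that("marker rules force the expected subtype labels", {
  # cluster 1 maximal on NKX2.1 + MAF1, cluster 2 ambiguous between two rules
  genes <- c("NKX2.1", "MAF1", "SST", "LHX6", "COUP-TFII", "SP8", "TBR1",
             "CALB2", "VIP", "GAD1", "SATB2")
  set.seed(fixture_seed)
  v <- matrix(runif(40 * length(genes), 0, 2), 40, length(genes),
              dimnames = list(1:40, genes))
  v[1:20, c("NKX2.1", "MAF1")] <- 80
  v[21:40, c("SST", "LHX6", "VIP", "GAD1")] <- 80  # two rules tie
  m <- expression_matrix(v, "median_zeroed")
  cl <- structure(
    list(cluster = setNames(rep(1:2, each = 20), 1:40)),
    class = "cluster_result"
  )
  lab <- assign_subtypes(cl, m, margin = 0.25)
  expect_true(all(lab[1:20] == "NKX2.1+MAF1+"))
  expect_true(all(lab[21:40] == "unassigned"))
  expect_error(assign_subtypes(cl, m, rules = list()), "non-empty")
  expect_error(
    assign_subtypes(cl, m, rules = list(X = "NOT_A_GENE")), "absent"
  )
})

test_that("planted six-subtype simulation is recovered end to end", {
  ps <- simulate_arc_fish(n_cells_per_type = 60, seed = fixture_seed)
  X <- build_expression_matrix(ps, min_object_px = 2)
  mz <- median_zero(X)
  cl <- normalize_cluster_embed(mz, resolution = 1, k = 20, seed = 5)
  lab <- assign_subtypes(cl, mz)
  truth <- ps$cells$type[match(as.integer(names(cl$cluster)),
                               ps$cells$cell_id)]
  expect_gte(mean(lab == truth), 0.9)
  expect_gt(mclust::adjustedRandIndex(lab, truth), 0.8)
})
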