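four_cell_fixture <- function() {
  data.frame(cell_id = 1:4, image_id = "img",
             x = c(0, 1, 20, 40), y = c(0, 0, 0, 0),
             type = c("A", "A", "B", "B"),
             stringsAsFactors = FALSE)
}

test_that("neighbor edges follow the strict distance rule", {
  cells <- data.frame(cell_id = 1:3, image_id = "i",
                      x = c(0, 3, 6), y = c(0, 0, 0), type = "A")
  g <- build_neighbor_graph(cells, 4)
  expect_equal(g$edges, rbind(c(1L, 2L), c(2L, 3L)))
  # a pair at exactly the threshold distance is NOT a neighbor
  pair <- data.frame(cell_id = 1:2, image_id = "i",
                     x = c(0, 4), y = c(0, 0), type = "A")
  expect_equal(nrow(build_neighbor_graph(pair, 4)$edges), 0L)
  expect_error(build_neighbor_graph(pair, 0), "positive")
  two_img <- cells; two_img$image_id <- c("a", "a", "b")
  expect_error(build_neighbor_graph(two_img, 4), "one image")
})

test_that("random maps match the all-pairs distance oracle", {
  for (i in 1:3) {
    cm <- generate_cell_map(50, c(A = 0.6, B = 0.4), interaction_spec("csr"),
                            c(30, 30), seed = fixture_seed + i)
    g <- build_neighbor_graph(cm, 4)
    expect_equal(g$edges, oracle_edges(cm, 4))
  }
})

test_that("interaction statistic equals brute-force neighbor tallies", {
  cells <- four_cell_fixture()
  g <- build_neighbor_graph(cells, 4)
  expect_equal(interaction_statistic(g, cells$type, c("A", "A")), 1.0)
  expect_equal(interaction_statistic(g, cells$type, c("A", "B")), 0)
  expect_error(interaction_statistic(g, cells$type, c("A", "Z")), "known")
  for (i in 1:3) {
    cm <- generate_cell_map(60, c(A = 0.5, B = 0.3, C = 0.2),
                            interaction_spec("csr"), c(25, 25),
                            seed = fixture_seed + 10 + i)
    g <- build_neighbor_graph(cm, 4)
    for (pair in list(c("A", "B"), c("B", "A"), c("A", "A"), c("C", "B"))) {
      expect_equal(interaction_statistic(g, cm$type, pair),
                   oracle_interaction_stat(cm, cm$type, pair, 4))
    }
  }
})

test_that("isolated nodes give statistic 0 for every present pair", {
  cells <- data.frame(cell_id = 1:4, image_id = "i",
                      x = c(0, 10, 20, 30), y = 0,
                      type = c("A", "A", "B", "B"))
  g <- build_neighbor_graph(cells, 4)
  expect_equal(interaction_statistic(g, cells$type, c("A", "B")), 0)
  expect_equal(interaction_statistic(g, cells$type, c("B", "B")), 0)
})

test_that("Monte-Carlo p converges to the exhaustive 1/6 on the fixture", {
  cells <- four_cell_fixture()
  g <- build_neighbor_graph(cells, 4)
  # exhaustive: 6 ways to place the two A labels; only one yields
  # an A-A contact, so P(null >= observed) = 1/6
  n_perm <- 10000
  r <- permutation_test(g, cells$type, c("A", "A"),
                        n_permutations = n_perm, seed = 99)
  se <- sqrt((1 / 6) * (5 / 6) / n_perm)
  expect_lt(abs(r$p_value - 1 / 6), 3 * se)
  expect_equal(r$observed, 1.0)
})

test_that("permutation p-values respect the add-one floor and determinism", {
  cells <- four_cell_fixture()
  g <- build_neighbor_graph(cells, 4)
  r <- permutation_test(g, cells$type, c("A", "A"), 200, seed = 1)
  expect_gte(r$p_value, 1 / 201)
  expect_identical(
    r, permutation_test(g, cells$type, c("A", "A"), 200, seed = 1)
  )
  expect_error(
    permutation_test(g, cells$type, c("A", "A"), 0, seed = 1), "at least 1"
  )
})

test_that("pairs with an absent type are flagged not present, untested", {
  cells <- four_cell_fixture()
  cells$type <- "A"
  g <- build_neighbor_graph(cells, 4)
  r <- permutation_test(g, cells$type, c("A", "B"), 100, seed = 1,
                        types = c("A", "B"))
  expect_false(r$present)
  expect_true(is.na(r$p_value))
})

test_that("aggregation applies the 30%/90% conjunction with >=", {
  fake <- function(n_sig, n_present, n = 20) {
    data.frame(
      image_id = seq_len(n), type_a = "A", type_b = "B",
      present = seq_len(n) <= n_present,
      observed = 1, null_mean = 0.5, null_sd = 0.1,
      p_value = ifelse(seq_len(n) <= n_sig, 0.01, 0.5),
      n_permutations = 100L
    )
  }
  expect_true(aggregate_images(fake(7, 19))$keep)    # 35% sig, 95% present
  expect_false(aggregate_images(fake(5, 20))$keep)   # 25% significant
  expect_false(aggregate_images(fake(10, 17))$keep)  # 85% present
  expect_true(aggregate_images(fake(6, 18))$keep)    # exactly 30% and 90%
  expect_error(aggregate_images(fake(0, 0)[0, ]), "at least one")
})

test_that("stream mapping matches a dense-sampling oracle", {
  path <- stream_path(rbind(c(0, 0), c(10, 0), c(10, 10), c(20, 10)))
  at_start <- map_to_stream(data.frame(x = 0, y = 0), path)
  expect_equal(at_start$position, 0)
  straight <- stream_path(rbind(c(0, 0), c(10, 0)))
  expect_equal(map_to_stream(data.frame(x = 5, y = 3), straight)$position, 0.5)
  expect_error(stream_path(rbind(c(0, 0), c(0, 0))), "degenerate")

  set.seed(fixture_seed)
  cells <- data.frame(x = runif(25, -2, 22), y = runif(25, -2, 12))
  got <- map_to_stream(cells, path)
  # dense sampling of the polyline as the independent reference
  dense <- do.call(rbind, lapply(1:3, function(s) {
    a <- path$vertices[s, ]; b <- path$vertices[s + 1, ]
    t <- seq(0, 1, length.out = 4000)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          path$cumlen[s] + t * path$seglen[s])
  }))
  for (i in seq_len(nrow(cells))) {
    d <- sqrt((dense[, 1] - cells$x[i])^2 + (dense[, 2] - cells$y[i])^2)
    ref_pos <- dense[which.min(d), 3] / path$total
    expect_lt(abs(got$position[i] - ref_pos) * path$total, 0.5)
    expect_lt(abs(abs(got$offset[i]) - min(d)), 0.01)
  }
})
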