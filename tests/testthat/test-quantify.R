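test_that("quantify_cell is exact pixel counting", {
  roi <- matrix(FALSE, 10, 10); roi[1:10, 1:10] <- TRUE
  expect_equal(quantify_cell(matrix(FALSE, 10, 10), roi), 0)
  probe <- matrix(TRUE, 10, 10)
  expect_equal(quantify_cell(probe, roi), 100)
  probe30 <- matrix(FALSE, 10, 10); probe30[1:3, ] <- TRUE
  expect_equal(quantify_cell(probe30, roi), 30)
  expect_error(quantify_cell(probe, matrix(FALSE, 10, 10)), "empty ROI")
  expect_error(quantify_cell(matrix(FALSE, 5, 5), roi), "dimensions")
})

test_that("adding probe pixels never decreases the value", {
  set.seed(fixture_seed)
  roi <- matrix(runif(400) < 0.5, 20, 20)
  probe <- matrix(runif(400) < 0.2, 20, 20)
  v0 <- quantify_cell(probe, roi)
  off <- which(!probe)
  probe[sample(off, 25)] <- TRUE
  expect_gte(quantify_cell(probe, roi), v0)
})

test_that("pipeline recovers planted expression exactly without speckle", {
  cm <- generate_cell_map(40, c(A = 0.5, B = 0.5), interaction_spec("csr"),
                          c(90, 90), seed = fixture_seed, margin = 5)
  em <- expression_model(
    rbind(A = c(G1 = 0.3, G2 = 1, G3 = 0),
          B = c(G1 = 0.8, G2 = 0.1, G3 = 0)),
    speckle_rate = 0, roi_radius = 4
  )
  ps <- generate_probe_images(cm, em, seed = 2)
  X <- build_expression_matrix(ps, min_object_px = 0)
  expect_equal(unclass(X)[, colnames(ps$truth)], ps$truth,
               ignore_attr = TRUE, tolerance = 0)
  expect_identical(attr(X, "stage"), "raw")
})

test_that("probability-one plants quantify to 100 everywhere", {
  cm <- generate_cell_map(15, c(A = 1), interaction_spec("csr"),
                          c(60, 60), seed = 4, margin = 5)
  em <- expression_model(rbind(A = c(G = 1)), speckle_rate = 0,
                         roi_radius = 3)
  X <- build_expression_matrix(generate_probe_images(cm, em, seed = 5))
  expect_true(all(X == 100))
})

test_that("component filter removes speckle smaller than min_object_px", {
  cm <- generate_cell_map(15, c(A = 1), interaction_spec("csr"),
                          c(80, 80), seed = 6, margin = 6)
  # no true signal, only single-pixel speckle
  em <- expression_model(rbind(A = c(G = 0)), speckle_rate = 0.005,
                         roi_radius = 3)
  ps <- generate_probe_images(cm, em, seed = 7)
  X <- build_expression_matrix(ps, min_object_px = 2)
  expect_true(all(X[, "G"] == 0))
})

test_that("matrix construction validates its inputs", {
  roi <- matrix(0L, 10, 10); roi[3:5, 3:5] <- 1L
  img <- matrix(c(rep(0, 90), rep(255, 10)), 10, 10)
  expect_error(build_expression_matrix(list(img, img), roi), "named")
  expect_error(
    build_expression_matrix(list(G = img, G = img), roi), "duplicated"
  )
  expect_error(build_expression_matrix(list(G = img), matrix(0L, 10, 10)),
               "no positive labels")
  expect_error(build_expression_matrix(list(G = matrix(0, 5, 5)), roi),
               "differ in size")
  # constant channel quantifies to zero rather than erroring
  X <- build_expression_matrix(list(G = matrix(0, 10, 10)), roi)
  expect_true(all(X == 0))
})
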