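test_that("area ratio is exact pixel counting on constructed masks", {
  m <- generate_region_masks(c(500, 9500), c(100, 100))
  region <- m == 1
  brain <- m > 0
  expect_equal(as.numeric(area_ratio(region, brain)), 5.0)
  expect_equal(as.numeric(area_ratio(brain, brain)), 100.0)
  expect_error(area_ratio(region, matrix(0, 100, 100)), "empty brain")
  expect_warning(area_ratio(region, m == 2), "outside")
  req <- c(730, 1270, 4000)
  m2 <- generate_region_masks(req, c(100, 100))
  expect_equal(as.numeric(area_ratio(m2 == 1, m2 > 0)),
               100 * req[1] / sum(req))
})

test_that("tier areas follow the subtraction rule", {
  arc <- matrix(FALSE, 50, 50); arc[1:40, 1:25] <- TRUE   # 1000 px
  t1 <- matrix(FALSE, 50, 50); t1[1:8, 1:25] <- TRUE      # 200 px
  expect_equal(tier_areas(arc, t1), c(tier1 = 200, tiers2_3 = 800))
  expect_equal(tier_areas(arc, arc), c(tier1 = 1000, tiers2_3 = 0))
  bad <- matrix(FALSE, 50, 50); bad[45, 45] <- TRUE
  expect_error(tier_areas(arc, bad), "not contained")
  set.seed(fixture_seed)
  inner <- arc & matrix(runif(2500) < 0.3, 50, 50)
  expect_equal(unname(tier_areas(arc, inner)),
               c(sum(inner), sum(arc) - sum(inner)))
})

test_that("gyrification index: circle gives 1, folding matches ground truth", {
  circ <- generate_contour(10, 0, 0, n_points = 2048)
  expect_equal(as.numeric(gyrification_index(circ)), 1.0, tolerance = 1e-6)
  folded <- generate_contour(10, 2, 8, n_points = 4096)
  gi <- as.numeric(gyrification_index(folded))
  expect_lt(abs(gi - attr(folded, "true_gi")) / attr(folded, "true_gi"),
            0.005)
})

test_that("GI is invariant to rigid motion and uniform scaling", {
  cs <- generate_contour(10, 2, 8, n_points = 1024)
  gi <- as.numeric(gyrification_index(cs))
  th <- 0.7; rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- contour_set(sweep(cs$full %*% rot, 2, c(5, -3), `+`) * 2.5,
                       sweep(cs$outer %*% rot, 2, c(5, -3), `+`) * 2.5)
  expect_equal(as.numeric(gyrification_index(moved)), gi, tolerance = 1e-9)
})

test_that("convex-hull envelope is used when no outer contour is given", {
  cs <- generate_contour(10, 2, 8, n_points = 2048)
  gi <- as.numeric(gyrification_index(contour_set(cs$full)))
  # hull length is close to (and at most) the circumscribing circle
  expect_gte(gi, attr(cs, "true_gi") * 0.999)
  expect_lt(gi, attr(cs, "true_gi") * 1.05)
  expect_equal(as.numeric(gyrification_index(contour_set(cs$outer))), 1.0,
               tolerance = 1e-4)
})

test_that("positive area fraction equals brute-force counting", {
  region <- matrix(TRUE, 30, 30)
  expect_equal(as.numeric(positive_area_fraction(matrix(0, 30, 30), region,
                                                 threshold = 0.5)), 0)
  ind <- matrix(0, 30, 30); ind[1:10, ] <- 1
  expect_equal(
    as.numeric(positive_area_fraction(ind, region, threshold = 0)),
    100 * sum(ind > 0) / 900
  )
  set.seed(fixture_seed)
  img <- matrix(runif(900, 0, 255), 30, 30)
  mask <- matrix(runif(900) < 0.6, 30, 30)
  expect_equal(
    as.numeric(positive_area_fraction(img, mask, threshold = 100)),
    100 * sum(img > 100 & mask) / sum(mask)
  )
  expect_error(positive_area_fraction(img, matrix(FALSE, 30, 30), 1),
               "empty region")
})

test_that("tier intensity profile reads step levels and flags empty bands", {
  img <- matrix(0, 40, 30)
  img[1:5, ] <- 50; img[6:15, ] <- 120; img[16:30, ] <- 200
  tiers <- tier_spec(x0 = 0, y0 = 0, width = 30,
                     boundaries = c(5, 15, 30))
  expect_equal(tier_intensity_profile(img, tiers, threshold = 10),
               c(50, 120, 200))
  # uniform image: identical value in every tier
  expect_equal(tier_intensity_profile(matrix(80, 40, 30), tiers,
                                      threshold = 10), rep(80, 3))
  # band entirely below threshold is a missing value, not an error
  img2 <- img; img2[1:5, ] <- 0
  expect_true(is.na(tier_intensity_profile(img2, tiers, threshold = 10)[1]))
  expect_error(tier_intensity_profile(img, tier_spec(0, 0, 31, c(5, 40))),
               "inside the image")
  expect_error(tier_spec(0, 0, 10, c(5, 5)), "strictly increasing")
})

test_that("frustum volume identities hold", {
  # constant areas: (n-1) * A * h
  expect_equal(estimate_volume(section_series(rep(3, 6), spacing = 0.75)),
               5 * 3 * 0.75)
  # exact for a cone sectioned from the apex
  ss <- generate_section_profile(solid_spec("cone", c(2, 3), 7, spacing = 0.5))
  expect_equal(estimate_volume(ss), pi * 4 * 3 / 3, tolerance = 1e-13)
  # exact for any frustum stack
  ss2 <- generate_section_profile(
    solid_spec("frustum_stack", c(1, 2.5, 0.3, 4), 4, spacing = 0.75)
  )
  expect_equal(estimate_volume(ss2), attr(ss2, "true_volume"),
               tolerance = 1e-13)
  # per-gap spacing
  v <- estimate_volume(section_series(c(1, 1, 1), spacing = c(1, 2)))
  expect_equal(v, 3)
})

test_that("sphere volume error is within 1% and shrinks with refinement", {
  vol_err <- function(n) {
    ss <- generate_section_profile(solid_spec("sphere", 1, n, 2 / (n - 1)))
    abs(estimate_volume(ss) - 4 * pi / 3) / (4 * pi / 3)
  }
  expect_lt(vol_err(21), 0.01)
  expect_lt(vol_err(41), vol_err(21))
  expect_lt(vol_err(81), vol_err(41))
})

test_that("correlation matches the closed form", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlate(x, 2 * x + 1)$r, 1.0)
  expect_equal(correlate(x, -x)$r, -1.0)
  y <- c(2.1, 1.9, 3.5, 3.2, 5.0, 4.4)
  got <- correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand)
  tstat <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df = 4))
  expect_equal(got$n, 6)
  expect_error(correlate(x, rep(1, 6)), "zero variance")
  expect_error(correlate(1:2, 1:2), "length >= 3")
})
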