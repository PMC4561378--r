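test_that("threshold set follows T = I_max * W with the I_min floor", {
  # full-range image: equally spaced values up to I_max
  img <- matrix(seq(0, 1, length.out = 25), 5, 5)
  th <- compute_thresholds(img, 5)
  expect_equal(th$values, c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(th$weights, c(0.2, 0.4, 0.6, 0.8, 1.0))

  # narrow-range image: thresholds below I_min are dropped with a warning
  img2 <- matrix(seq(0.5, 0.8, length.out = 25), 5, 5)
  expect_warning(th2 <- compute_thresholds(img2, 4), "dropped")
  expect_equal(th2$values, c(0.6, 0.8))
  expect_equal(th2$n_levels, 2L)

  expect_error(compute_thresholds(matrix(0.4, 5, 5)), "degenerate")
  expect_error(compute_thresholds(img, 1), "n_levels")
})

test_that("a radially decreasing blob yields a single nested chain", {
  h <- 81; w <- 81
  g <- pixel_grid(h, w)
  r <- sqrt((g$x - 41)^2 + (g$y - 41)^2)
  img <- pmax(1 - r / 45, 0)   # bright center, falls with radius
  th <- compute_thresholds(img, 8)
  map <- iso_level_map(img, th, min_area = 16)
  chains <- mammoseg:::nesting_chains(map)
  expect_gte(length(map$contours), 5)
  expect_equal(length(chains), 1L)
  chain <- chains[[1]]
  # containment oracle: every inner contour's vertices lie inside its parent
  for (k in seq_len(length(chain) - 1)) {
    outer <- mammoseg:::open_vertices(map$contours[[chain[k]]]$xy)
    inner <- mammoseg:::open_vertices(map$contours[[chain[k + 1]]]$xy)
    expect_true(all(pracma::inpolygon(inner[, 1], inner[, 2],
                                      outer[, 1], outer[, 2],
                                      boundary = TRUE)))
  }
  # levels decrease inward for a bright-center blob (sub-level regions
  # {I <= t} shrink toward the peak as t grows... outermost has highest t)
  lv <- vapply(chain, function(i) map$contours[[i]]$level, numeric(1))
  expect_true(all(diff(lv) < 0) || all(diff(lv) > 0))
})

test_that("two separated blobs give a two-root nesting forest", {
  h <- 61; w <- 121
  g <- pixel_grid(h, w)
  img <- 0.9 * exp(-((g$x - 30)^2 + (g$y - 30)^2) / 200) +
    0.9 * exp(-((g$x - 90)^2 + (g$y - 30)^2) / 200)
  map <- iso_level_map(img, compute_thresholds(img, 6), min_area = 16)
  roots <- sum(vapply(map$contours, function(cc) is.na(cc$parent), TRUE))
  expect_equal(roots, 2L)
})

test_that("sub-level monotonicity holds on random smooth fields", {
  set.seed(5)
  for (rep in 1:3) {
    base <- matrix(runif(9), 3, 3)
    img <- matrix(0, 33, 33)
    for (i in 1:33) for (j in 1:33) {
      u <- (i - 1) / 16; v <- (j - 1) / 16
      i0 <- pmin(floor(u) + 1, 2); j0 <- pmin(floor(v) + 1, 2)
      fu <- u - (i0 - 1); fv <- v - (j0 - 1)
      img[i, j] <- (1 - fu) * (1 - fv) * base[i0, j0] +
        fu * (1 - fv) * base[i0 + 1, j0] +
        (1 - fu) * fv * base[i0, j0 + 1] + fu * fv * base[i0 + 1, j0 + 1]
    }
    th <- suppressWarnings(compute_thresholds(img, 6))
    for (k in seq_len(th$n_levels - 1)) {
      expect_true(all((img <= th$values[k]) <= (img <= th$values[k + 1])))
    }
  }
})

test_that("nesting parents always enclose a larger area", {
  h <- 81; w <- 81
  g <- pixel_grid(h, w)
  img <- 0.9 * exp(-((g$x - 41)^2 + (g$y - 41)^2) / 500)
  map <- iso_level_map(img, compute_thresholds(img, 8), min_area = 16)
  for (cc in map$contours) {
    if (!is.na(cc$parent))
      expect_gt(map$contours[[cc$parent]]$area, cc$area)
  }
})

test_that("a sharp-edged disk concentrates nearly all contours in the band", {
  h <- 101; w <- 101
  mask <- disk_mask(h, w, 51, 51, 30)
  img <- 0.2 + 0.7 * mammoseg:::gaussian_blur(mask, 1)
  map <- suppressWarnings(iso_level_map(img, compute_thresholds(img, 24)))
  band <- extract_search_band(map)
  expect_gte(length(band$members) / length(map$contours), 0.8)
  # band mask covers the innermost member contour
  inner <- Filter(function(cc) cc$id == band$innermost_id, band$members)[[1]]
  v <- mammoseg:::open_vertices(inner$xy)
  idx <- cbind(pmin(pmax(round(v[, 2]), 1), h), pmin(pmax(round(v[, 1]), 1), w))
  expect_gte(mean(band$band_mask[idx] > 0), 0.95)
})

test_that("uniformly spaced contours are rejected as a search band", {
  # radial cone: equally spaced circular iso-contours, spacing ~8 px at
  # 10 levels; no dense structure anywhere
  h <- 161; w <- 161
  g <- pixel_grid(h, w)
  r <- sqrt((g$x - 81)^2 + (g$y - 81)^2)
  img <- pmax(1 - r / 85, 0)
  map <- iso_level_map(img, compute_thresholds(img, 10))
  expect_error(extract_search_band(map), "search band not found")
})
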