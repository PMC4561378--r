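test_that("radial profile picks the maximum-gradient intersection", {
  # gradient field peaked on a circle of radius 30; candidate contours at
  # radii 24..36 -> the r=30 member must win on every ray
  h <- 101; w <- 101; cx <- 51; cy <- 51
  g <- pixel_grid(h, w)
  rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  grad <- exp(-(rr - 30)^2 / 8)
  band <- make_band(lapply(seq(36, 24, by = -2), function(r)
    circle_points(cx, cy, r, 180)), c(h, w))
  prof <- radial_profile(band, grad, m = 90, ref = c(cx, cy))
  expect_length(prof$radii, 90)
  expect_true(all(abs(prof$radii - 30) <= 0.5))
  expect_false(any(prof$interpolated))
})

test_that("square-edge rays hit the square and ties go to the nearest", {
  h <- 61; w <- 61; cx <- 31; cy <- 31
  sq <- cbind(x = c(21, 41, 41, 21), y = c(21, 21, 41, 41))
  grad <- matrix(1, h, w)   # uniform gradient: every intersection ties
  band <- make_band(list(sq), c(h, w))
  prof <- radial_profile(band, grad, m = 4 * 8, ref = c(cx, cy))
  # oracle: first positive crossing of the square's face lines per ray
  for (j in seq_along(prof$angles)) {
    a <- prof$angles[j]
    d <- c(cos(a), sin(a))
    ts <- numeric(0)
    if (abs(d[1]) > 1e-9) ts <- c(ts, (c(21, 41) - cx) / d[1])
    if (abs(d[2]) > 1e-9) ts <- c(ts, (c(21, 41) - cy) / d[2])
    expect_equal(prof$radii[j], min(ts[ts > 0]), tolerance = 1e-8)
  }

  # two concentric squares, uniform gradient: nearest intersection wins
  outer_sq <- cbind(x = c(16, 46, 46, 16), y = c(16, 16, 46, 46))
  band2 <- make_band(list(outer_sq, sq), c(h, w))
  prof2 <- radial_profile(band2, grad, m = 8, ref = c(cx, cy))
  expect_true(all(prof2$radii <= 10 * sqrt(2) + 1e-6))
})

test_that("clipping follows the r_ave + n * r_std rule exactly", {
  p <- make_profile(c(1, 1, 10))
  out <- clip_profile(p, n = 1)
  expect_equal(out$radii, c(1, 1, 4))
  expect_equal(attr(out, "r_ave"), 4)
  expect_equal(attr(out, "r_std"), sqrt(27), tolerance = 1e-12)
  expect_equal(attr(out, "replaced"), 3L)

  # equal radii: every r_i sits exactly at the cutoff and is replaced by
  # r_ave = r_i, so the profile is unchanged
  p2 <- make_profile(rep(5, 12))
  out2 <- clip_profile(p2, n = 1)
  expect_equal(out2$radii, rep(5, 12))
  expect_equal(length(attr(out2, "replaced")), 12L)

  expect_error(clip_profile(make_profile(3), 1), "at least 2")
  expect_error(clip_profile(p, n = 3), "must be 1 or 2")
})

test_that("clipping matches a brute-force recount on random profiles", {
  set.seed(99)
  for (rep in 1:20) {
    m <- sample(8:400, 1)
    radii <- abs(rnorm(m, 50, sample(c(2, 10, 25), 1))) + 1
    n <- sample(c(1, 2), 1)
    out <- clip_profile(make_profile(radii), n)
    cutoff <- mean(radii) + n * sd(radii)
    brute <- which(radii >= cutoff)
    expect_identical(attr(out, "replaced"), brute)
    expect_equal(out$radii[brute], rep(mean(radii), length(brute)))
    expect_equal(out$radii[-brute], radii[-brute])
    expect_lte(max(out$radii), max(radii) + 1e-12)
  }

  # tight profiles rarely clip at n = 2
  set.seed(123)
  radii <- rnorm(360, 50, 2)
  out <- clip_profile(make_profile(radii), 2)
  expect_lte(length(attr(out, "replaced")), 15)
})

test_that("a circular profile becomes a simple polygon recovering the ring", {
  p <- make_profile(rep(30, 360), ref = c(x = 50, y = 50))
  ic <- profile_to_contour(p)
  v <- mammoseg:::open_vertices(ic)
  expect_equal(nrow(v), 360)
  expect_true(all(abs(sqrt((v[, 1] - 50)^2 + (v[, 2] - 50)^2) - 30) < 0.5))
  expect_equal(shoelace(v), pi * 30^2, tolerance = 0.02 * pi * 30^2)
  expect_identical(attr(ic, "source"), "proposed")
})

test_that("ring recovery through the full radial chain is within 1 px", {
  h <- 121; w <- 121; cx <- 61; cy <- 61
  g <- pixel_grid(h, w)
  rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  grad <- exp(-(rr - 40)^2 / 4)
  band <- make_band(lapply(seq(46, 34, by = -3), function(r)
    circle_points(cx, cy, r, 360)), c(h, w))
  prof <- radial_profile(band, grad, m = 360, ref = c(cx, cy))
  ic <- profile_to_contour(clip_profile(prof, 1))
  v <- mammoseg:::open_vertices(ic)
  expect_true(all(abs(sqrt((v[, 1] - cx)^2 + (v[, 2] - cy)^2) - 40) <= 1))
})

test_that("manual contours are validated", {
  tri <- manual_contour(cbind(c(0, 10, 0), c(0, 0, 10)))
  expect_s3_class(tri, "polyline")
  expect_equal(nrow(tri), 4)   # closed
  expect_identical(attr(tri, "source"), "manual")

  expect_error(manual_contour(cbind(c(0, 1), c(0, 1))), "at least 3")
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(manual_contour(bowtie), "self-intersecting")
})
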