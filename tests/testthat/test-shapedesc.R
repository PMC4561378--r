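test_that("centroid distance function matches analytic shapes", {
  d <- disk_mask(81, 81, 41, 41, 30)
  cdf <- centroid_distance(d, 256)
  expect_equal(cdf$N, 256)
  expect_true(all(abs(cdf$r - 30) <= 0.6))

  sq <- rect_mask(61, 61, 21, 40, 21, 40)   # side 20
  cdf_sq <- centroid_distance(sq, 256)
  expect_equal(min(cdf_sq$r), 10, tolerance = 0.6 / 10)
  expect_equal(max(cdf_sq$r), 10 * sqrt(2), tolerance = 0.6 / 14.1)

  # translation invariance (centroid-relative)
  sq2 <- rect_mask(61, 61, 28, 47, 18, 37)  # shifted by (7, -3)
  cdf_sq2 <- centroid_distance(sq2, 256)
  expect_equal(sort(cdf_sq$r), sort(cdf_sq2$r), tolerance = 1e-6)

  expect_warning(centroid_distance(rect_mask(20, 20, 1, 10, 5, 15), 256),
                 "border")
  expect_error(centroid_distance(d, 64), "n_samples")
})

test_that("boundary moments follow the normalized central-moment formulas", {
  expect_equal(unname(boundary_moments(rep(7, 100))), c(0, 0, 0))

  f <- boundary_moments(c(1, 3))
  expect_equal(unname(f), c(0.5, 0.5, 0))

  set.seed(4)
  r <- runif(200, 10, 30)
  f1 <- boundary_moments(r)
  f2 <- boundary_moments(3.7 * r)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(unname(f1["F3"]), unname(abs(f1["F1"] - f1["F2"])))
})

test_that("Fourier descriptors isolate harmonics and obey invariances", {
  N <- 512
  n <- 0:(N - 1)
  expect_true(all(fourier_descriptors(rep(5, N)) == 0))

  r <- 10 + 2 * cos(2 * pi * 3 * n / N)
  fd <- fourier_descriptors(r)
  expect_equal(unname(fd[3]), 0.1, tolerance = 1e-6)
  expect_lt(max(fd[-3]), 1e-6)

  # start-point (circular shift) invariance
  fd_shift <- fourier_descriptors(c(r[101:N], r[1:100]))
  expect_equal(fd, fd_shift, tolerance = 1e-9)

  # Parseval under the 1/N DFT normalization
  set.seed(31)
  r2 <- runif(N, 5, 15)
  a <- fft(r2) / N
  expect_equal(sum(Mod(a)^2), mean(r2^2), tolerance = 1e-9)

  expect_error(fourier_descriptors(rep(1, 100), k = 60), "samples")
})

test_that("convexity matches a brute-force hull and detects notches", {
  d <- disk_mask(81, 81, 41, 41, 30)
  expect_gte(convexity(d), 0.99)
  expect_lte(convexity(d), 1)

  # plus sign: arms 10 wide, 30 long
  cross <- pmax(rect_mask(61, 61, 16, 45, 26, 35),
                rect_mask(61, 61, 26, 35, 16, 45))
  sc <- convexity(cross)
  idx <- which(cross > 0, arr.ind = TRUE)
  pts <- cbind(idx[, 2], idx[, 1])
  hull <- giftwrap_hull(pts)
  g <- pixel_grid(61, 61)
  hull_px <- sum(pracma::inpolygon(as.vector(g$x), as.vector(g$y),
                                   hull[, 1], hull[, 2], boundary = TRUE) |
                   as.vector(cross > 0))
  expect_equal(sc, sum(cross) / hull_px, tolerance = 1e-12)

  notched <- d
  notched[35:47, 41:71] <- 0   # deep wedge into the disk
  expect_lt(convexity(notched), convexity(d))
})

test_that("rectangularity is 1 for rectangles and pi/4 for disks", {
  r1 <- rect_mask(81, 81, 21, 60, 31, 50)   # 40 x 20
  expect_gte(rectangularity(r1), 0.99)
  expect_lte(rectangularity(r1), 1)

  # same rectangle rotated 30 degrees: minimum rectangle is orientation-free
  th <- 30 * pi / 180
  corners <- cbind(c(-20, 20, 20, -20), c(-10, -10, 10, 10))
  rot <- corners %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  r2 <- poly_mask(81, 81, cbind(rot[, 1] + 41, rot[, 2] + 41))
  sr2 <- rectangularity(r2)
  expect_gte(sr2, 0.97)
  # oracle: exhaustive rotating search at 0.1 degree steps over the same
  # boundary polygon (rotating calipers must match the dense angle scan)
  pts <- mammoseg:::boundary_polygon(r2, window = 13)
  best <- Inf
  for (ang in seq(0, 90, by = 0.1) * pi / 180) {
    u <- pts[, 1] * cos(ang) + pts[, 2] * sin(ang)
    v <- -pts[, 1] * sin(ang) + pts[, 2] * cos(ang)
    best <- min(best, (max(u) - min(u)) * (max(v) - min(v)))
  }
  expect_equal(sr2, min(1, shoelace(pts) / best), tolerance = 2e-3)

  d <- disk_mask(81, 81, 41, 41, 30)
  expect_lt(abs(rectangularity(d) - pi / 4), 0.01)
})

test_that("describe_mask bundles all descriptors deterministically", {
  d <- disk_mask(81, 81, 41, 41, 30)
  b1 <- describe_mask(d)
  b2 <- describe_mask(d)
  expect_identical(b1, b2)
  expect_lt(b1$F1, 0.02)
  expect_lt(max(b1$FD), 0.01)
  expect_gte(b1$SC, 0.99)
  expect_lt(abs(b1$SR - pi / 4), 0.01)
  expect_equal(b1$F3, abs(b1$F1 - b1$F2))
  expect_equal(b1$area, sum(d))

  # spiculated blob vs its convex hull: rougher boundary, lower convexity
  th <- (0:359) * pi / 180
  rr <- 25 * (1 + 0.25 * cos(8 * th))
  spic <- poly_mask(81, 81, cbind(41 + rr * cos(th), 41 + rr * sin(th)))
  idx <- which(spic > 0, arr.ind = TRUE)
  hull <- giftwrap_hull(cbind(idx[, 2], idx[, 1]))
  hull_mask <- poly_mask(81, 81, hull)
  d_spic <- describe_mask(spic)
  d_hull <- describe_mask(hull_mask)
  expect_gt(d_spic$F1, d_hull$F1)
  expect_lt(d_spic$SC, d_hull$SC)
})
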