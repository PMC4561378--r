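test_that("init_levelset builds a signed distance field, positive inside", {
  ic <- manual_contour(circle_points(30, 30, 20, 72))
  phi <- init_levelset(ic, c(60, 60))
  expect_equal(phi[30, 30], 20, tolerance = 1.5)
  expect_equal(sum(phi > 0), pi * 20^2, tolerance = 0.03 * pi * 20^2)
  # |phi| small on the contour itself
  v <- circle_points(30, 30, 20, 36)
  expect_true(all(abs(phi[cbind(round(v[, 2]), round(v[, 1]))]) <= 1.5))

  # smallest polygon still yields both signs
  phi3 <- init_levelset(manual_contour(cbind(c(10, 16, 10), c(10, 10, 16))),
                        c(30, 30))
  expect_true(any(phi3 > 0) && any(phi3 < 0))

  expect_error(init_levelset(manual_contour(circle_points(5, 5, 20)),
                             c(30, 30)), "outside")
})

test_that("region means recover the phase values and obey symmetry", {
  tp <- two_phase_disk()
  phi <- mammoseg:::signed_distance(tp$mask)
  rm <- region_means(tp$img, phi, eps = 1e-3)
  expect_equal(rm$c1, 0.9, tolerance = 0.01)
  expect_equal(rm$c2, 0.2, tolerance = 0.01)

  flat <- matrix(0.4, 120, 120)
  rmf <- region_means(flat, phi, eps = 1)
  expect_equal(rmf$c1, 0.4)
  expect_equal(rmf$c2, 0.4)

  sw <- region_means(tp$img, -phi, eps = 1e-3)
  expect_equal(sw$c1, rm$c2)
  expect_equal(sw$c2, rm$c1)
})

test_that("Chan-Vese segments a two-phase disk from a loose init", {
  tp <- two_phase_disk()
  init <- manual_contour(circle_points(tp$cx, tp$cy, tp$r + 12, 72))
  phi0 <- init_levelset(init, dim(tp$img))
  res <- evolve_chan_vese(tp$img, phi0)
  mask <- mask_from_levelset(res$phi)
  expect_gte(jaccard(mask, tp$mask), 0.98)
  # recovered hard phase means
  expect_equal(mean(tp$img[mask > 0]), tp$hi, tolerance = 0.01)
  expect_equal(mean(tp$img[mask == 0]), tp$lo, tolerance = 0.01)
  # region-mean consistency at convergence (eps-induced tolerance)
  rm <- region_means(tp$img, res$phi, eps = 1)
  expect_equal(rm$c1, res$stats$c1, tolerance = 1e-6)
})

test_that("Chan-Vese with mu = 0 leaves the mask of a flat image unchanged", {
  flat <- matrix(0.5, 60, 60)
  phi0 <- init_levelset(manual_contour(circle_points(30, 30, 15, 72)),
                        c(60, 60))
  res <- evolve_chan_vese(flat, phi0,
                          chan_vese_params(mu = 0, max_iters = 80,
                                           reinit_every = 0))
  expect_identical(res$phi > 0, phi0 > 0)
})

test_that("region weights change the outcome on an inhomogeneous phantom", {
  set.seed(21)
  tp <- two_phase_disk(hi = 0.7)
  img <- pmin(pmax(tp$img + matrix(rnorm(120 * 120, 0, 0.08), 120, 120),
                   0), 1)
  phi0 <- init_levelset(manual_contour(circle_points(60, 60, 40, 72)),
                        dim(img))
  m1 <- mask_from_levelset(
    evolve_chan_vese(img, phi0,
                     chan_vese_params(lam1 = 2.5, max_iters = 150))$phi)
  m2 <- mask_from_levelset(
    evolve_chan_vese(img, phi0,
                     chan_vese_params(lam1 = 1, max_iters = 150))$phi)
  expect_gt(sum(m1 != m2), 0)
})

test_that("spf map is a signed normalized deviation from the mean of means", {
  img <- matrix(c(0, 1), 10, 10)
  stats <- structure(list(c1 = 1, c2 = 0), class = "region_stats")
  s <- spf_map(img, stats)
  expect_true(all(s[img == 1] == 1))
  expect_true(all(s[img == 0] == -1))

  set.seed(8)
  img2 <- matrix(runif(100), 10, 10)
  st2 <- structure(list(c1 = 0.81, c2 = 0.33), class = "region_stats")
  s2 <- spf_map(img2, st2)
  expect_equal(max(abs(s2)), 1)
  brute <- (img2 - 0.57) / max(abs(img2 - 0.57))
  expect_equal(s2, brute, tolerance = 1e-12)

  expect_error(spf_map(matrix(0.5, 5, 5),
                       structure(list(c1 = 0.5, c2 = 0.5),
                                 class = "region_stats")),
               "degenerate")
})

test_that("SBGFRLS segments the disk, grows from inside, is deterministic", {
  tp <- two_phase_disk()
  init_out <- manual_contour(circle_points(tp$cx, tp$cy, tp$r + 12, 72))
  phi0 <- init_levelset(init_out, dim(tp$img))
  res <- evolve_sbgfrls(tp$img, phi0)
  expect_gte(jaccard(mask_from_levelset(res$phi), tp$mask), 0.98)

  # starting strictly inside a bright disk, alpha > 0 grows the area
  init_in <- manual_contour(circle_points(tp$cx, tp$cy, 10, 72))
  phi_in <- init_levelset(init_in, dim(tp$img))
  res_in <- evolve_sbgfrls(tp$img, phi_in, spf_params(max_iters = 60))
  areas <- res_in$log$area
  expect_true(all(diff(areas[1:20]) >= 0))
  expect_gt(areas[length(areas)], areas[1])

  res2 <- evolve_sbgfrls(tp$img, phi0)
  expect_identical(res$phi, res2$phi)
})

test_that("mask extraction keeps the largest component and can fill holes", {
  phi <- matrix(-1, 40, 40)
  phi[5:10, 5:10] <- 1      # 36 px island
  phi[20:35, 20:35] <- 1    # 256 px island
  m <- mask_from_levelset(phi)
  expect_equal(sum(m), 256)
  expect_equal(sum(m[5:10, 5:10]), 0)

  ann <- disk_mask(60, 60, 30, 30, 20) - disk_mask(60, 60, 30, 30, 10)
  phi_ann <- ann * 2 - 1
  filled <- mask_from_levelset(phi_ann, fill_holes = TRUE)
  expect_equal(sum(filled), sum(disk_mask(60, 60, 30, 30, 20)))

  expect_error(mask_from_levelset(matrix(-1, 10, 10)), "empty")
})
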