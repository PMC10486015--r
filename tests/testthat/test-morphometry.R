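test_that("phase volumes follow voxel-count arithmetic", {
  n <- 50
  mineral <- array(TRUE, c(n, n, n))
  lac <- array(0L, dim(mineral))
  masks <- phase_masks(mineral, array(FALSE, dim(mineral)), lac, 1)
  pv <- phase_volumes(masks)
  expect_equal(pv$TV_mm3, n^3 * 1e-9)
  expect_equal(pv$BV_mm3, pv$TV_mm3)
  expect_equal(pv$vessel_porosity_pct, 0)
  # 50 vessel voxels at 2.27 um
  vessel <- array(FALSE, c(20, 20, 20))
  vessel[1:50] <- TRUE
  min2 <- array(TRUE, dim(vessel)) & !vessel
  m2 <- phase_masks(min2, vessel, array(0L, dim(vessel)), 2.27)
  pv2 <- phase_volumes(m2)
  expect_equal(pv2$VV_um3, 50 * 2.27^3)
  expect_equal(pv2$vessel_porosity_pct, 100 * 50 / (8000 - 50))
})

test_that("phantom vessel porosity is recovered within 15 percent", {
  p <- small_phantom(seed = 33, n = 128, vessels = 2)
  seg <- segment_phases(p$volume)
  pv <- phase_volumes(seg$masks)
  truth <- 100 * p$truth$true_vessel_porosity
  expect_lt(abs(pv$vessel_porosity_pct - truth) / truth, 0.15)
})

test_that("cumulative distances of a uniform slab hit 50 and 95 percent", {
  nx <- 102
  src <- array(FALSE, c(nx, 8, 8))
  ref <- array(FALSE, c(nx, 8, 8))
  ref[1, , ] <- TRUE                          # planar vessel face
  src[2:101, , ] <- TRUE                      # mineral at distances 1..100
  d <- cumulative_distance(src, ref, c(0.5, 0.95, 1), 1)
  expect_equal(unname(d[1]), 50, tolerance = 1.01)
  expect_equal(unname(d[2]), 95, tolerance = 1.01)
  expect_equal(unname(d[3]), 100)             # f = 1 is the maximum
})

test_that("hollow-cylinder median distance matches the analytic value", {
  a <- 10; b <- 40
  n <- 2 * b + 7
  cx <- (n + 1) / 2
  r <- sqrt(outer((1:n - cx)^2, (1:n - cx)^2, "+"))
  canal <- array(rep(r <= a, 8), c(n, n, 8))
  annulus <- array(rep(r > a & r <= b, 8), c(n, n, 8))
  d <- cumulative_distance(annulus, canal, 0.5, 1)
  # volume-weighted median of (r - a): m = sqrt((a^2 + b^2) / 2) - a
  analytic <- sqrt((a^2 + b^2) / 2) - a
  expect_equal(unname(d), analytic, tolerance = 1.5 / analytic)
})

test_that("cumulative distance is monotone in f and scales with geometry", {
  p <- small_phantom(seed = 35, n = 72, vessels = 2, density = 0)
  m <- p$truth$masks
  fr <- c(0.25, 0.5, 0.75, 0.95, 1)
  d1 <- cumulative_distance(m$mineral, m$vessel, fr, 0.64)
  expect_true(all(diff(d1) >= 0))
  d2 <- cumulative_distance(m$mineral, m$vessel, fr, 1.28)
  expect_equal(unname(d2), unname(2 * d1))
  expect_error(cumulative_distance(m$mineral, array(FALSE, dim(m$mineral)),
                                   0.5, 1), "empty reference")
  expect_error(cumulative_distance(m$mineral, m$vessel, c(0, 0.5), 1),
               "fractions")
})

test_that("surface area estimator matches closed forms", {
  ball <- digital_ball(20, 1)
  expect_equal(surface_area(ball, 1), 4 * pi * 400, tolerance = 0.05)
  ball2 <- digital_ball(20, 0.8)              # finer grid converges too
  expect_equal(surface_area(ball2, 0.8), 4 * pi * 400, tolerance = 0.05)
  cube <- array(FALSE, c(20, 20, 20))
  cube[6:15, 6:15, 6:15] <- TRUE              # 10 um cube at 1 um voxels
  sa_cube <- surface_area(cube, 1)
  expect_lte(sa_cube, 600)
  expect_gte(sa_cube, pi / 6 * 600)
  expect_equal(surface_area(array(FALSE, c(8, 8, 8)), 1), 0)
})

test_that("tube SA/VV approximates 2/r and decreases with radius", {
  # reflective boundary handling continues the tube through the end faces,
  # so the estimator measures the lateral (cylinder) surface: SA/VV = 2/r
  ratios <- vapply(c(8, 10, 12), function(r_vox) {
    tube <- digital_tube(r_vox, nz = 30)
    surface_area(tube, 1) / sum(tube)
  }, 0)
  expect_equal(ratios, 2 / c(8, 10, 12), tolerance = 0.08)
  expect_true(all(diff(ratios) < 0))
})

test_that("compile_report on truth masks reproduces the true density exactly", {
  p <- small_phantom(seed = 37, n = 96)
  rep <- compile_report(p$truth$masks, p$truth$lacuna_records,
                        sample_id = "truth", site = "phantom")
  expect_identical(rep$NLc_per_mm3, p$truth$true_density_per_mm3)
  expect_equal(rep$vessel_porosity_pct, 100 * p$truth$true_vessel_porosity)
  expect_gte(rep$L_dist_min95_um, rep$L_dist_min50_um)
  expect_gte(rep$L_dist_vessel95_um, rep$L_dist_vessel50_um)
  expect_true(is.na(rep$LOA))                 # no orientation summary given
  expect_true(is.na(rep$ratio_EV_mean))       # no permeability run
  expect_gte(rep$TV_mm3, rep$BV_mm3)
})

test_that("reports without a vessel phase flag the distances as missing", {
  p <- generate_phantom(phantom_spec(c(48, 48, 48), vessel_count = 0,
                                     lacunar_density_per_mm3 = 20000,
                                     seed = 39))
  rep <- compile_report(p$truth$masks, p$truth$lacuna_records)
  expect_true(is.na(rep$L_dist_min50_um))
  expect_true(is.na(rep$SA_VV_per_mm))
  expect_gt(rep$NLc_per_mm3, 0)
})
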