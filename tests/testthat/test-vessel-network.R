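test_that("a straight tube skeletonizes to one segment of the tube length", {
  vox <- 2
  tube <- digital_tube(5, nz = 60)
  g <- skeletonize_vessels(tube, vox)
  expect_equal(nrow(g$segments), 1)
  true_len <- (60 - 1) * vox
  expect_lt(abs(g$segments$length_um - true_len), 5)
  expect_equal(g$segments$phi_deg, 0)
  expect_true(is.na(g$segments$theta_deg))
  # thickness ~ tube diameter
  expect_equal(g$segments$mean_thickness_um, 2 * 5 * vox, tolerance = 0.25)
  # homotopy: a simple tube has no loops, the skeleton is one open curve
  expect_equal(g$n_nodes, 2)
})

test_that("two tubes meeting in a T give three segments and one junction", {
  m <- array(FALSE, c(41, 21, 41))
  cy <- 11
  for (i in 1:41) for (j in (cy - 3):(cy + 3)) for (k in 19:25)
    if ((j - cy)^2 + (k - 22)^2 <= 9) m[i, j, k] <- TRUE
  for (k in 22:41) for (i in 18:24) for (j in (cy - 3):(cy + 3))
    if ((i - 21)^2 + (j - cy)^2 <= 9) m[i, j, k] <- TRUE
  g <- skeletonize_vessels(m, 1)
  expect_equal(nrow(g$segments), 3)
  junctions <- g$n_nodes - sum(g$segments$cord_length_um >= 0) # ends counted
  expect_gte(g$n_nodes, 4)                    # 3 ends + 1 junction cluster
  expect_lte(g$n_nodes, 5)
})

test_that("segment angles follow the axis conventions", {
  expect_equal(unname(segment_angles(c(0, 0, 1))["phi_deg"]), 0)
  expect_true(is.na(segment_angles(c(0, 0, 1))["theta_deg"]))
  expect_equal(unname(segment_angles(c(1, 0, 0))), c(90, 0))
  expect_equal(unname(segment_angles(c(1, 1, 0))), c(90, 45))
  expect_equal(unname(segment_angles(c(0, 1, 0))), c(90, 90))
  expect_true(all(is.na(segment_angles(c(0, 0, 0)))))
  # undirected: sign flips change nothing
  expect_equal(segment_angles(c(1, -2, 3)), segment_angles(c(-1, 2, -3)))
})

test_that("histogram amplitudes sum to one and variances follow closed forms", {
  segs <- data.frame(phi_deg = seq(1.25, 88.75, by = 2.5),
                     theta_deg = seq(1.25, 88.75, by = 2.5),
                     length_um = rep(10, 36), volume_um3 = rep(5, 36))
  for (w in c("length", "volume", "count")) {
    s <- orientation_histogram(segs, w, 36)
    expect_equal(sum(s$hist_phi), 1, tolerance = 1e-9)
    expect_equal(sum(s$hist_theta), 1, tolerance = 1e-9)
    # perfectly uniform orientations: zero variance, LOA = 0
    expect_equal(s$s_phi, 0)
    expect_equal(s$LOA, 0)
  }
  one <- data.frame(phi_deg = rep(10, 5), theta_deg = rep(80, 5),
                    length_um = 1:5, volume_um3 = 1:5)
  s1 <- orientation_histogram(one, "length", 36)
  expect_equal(s1$s_phi, 35 / 1296, tolerance = 1e-12)
  expect_equal(s1$s_theta, 35 / 1296, tolerance = 1e-12)
  expect_equal(s1$LOA, (35 / 1296)^2, tolerance = 1e-12)
  expect_error(orientation_histogram(one, "length", 1), "n_bins")
})

test_that("LOA products and FB/AB ratios match the reference rows", {
  expect_equal(round(5.17e-3 * 10.29e-3 * 1e5, 2), 5.32)
  s_ab <- structure(list(LOA = 5.32e-5), class = "orientation_summary")
  s_fb <- structure(list(LOA = 0.70e-5), class = "orientation_summary")
  expect_equal(round(loa_ratio(s_fb, s_ab), 2), 0.13)
  expect_equal(round(loa_ratio(2.74e-5, 1.01e-5), 2), 2.71)
  expect_equal(loa_ratio(s_ab, s_ab), 1)
  expect_error(loa_ratio(1e-5, 0), "positive")
})

test_that("rotating the volume 90 deg about z keeps phi and flips theta", {
  # three disjoint straight tubes along x, z and the xy diagonal
  n <- 40L
  v <- array(FALSE, c(n, n, n))
  add_tube <- function(m, a, b, r = 2) {
    co <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
    ab <- b - a
    rel <- sweep(co, 2, a)
    tt <- pmin(1, pmax(0, as.vector(rel %*% ab) / sum(ab^2)))
    d2 <- rowSums((rel - outer(tt, ab))^2)
    m[co[d2 <= r^2, , drop = FALSE]] <- TRUE
    m
  }
  v <- add_tube(v, c(3, 8, 8), c(38, 8, 8))       # along x
  v <- add_tube(v, c(30, 30, 3), c(30, 30, 38))   # along z
  v <- add_tube(v, c(4, 14, 30), c(24, 34, 30))   # xy diagonal
  g1 <- skeletonize_vessels(v, 1)
  # rotate +90 deg about z: new[i, j, k] = old[j, n + 1 - i, k]
  vr <- aperm(v, c(2, 1, 3))[, n:1, , drop = FALSE]
  g2 <- skeletonize_vessels(vr, 1)
  expect_equal(nrow(g1$segments), 3)
  expect_equal(nrow(g2$segments), 3)
  expect_equal(sort(g1$segments$phi_deg), sort(g2$segments$phi_deg),
               tolerance = 1e-6)
  th1 <- sort(g1$segments$theta_deg[!is.na(g1$segments$theta_deg)])
  th2 <- sort(90 - g2$segments$theta_deg[!is.na(g2$segments$theta_deg)])
  expect_equal(th1, th2, tolerance = 1e-6)
})

test_that("tube-count phantoms yield about one segment per tube", {
  p <- generate_phantom(phantom_spec(c(64, 64, 96), voxel_size_um = 2.27,
                                     vessel_count = 10,
                                     vessel_orientation_kappa = 50,
                                     vessel_radius_um = c(6, 1),
                                     lacunar_density_per_mm3 = 0, seed = 13))
  g <- skeletonize_vessels(p$truth$masks$vessel, 2.27)
  n_tubes <- length(p$truth$vessel_centerlines)
  # main segments (those of appreciable length); merges at crossings allowed
  main <- sum(g$segments$length_um > 20)
  expect_gte(main, ceiling(0.6 * n_tubes))
  expect_lte(nrow(g$segments), 3 * n_tubes)
})

test_that("an aligned phantom has a larger LOA than an isotropic one", {
  mk <- function(kappa, seed) {
    p <- generate_phantom(phantom_spec(c(72, 72, 72), voxel_size_um = 2.27,
                                       vessel_count = 10,
                                       vessel_orientation_kappa = kappa,
                                       vessel_radius_um = c(8, 2),
                                       lacunar_density_per_mm3 = 0,
                                       seed = seed))
    g <- skeletonize_vessels(p$truth$masks$vessel, 2.27)
    orientation_histogram(g, "length")$LOA
  }
  expect_gt(mk(50, 7), mk(0, 7))
})
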