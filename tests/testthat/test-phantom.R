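test_that("identical spec and seed give bit-identical volumes", {
  sp <- phantom_spec(c(48, 48, 48), voxel_size_um = 2.27, vessel_count = 3,
                     lacunar_density_per_mm3 = 20000, seed = 2)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$lacuna_records, b$truth$lacuna_records)
})

test_that("a phantom without pores is pure mineral plus noise", {
  sp <- phantom_spec(c(32, 32, 32), voxel_size_um = 2.27, vessel_count = 0,
                     lacunar_density_per_mm3 = 0, seed = 3)
  p <- generate_phantom(sp)
  expect_true(all(p$truth$masks$mineral))
  expect_false(any(p$truth$masks$vessel))
  expect_equal(max(p$truth$masks$lacunae), 0L)
  expect_equal(mean(p$volume$data), 200, tolerance = 0.01)
  expect_equal(sd(as.vector(p$volume$data)), 10, tolerance = 0.1)
})

test_that("realized lacuna counts follow the Poisson law of the density", {
  # oracle: the count is Poisson with mean density x mineral volume; any
  # realization must fall within +/- 4 sqrt(mean) of the mean
  density <- 20000
  counts <- vapply(1:4, function(s) {
    p <- generate_phantom(phantom_spec(c(96, 96, 96), voxel_size_um = 2.27,
                                       vessel_count = 2,
                                       lacunar_density_per_mm3 = density,
                                       seed = s), rasterize = FALSE)
    nrow(p$truth$lacuna_records)
  }, 0)
  box_mm3 <- (96 * 2.27e-3)^3
  mu <- density * box_mm3                     # vessels occupy a few percent
  expect_true(all(abs(counts - mu) < 4 * sqrt(mu) + 0.1 * mu))
  # direct Poisson simulation brackets the same interval
  sim <- rpois(2000, mu)
  expect_gt(mean(counts >= min(sim) & counts <= max(sim)), 0.9)
})

test_that("kappa = 50 concentrates tube directions about +z", {
  p <- generate_phantom(phantom_spec(c(64, 64, 220), voxel_size_um = 2.27,
                                     vessel_count = 30,
                                     vessel_orientation_kappa = 50,
                                     lacunar_density_per_mm3 = 0, seed = 9),
                        rasterize = FALSE)
  angs <- vapply(p$truth$geometry$tubes, function(tb) {
    d <- tb$direction
    acos(abs(d[3]) / sqrt(sum(d^2))) * 180 / pi
  }, 0)
  expect_gte(mean(angs <= 25), 0.9)
  # oracle: direct sampling of the direction distribution
  set.seed(1)
  d <- cortmorph:::sample_axis_vmf(5000, 50)
  oracle <- acos(pmin(1, abs(d[, 3]))) * 180 / pi
  expect_gte(mean(oracle <= 25), 0.9)
})

test_that("ground-truth vessel porosity equals the voxel-count ratio exactly", {
  p <- small_phantom(seed = 17, n = 96, density = 15000)
  m <- p$truth$masks
  expect_identical(p$truth$true_vessel_porosity, sum(m$vessel) / sum(m$mineral))
  expect_identical(p$truth$true_density_per_mm3,
                   nrow(p$truth$lacuna_records) /
                     (sum(m$mineral) * 0.64^3 * 1e-9))
})

test_that("phantom_to_table reports geometric truth", {
  p <- generate_phantom(phantom_spec(c(96, 96, 96), voxel_size_um = 1.5,
                                     vessel_count = 2,
                                     lacunar_density_per_mm3 = 25000,
                                     seed = 12))
  tab <- phantom_to_table(p$truth)
  expect_equal(tab$true_density_per_mm3,
               tab$n_lacunae / (sum(p$truth$masks$mineral) * 1.5^3 * 1e-9))
  expect_equal(tab$mean_r13, 3.0, tolerance = 0.25)
  expect_equal(tab$mean_r23, 1.4, tolerance = 0.12)
  empty <- generate_phantom(phantom_spec(c(32, 32, 32), vessel_count = 0,
                                         lacunar_density_per_mm3 = 0,
                                         seed = 1))
  etab <- phantom_to_table(empty$truth)
  expect_equal(etab$true_density_per_mm3, 0)
  expect_true(etab$shape_missing)
  expect_true(is.na(etab$mean_lacuna_volume_um3))
})

test_that("infeasible lacunar densities are rejected up front", {
  sp <- phantom_spec(c(32, 32, 32), lacunar_density_per_mm3 = 5e8, seed = 1)
  expect_error(generate_phantom(sp), "infeasible")
})

test_that("mineral must be the bright phase", {
  expect_error(phantom_spec(c(32, 32, 32), intensity_levels = c(50, 200, 5)),
               "bright")
})

test_that("re-rasterizing at another voxel size keeps the same specimen", {
  p <- generate_phantom(phantom_spec(c(48, 48, 48), voxel_size_um = 2.27,
                                     vessel_count = 2,
                                     lacunar_density_per_mm3 = 22000,
                                     seed = 6))
  q <- rasterize_phantom(p, 1.2)
  expect_identical(p$truth$lacuna_records, q$truth$lacuna_records)
  expect_equal(q$truth$voxel_size_um, 1.2)
  # rasterized porosity converges to the same physical quantity
  expect_equal(q$truth$true_vessel_porosity, p$truth$true_vessel_porosity,
               tolerance = 0.1)
})
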