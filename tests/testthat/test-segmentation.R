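test_that("binarization separates a two-level volume at a sane threshold", {
  a <- array(10, c(12, 12, 12))
  a[5:8, 5:8, 5:8] <- 100
  v <- volume_image(a, 1)
  b <- binarize(v)
  expect_gt(attr(b, "threshold"), 10)
  expect_lt(attr(b, "threshold"), 100)
  expect_equal(sum(b), 64)
  expect_true(all(b[5:8, 5:8, 5:8]))
})

test_that("degenerate binarization inputs are handled per contract", {
  flat <- volume_image(array(7, c(8, 8, 8)), 1)
  expect_error(binarize(flat), "degenerate")
  v <- volume_image(array(runif(8^3, 0, 50), c(8, 8, 8)), 1)
  expect_warning(binarize(v, "fixed", threshold = 51), "empty")
  expect_error(binarize(v, "fixed"), "required")
})

test_that("phantom binarization misclassifies under 1 percent of voxels", {
  sp <- phantom_spec(c(96, 96, 96), voxel_size_um = 2.27, vessel_count = 3,
                     lacunar_density_per_mm3 = 15000,
                     intensity_levels = c(200, 50, 5), seed = 8)
  p <- generate_phantom(sp)
  b <- binarize(p$volume)
  mis <- mean(xor(array(as.logical(b), dim(b)), p$truth$masks$mineral))
  expect_lt(mis, 0.01)
})

test_that("closing fills cavities below the radius threshold", {
  cube <- array(TRUE, c(40, 40, 40))
  ball <- digital_ball(10, 1)                 # radius 10 um cavity
  off <- (40 - dim(ball)[1]) %/% 2
  idx <- seq_len(dim(ball)[1]) + off
  cube[idx, idx, idx][ball] <- FALSE
  closed <- close_mineral_mask(cube, 20, 1)
  expect_true(all(closed))
  # a through-going canal narrower than the radius is filled too
  block <- array(TRUE, c(40, 40, 40))
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 100) block[i, j, ] <- FALSE
  closed2 <- close_mineral_mask(block, 40, 2)  # 20 um canal, 40 um radius
  expect_true(all(closed2))
  empty <- array(FALSE, c(8, 8, 8))
  expect_equal(close_mineral_mask(empty, 10, 1), empty)
  expect_error(close_mineral_mask(cube, 0, 1), "positive")
})

test_that("distance-map closing agrees with brute-force ball closing", {
  set.seed(4)
  m <- array(FALSE, c(40, 40, 40))
  m[8:32, 8:32, 8:32] <- TRUE
  m[15:20, 15:20, 15:20] <- FALSE            # internal cavity
  m[25:27, 10:30, 10:30] <- FALSE            # slab-shaped pore
  r <- 4                                      # voxels
  # oracle: explicit ball-offset dilation then erosion
  ball_off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  ball_off <- ball_off[rowSums(ball_off^2) <= r^2, ]
  shift_union <- function(x, offs, combine) {
    out <- array(!combine, dim(x))
    n <- dim(x)
    for (t in seq_len(nrow(offs))) {
      sx <- pmin(pmax(1, (1:n[1]) + offs[t, 1]), n[1])
      sy <- pmin(pmax(1, (1:n[2]) + offs[t, 2]), n[2])
      sz <- pmin(pmax(1, (1:n[3]) + offs[t, 3]), n[3])
      shifted <- x[sx, sy, sz]
      out <- if (combine) out | shifted else out & shifted
    }
    out
  }
  dil <- shift_union(m, ball_off, TRUE)
  ero <- shift_union(dil, ball_off, FALSE)
  oracle <- ero | m
  ours <- close_mineral_mask(m, r, 1)
  # agree away from the volume faces (boundary handling differs)
  core <- 6:35
  agree <- mean(ours[core, core, core] == oracle[core, core, core])
  expect_gt(agree, 0.98)
  expect_true(all(ours[m]))                   # superset of the input
})

test_that("vessel extraction separates canal-scale from lacuna-scale pores", {
  vox <- 2
  binm <- array(TRUE, c(48, 48, 48))
  for (i in 1:48) for (j in 1:48)
    if ((i - 14)^2 + (j - 14)^2 <= 25) binm[i, j, ] <- FALSE  # canal
  binm[34:37, 34:37, 34:37] <- FALSE          # 64 voxels = 512 um^3 cavity
  mineral <- array(TRUE, dim(binm))
  vm <- extract_vessel_mask(binm, mineral, vox)
  expect_true(all(vm[12, 12, ]))              # canal recovered
  expect_false(any(vm[34:37, 34:37, 34:37])) # lacuna-scale cavity excluded
  # no pores at all
  expect_false(any(extract_vessel_mask(mineral, mineral, vox)))
  expect_error(extract_vessel_mask(mineral, binm, vox), "contain")
})

test_that("vessel mask recovery on a phantom reaches Jaccard 0.8", {
  p <- small_phantom(seed = 19, n = 128, vessels = 2, density = 10000)
  seg <- segment_phases(p$volume)
  tv <- p$truth$masks$vessel
  sv <- seg$masks$vessel
  jac <- sum(tv & sv) / sum(tv | sv)
  expect_gte(jac, 0.8)
})

test_that("the lacuna filter enforces the volume and length/width bounds", {
  params <- lacuna_filter_params()
  stats <- data.frame(
    volume_um3 = c(20, 500, 2000, 30, 8000, 8001),
    L1_um = c(5, 20, 150, 6, 40, 40),
    L2_um = c(3, 8, 10, 4, 20, 20))
  keep <- cortmorph:::lacuna_filter_keep(stats, params)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  # width rule
  wide <- data.frame(volume_um3 = 4000, L1_um = 60, L2_um = 35)
  expect_false(cortmorph:::lacuna_filter_keep(wide, params))
  # idempotence: filtering a filtered set changes nothing
  kept <- stats[keep, ]
  expect_true(all(cortmorph:::lacuna_filter_keep(kept, params)))
})

test_that("extract_lacunae finds dark blobs and applies the filter", {
  vox <- 1
  a <- array(200, c(64, 64, 64))
  ell <- digital_ellipsoid(10, 5, 4, vox)     # ~800 um^3, kept
  d <- dim(ell)
  a[10 + seq_len(d[1]), 10 + seq_len(d[2]), 10 + seq_len(d[3])][ell] <- 50
  a[50:51, 50, 50] <- 50                      # 2 um^3 speck, rejected
  v <- volume_image(a + array(rnorm(64^3, 0, 5), dim(a)), vox)
  v$data <- cortmorph:::gaussian_blur(v$data, 1)
  res <- extract_lacunae(v, array(TRUE, dim(a)), bottomhat_radius_um = 12)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$volume_um3, 4 / 3 * pi * 10 * 5 * 4,
               tolerance = 0.25)
  expect_equal(res$records$r13, 10 / 4, tolerance = 0.2)
  expect_error(extract_lacunae(v, array(TRUE, dim(a)),
                               bottomhat_radius_um = 0.5), "voxel")
})

test_that("segment_phases produces disjoint phases with consecutive labels", {
  p <- small_phantom(seed = 23, n = 96)
  seg <- segment_phases(p$volume)
  m <- seg$masks
  expect_false(any(m$mineral & m$vessel))
  expect_false(any(m$mineral & m$lacunae > 0L))
  expect_false(any(m$vessel & m$lacunae > 0L))
  ids <- sort(unique(m$lacunae[m$lacunae > 0L]))
  expect_identical(as.integer(ids), seq_along(ids))
  expect_equal(max(0L, max(m$lacunae)), nrow(seg$lacuna_records))
})

test_that("lacuna counts are recovered within 10 percent on a phantom", {
  p <- small_phantom(seed = 29, n = 128)
  seg <- segment_phases(p$volume)
  n_true <- nrow(p$truth$lacuna_records)
  expect_gt(n_true, 5)
  expect_lt(abs(nrow(seg$lacuna_records) - n_true) / n_true, 0.10)
})
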