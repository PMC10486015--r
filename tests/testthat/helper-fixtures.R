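# Digital solids and small phantom factories shared across the suite.

# logical mask of a ball of radius r_um centred in a cube, voxel centres at
# (i - 1) * vox
digital_ball <- function(r_um, vox, pad = 3L) {
  n <- 2L * ceiling(r_um / vox) + 2L * pad + 1L
  c0 <- ((n + 1) / 2 - 1) * vox
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  d2 <- ((g$i - 1) * vox - c0)^2 + ((g$j - 1) * vox - c0)^2 +
    ((g$k - 1) * vox - c0)^2
  array(d2 <= r_um^2, c(n, n, n))
}

# axis-aligned digital ellipsoid with semi-axes (a, b, c) um
digital_ellipsoid <- function(a, b, c, vox, pad = 3L) {
  nx <- 2L * ceiling(a / vox) + 2L * pad + 1L
  ny <- 2L * ceiling(b / vox) + 2L * pad + 1L
  nz <- 2L * ceiling(c / vox) + 2L * pad + 1L
  cx <- ((nx + 1) / 2 - 1) * vox
  cy <- ((ny + 1) / 2 - 1) * vox
  cz <- ((nz + 1) / 2 - 1) * vox
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  q <- (((g$i - 1) * vox - cx) / a)^2 + (((g$j - 1) * vox - cy) / b)^2 +
    (((g$k - 1) * vox - cz) / c)^2
  array(q <= 1, c(nx, ny, nz))
}

# straight z-axis tube of radius r_vox voxels in an nx x ny x nz grid
digital_tube <- function(r_vox, nx = 2L * r_vox + 5L, ny = nx, nz = 40L) {
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  sl <- outer(seq_len(nx) - cx, seq_len(ny) - cy,
              function(a, b) a^2 + b^2 <= r_vox^2)
  array(rep(sl, nz), c(nx, ny, nz))
}

# small standard phantom used by several segmentation/morphometry tests
small_phantom <- function(seed = 11, n = 160, vox = 0.64,
                          density = 22000, vessels = 2) {
  generate_phantom(phantom_spec(rep(n, 3), voxel_size_um = vox,
                                vessel_count = vessels,
                                vessel_radius_um = c(15, 3),
                                lacunar_density_per_mm3 = density,
                                seed = seed))
}
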