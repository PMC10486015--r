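#' Specification of a synthetic cortical-bone phantom
#'
#' The phantom emulates a mineralized cortical matrix containing (a) a network
#' of tubular vessel pores whose directions concentrate around the anatomical
#' long axis (`+z`) with tunable concentration `kappa`, and (b) ellipsoidal
#' osteocyte lacunae with log-normal volumes and prescribed principal-axis
#' ratios, followed by Gaussian blur and additive Gaussian noise emulating
#' detector blur and photon noise. Defaults reflect human cortical bone:
#' canal radii of a few tens of micrometres, lacunar densities around
#' 22,000 per mm^3, lacunar volumes of roughly 30-8,000 um^3 with mean near
#' 600 um^3 and axis ratios L1/L3 of about 3 and L2/L3 of about 1.4.
#'
#' All geometry is drawn in physical units before any rasterization, so the
#' same `seed` yields the same continuous specimen at any voxel size; this is
#' what makes cross-resolution comparisons on "the same" phantom meaningful.
#'
#' @param shape integer triple, volume extent in voxels.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param vessel_count number of vessel tubes.
#' @param vessel_radius_um length-2 vector `(mean, sd)` of tube radii (um),
#'   truncated below at 5 um.
#' @param vessel_orientation_kappa concentration (>= 0) of the axial
#'   von Mises-Fisher direction distribution about `+z`; 0 is isotropic.
#' @param lacunar_density_per_mm3 expected lacuna count per mm^3 of mineral.
#' @param lacuna_volume_um3 length-2 vector `(log_mean, log_sd)` of the
#'   log-normal lacuna volume distribution, truncated to `[30, 8000]` um^3.
#' @param lacuna_axis_ratios length-2 vector of mean `(L1/L3, L2/L3)` ratios.
#' @param lacuna_ratio_sd length-2 vector of SDs for the two ratios.
#' @param lacuna_orientation_kappa concentration of the lacuna long-axis
#'   distribution about `+z`; defaults to `vessel_orientation_kappa`.
#' @param intensity_levels length-3 vector `(mineral_mean, pore_mean,
#'   noise_sd)` of grayscale levels; mineral must be the bright phase.
#' @param blur_sigma_um Gaussian blur sigma in micrometres (>= 0), the
#'   point-spread width of the emulated imaging setup. The default `NULL`
#'   means one voxel of the rasterization grid: detector resolution tracks
#'   the voxel size of the scan setup, and a sub-voxel point spread would be
#'   unphysical. Re-voxelizing the same specimen at a finer grid
#'   (see [rasterize_phantom()]) then also images it more sharply, as a finer
#'   scan setup does.
#' @param seed integer RNG seed; identical spec + seed gives an identical
#'   volume.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape,
                         voxel_size_um = 2.27,
                         vessel_count = 10,
                         vessel_radius_um = c(20, 5),
                         vessel_orientation_kappa = 20,
                         lacunar_density_per_mm3 = 22000,
                         lacuna_volume_um3 = c(log(450), 0.6),
                         lacuna_axis_ratios = c(3.0, 1.4),
                         lacuna_ratio_sd = c(0.8, 0.25),
                         lacuna_orientation_kappa = NULL,
                         intensity_levels = c(200, 50, 10),
                         blur_sigma_um = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L), voxel_size_um > 0,
            vessel_count >= 0, vessel_orientation_kappa >= 0,
            lacunar_density_per_mm3 >= 0,
            is.null(blur_sigma_um) || blur_sigma_um >= 0,
            length(intensity_levels) == 3L)
  if (intensity_levels[1] <= intensity_levels[2])
    stop("mineral must be the bright phase: mineral_mean > pore_mean",
         call. = FALSE)
  if (is.null(lacuna_orientation_kappa))
    lacuna_orientation_kappa <- vessel_orientation_kappa
  structure(list(
    shape = shape, voxel_size_um = voxel_size_um,
    vessel_count = as.integer(vessel_count),
    vessel_radius_um = vessel_radius_um,
    vessel_orientation_kappa = vessel_orientation_kappa,
    lacunar_density_per_mm3 = lacunar_density_per_mm3,
    lacuna_volume_um3 = lacuna_volume_um3,
    lacuna_volume_bounds_um3 = c(30, 8000),
    lacuna_axis_ratios = lacuna_axis_ratios,
    lacuna_ratio_sd = lacuna_ratio_sd,
    lacuna_orientation_kappa = lacuna_orientation_kappa,
    intensity_levels = intensity_levels,
    blur_sigma_um = blur_sigma_um,
    seed = as.integer(seed)), class = "phantom_spec")
}

# axial von Mises-Fisher sample about +z; rows are unit vectors with dz >= 0
sample_axis_vmf <- function(n, kappa) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (kappa < 1e-8) {
    w <- runif(n, -1, 1)
  } else {
    u <- runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  ang <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  d <- cbind(s * cos(ang), s * sin(ang), w)
  flip <- d[, 3] < 0
  d[flip, ] <- -d[flip, ]
  d
}

# entry/exit parameters of the line p0 + t*d through the box [0, L]
line_box_span <- function(p0, d, L) {
  t0 <- -Inf; t1 <- Inf
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) {
      if (p0[ax] < 0 || p0[ax] > L[ax]) return(NULL)
    } else {
      ta <- (0 - p0[ax]) / d[ax]
      tb <- (L[ax] - p0[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  tt <- sum((p - a) * ab) / sum(ab * ab)
  tt <- min(1, max(0, tt))
  sqrt(sum((p - a - tt * ab)^2))
}

#' Generate a synthetic bone phantom with ground truth
#'
#' Draws the vessel tubes and lacuna ellipsoids prescribed by the spec, carves
#' them out of a bright mineral matrix at pore intensity, applies Gaussian
#' blur and additive noise, and returns both the grayscale volume and the
#' pre-noise ground truth (phase masks, per-lacuna records, vessel
#' centerlines, true density and porosity). Lacunae are resampled when they
#' would intersect a vessel lumen or another lacuna.
#'
#' @param spec a [phantom_spec].
#' @param rasterize if `FALSE`, skip voxelization and return geometry-only
#'   truth (no volume, no masks); useful when only centerline/record
#'   statistics are needed.
#' @return a list with elements `volume` (a [volume_image], `NULL` when
#'   `rasterize = FALSE`) and `truth` (class `phantom_truth`).
#' @examples
#' p <- generate_phantom(phantom_spec(c(32, 32, 32), voxel_size_um = 4,
#'                                    vessel_count = 1,
#'                                    lacunar_density_per_mm3 = 0, seed = 7))
#' p$truth$true_vessel_porosity
#' @export
generate_phantom <- function(spec, rasterize = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec, rasterize))
}

generate_phantom_impl <- function(spec, rasterize) {
  vox <- spec$voxel_size_um
  L <- spec$shape * vox                      # physical box, um
  TV_um3 <- prod(L)

  # ---- vessels (physical geometry) ----
  dirs <- sample_axis_vmf(spec$vessel_count, spec$vessel_orientation_kappa)
  tubes <- list()
  vessel_vol_um3 <- 0
  for (t in seq_len(spec$vessel_count)) {
    p0 <- runif(3) * L
    r <- max(5, rnorm(1, spec$vessel_radius_um[1], spec$vessel_radius_um[2]))
    span <- line_box_span(p0, dirs[t, ], L)
    if (is.null(span)) next
    a <- p0 + span[1] * dirs[t, ]
    b <- p0 + span[2] * dirs[t, ]
    tubes[[length(tubes) + 1L]] <-
      list(a = a, b = b, radius = r, direction = dirs[t, ],
           length_um = span[2] - span[1])
    vessel_vol_um3 <- vessel_vol_um3 + pi * r^2 * (span[2] - span[1])
  }
  vessel_vol_um3 <- min(vessel_vol_um3, 0.5 * TV_um3)
  mineral_um3_analytic <- TV_um3 - vessel_vol_um3
  mineral_mm3_analytic <- mineral_um3_analytic * 1e-9

  # ---- lacunae (physical geometry) ----
  meanlog <- spec$lacuna_volume_um3[1]
  sdlog <- spec$lacuna_volume_um3[2]
  vb <- spec$lacuna_volume_bounds_um3
  exp_vol <- exp(meanlog + sdlog^2 / 2)
  if (spec$lacunar_density_per_mm3 * exp_vol * 1e-9 > 0.2)
    stop("infeasible phantom: requested lacunar density implies > 20% of the mineral volume occupied by lacunae",
         call. = FALSE)
  n_lac <- if (spec$lacunar_density_per_mm3 > 0)
    rpois(1, spec$lacunar_density_per_mm3 * mineral_mm3_analytic) else 0L

  lac <- list()
  if (n_lac > 0) {
    e1s <- sample_axis_vmf(n_lac, spec$lacuna_orientation_kappa)
    cents <- matrix(NA_real_, 0, 3)
    radii_a <- numeric(0)
    for (i in seq_len(n_lac)) {
      V <- NA_real_
      for (try in 1:100) {
        V <- exp(rnorm(1, meanlog, sdlog))
        if (V >= vb[1] && V <= vb[2]) break
      }
      V <- min(max(V, vb[1]), vb[2])
      r23 <- max(1.01, rnorm(1, spec$lacuna_axis_ratios[2],
                             spec$lacuna_ratio_sd[2]))
      r13 <- max(r23, rnorm(1, spec$lacuna_axis_ratios[1],
                            spec$lacuna_ratio_sd[1]))
      cc <- (3 * V / (4 * pi * r13 * r23))^(1/3)
      aa <- r13 * cc
      bb <- r23 * cc
      e1 <- e1s[i, ]
      ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      b2 <- ref - sum(ref * e1) * e1
      b2 <- b2 / sqrt(sum(b2^2))
      b3 <- c(e1[2] * b2[3] - e1[3] * b2[2],
              e1[3] * b2[1] - e1[1] * b2[3],
              e1[1] * b2[2] - e1[2] * b2[1])
      psi <- runif(1, 0, 2 * pi)
      e2 <- cos(psi) * b2 + sin(psi) * b3
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])

      placed <- FALSE
      for (try in 1:100) {
        cen <- aa + runif(3) * pmax(L - 2 * aa, 0)
        hit <- FALSE
        for (tb in tubes)
          if (point_segment_distance(cen, tb$a, tb$b) < tb$radius + aa) {
            hit <- TRUE; break
          }
        if (!hit && nrow(cents) > 0) {
          dd <- sqrt(colSums((t(cents) - cen)^2))
          if (any(dd < radii_a + aa)) hit <- TRUE
        }
        if (!hit) { placed <- TRUE; break }
      }
      if (!placed) next
      cents <- rbind(cents, cen)
      radii_a <- c(radii_a, aa)
      lac[[length(lac) + 1L]] <- list(
        centroid = cen, volume_um3 = V,
        semi_axes = c(aa, bb, cc), axes = rbind(e1, e2, e3),
        r13 = r13, r12 = r13 / r23, r23 = r23)
    }
  }

  records <- if (length(lac)) {
    data.frame(
      id = seq_along(lac),
      x_um = vapply(lac, function(l) l$centroid[1], 0),
      y_um = vapply(lac, function(l) l$centroid[2], 0),
      z_um = vapply(lac, function(l) l$centroid[3], 0),
      volume_um3 = vapply(lac, function(l) l$volume_um3, 0),
      L1_um = vapply(lac, function(l) 2 * l$semi_axes[1], 0),
      L2_um = vapply(lac, function(l) 2 * l$semi_axes[2], 0),
      L3_um = vapply(lac, function(l) 2 * l$semi_axes[3], 0),
      r13 = vapply(lac, function(l) l$r13, 0),
      r12 = vapply(lac, function(l) l$r12, 0),
      r23 = vapply(lac, function(l) l$r23, 0),
      ux = vapply(lac, function(l) l$axes[1, 1], 0),
      uy = vapply(lac, function(l) l$axes[1, 2], 0),
      uz = vapply(lac, function(l) l$axes[1, 3], 0))
  } else {
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0), volume_um3 = numeric(0), L1_um = numeric(0),
               L2_um = numeric(0), L3_um = numeric(0), r13 = numeric(0),
               r12 = numeric(0), r23 = numeric(0), ux = numeric(0),
               uy = numeric(0), uz = numeric(0))
  }

  centerlines <- lapply(tubes, function(tb)
    list(points = rbind(tb$a, tb$b), radius_um = tb$radius))
  geometry <- list(tubes = tubes, lacunae = lac, box_um = L)

  if (!rasterize) {
    truth <- structure(list(
      masks = NULL, lacuna_records = records,
      vessel_centerlines = centerlines, geometry = geometry,
      true_density_per_mm3 = nrow(records) / mineral_mm3_analytic,
      true_vessel_porosity = vessel_vol_um3 / mineral_um3_analytic,
      voxel_size_um = vox), class = "phantom_truth")
    return(list(volume = NULL, truth = truth, spec = spec))
  }

  rasterize_geometry(geometry, records, centerlines, spec, spec$shape, vox)
}

# voxelize a fixed continuous specimen at a given grid
rasterize_geometry <- function(geometry, records, centerlines, spec, dm, vox) {
  tubes <- geometry$tubes
  lac <- geometry$lacunae
  if (length(tubes)) {
    pts <- do.call(rbind, lapply(tubes, function(tb) {
      tt <- seq(0, tb$length_um, by = vox / 2)
      sweep(outer(tt, tb$direction), 2, tb$a, "+")
    }))
    rr <- unlist(lapply(tubes, function(tb)
      rep(tb$radius, length(seq(0, tb$length_um, by = vox / 2)))))
    vessel <- array(stamp_balls_cpp(dm, vox, pts, rr), dm)
  } else {
    vessel <- array(FALSE, dm)
  }

  lac_lab <- array(0L, dm)
  for (i in seq_along(lac)) {
    l <- lac[[i]]
    aa <- l$semi_axes[1]
    i0 <- pmax(1L, floor((l$centroid - aa) / vox) + 1L)
    i1 <- pmin(dm, ceiling((l$centroid + aa) / vox) + 1L)
    if (any(i0 > i1)) next
    gx <- (seq.int(i0[1], i1[1]) - 1) * vox
    gy <- (seq.int(i0[2], i1[2]) - 1) * vox
    gz <- (seq.int(i0[3], i1[3]) - 1) * vox
    P <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    Prel <- sweep(P, 2, l$centroid)
    U <- Prel %*% t(l$axes)
    inside <- (U[, 1] / l$semi_axes[1])^2 + (U[, 2] / l$semi_axes[2])^2 +
      (U[, 3] / l$semi_axes[3])^2 <= 1
    if (!any(inside)) next
    block <- lac_lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    vblock <- vessel[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    sel <- array(inside, dim(block)) & block == 0L & !vblock
    block[sel] <- i
    lac_lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- block
  }

  mineral <- !(vessel | lac_lab > 0L)
  masks <- phase_masks(mineral = mineral, vessel = vessel,
                       lacunae = relabel_consecutive(lac_lab),
                       voxel_size_um = vox)

  gray <- array(spec$intensity_levels[2], dm)
  gray[mineral] <- spec$intensity_levels[1]
  blur_um <- if (is.null(spec$blur_sigma_um)) vox else spec$blur_sigma_um
  if (blur_um > 0)
    gray <- gaussian_blur(gray, blur_um / vox)
  if (spec$intensity_levels[3] > 0)
    gray <- gray + array(rnorm(prod(dm), 0, spec$intensity_levels[3]), dm)

  BV_mm3 <- sum(mineral) * vox^3 * 1e-9
  truth <- structure(list(
    masks = masks, lacuna_records = records,
    vessel_centerlines = centerlines,
    geometry = geometry,
    true_density_per_mm3 = nrow(records) / BV_mm3,
    true_vessel_porosity = sum(vessel) / sum(mineral),
    voxel_size_um = vox), class = "phantom_truth")

  vol <- volume_image(gray, vox, sample_id = sprintf("phantom-%d", spec$seed),
                      site = "phantom")
  list(volume = vol, truth = truth, spec = spec)
}

#' Re-voxelize an existing phantom at a different voxel size
#'
#' Rasterizes the continuous specimen geometry of a generated phantom on a
#' new grid: the identical tubes and lacunae are imaged at a different voxel
#' size (the scan-resolution experiment). The new grid covers the same
#' physical box; blur and noise parameters are taken from the original spec
#' (blur is specified in micrometres, so its physical width is unchanged).
#'
#' @param phantom result of [generate_phantom()].
#' @param voxel_size_um new voxel size (um).
#' @return a list like [generate_phantom()]'s (`volume`, `truth`).
#' @export
rasterize_phantom <- function(phantom, voxel_size_um) {
  stopifnot(inherits(phantom$truth, "phantom_truth"),
            inherits(phantom$spec, "phantom_spec"))
  geom <- phantom$truth$geometry
  dm <- as.integer(round(geom$box_um / voxel_size_um))
  withr::with_seed(phantom$spec$seed + 1L,
    rasterize_geometry(geom, phantom$truth$lacuna_records,
                       phantom$truth$vessel_centerlines, phantom$spec, dm,
                       voxel_size_um))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d lacunae, %d vessel tubes, true density %.0f /mm^3, vessel porosity %.2f%%\n",
              nrow(x$lacuna_records), length(x$vessel_centerlines),
              x$true_density_per_mm3, 100 * x$true_vessel_porosity))
  invisible(x)
}

#' Tabulate ground-truth metrics of one or more phantoms
#'
#' Returns the true values of the morphometric parameters that are computable
#' from the generating geometry (lacunar density, vessel porosity, mean
#' lacunar volume, mean axis ratios); used as the reference when testing
#' parameter recovery by the segmentation/morphometry pipeline.
#'
#' @param truths a single `phantom_truth` or a list of them.
#' @return a data frame, one row per phantom. Phantoms without lacunae report
#'   density 0 and `NA` shape statistics (flagged in `shape_missing`).
#' @export
phantom_to_table <- function(truths) {
  if (inherits(truths, "phantom_truth")) truths <- list(truths)
  if (!length(truths)) stop("need at least one phantom truth", call. = FALSE)
  rows <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    rec <- tr$lacuna_records
    has <- nrow(rec) > 0
    data.frame(
      phantom = i,
      n_lacunae = nrow(rec),
      true_density_per_mm3 = if (has) tr$true_density_per_mm3 else 0,
      true_vessel_porosity_pct = 100 * tr$true_vessel_porosity,
      mean_lacuna_volume_um3 = if (has) mean(rec$volume_um3) else NA_real_,
      sd_lacuna_volume_um3 = if (has && nrow(rec) > 1) sd(rec$volume_um3)
                             else NA_real_,
      mean_r13 = if (has) mean(rec$r13) else NA_real_,
      mean_r12 = if (has) mean(rec$r12) else NA_real_,
      mean_r23 = if (has) mean(rec$r23) else NA_real_,
      shape_missing = !has)
  })
  do.call(rbind, rows)
}
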