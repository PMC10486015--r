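#' Phase volumes and porosities
#'
#' Each phase volume is its voxel count times the voxel volume. Total volume
#' (TV) is the volume of the segmented envelope (mineral, vessel and lacuna
#' phases together); vessel and lacunar porosities are expressed relative to
#' the mineral volume (`VV/BV * 100`, `LcV/BV * 100`), the convention used
#' in cortical-bone morphometry.
#'
#' @param masks a [phase_masks].
#' @return list with `TV_mm3`, `BV_mm3`, `VV_um3`, `LcV_um3`,
#'   `vessel_porosity_pct`, `lacunar_porosity_pct`, `n_lacunae`,
#'   `NLc_per_mm3`. If `BV` is zero the porosities and density are `NA` and
#'   `undefined = TRUE`.
#' @export
phase_volumes <- function(masks) {
  stopifnot(inherits(masks, "phase_masks"))
  v3 <- masks$voxel_size_um^3
  nB <- sum(masks$mineral)
  nV <- sum(masks$vessel)
  nL <- sum(masks$lacunae > 0L)
  n_lac <- max(0L, max(masks$lacunae))
  TV_mm3 <- (nB + nV + nL) * v3 * 1e-9
  BV_mm3 <- nB * v3 * 1e-9
  undefined <- nB == 0L
  list(TV_mm3 = TV_mm3, BV_mm3 = BV_mm3,
       VV_um3 = nV * v3, LcV_um3 = nL * v3,
       vessel_porosity_pct = if (undefined) NA_real_ else 100 * nV / nB,
       lacunar_porosity_pct = if (undefined) NA_real_ else 100 * nL / nB,
       n_lacunae = n_lac,
       NLc_per_mm3 = if (undefined) NA_real_ else n_lac / BV_mm3,
       undefined = undefined)
}

#' Surface area of a binary mask
#'
#' Smoothed-gradient (co-area) estimator: the binary indicator is Gaussian
#' smoothed and the surface area is the integral of the gradient magnitude.
#' This avoids the systematic over-estimate (up to 1.5x) of naive voxel-face
#' counting and converges to within a few percent of the true area for
#' smooth shapes at adequate resolution.
#'
#' @param mask logical 3D array.
#' @param voxel_size_um voxel edge length (um).
#' @param sigma_voxels smoothing sigma in voxels.
#' @return surface area in um^2 (0 for an empty mask).
#' @export
surface_area <- function(mask, voxel_size_um, sigma_voxels = 1.2) {
  stopifnot_mask(mask)
  if (!any(mask)) return(0)
  u <- gaussian_blur(array(as.double(mask), dim(mask)), sigma_voxels)
  d <- dim(u)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (u[3:d[1], , ] - u[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (u[, 3:d[2], ] - u[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (u[, , 3:d[3]] - u[, , 1:(d[3] - 2)]) / 2
  # gradient in 1/voxel units; |grad| integrated over voxels gives area in
  # voxel^2, scaled to um^2
  sum(sqrt(gx^2 + gy^2 + gz^2)) * voxel_size_um^2
}

#' Vessel surface area and its ratios
#'
#' @param masks a [phase_masks].
#' @param sigma_voxels smoothing for the surface estimator.
#' @return list with `SA_um2` and the ratios `SA_VV_per_mm`, `SA_TV_per_mm`,
#'   `SA_BV_per_mm` (1/mm). With an empty vessel mask, `SA = 0` and `SA/VV`
#'   is `NA` (flagged `undefined`).
#' @export
vessel_surface_area <- function(masks, sigma_voxels = 1.2) {
  stopifnot(inherits(masks, "phase_masks"))
  pv <- phase_volumes(masks)
  SA_um2 <- surface_area(masks$vessel, masks$voxel_size_um, sigma_voxels)
  SA_mm2 <- SA_um2 * 1e-6
  undefined <- pv$VV_um3 == 0
  list(SA_um2 = SA_um2,
       SA_VV_per_mm = if (undefined) NA_real_ else SA_mm2 / (pv$VV_um3 * 1e-9),
       SA_TV_per_mm = if (pv$TV_mm3 > 0) SA_mm2 / pv$TV_mm3 else NA_real_,
       SA_BV_per_mm = if (pv$BV_mm3 > 0) SA_mm2 / pv$BV_mm3 else NA_real_,
       undefined = undefined)
}

#' Distances at cumulative volume fractions
#'
#' Computes the Euclidean distance from every voxel of `source` to the
#' nearest voxel of `reference`, accumulates the volume-weighted distance
#' histogram (bin width one voxel, linear interpolation within bins) and
#' returns, for each requested fraction `f`, the smallest distance below
#' which a fraction `f` of the source volume lies. `f = 0.5` is the
#' volume-weighted median distance; `f = 1` is the maximum.
#'
#' @param source logical array whose voxels are measured.
#' @param reference logical array of target voxels (e.g. the vessel pores).
#' @param fractions numeric vector in (0, 1].
#' @param voxel_size_um voxel edge length (um).
#' @return named numeric vector of distances in um, one per fraction.
#' @export
cumulative_distance <- function(source, reference, fractions = c(0.5, 0.95),
                                voxel_size_um = 1) {
  stopifnot_mask(source)
  stopifnot_mask(reference)
  if (!any(source)) stop("empty source mask", call. = FALSE)
  if (!any(reference))
    stop("empty reference mask: distances are infinite", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  d <- sqrt(edt_sq_cpp(as.logical(reference), dim(reference)))
  d <- d[as.logical(source)] * voxel_size_um
  dmax <- max(d)
  width <- voxel_size_um
  n_bins <- max(1L, ceiling(dmax / width + 1e-9))
  breaks <- seq(0, n_bins * width, by = width)
  h <- tabulate(pmin(n_bins, floor(d / width) + 1L), nbins = n_bins)
  cum <- c(0, cumsum(h)) / length(d)
  out <- vapply(fractions, function(f) {
    j <- which(cum >= f - 1e-12)[1]            # first break index with cum >= f
    if (j <= 1) return(0)
    lo <- cum[j - 1]; hi <- cum[j]
    if (hi > lo) breaks[j - 1] + (f - lo) / (hi - lo) * width
    else breaks[j]
  }, 0)
  out <- pmin(out, dmax)
  names(out) <- sprintf("f%g", fractions)
  out
}

#' Compile a full morphometry report for one volume of interest
#'
#' Assembles phase volumes and porosities, vessel surface ratios, the
#' cumulative mineral-to-vessel and intra-vessel distance statistics,
#' lacunar density and shape statistics, and (when supplied) the vessel
#' orientation summary and permeability anisotropy summary into one record.
#' Mineral distances use the mineral phase as source and the vessel pores as
#' reference; vessel distances measure lumen voxels to the nearest lumen
#' wall (an internal canal-radius statistic).
#'
#' @param masks a [phase_masks].
#' @param lacuna_records data frame of lacuna records (may be `NULL`; then
#'   taken from the label image's component statistics).
#' @param orientation_summary optional [orientation_histogram()] result.
#' @param permeability_summary optional [anisotropy_summary()] result.
#' @param sample_id,site metadata.
#' @return an object of class `morphometry_report`.
#' @export
compile_report <- function(masks, lacuna_records = NULL,
                           orientation_summary = NULL,
                           permeability_summary = NULL,
                           sample_id = "", site = "phantom") {
  stopifnot(inherits(masks, "phase_masks"))
  vox <- masks$voxel_size_um
  pv <- phase_volumes(masks)
  sa <- vessel_surface_area(masks)

  if (is.null(lacuna_records))
    lacuna_records <- component_shape_stats(masks$lacunae, vox)
  lst <- if (pv$BV_mm3 > 0) lacuna_statistics(lacuna_records, pv$BV_mm3)
         else list(mean_volume_um3 = NA_real_, sd_volume_um3 = NA_real_,
                   mean_r13 = NA_real_, mean_r12 = NA_real_,
                   mean_r23 = NA_real_, shape_missing = TRUE)

  have_vessel <- any(masks$vessel)
  mineral_dist <- c(f0.5 = NA_real_, f0.95 = NA_real_)
  vessel_dist <- c(f0.5 = NA_real_, f0.95 = NA_real_)
  if (have_vessel && any(masks$mineral)) {
    mineral_dist <- cumulative_distance(masks$mineral, masks$vessel,
                                        c(0.5, 0.95), vox)
    vessel_dist <- cumulative_distance(masks$vessel, !masks$vessel,
                                       c(0.5, 0.95), vox)
  }

  structure(list(
    sample_id = sample_id, site = site, voxel_size_um = vox,
    TV_mm3 = pv$TV_mm3, BV_mm3 = pv$BV_mm3,
    VV_um3 = pv$VV_um3, LcV_um3 = pv$LcV_um3,
    vessel_porosity_pct = pv$vessel_porosity_pct,
    lacunar_porosity_pct = pv$lacunar_porosity_pct,
    NLc_per_mm3 = pv$NLc_per_mm3, n_lacunae = pv$n_lacunae,
    L_dist_min50_um = unname(mineral_dist[1]),
    L_dist_min95_um = unname(mineral_dist[2]),
    L_dist_vessel50_um = unname(vessel_dist[1]),
    L_dist_vessel95_um = unname(vessel_dist[2]),
    SA_VV_per_mm = sa$SA_VV_per_mm, SA_TV_per_mm = sa$SA_TV_per_mm,
    SA_BV_per_mm = sa$SA_BV_per_mm,
    mean_lacuna_volume_um3 = lst$mean_volume_um3,
    sd_lacuna_volume_um3 = lst$sd_volume_um3,
    mean_r13 = lst$mean_r13, mean_r12 = lst$mean_r12,
    mean_r23 = lst$mean_r23,
    s_phi = if (is.null(orientation_summary)) NA_real_
            else orientation_summary$s_phi,
    s_theta = if (is.null(orientation_summary)) NA_real_
              else orientation_summary$s_theta,
    LOA = if (is.null(orientation_summary)) NA_real_
          else orientation_summary$LOA,
    ratio_EV_mean = if (is.null(permeability_summary)) NA_real_
                    else permeability_summary$ratio_EV_mean,
    invert = if (is.null(permeability_summary)) NA_real_
             else permeability_summary$invert),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %s (%s) @ %g um\n", x$sample_id, x$site,
              x$voxel_size_um))
  cat(sprintf("  TV %.4g mm^3 | BV %.4g mm^3 | vessel porosity %.2f%% | lacunar porosity %.3f%%\n",
              x$TV_mm3, x$BV_mm3, x$vessel_porosity_pct,
              x$lacunar_porosity_pct))
  cat(sprintf("  lacunae: n = %d, density %.0f /mm^3, volume %.0f +/- %.0f um^3, L1/L3 %.2f\n",
              x$n_lacunae, x$NLc_per_mm3, x$mean_lacuna_volume_um3,
              x$sd_lacuna_volume_um3, x$mean_r13))
  cat(sprintf("  distances (um): mineral 50/95 = %.1f/%.1f, vessel 50/95 = %.1f/%.1f\n",
              x$L_dist_min50_um, x$L_dist_min95_um, x$L_dist_vessel50_um,
              x$L_dist_vessel95_um))
  if (!is.na(x$LOA))
    cat(sprintf("  orientation: s_phi %.3g, s_theta %.3g, LOA %.3g\n",
                x$s_phi, x$s_theta, x$LOA))
  if (!is.na(x$ratio_EV_mean))
    cat(sprintf("  permeability anisotropy: EV-mean ratio %.4f (invert %.1f)\n",
                x$ratio_EV_mean, x$invert))
  invisible(x)
}

#' @export
as.data.frame.morphometry_report <- function(x, ...) {
  df <- data.frame(
    x$sample_id, x$site, x$TV_mm3, x$BV_mm3, x$LcV_um3,
    x$lacunar_porosity_pct, x$NLc_per_mm3,
    x$L_dist_min50_um, x$L_dist_min95_um,
    x$L_dist_vessel50_um, x$L_dist_vessel95_um,
    x$mean_lacuna_volume_um3, x$sd_lacuna_volume_um3,
    x$VV_um3, x$vessel_porosity_pct,
    x$SA_VV_per_mm, x$SA_TV_per_mm, x$SA_BV_per_mm,
    x$mean_r13, x$mean_r12, x$mean_r23,
    x$s_phi, x$s_theta, x$LOA, x$ratio_EV_mean, x$invert,
    check.names = FALSE)
  names(df) <- report_columns
  df
}
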