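#' 3D grayscale volume with physical voxel size
#'
#' The basic container for a reconstructed micro-CT scan (or a synthetic
#' phantom). The array is indexed `[x, y, z]` with a fixed anatomical
#' convention: axis 3 (`z`) is the bone's long axis, axis 1 (`x`) lies in the
#' bone-surface plane, axis 2 is `y`. Voxels are isotropic; the physical
#' position of voxel `(i, j, k)` (1-based R indices) is
#' `(i - 1, j - 1, k - 1) * voxel_size_um` (voxel-centre convention).
#'
#' @param data 3D numeric array of grayscale intensities (arbitrary units).
#' @param voxel_size_um positive scalar, isotropic voxel edge length in
#'   micrometres.
#' @param sample_id free-text sample identifier.
#' @param site one of `"AB"` (alveolar/recipient), `"FB"` (fibula/donor) or
#'   `"phantom"`.
#' @return an object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(4, 4, 4)), voxel_size_um = 2.27)
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size_um, sample_id = "",
                         site = c("phantom", "AB", "FB")) {
  site <- match.arg(site)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("all three dimensions must be at least 2 voxels", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 sample_id = sample_id, site = site),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %s%s  %d x %d x %d voxels @ %g um (%.4g x %.4g x %.4g mm)\n",
              if (nzchar(x$sample_id)) paste0(x$sample_id, " ") else "",
              x$site, d[1], d[2], d[3], x$voxel_size_um,
              d[1] * x$voxel_size_um / 1000, d[2] * x$voxel_size_um / 1000,
              d[3] * x$voxel_size_um / 1000))
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' Volume of interest
#'
#' A rectangular sub-volume given by a 0-based voxel origin and a shape in
#' voxels. Bounds are validated against a parent volume at crop time.
#'
#' @param origin integer triple, 0-based voxel index of the VOI corner.
#' @param shape integer triple, VOI extent in voxels (all `>= 1`).
#' @return an object of class `voi`.
#' @examples
#' voi(c(0, 0, 0), c(8, 8, 8))
#' @export
voi <- function(origin, shape) {
  origin <- as.integer(origin)
  shape <- as.integer(shape)
  if (length(origin) != 3L || length(shape) != 3L)
    stop("`origin` and `shape` must be integer triples", call. = FALSE)
  if (any(origin < 0L)) stop("`origin` must be non-negative", call. = FALSE)
  if (any(shape < 1L)) stop("`shape` must be positive", call. = FALSE)
  structure(list(origin = origin, shape = shape), class = "voi")
}

#' Crop a volume of interest out of a volume
#'
#' @param vol a [volume_image].
#' @param roi a [voi]; must fit inside `vol`.
#' @return a [volume_image] of shape `roi$shape` with unchanged voxel size.
#' @examples
#' v <- volume_image(array(seq_len(16^3), c(16, 16, 16)), 1)
#' crop_voi(v, voi(c(0, 0, 0), c(8, 8, 8)))
#' @export
crop_voi <- function(vol, roi) {
  stopifnot(is_volume_image(vol), inherits(roi, "voi"))
  d <- dim(vol$data)
  hi <- roi$origin + roi$shape
  over <- which(hi > d)
  if (length(over))
    stop(sprintf("VOI exceeds volume bounds along axis %s (%d + %d > %d)",
                 paste(c("x", "y", "z")[over], collapse = ", "),
                 roi$origin[over[1]], roi$shape[over[1]], d[over[1]]),
         call. = FALSE)
  idx <- Map(function(o, s) seq.int(o + 1L, o + s), roi$origin, roi$shape)
  out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  volume_image(out, vol$voxel_size_um, sample_id = vol$sample_id,
               site = vol$site)
}
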