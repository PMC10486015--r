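# Internal wrappers around the compiled 3D primitives. All masks are logical
# arrays with a dim attribute of length 3; distances are returned in voxel
# units unless a voxel size is applied by the caller.

stopifnot_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  if (!is.logical(x))
    stop(sprintf("`%s` must be a logical mask", name), call. = FALSE)
  invisible(x)
}

# Euclidean distance (voxels) from every voxel to the nearest TRUE voxel.
edt_voxels <- function(feature) {
  stopifnot_mask(feature)
  if (!any(feature))
    stop("distance transform of an empty feature set is infinite everywhere",
         call. = FALSE)
  d2 <- edt_sq_cpp(as.logical(feature), dim(feature))
  array(sqrt(d2), dim(feature))
}

edt_sq_voxels <- function(feature) {
  stopifnot_mask(feature)
  array(edt_sq_cpp(as.logical(feature), dim(feature)), dim(feature))
}

# Grayscale dilation/erosion with a cube structuring element (half-width in
# voxels); separable running max/min.
cube_dilate <- function(vol, half) {
  array(cube_filter_cpp(as.double(vol), dim(vol), as.integer(half), 1L),
        dim(vol))
}

cube_erode <- function(vol, half) {
  array(cube_filter_cpp(as.double(vol), dim(vol), as.integer(half), 0L),
        dim(vol))
}

cube_close_gray <- function(vol, half) {
  cube_erode(cube_dilate(vol, half), half)
}

gaussian_blur <- function(vol, sigma_voxels) {
  array(gaussian_blur_cpp(as.double(vol), dim(vol), sigma_voxels), dim(vol))
}

# 26- (default) or 6-connected component labels, consecutive from 1.
label_components <- function(mask, connectivity = 26L) {
  stopifnot_mask(mask)
  lab <- label_components_cpp(as.logical(mask), dim(mask),
                              as.integer(connectivity))
  out <- array(lab, dim(mask))
  attr(out, "n_labels") <- attr(lab, "n_labels")
  out
}

n_labels <- function(lab) {
  n <- attr(lab, "n_labels")
  if (is.null(n)) n <- max(0L, max(lab))
  n
}

# Per-label second-moment summaries; returns a matrix with one row per label.
label_moments <- function(lab) {
  n <- n_labels(lab)
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = 10))
  label_moments_cpp(as.integer(lab), dim(lab), as.integer(n))
}
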