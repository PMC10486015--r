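#' Read a 3D volume from a multi-page TIFF stack or an NRRD file
#'
#' TIFF stacks carry no physical metadata, so `voxel_size_um` must be given.
#' NRRD headers may carry per-axis `spacings`; when present (and isotropic)
#' they are used unless overridden. Integer intensities survive a
#' write/read round trip bit-exactly.
#'
#' @param path file path.
#' @param voxel_size_um isotropic voxel edge length in micrometres; required
#'   for TIFF, optional for NRRD with header spacings.
#' @param format `"auto"` (by file extension), `"tiff_stack"` or `"nrrd"`.
#' @param sample_id,site metadata passed to [volume_image()].
#' @return a [volume_image].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, voxel_size_um = NULL,
                        format = c("auto", "tiff_stack", "nrrd"),
                        sample_id = "", site = "phantom") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nrrd", "nhdr")) "nrrd" else "tiff_stack"
  }
  if (format == "tiff_stack") {
    if (is.null(voxel_size_um))
      stop("`voxel_size_um` is required for TIFF stacks (no physical metadata in the file)",
           call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shp <- dim(pages[[1]])
    ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
    if (!all(ok))
      stop("inconsistent slice shapes in TIFF stack", call. = FALSE)
    data <- array(unlist(pages, use.names = FALSE),
                  c(shp[1], shp[2], length(pages)))
    volume_image(data, voxel_size_um, sample_id = sample_id, site = site)
  } else {
    nr <- read_nrrd(path)
    vs <- voxel_size_um
    if (is.null(vs)) vs <- nr$spacing
    if (is.null(vs))
      stop("NRRD file has no spacings; supply `voxel_size_um`", call. = FALSE)
    volume_image(nr$data, vs, sample_id = sample_id, site = site)
  }
}

#' Write a 3D volume to a multi-page TIFF stack or an NRRD file
#'
#' TIFF output is integer (8 or 16 bit) and requires integer-valued data in
#' range; arbitrary (floating point) intensities go to NRRD, which stores
#' doubles losslessly and records the voxel spacing in the header.
#'
#' @param vol a [volume_image].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"tiff_stack"` or `"nrrd"`.
#' @param bits TIFF bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff_stack", "nrrd"),
                         bits = 16L) {
  stopifnot(is_volume_image(vol))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nrrd", "nhdr")) "nrrd" else "tiff_stack"
  }
  if (format == "tiff_stack") {
    x <- vol$data
    maxv <- 2^bits - 1
    if (any(x != round(x)) || min(x) < 0 || max(x) > maxv)
      stop(sprintf("TIFF output requires integer intensities in [0, %d]; use NRRD for floating point data",
                   maxv), call. = FALSE)
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / maxv)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("cannot write TIFF to '%s'", path), call. = FALSE)
  } else {
    write_nrrd(vol$data, path, spacing = vol$voxel_size_um)
  }
  invisible(path)
}

# -- minimal NRRD (raw / gzip encodings, little endian) -----------------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic))
    stop(sprintf("'%s' is not an NRRD file", path), call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[tolower(trimws(kv[1]))]] <- trimws(sub("^=", "", kv[2]))
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L)
    stop("only 3-dimensional NRRD volumes are supported", call. = FALSE)
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic voxels are not supported", call. = FALSE)
    spacing <- sp[1]
  }
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw")
    stop(sprintf("unsupported NRRD encoding '%s'", enc), call. = FALSE)
  data <- switch(type,
    "double" = , "float64" = readBin(payload, "double", n = n, size = 8,
                                     endian = "little"),
    "float" = , "float32" = readBin(payload, "double", n = n, size = 4,
                                    endian = "little"),
    "uint8" = , "uchar" = as.integer(readBin(payload, "integer", n = n,
                                             size = 1, signed = FALSE)),
    "uint16" = , "ushort" = readBin(payload, "integer", n = n, size = 2,
                                    signed = FALSE, endian = "little"),
    "int" = , "int32" = readBin(payload, "integer", n = n, size = 4,
                                endian = "little"),
    stop(sprintf("unsupported NRRD type '%s'", type), call. = FALSE))
  list(data = array(data, sizes), spacing = spacing)
}

write_nrrd <- function(data, path, spacing = NULL) {
  int_ok <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)) &&
       min(data) >= 0 && max(data) <= 65535)
  type <- if (int_ok) "uint16" else "double"
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot write NRRD to '%s'", path), call. = FALSE)
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", dim(data)[1], dim(data)[2], dim(data)[3]),
           "encoding: raw",
           "endian: little")
  if (!is.null(spacing))
    hdr <- c(hdr, sprintf("spacings: %.10g %.10g %.10g", spacing, spacing,
                          spacing))
  writeLines(c(hdr, ""), con)
  if (type == "uint16")
    writeBin(as.integer(data), con, size = 2, endian = "little")
  else
    writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}

# -- phase-label volumes ------------------------------------------------------

#' Write phase masks as an 8-bit label volume
#'
#' Encoding: 0 background, 1 mineral, 2 vessel pore, 3 osteocyte lacuna.
#' Individual lacuna labels are not preserved (re-derivable by connected
#' components on read).
#'
#' @param masks a [phase_masks] object.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(masks, path) {
  stopifnot(inherits(masks, "phase_masks"))
  lab <- array(0L, dim(masks$mineral))
  lab[masks$mineral] <- 1L
  lab[masks$vessel] <- 2L
  lab[masks$lacunae > 0L] <- 3L
  write_volume(volume_image(lab, masks$voxel_size_um), path,
               format = "tiff_stack", bits = 8L)
}

#' Read an 8-bit phase-label volume back into phase masks
#'
#' @param path label TIFF written by [write_labels()].
#' @param voxel_size_um voxel edge length in micrometres.
#' @return a [phase_masks] object (lacuna ids re-derived by 26-connected
#'   component labeling).
#' @export
read_labels <- function(path, voxel_size_um) {
  v <- read_volume(path, voxel_size_um, format = "tiff_stack")
  lac <- label_components(v$data == 3L)
  phase_masks(mineral = v$data == 1L, vessel = v$data == 2L, lacunae = lac,
              voxel_size_um = voxel_size_um)
}

# -- morphometry report tables ------------------------------------------------

report_columns <- c(
  "sample_id", "site", "TV", "BV", "LcV", "LcV/BV", "NLc/BV",
  "L_dist,min50", "L_dist,min95", "L_dist,vessel50", "L_dist,vessel95",
  "V_lac", "sd_lac", "VV", "VV/BV", "SA/VV", "SA/TV", "SA/BV",
  "L1/L3", "L1/L2", "L2/L3", "s_phi", "s_theta", "LOA",
  "EV_mean", "invert")

#' Write a collection of morphometry reports to CSV or JSON
#'
#' One row (record) per sample; numeric values round-trip with at least six
#' significant digits. Column names follow the standard morphometric symbols
#' (`TV`, `BV`, `NLc/BV`, `L_dist,min50`, `VV/BV`, `LOA`, ...).
#'
#' @param reports a single [morphometry_report] or a list of them.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "morphometry_report")) reports <- list(reports)
  if (!length(reports))
    stop("empty report collection; nothing to write", call. = FALSE)
  rows <- lapply(reports, as.data.frame)
  df <- do.call(rbind, rows)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  close(con)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a morphometry report table written by [write_report()]
#'
#' @param path CSV or JSON path.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @return a data frame, one row per sample.
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "csv")
    read.csv(path, check.names = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
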