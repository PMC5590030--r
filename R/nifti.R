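# Minimal NIfTI-1 I/O.
#
# The pre-installed R stack carries no NIfTI package, so the pipeline ships a
# small single-file reader/writer covering what it needs: 3D/4D magnitude
# images and label maps, voxel spacing via pixdim + an axis-aligned sform
# (RAS+), common scalar dtypes, optional gzip. Tests cross-check round trips
# against Python's nibabel, which is present in the same image.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Write a volume as NIfTI-1
#'
#' Writes a 3D (`vol3d`, logical mask) or 4D (`multiecho`) image as a
#' single-file NIfTI-1 (`.nii` or `.nii.gz`), RAS+ axis-aligned, spacing in mm
#' carried in `pixdim` and the sform.
#'
#' @param volume a `vol3d`, a logical 3D array (written as uint8 labels), or a
#'   `multiecho` (written as 4D with TE spacing in `pixdim[4]`).
#' @param path output path; compressed when it ends in `.gz`.
#' @param datatype one of `"float64"`, `"float32"`, `"int16"`, `"uint8"`.
#'   Masks default to `"uint8"`, images to `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = NULL) {
  if (is.array(volume) && is.logical(volume)) {
    dat <- array(as.integer(volume), dim = dim(volume))
    spacing <- c(1, 1, 1)
    if (is.null(datatype)) datatype <- "uint8"
    tdim <- NULL
  } else if (inherits(volume, "multiecho")) {
    dat <- volume$data
    spacing <- volume$spacing
    tdim <- dim(dat)[4]
    if (is.null(datatype)) datatype <- "float64"
  } else {
    volume <- as_vol3d(volume)
    dat <- volume$data
    spacing <- volume$spacing
    tdim <- NULL
    if (is.null(datatype)) datatype <- "float64"
  }
  code <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L,
                 int16 = 4L, uint8 = 2L,
                 stop("unsupported datatype: ", datatype))
  spec <- NIFTI_DTYPES[[as.character(code)]]

  nd <- if (is.null(tdim)) 3L else 4L
  dims <- rep(1L, 8); dims[1] <- nd
  dims[2:4] <- dim(dat)[1:3]
  if (nd == 4L) dims[5] <- tdim
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- spacing
  if (nd == 4L) pixdim[5] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wchar <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wb(348L, 4L)                                  # sizeof_hdr
  wchar("", 10L); wchar("", 18L)                # data_type, db_name
  wb(0L, 4L); wb(0L, 2L); wchar("r", 1L); wchar("", 1L)
  wb(as.integer(dims), 2L)                      # dim
  wb(numeric(3), 4L); wb(0L, 2L)                # intent
  wb(code, 2L); wb(spec$size * 8L, 2L); wb(0L, 2L)
  wb(pixdim, 4L)                                # pixdim
  wb(352, 4L)                                   # vox_offset
  wb(1, 4L); wb(0, 4L)                          # scl_slope / scl_inter
  wb(0L, 2L); wchar("", 1L); wchar("", 1L)      # slice_end/code, xyzt_units
  wb(numeric(4), 4L)                            # cal_max/min, slice_dur, toffset
  wb(0L, 4L); wb(0L, 4L)                        # glmax, glmin
  wchar("mpioquant", 80L); wchar("", 24L)       # descrip, aux_file
  wb(0L, 2L); wb(1L, 2L)                        # qform_code, sform_code
  wb(numeric(6), 4L)                            # quatern, qoffset
  wb(c(spacing[1], 0, 0, 0), 4L)                # srow_x
  wb(c(0, spacing[2], 0, 0), 4L)                # srow_y
  wb(c(0, 0, spacing[3], 0), 4L)                # srow_z
  wchar("", 16L)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # no extensions
  if (spec$what == "double") {
    wb(as.numeric(dat), spec$size)
  } else {
    wb(as.integer(dat), spec$size)
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")   # transparently handles plain .nii too
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rb <- function(off, what, n, size, endian, signed = TRUE)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rb(0, "integer", 1, 4, "little") != 348L) {
    if (rb(0, "integer", 1, 4, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dims <- rb(40, "integer", 8, 2, endian)
  datatype <- rb(70, "integer", 1, 2, endian)
  pixdim <- rb(76, "numeric", 8, 4, endian)
  vox_offset <- rb(108, "numeric", 1, 4, endian)
  scl_slope <- rb(112, "numeric", 1, 4, endian)
  scl_inter <- rb(116, "numeric", 1, 4, endian)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype,
                          " in ", path)
  nd <- dims[1]
  shape <- dims[2:(1 + max(nd, 1))]
  nvox <- prod(shape)
  # skip to vox_offset (we are at byte 348 of a single-file NIfTI)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  dat <- readBin(con, spec$what, n = nvox, size = spec$size,
                 endian = endian, signed = spec$signed)
  if (length(dat) != nvox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  list(data = array(as.numeric(dat), dim = shape), ndim = nd,
       spacing = pixdim[2:4], pixdim = pixdim)
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a `vol3d` with spacing taken from `pixdim` (mm).
#' @export
read_volume <- function(path) {
  raw <- read_nifti_raw(path)
  if (raw$ndim != 3L)
    stop("expected a 3D volume, got ", raw$ndim, "D data in ", path)
  vol3d(raw$data, raw$spacing)
}

#' Read a 4D multi-echo series from NIfTI-1
#'
#' @param path a 4D `.nii`/`.nii.gz` file, echoes along the 4th axis.
#' @param echo_times echo times in ms, one per 4th-axis index.
#' @return a `multiecho`.
#' @export
read_multiecho <- function(path, echo_times) {
  raw <- read_nifti_raw(path)
  if (raw$ndim != 4L)
    stop("expected a 4D series, got ", raw$ndim, "D data in ", path)
  multiecho(raw$data, echo_times, raw$spacing)
}

#' Write an ROI set as an integer label map plus JSON name table
#'
#' Masks may overlap (e.g. `core` inside `ipsi_hemisphere`), so each mask is
#' encoded as a bit in an integer label volume; the sidecar JSON maps mask
#' names to bit values.
#'
#' @param rois a `roi_set`.
#' @param path output `.nii`/`.nii.gz`; the JSON sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  if (length(rois$masks) > 31L) stop("too many masks for bit encoding")
  lab <- array(0, dim = dim(rois$masks[[1]]))
  bits <- stats::setNames(2^(seq_along(rois$masks) - 1), names(rois$masks))
  for (nm in names(rois$masks)) lab <- lab + bits[[nm]] * rois$masks[[nm]]
  write_volume(vol3d(lab, rois$spacing), path, datatype = "int32")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(bits = as.list(bits), spacing = rois$spacing),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set written by [write_roi_set()]
#' @param path the label-map NIfTI path.
#' @return a `roi_set`.
#' @export
read_roi_set <- function(path) {
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing ROI sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vol <- read_volume(path)
  lab <- array(as.integer(round(vol$data)), dim = dim(vol$data))
  masks <- lapply(meta$bits, function(b)
    array(bitwAnd(lab, as.integer(b)) != 0L, dim = dim(lab)))
  roi_set(masks, vol$spacing)
}
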