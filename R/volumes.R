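#' 3D scalar volume with voxel spacing
#'
#' Minimal container for a 3D image: a numeric array plus voxel spacing in mm.
#' All pipeline stages operate on `vol3d` objects (signal intensity, fitted T2,
#' probability maps) and on plain logical arrays for masks.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @return An object of class `vol3d`: a list with elements `data` and `spacing`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat("<vol3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  rng <- range(x$data, finite = TRUE)
  cat("  intensity range [", signif(rng[1], 6), ", ", signif(rng[2], 6), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

as_vol3d <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "vol3d")) return(x)
  vol3d(x, spacing)
}

#' Voxel volume in mm^3
#' @param spacing numeric length-3 spacing (mm) or a `vol3d`.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(spacing) {
  if (inherits(spacing, "vol3d")) spacing <- spacing$spacing
  prod(as.numeric(spacing))
}

#' Multi-echo spin-echo series
#'
#' A stack of 3D volumes at known, strictly increasing echo times; the input to
#' \code{\link{fit_t2_map}}.
#'
#' @param data numeric 4D array `[x, y, z, echo]`.
#' @param echo_times numeric vector of distinct positive echo times (ms),
#'   length matching the 4th dimension. Simulation produces them in
#'   increasing order; the fit is invariant to echo order.
#' @param spacing voxel spacing in mm.
#' @return An object of class `multiecho`.
#' @export
multiecho <- function(data, echo_times, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array [x, y, z, echo]")
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) != dim(data)[4])
    stop("length(echo_times) must equal the number of echoes in `data`")
  if (any(echo_times <= 0) || anyDuplicated(echo_times))
    stop("`echo_times` must be positive and distinct")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(data = data, echo_times = echo_times, spacing = spacing),
            class = "multiecho")
}

#' @export
print.multiecho <- function(x, ...) {
  cat("<multiecho> ", paste(dim(x$data)[1:3], collapse = " x "), " voxels, ",
      dim(x$data)[4], " echoes (TE ", min(x$echo_times), "-",
      max(x$echo_times), " ms)\n", sep = "")
  invisible(x)
}

# ---- masks -------------------------------------------------------------

new_mask <- function(mask, provenance = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!is.null(provenance)) attr(mask, "provenance") <- provenance
  mask
}

check_mask <- function(mask, name = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`", name, "` must be a 3D array")
  if (!is.logical(mask)) {
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1, NA)))
      stop("`", name, "` must be binary (logical or 0/1)")
    mask <- array(mask != 0, dim = dim(mask))
  }
  mask
}

same_grid <- function(a, b) identical(dim(a), dim(b))

#' Named set of analysis regions of interest
#'
#' Bundles the masks used by the quantification stages on one voxel grid:
#' lesion `core`, perilesional `borderzone`, mirrored `contralesional`
#' homolog, the two hemispheres, and the anatomical exclusion masks
#' (`ventricles`, `corpus_callosum`).
#'
#' Enforced invariants: all masks share one grid; `core` and `borderzone` are
#' disjoint; `borderzone` does not intersect the exclusions; `contralesional`
#' lies inside `contra_hemisphere`.
#'
#' @param masks named list of logical 3D arrays.
#' @param spacing voxel spacing in mm.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, spacing = c(1, 1, 1)) {
  stopifnot(is.list(masks), !is.null(names(masks)), all(nzchar(names(masks))))
  masks <- lapply(stats::setNames(names(masks), names(masks)),
                  function(nm) check_mask(masks[[nm]], nm))
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1L)
    stop("all ROI masks must share one grid")
  has <- function(nm) nm %in% names(masks)
  if (has("core") && has("borderzone") && any(masks$core & masks$borderzone))
    stop("roi_set invariant violated: core and borderzone overlap")
  if (has("borderzone")) {
    for (ex in c("ventricles", "corpus_callosum")) {
      if (has(ex) && any(masks$borderzone & masks[[ex]]))
        stop("roi_set invariant violated: borderzone intersects ", ex)
    }
  }
  if (has("contralesional") && has("contra_hemisphere") &&
      any(masks$contralesional & !masks$contra_hemisphere))
    stop("roi_set invariant violated: contralesional outside contra_hemisphere")
  structure(list(masks = masks, spacing = as.numeric(spacing)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> on ", paste(dim(x$masks[[1]]), collapse = " x "),
      " grid:\n", sep = "")
  for (nm in names(x$masks))
    cat(sprintf("  %-18s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Per-ROI volumes
#' @param rois a `roi_set`.
#' @return data.frame with roi name, voxel count and volume in mm^3.
#' @export
roi_volumes <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  vv <- voxel_volume(rois$spacing)
  counts <- vapply(rois$masks, sum, integer(1))
  data.frame(roi = names(counts), n_voxels = as.integer(counts),
             volume_mm3 = as.numeric(counts) * vv, row.names = NULL)
}
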