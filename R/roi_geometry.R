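# Construction of the three analysis ROIs from a lesion-core mask: the
# perilesional borderzone by in-plane morphological expansion with anatomical
# exclusions, and the contralesional homolog by midsagittal mirroring.

# one 8-connected in-plane dilation of a 2D logical matrix, implemented as
# convolution with an all-ones 3x3 kernel followed by binarization (> 0)
dilate2d_8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dx in -1:1) {
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    xd <- max(1, 1 - dx):min(nr, nr - dx)
    for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      ys <- max(1, 1 + dy):min(nc, nc + dy)
      yd <- max(1, 1 - dy):min(nc, nc - dy)
      out[xd, yd] <- out[xd, yd] | m[xs, ys]
    }
  }
  out
}

#' Expand a lesion core into its perilesional borderzone
#'
#' Per axial slice, the binary core is convolved twice with an all-ones 3x3
#' kernel, binarizing (> 0) after each pass -- i.e. two successive 8-connected
#' in-plane dilations, yielding an expansion ring of in-plane Chebyshev width
#' 2. The borderzone is the expansion minus the core itself, minus any
#' exclusion masks (ventricles, corpus callosum). The operation never crosses
#' slices: the acquisition is multi-slice 2D, so expansion is strictly
#' in-plane.
#'
#' @param core binary lesion mask (logical or 0/1 3D array), slices along the
#'   3rd axis.
#' @param exclusions list of logical arrays to remove from the borderzone
#'   (order irrelevant).
#' @param n_dilations number of 3x3 dilation passes (default 2, the "twofold
#'   convolution").
#' @return logical borderzone mask, disjoint from `core` and from every
#'   exclusion.
#' @export
expand_lesion_borderzone <- function(core, exclusions = list(),
                                     n_dilations = 2L) {
  if (is.numeric(core) && !all(unique(as.vector(core)) %in% c(0, 1)))
    stop("`core` must be a binary mask")
  core <- check_mask(core, "core")
  gs <- dim(core)
  expanded <- core
  for (z in seq_len(gs[3])) {
    sl <- expanded[, , z]
    if (!any(sl)) next
    for (k in seq_len(n_dilations)) sl <- dilate2d_8(sl)
    expanded[, , z] <- sl
  }
  bz <- expanded & !core
  for (ex in exclusions) {
    ex <- check_mask(ex, "exclusion")
    if (!same_grid(ex, core)) stop("exclusion mask grid mismatch")
    bz <- bz & !ex
  }
  new_mask(bz, provenance = "borderzone")
}

#' Mirror a region across the midsagittal plane
#'
#' Reflects a mask across the plane `index = midline_index` along
#' `midline_axis` (voxel index `i` maps to `round(2 * midline_index - i)`),
#' providing the contralesional homolog of a lesion ROI on symmetric
#' geometry. Voxels whose reflection falls outside the grid are dropped with
#' a message stating the count. With `midline_index = (n + 1) / 2` (the grid
#' center) the reflection is an involution.
#'
#' @param region logical 3D mask.
#' @param midline_axis axis (1..3) perpendicular to the midsagittal plane.
#' @param midline_index plane position in voxel index units (may be
#'   half-integer); default grid center.
#' @param clip_to optional mask (e.g. the contralesional hemisphere) the
#'   result is intersected with.
#' @return logical mirrored mask.
#' @export
mirror_contralesional <- function(region, midline_axis = 1L,
                                  midline_index = NULL, clip_to = NULL) {
  region <- check_mask(region, "region")
  gs <- dim(region)
  ax <- as.integer(midline_axis)
  if (!ax %in% 1:3) stop("midline_axis must be 1, 2 or 3")
  n <- gs[ax]
  if (is.null(midline_index)) midline_index <- (n + 1) / 2
  if (midline_index < 1 || midline_index > n)
    stop("midline_index must lie inside the grid")
  idx <- which(region)
  out <- array(FALSE, gs)
  if (length(idx)) {
    coords <- arrayInd(idx, gs)
    coords[, ax] <- as.integer(round(2 * midline_index - coords[, ax]))
    keep <- coords[, ax] >= 1L & coords[, ax] <= n
    if (any(!keep))
      message(sum(!keep), " voxel(s) reflected outside the grid were dropped")
    coords <- coords[keep, , drop = FALSE]
    out[coords] <- TRUE
  }
  if (!is.null(clip_to)) {
    clip_to <- check_mask(clip_to, "clip_to")
    if (!same_grid(clip_to, region)) stop("clip_to grid mismatch")
    out <- out & clip_to
  }
  out
}

#' Assemble the analysis ROI set from a lesion core
#'
#' Builds the three quantification ROIs on one grid: the lesion `core`
#' (cleaned of any overlap with exclusion masks, with a message), the
#' `borderzone` via [expand_lesion_borderzone()], and the `contralesional`
#' homolog via [mirror_contralesional()] clipped to the contralesional
#' hemisphere. The result is validated against the `roi_set` invariants.
#'
#' @param core binary lesion mask.
#' @param hemispheres list with logical masks `ipsi` and `contra`.
#' @param exclusions list with logical masks `ventricles` and
#'   `corpus_callosum` (either may be omitted).
#' @param spacing voxel spacing in mm.
#' @param contralesional_source `"core"` (default) mirrors the core alone;
#'   `"core_borderzone"` mirrors core plus borderzone.
#' @param midline_axis,midline_index passed to [mirror_contralesional()].
#' @return a `roi_set` with masks `core`, `borderzone`, `contralesional`,
#'   `ipsi_hemisphere`, `contra_hemisphere`, and the exclusions.
#' @export
build_roi_set <- function(core, hemispheres, exclusions = list(),
                          spacing = c(1, 1, 1),
                          contralesional_source = c("core", "core_borderzone"),
                          midline_axis = 1L, midline_index = NULL) {
  contralesional_source <- match.arg(contralesional_source)
  core <- check_mask(core, "core")
  ipsi <- check_mask(hemispheres$ipsi, "ipsi hemisphere")
  contra <- check_mask(hemispheres$contra, "contra hemisphere")
  if (!same_grid(core, ipsi) || !same_grid(core, contra))
    stop("core and hemisphere masks must share one grid")
  exclusions <- lapply(exclusions, check_mask)
  ex_all <- Reduce(`|`, exclusions, array(FALSE, dim(core)))
  if (!same_grid(ex_all, core)) stop("exclusion mask grid mismatch")

  overlap <- sum(core & ex_all)
  if (overlap > 0) {
    message("core overlaps exclusion masks in ", overlap,
            " voxel(s); removed from core")
    core <- core & !ex_all
  }
  borderzone <- expand_lesion_borderzone(core, exclusions)
  src <- if (contralesional_source == "core") core else core | borderzone
  contralesional <- mirror_contralesional(src, midline_axis, midline_index,
                                          clip_to = contra)
  masks <- list(core = new_mask(core, "consensus_input"),
                borderzone = borderzone,
                contralesional = contralesional,
                ipsi_hemisphere = ipsi,
                contra_hemisphere = contra)
  if (!is.null(exclusions$ventricles))
    masks$ventricles <- exclusions$ventricles
  if (!is.null(exclusions$corpus_callosum))
    masks$corpus_callosum <- exclusions$corpus_callosum
  roi_set(masks, spacing)
}
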