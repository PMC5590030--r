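# Lesion identification on T2 maps: ischemic tissue shows prolonged T2 at
# subacute stages, so the lesion is found either by a reference-relative
# threshold or by a supervised voxel classifier over T2 and location.

#' Segment the lesion by a reference-relative T2 threshold
#'
#' Lesion voxels are those in the ipsilesional hemisphere whose T2 exceeds
#' `mean + k * SD` of the reference region (normally the contralesional
#' hemisphere). Only the largest 26-connected component is kept, removing
#' isolated noise voxels.
#'
#' @param t2_map a `vol3d` T2 map (ms).
#' @param ipsi_mask logical mask of the ipsilesional hemisphere.
#' @param reference_mask logical mask of reference tissue (non-empty).
#' @param k threshold multiplier in reference SD units (default 2).
#' @param keep_largest keep only the largest connected component.
#' @return logical lesion mask with `provenance` attribute `"threshold"`.
#' @export
segment_lesion_by_threshold <- function(t2_map, ipsi_mask, reference_mask,
                                        k = 2, keep_largest = TRUE) {
  t2_map <- as_vol3d(t2_map)
  ipsi_mask <- check_mask(ipsi_mask, "ipsi_mask")
  reference_mask <- check_mask(reference_mask, "reference_mask")
  if (!same_grid(t2_map$data, ipsi_mask) ||
      !same_grid(t2_map$data, reference_mask))
    stop("t2 map and masks must share one grid")
  ref <- t2_map$data[reference_mask]
  ref <- ref[is.finite(ref)]
  if (!length(ref)) stop("reference region is empty")
  thr <- mean(ref) + k * stats::sd(ref)
  if (is.na(thr)) thr <- mean(ref)   # single-voxel reference: SD undefined
  mask <- ipsi_mask & !is.na(t2_map$data) & t2_map$data > thr
  if (keep_largest && any(mask)) mask <- largest_component(mask)
  new_mask(mask, provenance = "threshold")
}

#' Combine two expert lesion masks into a consensus
#'
#' @param mask_a,mask_b logical masks on one grid.
#' @param rule `"intersection"` keeps voxels present in both;
#'   `"majority"` keeps voxels present in a strict majority of the inputs,
#'   which for two masks coincides with the intersection.
#' @return logical mask with `provenance` attribute `"consensus"`.
#' @export
consensus_mask <- function(mask_a, mask_b,
                           rule = c("intersection", "majority")) {
  rule <- match.arg(rule)
  mask_a <- check_mask(mask_a, "mask_a")
  mask_b <- check_mask(mask_b, "mask_b")
  if (!same_grid(mask_a, mask_b)) stop("masks must share one grid")
  out <- switch(rule,
    intersection = mask_a & mask_b,
    majority = (mask_a + mask_b) > 1   # strict majority of 2
  )
  new_mask(array(out, dim(mask_a)), provenance = "consensus")
}

#' Build a per-voxel feature table for the lesion classifier
#'
#' Features are the fitted T2 value and the voxel's template-space
#' coordinates. On phantoms the template frame is the native grid (identity
#' registration); for real data externally computed template coordinates can
#' be supplied.
#'
#' @param t2_map a `vol3d` T2 map.
#' @param label_mask optional logical ground-truth/consensus lesion mask; adds
#'   a `label` column (1 = lesion).
#' @param brain_mask optional logical mask restricting rows (default: all
#'   voxels with finite T2).
#' @param coordinates optional n x 3 matrix of template coordinates matching
#'   the retained voxels; default voxel index times spacing (mm).
#' @return data.frame with columns `t2`, `x`, `y`, `z` and optionally `label`,
#'   plus a `voxel_index` column mapping rows back to the grid.
#' @export
voxel_feature_table <- function(t2_map, label_mask = NULL, brain_mask = NULL,
                                coordinates = NULL) {
  t2_map <- as_vol3d(t2_map)
  gs <- dim(t2_map$data)
  keep <- is.finite(t2_map$data)
  if (!is.null(brain_mask)) {
    brain_mask <- check_mask(brain_mask, "brain_mask")
    if (!same_grid(brain_mask, t2_map$data)) stop("brain_mask grid mismatch")
    keep <- keep & brain_mask
  }
  idx <- which(keep)
  coords <- if (is.null(coordinates)) {
    sweep(arrayInd(idx, gs), 2, t2_map$spacing, `*`)
  } else {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != length(idx) || ncol(coordinates) != 3L)
      stop("coordinates must be an n x 3 matrix matching retained voxels")
    coordinates
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  tab <- data.frame(t2 = t2_map$data[idx], x = coords[, 1], y = coords[, 2],
                    z = coords[, 3], voxel_index = idx)
  if (!is.null(label_mask)) {
    label_mask <- check_mask(label_mask, "label_mask")
    if (!same_grid(label_mask, t2_map$data)) stop("label_mask grid mismatch")
    tab$label <- as.integer(label_mask[idx])
  }
  tab
}

CLASSIFIER_FEATURES <- c("t2", "x", "y", "z")

#' Train the supervised lesion voxel classifier
#'
#' A seeded random-forest ensemble over the features T2 and template-space
#' location (x, y, z), trained on expert-consensus labels. Training is
#' deterministic given `seed`.
#'
#' @param table a [voxel_feature_table()] with a `label` column containing
#'   both classes.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed.
#' @param max_depth,min_node,max_sample tree-growing controls; per-tree
#'   bootstrap samples are capped at `max_sample` rows for desk-scale runs.
#' @return an object of class `lesion_classifier`.
#' @export
train_lesion_classifier <- function(table, n_trees = 100L, seed = 1L,
                                    max_depth = 10L, min_node = 5L,
                                    max_sample = 5000L) {
  if (!all(CLASSIFIER_FEATURES %in% names(table)))
    stop("table must contain features: ",
         paste(CLASSIFIER_FEATURES, collapse = ", "))
  if (!"label" %in% names(table)) stop("table must contain a `label` column")
  y <- table$label
  if (length(unique(y)) < 2L)
    stop("training table contains a single class; need lesion and non-lesion rows")
  # canonical row order: training is invariant to how the table was assembled
  ord <- do.call(order, c(unname(as.list(table[CLASSIFIER_FEATURES])),
                          list(y)))
  table <- table[ord, , drop = FALSE]
  y <- y[ord]
  model <- rf_train(as.matrix(table[CLASSIFIER_FEATURES]), y,
                    n_trees = n_trees, max_depth = max_depth,
                    min_node = min_node, max_sample = max_sample, seed = seed)
  structure(list(forest = model, features = CLASSIFIER_FEATURES,
                 n_trees = n_trees, seed = seed),
            class = "lesion_classifier")
}

#' Predict lesion probability for a feature table
#'
#' @param model a [train_lesion_classifier()] model.
#' @param table a feature table with the model's feature columns.
#' @return numeric vector of lesion probabilities in `[0, 1]`.
#' @export
predict_lesion_prob <- function(model, table) {
  stopifnot(inherits(model, "lesion_classifier"))
  if (!all(model$features %in% names(table)))
    stop("feature mismatch: table lacks ",
         paste(setdiff(model$features, names(table)), collapse = ", "))
  rf_predict(model$forest, as.matrix(table[model$features]))
}

#' Apply the lesion classifier to a T2 map
#'
#' Per-voxel lesion probability thresholded at 0.5, keeping the largest
#' 26-connected component.
#'
#' @param model a `lesion_classifier`.
#' @param t2_map a `vol3d` T2 map.
#' @param brain_mask,coordinates as in [voxel_feature_table()].
#' @param threshold probability cut (default 0.5).
#' @return logical lesion mask (`provenance` `"classifier"`) with the
#'   probability map attached as attribute `prob_map` (a `vol3d`).
#' @export
classify_lesion <- function(model, t2_map, brain_mask = NULL,
                            coordinates = NULL, threshold = 0.5) {
  t2_map <- as_vol3d(t2_map)
  tab <- voxel_feature_table(t2_map, brain_mask = brain_mask,
                             coordinates = coordinates)
  prob <- predict_lesion_prob(model, tab)
  pmap <- array(NA_real_, dim(t2_map$data))
  pmap[tab$voxel_index] <- prob
  mask <- array(FALSE, dim(t2_map$data))
  mask[tab$voxel_index] <- prob > threshold
  if (any(mask)) mask <- largest_component(mask)
  out <- new_mask(mask, provenance = "classifier")
  attr(out, "prob_map") <- vol3d(pmap, t2_map$spacing)
  out
}

#' Hemispheric lesion fraction (percent)
#'
#' Lesion volume divided by ipsilesional hemisphere volume, times 100.
#' Volumes are voxel count times voxel volume, so the ratio is invariant to
#' voxel spacing. Lesion voxels outside the hemisphere are dropped with a
#' message stating the count.
#'
#' @param lesion logical lesion mask.
#' @param ipsi_hemisphere logical hemisphere mask (non-empty).
#' @param spacing voxel spacing in mm (cancels in the ratio; kept for the
#'   volume bookkeeping).
#' @return percent lesion fraction (scalar).
#' @export
hemispheric_lesion_fraction <- function(lesion, ipsi_hemisphere,
                                        spacing = c(1, 1, 1)) {
  lesion <- check_mask(lesion, "lesion")
  ipsi_hemisphere <- check_mask(ipsi_hemisphere, "ipsi_hemisphere")
  if (!same_grid(lesion, ipsi_hemisphere)) stop("masks must share one grid")
  n_hemi <- sum(ipsi_hemisphere)
  if (n_hemi == 0) stop("ipsilesional hemisphere mask is empty")
  outside <- sum(lesion & !ipsi_hemisphere)
  if (outside > 0)
    message(outside, " lesion voxel(s) outside the hemisphere were dropped")
  vv <- voxel_volume(spacing)
  100 * (sum(lesion & ipsi_hemisphere) * vv) / (n_hemi * vv)
}
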