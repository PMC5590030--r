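# Quantification of contrast-agent accumulation from the pre/post
# T2*-weighted pair. Bound iron-oxide particles shorten T2*, so voxels
# containing agent go dark; accumulation is measured per ROI as (i) the
# absolute drop in mean signal intensity and (ii) the net volume percentage
# of voxels more than n_sd pre-contrast SDs below the pre-contrast ROI mean.
# Pre and post images are compared only through ROI statistics -- never by
# voxelwise subtraction, which slight inter-scan brain motion rules out.

#' Pre-contrast baseline statistics of an ROI
#'
#' Mean and sample standard deviation (n - 1 denominator) of the pre-contrast
#' signal over the ROI; these define the hypointensity threshold
#' `mean - n_sd * SD` used by [ce_voxel_mask()].
#'
#' @param pre pre-contrast `vol3d`.
#' @param roi logical mask with at least 2 voxels.
#' @param roi_name optional label carried into results.
#' @return An object of class `roi_baseline`: list with `roi`, `mean`, `sd`,
#'   `n`.
#' @export
roi_baseline_stats <- function(pre, roi, roi_name = "roi") {
  pre <- as_vol3d(pre)
  roi <- check_mask(roi, "roi")
  if (!same_grid(pre$data, roi)) stop("pre image and roi must share one grid")
  vals <- pre$data[roi]
  if (length(vals) < 2L) stop("roi must contain at least 2 voxels")
  structure(list(roi = roi_name, mean = mean(vals), sd = stats::sd(vals),
                 n = length(vals)), class = "roi_baseline")
}

#' Contrast-enhanced voxel mask (the n-SD hypointensity rule)
#'
#' A voxel of the ROI is contrast-enhanced when its signal is strictly below
#' `mean - n_sd * SD` of the pre-contrast ROI baseline (default `n_sd = 2`).
#' With a degenerate baseline (`SD = 0`) the threshold collapses to the mean;
#' this is well-defined and is flagged with a message.
#'
#' @param volume image to threshold (pre- or post-contrast `vol3d`).
#' @param roi logical mask; only ROI voxels can be flagged.
#' @param stats a [roi_baseline_stats()] computed from the pre-contrast image
#'   on the same ROI.
#' @param n_sd threshold multiplier (default 2).
#' @return logical mask of CE voxels.
#' @export
ce_voxel_mask <- function(volume, roi, stats, n_sd = 2) {
  volume <- as_vol3d(volume)
  roi <- check_mask(roi, "roi")
  if (!same_grid(volume$data, roi)) stop("volume and roi must share one grid")
  stopifnot(inherits(stats, "roi_baseline"))
  if (stats$sd == 0)
    message("degenerate baseline (SD = 0) in ROI '", stats$roi,
            "': threshold equals the ROI mean")
  thr <- stats$mean - n_sd * stats$sd
  new_mask(roi & volume$data < thr, provenance = "ce")
}

#' Absolute signal reduction in an ROI
#'
#' Difference of ROI mean signal intensities, pre minus post; positive when
#' the post-contrast image is darker (agent accumulated).
#'
#' @param pre,post `vol3d` images on one grid.
#' @param roi non-empty logical mask.
#' @return scalar signal reduction (a.u.).
#' @export
eq1_signal_reduction <- function(pre, post, roi) {
  pre <- as_vol3d(pre); post <- as_vol3d(post)
  roi <- check_mask(roi, "roi")
  if (!same_grid(pre$data, post$data) || !same_grid(pre$data, roi))
    stop("pre, post and roi must share one grid")
  if (!any(roi)) stop("roi is empty")
  mean(pre$data[roi]) - mean(post$data[roi])
}

#' Contrast-enhanced volume percentage of an ROI
#'
#' Net CE volume: CE voxels are counted on the post- and on the pre-contrast
#' image, both against the pre-contrast baseline of the same ROI; the
#' difference is normalized by ROI volume and expressed in percent. The
#' pre-image count is the noise/confound baseline, so the null (no contrast)
#' is unbiased around 0. Values may be negative and are not clamped.
#'
#' @param pre,post `vol3d` images on one grid.
#' @param roi non-empty logical mask (>= 2 voxels).
#' @param n_sd threshold multiplier (default 2).
#' @return list with `percent`, `ce_count_pre`, `ce_count_post`, `n_voxels`.
#' @export
eq3_ce_volume_fraction <- function(pre, post, roi, n_sd = 2) {
  pre <- as_vol3d(pre); post <- as_vol3d(post)
  roi <- check_mask(roi, "roi")
  if (!same_grid(pre$data, post$data) || !same_grid(pre$data, roi))
    stop("pre, post and roi must share one grid")
  if (!any(roi)) stop("roi is empty")
  st <- roi_baseline_stats(pre, roi)
  ce_post <- ce_voxel_mask(post, roi, st, n_sd)
  ce_pre <- ce_voxel_mask(pre, roi, st, n_sd)
  n <- sum(roi)
  list(percent = 100 * (sum(ce_post) - sum(ce_pre)) / n,
       ce_count_pre = sum(ce_pre),
       ce_count_post = sum(ce_post),
       n_voxels = n)
}

#' Quantify contrast accumulation in every analysis ROI
#'
#' Runs [eq1_signal_reduction()] and [eq3_ce_volume_fraction()] for each named
#' ROI (by default the three analysis regions: core, borderzone,
#' contralesional), with baseline statistics computed per ROI.
#'
#' @param pre,post `vol3d` images.
#' @param rois a `roi_set`.
#' @param roi_names which masks to quantify; defaults to the analysis ROIs
#'   present in `rois`.
#' @param n_sd threshold multiplier (default 2).
#' @param timing free-text acquisition-timing tag carried into the result
#'   (default "30 min post-injection", when free circulating particles have
#'   largely cleared from the blood).
#' @return data.frame with one row per ROI: `roi`, `eq1_signal_reduction`,
#'   `eq3_ce_volume_percent`, `ce_count_pre`, `ce_count_post`, `n_voxels`,
#'   `timing`.
#' @export
quantify_rois <- function(pre, post, rois, roi_names = NULL, n_sd = 2,
                          timing = "30 min post-injection") {
  stopifnot(inherits(rois, "roi_set"))
  if (is.null(roi_names))
    roi_names <- intersect(c("core", "borderzone", "contralesional", "lesion"),
                           names(rois$masks))
  if (!length(roi_names)) stop("no ROI selected for quantification")
  missing_rois <- setdiff(roi_names, names(rois$masks))
  if (length(missing_rois))
    stop("unknown ROI(s): ", paste(missing_rois, collapse = ", "))
  rows <- lapply(roi_names, function(nm) {
    roi <- rois$masks[[nm]]
    e3 <- eq3_ce_volume_fraction(pre, post, roi, n_sd)
    data.frame(roi = nm,
               eq1_signal_reduction = eq1_signal_reduction(pre, post, roi),
               eq3_ce_volume_percent = e3$percent,
               ce_count_pre = e3$ce_count_pre,
               ce_count_post = e3$ce_count_post,
               n_voxels = e3$n_voxels,
               timing = timing)
  })
  do.call(rbind, rows)
}
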