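#' Phantom geometry and tissue parameters
#'
#' Describes a brain-like digital phantom: a uniform background tissue with a
#' unilateral spherical lesion of prolonged T2 (ischemic tissue shows T2
#' hyperintensity on maps at subacute stages), parametric ventricles
#' (ellipsoids, mirror-symmetric about the midline) and a corpus-callosum slab,
#' split into hemispheres along `midline_axis`.
#'
#' Defaults emulate a mouse brain acquisition at desk scale: in-plane spacing
#' 0.104 x 0.208 mm (20 mm FOV, 192 x 96 matrix) with 0.4 mm slices; tissue
#' T2 45 ms and lesion T2 80 ms (clearly prolonged); grid 64 x 64 x 16 so a
#' cohort of phantoms fits comfortably in memory.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_spacing numeric length-3 spacing in mm.
#' @param t2_background,t2_lesion tissue T2 in ms; the lesion must be
#'   T2-prolonged (`t2_lesion > t2_background`).
#' @param s0_background equilibrium signal (a.u.).
#' @param lesion_center voxel coordinates (1-based) of the lesion sphere.
#' @param lesion_radius sphere radius in voxel units; 0 gives no lesion.
#' @param ventricle_centers list of voxel-coordinate centers for ellipsoidal
#'   ventricles.
#' @param ventricle_semiaxes numeric length-3 ellipsoid semi-axes (voxels).
#' @param cc_box list with `from` and `to` voxel corners of the
#'   corpus-callosum slab.
#' @param midline_axis axis (1..3) perpendicular to the midsagittal plane.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_spacing = c(0.104, 0.208, 0.4),
                         t2_background = 45,
                         t2_lesion = 80,
                         s0_background = 1000,
                         lesion_center = c(46, 36, 8),
                         lesion_radius = 6,
                         ventricle_centers = list(c(27, 30, 8), c(38, 30, 8)),
                         ventricle_semiaxes = c(1.5, 3, 2),
                         cc_box = list(from = c(20, 20, 6), to = c(45, 23, 11)),
                         midline_axis = 1L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    t2_background = t2_background,
    t2_lesion = t2_lesion,
    s0_background = s0_background,
    lesion_center = as.numeric(lesion_center),
    lesion_radius = as.numeric(lesion_radius),
    ventricle_centers = lapply(ventricle_centers, as.numeric),
    ventricle_semiaxes = as.numeric(ventricle_semiaxes),
    cc_box = lapply(cc_box, as.numeric),
    midline_axis = as.integer(midline_axis)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  gs <- spec$grid_shape
  if (length(gs) != 3L || any(gs < 2L))
    stop("grid_shape must be 3 integers >= 2")
  if (any(spec$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (!(spec$t2_lesion > spec$t2_background))
    stop("t2_lesion must exceed t2_background (lesion tissue is T2-prolonged)")
  if (spec$t2_background <= 0) stop("t2_background must be positive")
  if (spec$s0_background <= 0) stop("s0_background must be positive")
  if (!spec$midline_axis %in% 1:3) stop("midline_axis must be 1, 2, or 3")
  if (spec$lesion_radius < 0) stop("lesion_radius must be >= 0")
  inside <- function(lo, hi, what) {
    if (any(lo < 1) || any(hi > gs))
      stop("geometry outside grid: ", what)
  }
  r <- spec$lesion_radius
  if (r > 0) {
    inside(spec$lesion_center - r, spec$lesion_center + r, "lesion sphere")
    # lesion confined to one hemisphere along the midline axis
    ax <- spec$midline_axis
    mid <- (gs[ax] + 1) / 2
    lo <- spec$lesion_center[ax] - r
    hi <- spec$lesion_center[ax] + r
    if (lo < mid && hi > mid)
      stop("geometry outside grid: lesion sphere crosses the midline")
  }
  for (i in seq_along(spec$ventricle_centers))
    inside(spec$ventricle_centers[[i]] - spec$ventricle_semiaxes,
           spec$ventricle_centers[[i]] + spec$ventricle_semiaxes,
           paste0("ventricle ", i))
  inside(spec$cc_box$from, spec$cc_box$to, "corpus callosum slab")
  invisible(spec)
}

#' Contrast administration model for the synthetic pre/post pair
#'
#' Parameters of the simulated T2*-weighted pre/post-contrast experiment.
#' MPIO binding is imposed as a multiplicative signal drop on a seeded subset
#' of voxels of each target ROI; the chronic-stage confound (tissue already
#' hypointense before injection, e.g. phagocytosed blood remains at day 21)
#' darkens a fraction of lesion voxels in both the pre and the post image.
#'
#' @param ce_fraction_per_roi named numeric vector in `[0, 1]`: target fraction
#'   of voxels rendered hypointense post-contrast per ROI name.
#' @param ce_amplitude multiplicative signal-drop factor in `(0, 1)` applied to
#'   seeded voxels (0.4 means the voxel keeps 40% of its signal).
#' @param pre_hypointense_fraction fraction of lesion voxels darkened in both
#'   pre and post (the day-7/21 confound); these voxels never enter the true CE
#'   mask.
#' @param noise_sigma Rician noise level in the same a.u. as S0.
#' @param gre_te gradient-echo TE (ms) used to turn (S0, T2) into the
#'   T2*-weighted baseline signal.
#' @param seed integer seed for voxel seeding and noise.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(ce_fraction_per_roi = c(lesion = 0.10),
                          ce_amplitude = 0.4,
                          pre_hypointense_fraction = 0,
                          noise_sigma = 20,
                          gre_te = 15,
                          seed = NULL) {
  cs <- structure(list(
    ce_fraction_per_roi = ce_fraction_per_roi,
    ce_amplitude = ce_amplitude,
    pre_hypointense_fraction = pre_hypointense_fraction,
    noise_sigma = noise_sigma,
    gre_te = gre_te,
    seed = seed
  ), class = "contrast_spec")
  validate_contrast_spec(cs)
  cs
}

validate_contrast_spec <- function(cs) {
  f <- cs$ce_fraction_per_roi
  if (length(f) && (is.null(names(f)) || !all(nzchar(names(f)))))
    stop("ce_fraction_per_roi must be a named vector of ROI fractions")
  if (any(f < 0) || any(f > 1))
    stop("ce_fraction_per_roi values must lie in [0, 1]")
  if (cs$ce_amplitude <= 0 || cs$ce_amplitude >= 1)
    stop("ce_amplitude must lie in (0, 1)")
  if (cs$pre_hypointense_fraction < 0 || cs$pre_hypointense_fraction > 1)
    stop("pre_hypointense_fraction must lie in [0, 1]")
  if (cs$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cs$gre_te <= 0) stop("gre_te must be positive")
  invisible(cs)
}

# ellipsoid / sphere voxelization: voxel centers at integer coordinates
voxelize_ellipsoid <- function(grid_shape, center, semiaxes) {
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - center[a]) /
                                   semiaxes[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  array(d2 <= 1, dim = grid_shape)
}

hemisphere_masks <- function(grid_shape, midline_axis) {
  idx <- slice.index(array(0L, grid_shape), midline_axis)
  mid <- (grid_shape[midline_axis] + 1) / 2
  list(low = idx < mid, high = idx > mid)
}

#' Build a noiseless phantom from its spec
#'
#' @param spec a [phantom_spec()].
#' @return list with `t2_map` and `s0_map` (`vol3d`) and `rois` (a `roi_set`
#'   holding `lesion`, `ipsi_hemisphere`, `contra_hemisphere`, `ventricles`,
#'   `corpus_callosum`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  gs <- spec$grid_shape

  lesion <- if (spec$lesion_radius > 0) {
    voxelize_ellipsoid(gs, spec$lesion_center, rep(spec$lesion_radius, 3))
  } else {
    array(FALSE, gs)
  }
  vent <- array(FALSE, gs)
  for (ctr in spec$ventricle_centers)
    vent <- vent | voxelize_ellipsoid(gs, ctr, spec$ventricle_semiaxes)
  cc <- array(FALSE, gs)
  fr <- pmax(ceiling(spec$cc_box$from), 1)
  to <- pmin(floor(spec$cc_box$to), gs)
  cc[fr[1]:to[1], fr[2]:to[2], fr[3]:to[3]] <- TRUE

  hemis <- hemisphere_masks(gs, spec$midline_axis)
  # ipsilesional = the hemisphere holding the lesion (default: high side)
  ipsi_is_high <- if (any(lesion)) {
    ax_mean <- mean(slice.index(lesion, spec$midline_axis)[lesion])
    ax_mean > (gs[spec$midline_axis] + 1) / 2
  } else TRUE
  ipsi <- if (ipsi_is_high) hemis$high else hemis$low
  contra <- if (ipsi_is_high) hemis$low else hemis$high

  t2 <- array(spec$t2_background, gs)
  t2[lesion] <- spec$t2_lesion
  s0 <- array(spec$s0_background, gs)

  list(
    t2_map = vol3d(t2, spec$voxel_spacing),
    s0_map = vol3d(s0, spec$voxel_spacing),
    rois = roi_set(list(lesion = lesion,
                        ipsi_hemisphere = ipsi,
                        contra_hemisphere = contra,
                        ventricles = vent,
                        corpus_callosum = cc),
                   spec$voxel_spacing)
  )
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude MRI noise: each voxel value `v` is replaced by
#' `sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` independent.
#' `sigma = 0` is the identity.
#'
#' @param volume a `vol3d` or numeric array.
#' @param sigma noise standard deviation (same a.u. as the signal), >= 0.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return same type as `volume`.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  dat <- if (inherits(volume, "vol3d")) volume$data else volume
  n <- length(dat)
  noisy <- with_seed(seed, {
    n1 <- stats::rnorm(n, 0, sigma)
    n2 <- stats::rnorm(n, 0, sigma)
    sqrt((as.vector(dat) + n1)^2 + n2^2)
  })
  out <- array(noisy, dim = dim(dat))
  if (inherits(volume, "vol3d")) vol3d(out, volume$spacing) else out
}

#' Simulate a multi-echo spin-echo series
#'
#' Noiseless signal at echo time TE is `S0 * exp(-TE / T2)`; Rician noise is
#' then applied per echo. Default echo times follow the emulated protocol:
#' 8 echoes, TE 12-96 ms in 12 ms steps.
#'
#' @param true_t2_map,s0_map `vol3d` parameter maps on one grid (T2 in ms).
#' @param echo_times strictly increasing positive echo times (ms).
#' @param noise_sigma Rician sigma (a.u.).
#' @param seed optional integer seed.
#' @return a `multiecho`.
#' @export
simulate_multiecho <- function(true_t2_map, s0_map,
                               echo_times = seq(12, 96, by = 12),
                               noise_sigma = 0, seed = NULL) {
  true_t2_map <- as_vol3d(true_t2_map)
  s0_map <- as_vol3d(s0_map)
  if (!same_grid(true_t2_map$data, s0_map$data))
    stop("t2 and s0 maps must share one grid")
  echo_times <- as.numeric(echo_times)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be positive and strictly increasing")
  gs <- dim(true_t2_map$data)
  dat <- array(0, dim = c(gs, length(echo_times)))
  t2 <- true_t2_map$data
  s0 <- s0_map$data
  for (e in seq_along(echo_times)) {
    sig <- s0 * exp(-echo_times[e] / t2)
    sig[t2 <= 0] <- 0
    if (noise_sigma > 0)
      sig <- add_rician_noise(sig, noise_sigma, derive_seed(seed, e))
    dat[, , , e] <- sig
  }
  multiecho(dat, echo_times, true_t2_map$spacing)
}

# sample k indices from pool without replacement, seeded
sample_voxels <- function(pool, k, seed) {
  if (k <= 0) return(integer(0))
  if (k > length(pool))
    stop("requested ", k, " voxels from a pool of ", length(pool))
  with_seed(seed, sample(pool, k))
}

#' Simulate a pre/post-contrast T2*-weighted pair with known ground truth
#'
#' The baseline (pre-contrast) image is `S0 * exp(-gre_te / T2)`. Per ROI named
#' in `cspec$ce_fraction_per_roi`, a seeded subset of voxels (count =
#' round-half-away-from-zero of fraction x ROI size, drawn without
#' replacement) has its post-contrast signal multiplied by `ce_amplitude`,
#' mimicking focal MPIO-induced hypointensity. A `pre_hypointense_fraction`
#' subset of lesion voxels is darkened in BOTH images (the chronic-stage
#' confound of pre-contrast signal loss); confound voxels are excluded from
#' seeding and from the true CE mask. Rician noise is applied last,
#' independently to pre and post.
#'
#' @param true_t2_map,s0_map `vol3d` parameter maps.
#' @param rois a `roi_set` whose mask names cover
#'   `names(cspec$ce_fraction_per_roi)`.
#' @param cspec a [contrast_spec()].
#' @return list with `pre`, `post` (`vol3d`) and `gt` (list: `true_ce_mask`,
#'   `confound_mask`, `lesion_mask`, `true_t2_map`, `seeded_counts`).
#' @export
simulate_contrast_pair <- function(true_t2_map, s0_map, rois, cspec) {
  stopifnot(inherits(rois, "roi_set"), inherits(cspec, "contrast_spec"))
  validate_contrast_spec(cspec)
  true_t2_map <- as_vol3d(true_t2_map)
  s0_map <- as_vol3d(s0_map)
  gs <- dim(true_t2_map$data)
  missing_rois <- setdiff(names(cspec$ce_fraction_per_roi), names(rois$masks))
  if (length(missing_rois))
    stop("requested ROIs absent from roi_set: ",
         paste(missing_rois, collapse = ", "))

  base <- s0_map$data * exp(-cspec$gre_te / true_t2_map$data)
  base[true_t2_map$data <= 0] <- 0

  lesion <- if ("lesion" %in% names(rois$masks)) rois$masks$lesion
            else if ("core" %in% names(rois$masks)) rois$masks$core
            else array(FALSE, gs)

  confound <- array(FALSE, gs)
  if (cspec$pre_hypointense_fraction > 0 && any(lesion)) {
    pool <- which(lesion)
    k <- round_half_away(cspec$pre_hypointense_fraction * length(pool))
    confound[sample_voxels(pool, k, derive_seed(cspec$seed, 101L))] <- TRUE
  }

  ce <- array(FALSE, gs)
  seeded_counts <- integer(0)
  for (i in seq_along(cspec$ce_fraction_per_roi)) {
    nm <- names(cspec$ce_fraction_per_roi)[i]
    frac <- cspec$ce_fraction_per_roi[[i]]
    roi <- rois$masks[[nm]]
    k <- round_half_away(frac * sum(roi))
    pool <- which(roi & !confound & !ce)
    idx <- sample_voxels(pool, min(k, length(pool)),
                         derive_seed(cspec$seed, 200L + i))
    ce[idx] <- TRUE
    seeded_counts[nm] <- length(idx)
  }

  pre <- base
  pre[confound] <- pre[confound] * cspec$ce_amplitude
  post <- pre
  post[ce] <- post[ce] * cspec$ce_amplitude

  if (cspec$noise_sigma > 0) {
    pre <- add_rician_noise(pre, cspec$noise_sigma,
                            derive_seed(cspec$seed, 301L))
    post <- add_rician_noise(post, cspec$noise_sigma,
                             derive_seed(cspec$seed, 302L))
  }

  list(
    pre = vol3d(pre, true_t2_map$spacing),
    post = vol3d(post, true_t2_map$spacing),
    gt = list(true_ce_mask = ce,
              confound_mask = confound,
              lesion_mask = lesion,
              true_t2_map = true_t2_map,
              seeded_counts = seeded_counts)
  )
}

#' Generate a synthetic cohort with group structure
#'
#' One independent phantom per subject (lesion center/radius jittered under a
#' per-subject derived seed) with a group-specific contrast model: targeted
#' agent groups get their stated CE fractions, control/saline groups get ~0,
#' mimicking scarce nonspecific signal reductions after a control agent.
#'
#' @param n_per_group subjects per group, >= 1.
#' @param groups data.frame with columns `agent` and `day` (one row per group),
#'   or a list of `list(agent=, day=)`.
#' @param spec base [phantom_spec()] shared by all subjects.
#' @param cspec_per_group a single [contrast_spec()] recycled to all groups, or
#'   a list of one spec per group row.
#' @param seed root seed; subject seeds are derived from it.
#' @param center_jitter,radius_jitter max absolute per-subject jitter (voxels).
#' @param simulate_series if `TRUE` each record carries a multi-echo series
#'   (noise `sigma = cspec$noise_sigma`) for T2 fitting.
#' @return list of subject records: `subject`, `agent`, `day`, `spec`,
#'   `phantom` (maps + rois), `pre`, `post`, `gt`, optional `series`.
#' @export
generate_cohort <- function(n_per_group, groups, spec = phantom_spec(),
                            cspec_per_group = contrast_spec(), seed = 1L,
                            center_jitter = 2L, radius_jitter = 1L,
                            simulate_series = FALSE) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i)
      list(agent = groups$agent[i], day = groups$day[i]))
  }
  if (!length(groups)) stop("group list must not be empty")
  if (inherits(cspec_per_group, "contrast_spec"))
    cspec_per_group <- rep(list(cspec_per_group), length(groups))
  if (length(cspec_per_group) != length(groups))
    stop("cspec_per_group must match the number of groups")

  records <- list()
  sidx <- 0L
  for (g in seq_along(groups)) {
    for (s in seq_len(n_per_group)) {
      sidx <- sidx + 1L
      sseed <- derive_seed(seed, sidx)
      jit <- with_seed(sseed, list(
        center = sample(seq(-center_jitter, center_jitter), 3, replace = TRUE),
        radius = sample(seq(-radius_jitter, radius_jitter), 1)
      ))
      sspec <- spec
      sspec$lesion_center <- spec$lesion_center + jit$center
      sspec$lesion_radius <- max(spec$lesion_radius + jit$radius, 0)
      # clamp so the jittered sphere stays inside the grid and its hemisphere
      gs <- sspec$grid_shape
      r_max <- min(floor((min(gs) - 1) / 2),
                   floor((gs[spec$midline_axis] - 2) / 4))
      sspec$lesion_radius <- min(sspec$lesion_radius, r_max)
      r <- sspec$lesion_radius
      sspec$lesion_center <- pmin(pmax(sspec$lesion_center, 1 + r), gs - r)
      ax <- sspec$midline_axis
      mid <- (gs[ax] + 1) / 2
      if (spec$lesion_center[ax] > mid) {
        sspec$lesion_center[ax] <- max(sspec$lesion_center[ax],
                                       ceiling(mid + r))
      } else {
        sspec$lesion_center[ax] <- min(sspec$lesion_center[ax],
                                       floor(mid - r))
      }
      validate_phantom_spec(sspec)
      ph <- make_phantom(sspec)
      cs <- cspec_per_group[[g]]
      cs$seed <- derive_seed(sseed, 7L)
      pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)
      rec <- list(subject = sprintf("S%03d", sidx),
                  agent = groups[[g]]$agent,
                  day = groups[[g]]$day,
                  spec = sspec,
                  phantom = ph,
                  pre = pair$pre, post = pair$post, gt = pair$gt)
      if (simulate_series)
        rec$series <- simulate_multiecho(ph$t2_map, ph$s0_map,
                                         noise_sigma = cs$noise_sigma,
                                         seed = derive_seed(sseed, 11L))
      records[[sidx]] <- rec
    }
  }
  records
}
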