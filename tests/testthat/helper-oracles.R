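# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force enumerations, independent of the package's vectorized paths.

# small phantom for fast tests: 32x32x8 grid, lesion radius 3
small_spec <- function(...) {
  defaults <- list(grid_shape = c(32L, 32L, 8L),
                   lesion_center = c(23, 18, 4),
                   lesion_radius = 3,
                   ventricle_centers = list(c(13, 14, 4), c(20, 14, 4)),
                   ventricle_semiaxes = c(1.5, 2, 1.5),
                   cc_box = list(from = c(10, 10, 3), to = c(23, 12, 6)))
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force voxel-center sphere inclusion (triple loop)
sphere_count_oracle <- function(grid_shape, center, radius) {
  cnt <- 0L
  for (i in seq_len(grid_shape[1]))
    for (j in seq_len(grid_shape[2]))
      for (k in seq_len(grid_shape[3]))
        if ((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <=
            radius^2) cnt <- cnt + 1L
  cnt
}

# exhaustive in-plane Chebyshev-distance-<=2 borderzone oracle
borderzone_oracle <- function(core, exclusions = list()) {
  gs <- dim(core)
  out <- array(FALSE, gs)
  for (z in seq_len(gs[3])) {
    cz <- which(core[, , z], arr.ind = TRUE)
    if (!nrow(cz)) next
    vx <- rep(seq_len(gs[1]), times = gs[2])
    vy <- rep(seq_len(gs[2]), each = gs[1])
    near <- (abs(outer(vx, cz[, 1], `-`)) <= 2) &
            (abs(outer(vy, cz[, 2], `-`)) <= 2)
    out[, , z] <- matrix(rowSums(near) > 0, gs[1], gs[2])
  }
  out <- out & !core
  for (ex in exclusions) out <- out & !ex
  out
}

random_core_3d <- function(nx, ny, nz = 1L, density = 0.1) {
  array(stats::runif(nx * ny * nz) < density, dim = c(nx, ny, nz))
}

# brute-force BH step-up: find the largest k with p_(k) <= k/m * q; adjusted
# p_i = min over k >= rank(i) of m * p_(k) / k, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# null group table for contrast calibration: 2 agents x rois x days, iid noise
null_group_table <- function(n_per_cell = 5, rois = c("core", "borderzone",
                                                      "contralesional"),
                             days = c(1, 2)) {
  grid <- expand.grid(agent = c("targeted", "control"), roi = rois,
                      day = days, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(subject = paste0(grid$agent[i], "_", seq_len(n_per_cell),
                                "_d", grid$day[i]),
               agent = grid$agent[i], roi = grid$roi[i], day = grid$day[i],
               eq3_ce_volume_percent = stats::rnorm(n_per_cell))
  }))
}
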