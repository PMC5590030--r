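# Connected-component labelling on 3D logical masks (26-connectivity by
# default), used to clean up voxelwise segmentations. BFS over precomputed
# neighbour offsets in flat index space; masks here are at most a few
# thousand voxels so plain R is fine.

neighbor_offsets <- function(gs, connectivity = 26L) {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  if (connectivity == 6L) d <- d[abs(d$dx) + abs(d$dy) + abs(d$dz) == 1, ]
  else if (connectivity == 18L) d <- d[abs(d$dx) + abs(d$dy) + abs(d$dz) <= 2, ]
  else if (connectivity != 26L) stop("connectivity must be 6, 18 or 26")
  as.matrix(d)
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- check_mask(mask)
  gs <- dim(mask)
  offs <- neighbor_offsets(gs, connectivity)
  labels <- array(0L, gs)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  coords <- arrayInd(idx, gs)
  coord_of <- matrix(NA_integer_, nrow = prod(gs), ncol = 3)
  coord_of[idx, ] <- coords
  lab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      vc <- coord_of[v, ]
      nb <- sweep(offs, 2, vc, `+`)
      keep <- nb[, 1] >= 1 & nb[, 1] <= gs[1] &
              nb[, 2] >= 1 & nb[, 2] <= gs[2] &
              nb[, 3] >= 1 & nb[, 3] <= gs[3]
      nb <- nb[keep, , drop = FALSE]
      ni <- nb[, 1] + gs[1] * (nb[, 2] - 1L) + gs[1] * gs[2] * (nb[, 3] - 1L)
      ni <- ni[mask[ni] & labels[ni] == 0L]
      if (length(ni)) {
        labels[ni] <- lab
        queue <- c(queue, ni)
      }
    }
  }
  labels
}

#' Keep only the largest connected component of a mask
#'
#' @inheritParams label_components
#' @return logical array; empty input returns empty output.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  labels <- label_components(mask, connectivity)
  if (!any(labels > 0L)) return(array(FALSE, dim(mask)))
  tab <- tabulate(labels[labels > 0L])
  array(labels == which.max(tab), dim(mask))
}
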