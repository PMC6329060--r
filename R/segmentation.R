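# Bone segmentation: HU thresholding, seeded region growing (26-connected),
# and seeded component removal (the paper's manual femur/vertebra removal,
# replaced here by file-supplied seeds).

#' Construct a binary mask
#'
#' @param voxels 3-d logical array.
#' @param geometry a [ct_volume()] (or another `binary_mask`) providing
#'   spacing/origin/direction; the grids must match.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, geometry) {
  if (!identical(dim(voxels), dim(geometry$voxels)))
    stop("mask grid does not match source volume grid")
  structure(list(voxels = voxels, spacing = geometry$spacing,
                 origin = geometry$origin, direction = geometry$direction),
            class = c("binary_mask"))
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d set (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' Threshold a volume into a bone mask
#'
#' A voxel is set iff `hu_low <= HU <= hu_high`. The default lower bound of
#' 200 HU is a configurable stand-in for the per-case expert threshold.
#'
#' @param vol a [ct_volume()].
#' @param hu_low,hu_high HU window bounds (`hu_high` may be `Inf`).
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(vol, hu_low = 200, hu_high = Inf) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!(hu_low < hu_high)) stop("hu_low must be below hu_high")
  binary_mask(vol$voxels >= hu_low & vol$voxels <= hu_high, vol)
}

# physical seed -> 0-based integer voxel index, with bounds check
seed_to_index <- function(mask, seed) {
  idx <- round(physical_to_voxel(mask, seed))
  d <- dim(mask$voxels)
  if (any(idx < 0) || any(idx >= d))
    stop(sprintf("seed (%.1f, %.1f, %.1f) maps outside the grid",
                 seed[1], seed[2], seed[3]))
  as.integer(idx)
}

seed_linear <- function(mask, seed, snap_radius = 0) {
  idx <- seed_to_index(mask, seed)
  d <- dim(mask$voxels)
  if (mask$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1])
    return(idx[1] + d[1] * (idx[2] + d[2] * idx[3]))
  # locate the nearest set voxel for the error hint / optional snapping
  set_idx <- which(mask$voxels)
  if (length(set_idx) == 0) stop("mask is empty; cannot place seed")
  k0 <- (set_idx - 1) %/% (d[1] * d[2])
  r <- (set_idx - 1) %% (d[1] * d[2])
  ijk <- cbind(r %% d[1], r %/% d[1], k0)
  pts <- voxel_to_physical(mask, ijk)
  dist <- sqrt(rowSums(sweep(pts, 2, seed)^2))
  j <- which.min(dist)
  if (snap_radius > 0 && dist[j] <= snap_radius) {
    idx <- ijk[j, ]
    return(idx[1] + d[1] * (idx[2] + d[2] * idx[3]))
  }
  stop(sprintf(paste0("seed (%.1f, %.1f, %.1f) is not on a set voxel; ",
                      "nearest set voxel is at (%.1f, %.1f, %.1f), %.1f mm away"),
               seed[1], seed[2], seed[3],
               pts[j, 1], pts[j, 2], pts[j, 3], dist[j]))
}

#' Keep the connected component containing a seed
#'
#' 26-connected region growing from a physical seed point.
#'
#' @param mask a [binary_mask()].
#' @param seed physical point (mm) that must fall on a set voxel.
#' @param snap_radius if positive, a seed that misses the mask is snapped to
#'   the nearest set voxel within this distance (mm) instead of erroring.
#' @return A [binary_mask()] containing only the seed's component.
#' @export
region_grow <- function(mask, seed, snap_radius = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  lin <- seed_linear(mask, seed, snap_radius)
  comp <- .flood_fill26(as.logical(mask$voxels), dim(mask$voxels), lin)
  binary_mask(array(comp, dim = dim(mask$voxels)), mask)
}

#' Delete the connected component containing a seed
#'
#' Seeded replacement for the manual removal of femoral heads and vertebrae:
#' the 26-connected component under the seed is cleared, all other voxels
#' are unchanged.
#'
#' @inheritParams region_grow
#' @return A [binary_mask()] without the seed's component.
#' @export
remove_component <- function(mask, seed, snap_radius = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  lin <- seed_linear(mask, seed, snap_radius)
  comp <- .flood_fill26(as.logical(mask$voxels), dim(mask$voxels), lin)
  binary_mask(array(mask$voxels & !comp, dim = dim(mask$voxels)), mask)
}

#' Write a mask as NIfTI (uint8-valued)
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  vol <- ct_volume(array(as.numeric(mask$voxels), dim = dim(mask$voxels)),
                   spacing = mask$spacing, origin = mask$origin,
                   direction = mask$direction)
  write_volume(vol, path)
}
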