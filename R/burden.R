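#' @include grid.R
NULL

# per-streamline voxel ids (unique, in-grid) after resampling at step mm
streamlineVoxelIds <- function(poly, grid, step) {
  pts <- resamplePolyline(poly, step)
  wv <- worldToVoxel(pts, grid)
  idx <- wv$index[wv$inGrid, , drop = FALSE]
  if (nrow(idx) == 0L) return(integer())
  unique(voxelId(idx, gridShape(grid)))
}

#' Voxelize a set of streamlines
#'
#' Each polyline is resampled so consecutive samples are at most half the
#' smallest voxel edge apart (so no voxel is skipped on straight segments),
#' every sample is mapped to its nearest voxel, and the union of in-grid
#' voxels is returned together with the volume it occupies.
#'
#' @param streamlines a \linkS4class{TractBundle} or list of n x 3 matrices.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param step resampling step in mm; default half the smallest voxel edge.
#' @return list with \code{voxels} (sorted 1-based linear voxel ids),
#'   \code{index} (matrix of 0-based triplets) and \code{volume} in mm^3.
#' @export
voxelizeStreamlines <- function(streamlines, grid, step = NULL) {
  name <- "streamlines"
  if (is(streamlines, "TractBundle")) {
    name <- bundleName(streamlines)
    streamlines <- streamlines(streamlines)
  }
  if (length(streamlines) == 0L) stop("no streamlines to voxelize")
  if (is.null(step)) step <- minSpacing(grid) / 2
  ids <- sort(unique(unlist(
    lapply(streamlines, streamlineVoxelIds, grid = grid, step = step))))
  if (length(ids) == 0L)
    stop(sprintf("all points of '%s' fall outside the grid", name))
  list(voxels = ids, index = idToIndex(ids, gridShape(grid)),
       volume = length(ids) * voxelVolume(grid))
}

# lesion voxel ids of a mask, on its own grid
maskVoxelIds <- function(mask) {
  which(as.vector(maskArray(mask)) == 1L)
}

checkSharedFrame <- function(bundle, mask) {
  shp <- gridShape(mask)
  corn <- as.matrix(expand.grid(c(0, shp[1] - 1), c(0, shp[2] - 1),
                                c(0, shp[3] - 1)))
  box <- applyAffine(worldAffine(mask), corn)
  lo <- apply(box, 2, min) - 2 * minSpacing(maskGrid(mask))
  hi <- apply(box, 2, max) + 2 * minSpacing(maskGrid(mask))
  pts <- do.call(rbind, streamlines(bundle))
  frac <- mean(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
               pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
               pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
  if (frac < 0.5)
    stop(sprintf(
      "bundle '%s' and mask do not share a world frame (%d%% of points in mask box)",
      bundleName(bundle), round(100 * frac)))
}

#' Partition a bundle into lesion-injured and spared streamlines
#'
#' A streamline is injured if at least one of its resampled points maps to a
#' lesion voxel; injured and spared together restore the input bundle, in
#' order.
#'
#' @param bundle a \linkS4class{TractBundle}.
#' @param mask a \linkS4class{LesionMask} in the same world frame.
#' @param step resampling step in mm (default half the smallest voxel edge).
#' @return list with \code{injured} and \code{spared}
#'   \linkS4class{TractBundle}s (NULL when the partition is empty) and the
#'   logical vector \code{isInjured}, aligned with the input streamlines.
#' @export
filterInjured <- function(bundle, mask, step = NULL) {
  checkSharedFrame(bundle, mask)
  grid <- maskGrid(mask)
  if (is.null(step)) step <- minSpacing(grid) / 2
  lesion <- maskVoxelIds(mask)
  isInjured <- vapply(streamlines(bundle), function(poly) {
    ids <- streamlineVoxelIds(poly, grid, step)
    any(ids %in% lesion)
  }, logical(1))
  injured <- streamlines(bundle)[isInjured]
  spared <- streamlines(bundle)[!isInjured]
  list(
    injured = if (length(injured)) tractBundle(paste0(bundleName(bundle), "_injured"), injured) else NULL,
    spared = if (length(spared)) tractBundle(paste0(bundleName(bundle), "_spared"), spared) else NULL,
    isInjured = isInjured)
}

#' Tract lesion burden from streamline filtering
#'
#' Lesion burden is the mean volume occupied by injured streamlines across
#' the two hemispheres divided by the mean volume occupied by all
#' streamlines of the canonical tract:
#' \deqn{burden = \frac{(V^{inj}_L + V^{inj}_R)/2}{(V^{can}_L + V^{can}_R)/2}}
#' Volumes are voxel-count volumes of the union of voxels traversed, so the
#' burden always lies in [0, 1].
#'
#' @param left,right \linkS4class{TractBundle}s for the two hemispheres.
#' @param mask a \linkS4class{LesionMask}.
#' @param grid optional \linkS4class{VoxelGrid}; defaults to the mask's.
#' @param tractName label for the result row; default from the left bundle.
#' @return one-row data.frame: tract, injured_vol_l/r, canonical_vol_l/r,
#'   n_injured_l/r, burden, total_lesion_volume.
#' @export
tractBurden <- function(left, right, mask, grid = NULL,
                        tractName = sub("_(left|l)$", "", bundleName(left))) {
  if (is.null(grid)) grid <- maskGrid(mask)
  sideVols <- function(bundle) {
    if (is.null(bundle) || length(streamlines(bundle)) == 0L)
      return(list(can = 0, inj = 0, n = 0L))
    can <- voxelizeStreamlines(bundle, grid)
    f <- filterInjured(bundle, mask)
    inj <- if (is.null(f$injured)) 0 else voxelizeStreamlines(f$injured, grid)$volume
    list(can = can$volume, inj = inj, n = sum(f$isInjured))
  }
  L <- sideVols(left); R <- sideVols(right)
  canMean <- (L$can + R$can) / 2
  if (canMean == 0)
    stop("undefined burden: both canonical tract volumes are zero")
  burden <- ((L$inj + R$inj) / 2) / canMean
  data.frame(tract = tractName,
             injured_vol_l = L$inj, injured_vol_r = R$inj,
             canonical_vol_l = L$can, canonical_vol_r = R$can,
             n_injured_l = L$n, n_injured_r = R$n,
             burden = burden,
             total_lesion_volume = totalLesionVolume(mask))
}

#' Total lesion volume of a mask
#'
#' @param mask a \linkS4class{LesionMask}.
#' @return lesion volume in mm^3.
#' @export
totalLesionVolume <- function(mask) {
  sum(maskArray(mask) == 1L) * voxelVolume(mask)
}
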