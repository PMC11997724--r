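#' @include AllClasses.R
NULL

# round half away from zero; fixed so voxel assignment is bit-reproducible
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct a VoxelGrid
#'
#' @param shape integer(3) grid dimensions.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix. Defaults to an
#'   isotropic grid of spacing \code{spacing} with the voxel (0,0,0) centred
#'   at the world origin.
#' @param spacing voxel edge length in mm, used when \code{affine} is NULL.
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelGrid <- function(shape, affine = NULL, spacing = 1) {
  shape <- as.integer(shape)
  if (is.null(affine))
    affine <- diag(c(rep(spacing, 3), 1))
  new("VoxelGrid", shape = shape, affine = affine,
      voxelVolume = abs(det(affine[1:3, 1:3])))
}

#' Construct a TractBundle
#'
#' @param name bundle label, e.g. "UF_left".
#' @param streamlines list of n x 3 matrices of world-mm points.
#' @return a \linkS4class{TractBundle}.
#' @export
tractBundle <- function(name, streamlines) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  new("TractBundle", name = name, streamlines = streamlines)
}

#' Construct a LesionMask
#'
#' @param grid 3D 0/1 array.
#' @param affine 4x4 voxel-to-world matrix (0-based indices); defaults to the
#'   identity with unit spacing.
#' @return a \linkS4class{LesionMask}.
#' @export
lesionMask <- function(grid, affine = NULL) {
  if (is.null(affine)) affine <- diag(4)
  storage.mode(grid) <- "integer"
  new("LesionMask", grid = grid, affine = affine,
      voxelVolume = abs(det(affine[1:3, 1:3])))
}

#' Extract the VoxelGrid of a LesionMask
#'
#' @param mask a \linkS4class{LesionMask}.
#' @return the \linkS4class{VoxelGrid} the mask lives on.
#' @export
maskGrid <- function(mask) {
  voxelGrid(dim(maskArray(mask)), worldAffine(mask))
}

#' Apply a 4x4 affine to 3D points
#'
#' @param affine 4x4 matrix.
#' @param points n x 3 matrix.
#' @return n x 3 matrix of transformed points.
#' @export
applyAffine <- function(affine, points) {
  points <- rbind(t(points), 1)
  t(affine %*% points)[, 1:3, drop = FALSE]
}

#' Map world-mm points to voxel indices
#'
#' Applies the inverse grid affine and rounds each continuous index to the
#' nearest integer (half away from zero). Points landing outside
#' \code{[0, shape)} are flagged, not clamped.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param grid a \linkS4class{VoxelGrid}.
#' @return list with \code{index} (n x 3 integer matrix of 0-based voxel
#'   indices) and \code{inGrid} (logical vector).
#' @export
worldToVoxel <- function(points, grid) {
  points <- matrixify(points)
  if (!all(is.finite(points)))
    stop("non-finite coordinates in world_to_voxel input")
  cont <- applyAffine(solve(worldAffine(grid)), points)
  idx <- roundHalfAway(cont)
  shp <- gridShape(grid)
  inGrid <- idx[, 1] >= 0 & idx[, 1] < shp[1] &
            idx[, 2] >= 0 & idx[, 2] < shp[2] &
            idx[, 3] >= 0 & idx[, 3] < shp[3]
  storage.mode(idx) <- "integer"
  list(index = idx, inGrid = inGrid)
}

matrixify <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  as.matrix(points)
}

# minimum voxel edge length along the three grid axes
minSpacing <- function(grid) {
  A <- worldAffine(grid)[1:3, 1:3]
  min(sqrt(colSums(A^2)))
}

#' Resample a polyline to a maximum step length
#'
#' Inserts linearly interpolated points so that consecutive samples are at
#' most \code{step} mm apart; original vertices are retained.
#'
#' @param poly n x 3 matrix.
#' @param step maximum inter-sample distance in mm.
#' @return m x 3 matrix with m >= n.
#' @export
resamplePolyline <- function(poly, step) {
  stopifnot(step > 0)
  n <- nrow(poly)
  segs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = k + 1L)
    if (i < n - 1L) tt <- tt[-length(tt)]  # avoid duplicating shared vertices
    segs[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                       a[2] + tt * (b[2] - a[2]),
                       a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, segs)
}

# linear voxel id (1-based) from 0-based index triplets
voxelId <- function(idx, shp) {
  as.integer(idx[, 1] + shp[1] * (idx[, 2] + shp[2] * idx[, 3]) + 1L)
}

idToIndex <- function(id, shp) {
  id0 <- id - 1
  cbind(id0 %% shp[1],
        (id0 %/% shp[1]) %% shp[2],
        id0 %/% (shp[1] * shp[2]))
}
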