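#' @include burden.R
NULL

# Precompute the tract incidence structure used by the greedy planter:
# per-streamline voxel sets and the voxel -> streamline map, for a bundle
# pair (left, right hemispheres treated jointly; volumes tracked per side).
tractIncidence <- function(bundlePair, grid) {
  step <- minSpacing(grid) / 2
  sides <- lapply(bundlePair, function(b)
    lapply(streamlines(b), streamlineVoxelIds, grid = grid, step = step))
  slVox <- c(sides[[1]], sides[[2]])
  side <- rep(c(1L, 2L), times = c(length(sides[[1]]), length(sides[[2]])))
  allVox <- sort(unique(unlist(slVox)))
  counts <- table(factor(unlist(slVox), levels = allVox))
  vox2sl <- vector("list", length(allVox))
  names(vox2sl) <- as.character(allVox)
  for (i in seq_along(slVox))
    for (v in as.character(slVox[[i]]))
      vox2sl[[v]] <- c(vox2sl[[v]], i)
  canVol <- c(length(unique(unlist(sides[[1]]))),
              length(unique(unlist(sides[[2]]))))
  list(slVox = slVox, side = side, allVox = allVox,
       counts = as.integer(counts), vox2sl = vox2sl, canVol = canVol)
}

# Greedy voxel selection: walk tract voxels ranked by streamline coverage
# (ascending, id tie-break) and keep adding until the recomputed burden
# reaches the target. Returns selected voxel ids and the achieved burden.
greedyPlant <- function(inc, target) {
  ord <- order(inc$counts, inc$allVox)
  injured <- logical(length(inc$slVox))
  voxCount <- integer(2)           # per-side union sizes of injured voxels
  seen <- list(integer(), integer())
  chosen <- integer()
  burden <- 0
  denom <- mean(inc$canVol)
  lastJump <- 0
  for (v in inc$allVox[ord]) {
    newSl <- inc$vox2sl[[as.character(v)]]
    newSl <- newSl[!injured[newSl]]
    chosen <- c(chosen, v)
    if (length(newSl)) {
      injured[newSl] <- TRUE
      for (i in newSl) {
        s <- inc$side[i]
        add <- setdiff(inc$slVox[[i]], seen[[s]])
        seen[[s]] <- c(seen[[s]], add)
        voxCount[s] <- voxCount[s] + length(add)
      }
      newBurden <- mean(voxCount) / denom
      lastJump <- newBurden - burden
      burden <- newBurden
    }
    if (burden >= target) break
  }
  list(voxels = chosen, burden = burden, lastJump = lastJump)
}

# plan lesion voxels for one target on a precomputed incidence structure
plantCore <- function(inc, target, tolerance) {
  if (target == 0)
    return(list(voxels = integer(), burden = 0, lastJump = 0))
  if (target >= 1)
    return(list(voxels = inc$allVox, burden = 1, lastJump = 0))
  plan <- greedyPlant(inc, target)
  if (abs(plan$burden - target) > tolerance)
    stop(sprintf(
      paste0("cannot plant burden %.3f within +/-%.3f: tract granularity ",
             "allows steps of up to %.3f (achieved %.3f); use denser ",
             "streamlines or a finer grid"),
      target, tolerance, plan$lastJump, plan$burden))
  plan
}

#' Plant a lesion mask achieving a target tract burden
#'
#' Chooses lesion voxels along a bundle pair so that the burden recomputed
#' by \code{\link{tractBurden}} matches \code{targetBurden}. Tract voxels
#' are ranked by the number of streamlines traversing them (fewest first,
#' deterministic id tie-break) and added greedily until the injured-volume
#' ratio reaches the (optionally noise-perturbed) target; this makes the
#' achieved burden monotone in the number of selected voxels and reachable
#' to voxel granularity.
#'
#' @param bundlePair list of two \linkS4class{TractBundle}s (left, right).
#' @param targetBurden desired burden in [0, 1].
#' @param grid a \linkS4class{VoxelGrid}.
#' @param noiseSd SD of Gaussian noise added to the target before planting
#'   (truncated back to [0, 1]); 0 for exact planting.
#' @param rng a \code{function(n)} returning standard-normal draws, so
#'   callers control the random stream; default \code{rnorm}.
#' @param tolerance maximal |achieved - target| before an error is raised.
#' @return list: \code{mask} (\linkS4class{LesionMask}), \code{achieved}
#'   burden, \code{target} (after noise), \code{voxels} (ids).
#' @export
plantLesionMask <- function(bundlePair, targetBurden, grid, noiseSd = 0,
                            rng = stats::rnorm, tolerance = 0.05) {
  stopifnot(targetBurden >= 0, targetBurden <= 1)
  target <- targetBurden
  if (noiseSd > 0)
    target <- min(1, max(0, target + rng(1) * noiseSd))
  inc <- tractIncidence(bundlePair, grid)
  plan <- plantCore(inc, target, tolerance)
  arr <- array(0L, dim = gridShape(grid))
  arr[plan$voxels] <- 1L
  mask <- new("LesionMask", grid = arr, affine = worldAffine(grid),
              voxelVolume = voxelVolume(grid))
  list(mask = mask, achieved = plan$burden, target = target,
       voxels = plan$voxels)
}

# Add n background lesion voxels drawn outside the given exclusion set.
addBackgroundLesion <- function(arr, nVoxels, excludeIds, rng01) {
  free <- setdiff(seq_along(arr), union(excludeIds, which(arr == 1L)))
  n <- min(nVoxels, length(free))
  if (n > 0) {
    pick <- free[ceiling(rng01(n) * length(free))]
    arr[unique(pick)] <- 1L
    # top up in case of duplicate draws
    deficit <- n - sum(arr[free] == 1L)
    if (deficit > 0) {
      rest <- setdiff(free, which(arr == 1L))
      arr[rest[seq_len(min(deficit, length(rest)))]] <- 1L
    }
  }
  arr
}
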