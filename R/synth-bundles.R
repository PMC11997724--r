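#' @include grid.R
NULL

# one arc streamline: half-circle in the y-z plane at fixed x, jittered;
# jitter draws are clamped to +/- 2 sd so bundles stay in their bands
arcStreamline <- function(cx, cy, cz, r, nPoints, jitter, rng) {
  th <- seq(-pi / 2, pi / 2, length.out = nPoints)
  clamp <- function(x) pmax(pmin(x, 2), -2)
  off <- clamp(rng(3)) * jitter
  rr <- r * (1 + clamp(rng(1)) * 0.08)
  cbind(cx + off[1],
        cy + off[2] + rr * sin(th),
        cz + off[3] + rr * cos(th))
}

#' Generate toy bilateral UF and fornix bundles
#'
#' Builds four parametric arc bundles standing in for atlas tracts: left and
#' right uncinate-fasciculus analogs (mirror-symmetric hook-like arcs in an
#' inferior band) and left/right fornix analogs (arcs in a superior band,
#' spatially disjoint from the UF arcs). Each streamline is a jittered copy
#' of the hemisphere's template arc; all points lie strictly inside the
#' world box implied by \code{gridShape * voxelSizeMm}.
#'
#' @param gridShape integer(3), template grid dimensions (each >= 16).
#' @param voxelSizeMm isotropic voxel edge in mm.
#' @param nStreamlinesPerSide streamlines per hemisphere per tract.
#' @param seed integer seed; output is deterministic given the seed.
#' @param nPoints vertices per streamline.
#' @return named list of four \linkS4class{TractBundle}s: UF_left, UF_right,
#'   fornix_left, fornix_right.
#' @export
makeToyBundles <- function(gridShape = c(64L, 64L, 64L), voxelSizeMm = 1,
                           nStreamlinesPerSide = 50L, seed = 1L,
                           nPoints = 40L) {
  stopifnot(nStreamlinesPerSide >= 1L, voxelSizeMm > 0)
  W <- gridShape * voxelSizeMm
  if (min(W) < 16)
    stop(sprintf(
      "grid too small for disjoint toy bundles: world extent %.1f mm < 16 mm minimum",
      min(W)))
  set.seed(seed %% .Machine$integer.max)
  rng <- function(n) stats::rnorm(n)
  jitter <- min(1.5, 0.03 * min(W))
  rUF <- 0.12 * min(W)
  rFx <- 0.10 * min(W)
  mk <- function(name, cx, cy, cz, r) {
    sl <- lapply(seq_len(nStreamlinesPerSide), function(i)
      arcStreamline(cx, cy, cz, r, nPoints, jitter, rng))
    tractBundle(name, sl)
  }
  bundles <- list(
    UF_left      = mk("UF_left",  0.30 * W[1], 0.32 * W[2], 0.28 * W[3], rUF),
    UF_right     = mk("UF_right", 0.70 * W[1], 0.32 * W[2], 0.28 * W[3], rUF),
    fornix_left  = mk("fornix_left",  0.38 * W[1], 0.55 * W[2], 0.68 * W[3], rFx),
    fornix_right = mk("fornix_right", 0.62 * W[1], 0.55 * W[2], 0.68 * W[3], rFx))
  eps <- 1e-6
  for (b in bundles) {
    pts <- do.call(rbind, streamlines(b))
    if (any(pts <= eps) || any(sweep(pts, 2, W, "-") >= -eps))
      stop(sprintf("bundle '%s' escapes the world box; enlarge the grid",
                   bundleName(b)))
  }
  bundles
}
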