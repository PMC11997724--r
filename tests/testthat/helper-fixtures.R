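# Shared fixtures and independent oracles used across the suite.

# random polyline bundle inside a world box [0, extent]^3
randomBundle <- function(nStreamlines = 5, nPoints = 8, extent = 20,
                         name = "rnd") {
  sl <- lapply(seq_len(nStreamlines), function(i) {
    start <- runif(3, 0.15 * extent, 0.85 * extent)
    steps <- matrix(runif(3 * (nPoints - 1), -1.5, 1.5), ncol = 3)
    pts <- apply(rbind(start, steps), 2, cumsum)
    pmin(pmax(pts, 0.05 * extent), 0.95 * extent)
  })
  tractBundle(name, sl)
}

# random lesion mask with a given lesion fraction on a grid
randomMask <- function(shape, frac = 0.1, affine = NULL) {
  arr <- array(as.integer(runif(prod(shape)) < frac), dim = shape)
  lesionMask(arr, affine)
}

# Brute-force voxel assignment: enumerate every voxel centre of the grid
# (diagonal affines only) and, for each sample point, find the unique voxel
# whose centre is within half a voxel edge along every axis, or NA when no
# in-grid voxel contains the point. Independent of worldToVoxel.
bruteGridCenters <- function(grid) {
  shp <- gridShape(grid)
  A <- worldAffine(grid)
  sp <- diag(A[1:3, 1:3])
  idx <- as.matrix(expand.grid(0:(shp[1] - 1), 0:(shp[2] - 1),
                               0:(shp[3] - 1)))
  list(centers = sweep(sweep(idx, 2, sp, "*"), 2, A[1:3, 4], "+"),
       ids = idx[, 1] + shp[1] * (idx[, 2] + shp[2] * idx[, 3]) + 1L,
       sp = sp)
}

bruteVoxelOf <- function(point, gc) {
  hit <- abs(gc$centers[, 1] - point[1]) < gc$sp[1] / 2 &
         abs(gc$centers[, 2] - point[2]) < gc$sp[2] / 2 &
         abs(gc$centers[, 3] - point[3]) < gc$sp[3] / 2
  w <- which(hit)
  if (length(w) == 0L) return(NA_integer_)
  stopifnot(length(w) == 1L)
  gc$ids[w]
}

# Brute-force voxelization of streamlines: resample (same contract as the
# implementation: samples at most step apart), then assign every sample by
# exhaustive scan over all (sample, voxel) pairs.
bruteVoxelize <- function(streamlines, grid, step = NULL) {
  if (is(streamlines, "TractBundle")) streamlines <- streamlines(streamlines)
  if (is.null(step)) step <- min(diag(worldAffine(grid)[1:3, 1:3])) / 2
  gc <- bruteGridCenters(grid)
  ids <- unlist(lapply(streamlines, function(poly) {
    pts <- resamplePolyline(poly, step)
    apply(pts, 1, bruteVoxelOf, gc = gc)
  }))
  sort(unique(ids[!is.na(ids)]))
}

# Brute-force injury call per streamline.
bruteInjured <- function(bundle, mask) {
  grid <- maskGrid(mask)
  lesion <- which(as.vector(maskArray(mask)) == 1L)
  vapply(streamlines(bundle), function(poly) {
    ids <- bruteVoxelize(list(poly), grid)
    any(ids %in% lesion)
  }, logical(1))
}

# Brute-force Benjamini-Hochberg: try every candidate threshold p_(k) and
# keep the largest k with p_(k) <= k*q/m; reject everything at or below.
bruteBH <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rejected <- logical(m)
  if (is.finite(k)) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# random EMR record generator for partition property tests
randomRecord <- function(dicts = codeDictionaries()) {
  pool <- c("G35", "F41.1", "F40.0", "F32.9", "F33.1", "I10", "E11.9",
            "F41.9", "M54.5")
  medPool <- c(dicts$anxiolyticMeds[1:3], dicts$antidepressantMeds[1:3],
               "metformin", "lisinopril")
  nPhq <- sample(0:2, 1)
  phq <- if (nPhq > 0) data.frame(
    instrument = sample(c("PHQ2", "PHQ9"), nPhq, replace = TRUE),
    score = sample(0:6, nPhq, replace = TRUE),
    date = as.Date("2015-01-01") + sample(0:100, nPhq)) else NULL
  patientRecord(
    patientId = "R1",
    icd10Codes = sample(pool, sample(0:4, 1)),
    medications = sample(medPool, sample(0:3, 1)),
    phqObs = phq,
    mriDates = as.Date("2015-06-01"))
}

# small analysis table simulated directly (no imaging) for GAM kernels
simTable <- function(n = 120, beta = 0, seed = 1) {
  set.seed(seed)
  sev <- sample(0:2, n, replace = TRUE, prob = c(0.27, 0.67, 0.06))
  age <- runif(n, 20, 70)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  tbv <- rnorm(n, 1.2e6, 1e5)
  y <- 0.05 + beta * sev + rnorm(n, 0, 0.03)
  data.frame(patient_id = sprintf("S%03d", seq_len(n)),
             anxiety = c("none", "mild", "severe")[sev + 1], severity = sev,
             depression = ifelse(sev > 0, "depression", "no_depression"),
             uf_burden = y, fornix_burden = rnorm(n, 0.05, 0.02),
             total_lesion_volume = rnorm(n, 5000, 1000),
             age = age, sex = factor(sex), total_brain_volume_mm3 = tbv,
             phq2 = sample(0:3, n, replace = TRUE))
}
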