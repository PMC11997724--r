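#' @import methods
NULL

#' VoxelGrid: a 3D sampling grid with a world affine
#'
#' Describes the discrete grid on which lesion masks live: its dimensions,
#' the 4x4 affine mapping 0-based voxel indices to world millimetre
#' coordinates (NIfTI convention: voxel centres at integer indices), and the
#' volume of a single voxel.
#'
#' @slot shape integer(3), grid dimensions.
#' @slot affine 4x4 numeric matrix, voxel-index -> world-mm transform.
#' @slot voxelVolume numeric(1), volume of one voxel in mm^3.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", affine = "matrix", voxelVolume = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)) || !all(is.finite(object@affine)))
      msg <- c(msg, "affine must be a finite 4x4 matrix")
    else {
      d <- det(object@affine[1:3, 1:3])
      if (abs(d) < 1e-12)
        msg <- c(msg, "affine is singular")
      else if (abs(object@voxelVolume - abs(d)) > 1e-6 * abs(d))
        msg <- c(msg, "voxelVolume must equal |det| of the 3x3 affine block")
    }
    if (length(msg)) msg else TRUE
  })

#' TractBundle: a named set of streamlines
#'
#' A bundle holds the streamlines of one hemisphere of one fascicle as
#' polylines in world millimetre coordinates (each an n x 3 matrix).
#'
#' @slot name character(1), e.g. "UF_left".
#' @slot streamlines list of numeric matrices, each n x 3 with n >= 2.
#' @export
setClass("TractBundle",
  representation(name = "character", streamlines = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (length(object@streamlines) == 0L)
      msg <- c(msg, "bundle must contain at least one streamline")
    ok <- vapply(object@streamlines, function(s)
      is.matrix(s) && ncol(s) == 3L && nrow(s) >= 2L && all(is.finite(s)),
      logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf("streamlines %s are not finite n x 3 matrices with n >= 2",
                            paste(which(!ok), collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' LesionMask: a binary lesion map on a voxel grid
#'
#' @slot grid 3D integer/logical array of 0/1 lesion indicators.
#' @slot affine 4x4 voxel-index -> world-mm transform (0-based indices).
#' @slot voxelVolume numeric(1), mm^3 per voxel.
#' @export
setClass("LesionMask",
  representation(grid = "array", affine = "matrix", voxelVolume = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3L)
      msg <- c(msg, "grid must be a 3D array")
    v <- unique(as.vector(object@grid))
    if (!all(v %in% c(0, 1)))
      msg <- c(msg, "grid values must be 0/1")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be 4x4")
    else {
      d <- det(object@affine[1:3, 1:3])
      if (abs(d) < 1e-12)
        msg <- c(msg, "affine is singular")
      else if (abs(object@voxelVolume - abs(d)) > 1e-6 * abs(d))
        msg <- c(msg, "voxelVolume must equal |det| of the 3x3 affine block")
    }
    if (length(msg)) msg else TRUE
  })

#' PatientRecord: one patient's EMR extract
#'
#' Diagnosis codes, medication orders, PHQ-2/PHQ-9 and PROMIS observations,
#' MRI dates and covariates for a single patient, as consumed by the
#' phenotyping rules.
#'
#' @slot patientId character(1).
#' @slot icd10Codes character vector of ICD-10 codes.
#' @slot medications character vector of normalised (lower-case) drug names.
#' @slot phqObs data.frame with columns instrument ("PHQ2"/"PHQ9"),
#'   score (integer), date (Date).
#' @slot promisObs data.frame with columns domain, score, date.
#' @slot mriDates Date vector (may be empty for non-imaging records).
#' @slot age numeric(1), years.
#' @slot sex character(1).
#' @slot totalBrainVolume numeric(1), mm^3.
#' @export
setClass("PatientRecord",
  representation(patientId = "character", icd10Codes = "character",
                 medications = "character", phqObs = "data.frame",
                 promisObs = "data.frame", mriDates = "Date",
                 age = "numeric", sex = "character",
                 totalBrainVolume = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@patientId) != 1L)
      msg <- c(msg, "patientId must be length 1")
    if (nrow(object@phqObs)) {
      bad2 <- object@phqObs$instrument == "PHQ2" &
        (object@phqObs$score < 0 | object@phqObs$score > 6)
      bad9 <- object@phqObs$instrument == "PHQ9" &
        (object@phqObs$score < 0 | object@phqObs$score > 27)
      if (any(bad2)) msg <- c(msg, "PHQ-2 scores must lie in [0, 6]")
      if (any(bad9)) msg <- c(msg, "PHQ-9 scores must lie in [0, 27]")
      if (!all(object@phqObs$instrument %in% c("PHQ2", "PHQ9")))
        msg <- c(msg, "phq instrument must be PHQ2 or PHQ9")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s, voxel %.3g mm^3\n",
              paste(object@shape, collapse = " x "), object@voxelVolume))
})

setMethod("show", "TractBundle", function(object) {
  np <- sum(vapply(object@streamlines, nrow, integer(1)))
  cat(sprintf("TractBundle '%s': %d streamlines, %d points\n",
              object@name, length(object@streamlines), np))
})

setMethod("show", "LesionMask", function(object) {
  cat(sprintf("LesionMask %s: %d lesion voxels (%.1f mm^3)\n",
              paste(dim(object@grid), collapse = " x "),
              sum(object@grid), sum(object@grid) * object@voxelVolume))
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord %s: %d codes, %d meds, %d PHQ obs, %d PROMIS obs\n",
              object@patientId, length(object@icd10Codes),
              length(object@medications), nrow(object@phqObs),
              nrow(object@promisObs)))
})
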