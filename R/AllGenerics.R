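#' @include AllClasses.R
NULL

#' Accessors for tractburden S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setMethod("streamlines", "TractBundle", function(x) x@streamlines)

#' @rdname accessors
#' @export
setGeneric("bundleName", function(x) standardGeneric("bundleName"))
#' @rdname accessors
#' @export
setMethod("bundleName", "TractBundle", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @rdname accessors
#' @export
setMethod("gridShape", "LesionMask", function(x) dim(x@grid))

#' @rdname accessors
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))
#' @rdname accessors
#' @export
setMethod("worldAffine", "VoxelGrid", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("worldAffine", "LesionMask", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setMethod("voxelVolume", "VoxelGrid", function(x) x@voxelVolume)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "LesionMask", function(x) x@voxelVolume)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "LesionMask", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "PatientRecord", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("icd10Codes", function(x) standardGeneric("icd10Codes"))
#' @rdname accessors
#' @export
setMethod("icd10Codes", "PatientRecord", function(x) x@icd10Codes)

#' @rdname accessors
#' @export
setGeneric("medications", function(x) standardGeneric("medications"))
#' @rdname accessors
#' @export
setMethod("medications", "PatientRecord", function(x) x@medications)

#' @rdname accessors
#' @export
setGeneric("phqObs", function(x) standardGeneric("phqObs"))
#' @rdname accessors
#' @export
setMethod("phqObs", "PatientRecord", function(x) x@phqObs)

#' @rdname accessors
#' @export
setGeneric("promisObs", function(x) standardGeneric("promisObs"))
#' @rdname accessors
#' @export
setMethod("promisObs", "PatientRecord", function(x) x@promisObs)

#' @rdname accessors
#' @export
setGeneric("mriDates", function(x) standardGeneric("mriDates"))
#' @rdname accessors
#' @export
setMethod("mriDates", "PatientRecord", function(x) x@mriDates)
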