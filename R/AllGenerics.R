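# Generics shared across modules. Accessors are defined here; methods live
# next to their classes.

#' Number of learnable parameters
#'
#' @param object a [HexplaneScene-class] or [SceneConfig-class].
#' @return integer parameter count (plane features plus MLP weights/biases).
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

#' Training history accessor
#'
#' @param object a fitted [HexplaneScene-class].
#' @return data.frame of logged losses, or NULL for an unfitted scene.
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))

#' Scene configuration accessor
#' @param object a [HexplaneScene-class].
#' @return the [SceneConfig-class] the scene was built from.
#' @export
setGeneric("sceneConfig", function(object) standardGeneric("sceneConfig"))

#' Feature-plane accessor
#' @param object a [HexplaneScene-class].
#' @return named list of the six feature-plane arrays.
#' @export
setGeneric("featurePlanes", function(object) standardGeneric("featurePlanes"))

#' Number of frames in a projection stack
#' @param object a [ProjectionSet-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' Per-frame acquisition angles (degrees)
#' @param object a [ProjectionSet-class] or [Radiograph-class].
#' @return numeric vector (or scalar) of angles in degrees.
#' @export
setGeneric("thetaDeg", function(object) standardGeneric("thetaDeg"))

#' Pixel payload accessor
#' @param object a [Radiograph-class] or [ProjectionSet-class].
#' @return the pixel matrix, or the rows x cols x frames array.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Angular windows of a schedule
#' @param object an [AcquisitionSchedule-class].
#' @return matrix (nTimepoints x 2) of unwrapped window bounds in degrees.
#' @export
setGeneric("scheduleWindows", function(object) standardGeneric("scheduleWindows"))

#' Total unwrapped angular coverage of a schedule (degrees)
#' @param object an [AcquisitionSchedule-class].
#' @return numeric, `nTimepoints * wedgeDeg` (not reduced modulo 360).
#' @export
setGeneric("totalCoverage", function(object) standardGeneric("totalCoverage"))

#' Resolution estimate of an FSC curve (voxels)
#' @param object an [FSCCurve-class].
#' @return numeric resolution in voxels (>= 2).
#' @export
setGeneric("resolutionVoxels", function(object) standardGeneric("resolutionVoxels"))

#' Number of time points of a 4D volume
#' @param object a [Volume4D-class].
#' @return integer.
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))

#' Extract one time point of a 4D volume as a 3D array
#' @param object a [Volume4D-class].
#' @param i time index (1-based).
#' @param channel `"delta"` or `"beta"`.
#' @return numeric 3D array.
#' @export
setGeneric("volumeAt", function(object, i, channel = "delta")
  standardGeneric("volumeAt"))
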