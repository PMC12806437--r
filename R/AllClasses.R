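#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib hextomo, .registration = TRUE
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Scene configuration
#'
#' Holds the sizes and options of a hexplane scene: the resolution of the six
#' feature planes, the per-plane channel count (the low-rank dimension), the
#' decoding MLP shape, how per-plane features are fused, and the output
#' activation. Defaults follow the reference configuration used for dynamic
#' synchrotron data: plane grids of 64 along every axis, 48 feature channels,
#' and a 3-layer, 64-neuron MLP.
#'
#' @slot spatialGrid integer, plane resolution along each spatial axis (>= 2).
#' @slot temporalGrid integer, plane resolution along the time axis (>= 2).
#' @slot featureDim integer, feature channels per plane (>= 1).
#' @slot mlpLayers integer, number of hidden MLP layers.
#' @slot mlpWidth integer, neurons per hidden layer.
#' @slot outChannels integer, 1 (delta only) or 2 (delta and beta).
#' @slot fusionMode `"concat"` (6F descriptor) or `"paired-product"`
#'   (elementwise product of paired planes, 3F descriptor).
#' @slot activation `"softplus"` (non-negative outputs) or `"linear"`.
#' @slot seed integer seed driving parameter initialization.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    spatialGrid = "integer", temporalGrid = "integer", featureDim = "integer",
    mlpLayers = "integer", mlpWidth = "integer", outChannels = "integer",
    fusionMode = "character", activation = "character", seed = "integer"),
  prototype(
    spatialGrid = 64L, temporalGrid = 64L, featureDim = 48L,
    mlpLayers = 3L, mlpWidth = 64L, outChannels = 1L,
    fusionMode = "concat", activation = "softplus", seed = 1L))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@spatialGrid < 2L) msg <- c(msg, "spatialGrid must be >= 2")
  if (object@temporalGrid < 2L) msg <- c(msg, "temporalGrid must be >= 2")
  if (object@featureDim < 1L) msg <- c(msg, "featureDim must be >= 1")
  if (object@mlpLayers < 1L) msg <- c(msg, "mlpLayers must be >= 1")
  if (object@mlpWidth < 1L) msg <- c(msg, "mlpWidth must be >= 1")
  if (!object@outChannels %in% c(1L, 2L))
    msg <- c(msg, "outChannels must be 1 or 2")
  if (!object@fusionMode %in% c("concat", "paired-product"))
    msg <- c(msg, "fusionMode must be 'concat' or 'paired-product'")
  if (!object@activation %in% c("softplus", "linear"))
    msg <- c(msg, "activation must be 'softplus' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' Hexplane scene model
#'
#' The learned 4D field: six feature planes over the coordinate pairs
#' (x,y), (z,t), (x,z), (y,t), (y,z), (x,t), plus a small MLP decoding fused
#' plane features into the refractive-index decrement delta (and optionally
#' the attenuation index beta). Query it with [queryFeatures()],
#' [decodeFeatures()], [evaluateField()] or [renderProjection()].
#'
#' @slot config a [SceneConfig-class].
#' @slot planes named list of six numeric arrays (`n1 x n2 x F`), in the order
#'   xy, zt, xz, yt, yz, xt.
#' @slot mlpWeights list of weight matrices (`out x in`), hidden layers first.
#' @slot mlpBiases list of bias vectors matching `mlpWeights`.
#' @slot history data.frame of training losses, or NULL before fitting.
#' @exportClass HexplaneScene
setClass("HexplaneScene",
  representation(config = "SceneConfig", planes = "list",
                 mlpWeights = "list", mlpBiases = "list",
                 history = "dfOrNULL"),
  prototype(history = NULL))

setValidity("HexplaneScene", function(object) {
  cfg <- object@config
  msg <- character()
  if (length(object@planes) != 6L ||
      !identical(names(object@planes), c("xy", "zt", "xz", "yt", "yz", "xt")))
    return("planes must be a named list: xy, zt, xz, yt, yz, xt")
  S <- cfg@spatialGrid; Tg <- cfg@temporalGrid; F <- cfg@featureDim
  want <- list(xy = c(S, S, F), zt = c(S, Tg, F), xz = c(S, S, F),
               yt = c(S, Tg, F), yz = c(S, S, F), xt = c(S, Tg, F))
  for (nm in names(want)) {
    d <- dim(object@planes[[nm]])
    if (!identical(as.integer(d), as.integer(want[[nm]])))
      msg <- c(msg, sprintf("plane '%s' has shape (%s), expected (%s)",
                            nm, paste(d, collapse = ","),
                            paste(want[[nm]], collapse = ",")))
    if (!all(is.finite(object@planes[[nm]])))
      msg <- c(msg, sprintf("plane '%s' contains non-finite values", nm))
  }
  if (length(object@mlpWeights) != cfg@mlpLayers + 1L)
    msg <- c(msg, "mlpWeights must hold mlpLayers + 1 matrices")
  if (length(msg)) msg else TRUE
})

#' Parallel-beam acquisition geometry
#'
#' Detector layout for the parallel-beam setup: the rotation axis is the
#' volume z axis and maps to detector rows; detector columns map to the
#' rotated lateral axis. `pixelSize` is expressed in normalized volume units
#' (the volume spans `[-1, 1]` per axis), so `2 / detectorCols` makes the
#' detector span the volume exactly.
#'
#' @slot detectorRows integer >= 1.
#' @slot detectorCols integer >= 1.
#' @slot pixelSize positive numeric, normalized units per pixel.
#' @exportClass Geometry
setClass("Geometry",
  representation(detectorRows = "integer", detectorCols = "integer",
                 pixelSize = "numeric"))

setValidity("Geometry", function(object) {
  msg <- character()
  if (object@detectorRows < 1L || object@detectorCols < 1L)
    msg <- c(msg, "detector dimensions must be >= 1")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' A single radiograph
#'
#' One detector frame with its acquisition angle, time stamps and contrast
#' domain. The native rendering/training currency is the line-integral domain
#' (`delta_line_integral` or `beta_line_integral`); conversions to intensity
#' are explicit operations ([intensityFromLineIntegrals()]).
#'
#' @slot pixels numeric matrix (rows x cols).
#' @slot thetaDeg acquisition angle in degrees.
#' @slot timeIndex integer time-point index (1-based).
#' @slot time normalized time in `[-1, 1]`.
#' @slot contrastDomain one of `delta_line_integral`, `beta_line_integral`,
#'   `intensity`, `phase`.
#' @slot wavelength numeric, X-ray wavelength metadata (NA if unused).
#' @exportClass Radiograph
setClass("Radiograph",
  representation(pixels = "matrix", thetaDeg = "numeric",
                 timeIndex = "integer", time = "numeric",
                 contrastDomain = "character", wavelength = "numeric"),
  prototype(timeIndex = 1L, time = 0, contrastDomain = "delta_line_integral",
            wavelength = NA_real_))

setValidity("Radiograph", function(object) {
  msg <- character()
  if (!all(is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  if (!object@contrastDomain %in%
      c("delta_line_integral", "beta_line_integral", "intensity", "phase"))
    msg <- c(msg, "unknown contrastDomain")
  if (length(msg)) msg else TRUE
})

#' Angle- and time-stamped radiograph stack
#'
#' @slot data numeric array (rows x cols x frames).
#' @slot thetaDeg numeric vector of per-frame angles (degrees).
#' @slot timeIndex integer vector of per-frame time-point indices (1-based).
#' @slot time numeric vector of per-frame normalized times in `[-1, 1]`.
#' @slot contrastDomain contrast domain shared by all frames.
#' @slot geometry a [Geometry-class].
#' @exportClass ProjectionSet
setClass("ProjectionSet",
  representation(data = "array", thetaDeg = "numeric", timeIndex = "integer",
                 time = "numeric", contrastDomain = "character",
                 geometry = "Geometry"))

setValidity("ProjectionSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a rows x cols x frames array")
  nf <- d[3]
  if (length(object@thetaDeg) != nf) msg <- c(msg, "thetaDeg length != frames")
  if (length(object@timeIndex) != nf) msg <- c(msg, "timeIndex length != frames")
  if (length(object@time) != nf) msg <- c(msg, "time length != frames")
  if (d[1] != object@geometry@detectorRows || d[2] != object@geometry@detectorCols)
    msg <- c(msg, "data shape disagrees with geometry")
  if (length(msg)) msg else TRUE
})

#' Wedge acquisition schedule
#'
#' Per-time-point angular windows for super time-resolved acquisition: window
#' i covers the half-open wedge `[start + i*wedge, start + (i+1)*wedge)`
#' degrees (unwrapped; taken modulo 360 for per-rotation extraction). The
#' temporal enhancement over a conventional 0-180 degree scan is
#' `180 / wedgeDeg`.
#'
#' @slot nTimepoints integer number of wedges.
#' @slot wedgeDeg wedge width per time point, degrees (> 0).
#' @slot framesPerRotation integer frames per full 360-degree rotation.
#' @slot rotationDirection +1 or -1.
#' @slot startAngleDeg starting angle in degrees.
#' @slot windows numeric matrix (nTimepoints x 2) of unwrapped window
#'   start/end angles in degrees.
#' @slot rotationIndex integer vector, source rotation of each window under
#'   per-rotation extraction.
#' @slot singleFrame logical, TRUE when a wedge spans fewer than one frame.
#' @exportClass AcquisitionSchedule
setClass("AcquisitionSchedule",
  representation(nTimepoints = "integer", wedgeDeg = "numeric",
                 framesPerRotation = "integer", rotationDirection = "integer",
                 startAngleDeg = "numeric", windows = "matrix",
                 rotationIndex = "integer", singleFrame = "logical"))

setValidity("AcquisitionSchedule", function(object) {
  msg <- character()
  if (object@wedgeDeg <= 0) msg <- c(msg, "wedgeDeg must be > 0")
  if (object@nTimepoints < 1L) msg <- c(msg, "nTimepoints must be >= 1")
  if (nrow(object@windows) != object@nTimepoints)
    msg <- c(msg, "windows must have one row per time point")
  if (length(msg)) msg else TRUE
})

#' Dense 4D volume
#'
#' Ground-truth or reconstructed refractive-index volumes over a common grid
#' of voxel centers in `[-1, 1]^3`, one 3D block per time point.
#'
#' @slot delta numeric 4D array (nx x ny x nz x T), refractive-index
#'   decrement.
#' @slot beta optional matching array of the attenuation index, or NULL.
#' @slot voxelSize physical size of a voxel edge (arbitrary length units).
#' @slot timeStamps numeric vector of normalized times, length T.
#' @slot extrapolated logical, TRUE when any time stamp lies outside the
#'   fitted range and values come from plane edge clamping.
#' @exportClass Volume4D
setClass("Volume4D",
  representation(delta = "array", beta = "arrayOrNULL", voxelSize = "numeric",
                 timeStamps = "numeric", extrapolated = "logical"),
  prototype(beta = NULL, voxelSize = 1, extrapolated = FALSE))

setValidity("Volume4D", function(object) {
  d <- dim(object@delta)
  msg <- character()
  if (length(d) != 4L) return("delta must be a 4D array (x, y, z, t)")
  if (length(object@timeStamps) != d[4])
    msg <- c(msg, "timeStamps length must equal the number of time points")
  if (!all(is.finite(object@delta))) msg <- c(msg, "delta must be finite")
  if (!is.null(object@beta) && !identical(dim(object@beta), d))
    msg <- c(msg, "beta must match delta's shape")
  if (length(msg)) msg else TRUE
})

#' Fourier shell correlation curve
#'
#' Shell-wise normalized cross-correlation of two volumes in frequency space,
#' with the half-bit information threshold and the derived resolution (in
#' voxels; never below the two-voxel Nyquist bound).
#'
#' @slot freq shell center frequencies, cycles/voxel (up to 0.5).
#' @slot fsc correlation per shell.
#' @slot nVoxels voxel count per shell (full sphere).
#' @slot threshold half-bit threshold per shell.
#' @slot crossing crossing frequency in cycles/voxel (NA when never crossing).
#' @slot resolutionVoxels resolution estimate, voxels.
#' @exportClass FSCCurve
setClass("FSCCurve",
  representation(freq = "numeric", fsc = "numeric", nVoxels = "numeric",
                 threshold = "numeric", crossing = "numeric",
                 resolutionVoxels = "numeric"))

#' Phantom specification
#'
#' Declarative description of a synthetic 4D test object. Supported kinds:
#' `merging_droplets` (two bodies approach, coalesce through a smooth neck,
#' then relax toward a single sphere), `melt_pool` (a static substrate slab
#' with an ellipsoidal molten region translating through it), and
#' `static_ball` (time-constant centered ball). Defaults for
#' `merging_droplets` emulate the reference simulated protocol: 75 time
#' points on a 128-cube grid.
#'
#' @slot kind one of `merging_droplets`, `melt_pool`, `static_ball`.
#' @slot gridSize integer voxels per axis (>= 8).
#' @slot nTimepoints integer (>= 1).
#' @slot deltaValue refractive-index decrement of the object (>= 0).
#' @slot betaValue attenuation index of the object (>= 0, 0 disables beta).
#' @slot params named list of kind-specific parameters.
#' @slot seed integer seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(kind = "character", gridSize = "integer",
                 nTimepoints = "integer", deltaValue = "numeric",
                 betaValue = "numeric", params = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("merging_droplets", "melt_pool", "static_ball"))
    msg <- c(msg, "unknown phantom kind")
  if (object@gridSize < 8L) msg <- c(msg, "gridSize must be >= 8")
  if (object@nTimepoints < 1L) msg <- c(msg, "nTimepoints must be >= 1")
  if (object@deltaValue < 0 || object@betaValue < 0)
    msg <- c(msg, "contrast levels must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' One "epoch" is one optimizer step on one random ray batch; the reference
#' configuration runs 50,000 such steps. Learning rates follow the usual
#' explicit-grid practice: fast on the feature planes, slower on the MLP,
#' cosine-decayed to a tenth over the run.
#'
#' @slot iterations integer optimizer steps (>= 1).
#' @slot raysPerBatch integer rays drawn per step (>= 1).
#' @slot nSamplesPerRay integer quadrature points per ray; `NA` picks the
#'   largest spatial plane resolution.
#' @slot lrPlanes learning rate for plane features.
#' @slot lrMLP learning rate for MLP parameters.
#' @slot cosineDecay logical, cosine learning-rate decay.
#' @slot lambdaReg regularization weight (>= 0).
#' @slot tvWeight relative weight of the TV term inside the regularizer.
#' @slot l1Weight relative weight of the L1 term.
#' @slot seed integer seed for batching and jitter.
#' @slot logEvery logging stride in iterations.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(iterations = "integer", raysPerBatch = "integer",
                 nSamplesPerRay = "integer", lrPlanes = "numeric",
                 lrMLP = "numeric", cosineDecay = "logical",
                 lambdaReg = "numeric", tvWeight = "numeric",
                 l1Weight = "numeric", seed = "integer", logEvery = "integer"),
  prototype(iterations = 50000L, raysPerBatch = 256L,
            nSamplesPerRay = NA_integer_, lrPlanes = 2e-2, lrMLP = 1e-3,
            cosineDecay = TRUE, lambdaReg = 1e-4, tvWeight = 0.5,
            l1Weight = 0.5, seed = 1L, logEvery = 100L))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@raysPerBatch < 1L) msg <- c(msg, "raysPerBatch must be >= 1")
  if (object@lambdaReg < 0) msg <- c(msg, "lambdaReg must be >= 0")
  if (object@tvWeight < 0 || object@l1Weight < 0)
    msg <- c(msg, "regularizer weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Single-distance phase-retrieval parameters
#'
#' Parameters of the homogeneous-object transport-of-intensity filter: the
#' material delta/beta ratio, propagation (sample-detector) distance,
#' wavelength and detector pixel size, all in consistent length units. The
#' attenuation coefficient convention is `mu = 4 * pi * beta / lambda`.
#'
#' @slot deltaOverBeta positive ratio delta/beta.
#' @slot distance propagation distance R (> 0 allowed to be 0 for the pure
#'   absorption limit).
#' @slot wavelength X-ray wavelength (> 0).
#' @slot pixelSize detector pixel size (> 0).
#' @exportClass PhaseRetrievalParams
setClass("PhaseRetrievalParams",
  representation(deltaOverBeta = "numeric", distance = "numeric",
                 wavelength = "numeric", pixelSize = "numeric"))

setValidity("PhaseRetrievalParams", function(object) {
  msg <- character()
  if (object@deltaOverBeta <= 0) msg <- c(msg, "deltaOverBeta must be > 0")
  if (object@distance < 0) msg <- c(msg, "distance must be >= 0")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})
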