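# Hexplane scene: construction, querying, decoding, dense evaluation and
# checkpointing.

.FUSION_CODE <- c(concat = 0L, `paired-product` = 1L)
.ACT_CODE <- c(softplus = 0L, linear = 1L)

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Create a scene configuration
#'
#' @param spatialGrid plane resolution along each spatial axis (default 64).
#' @param temporalGrid plane resolution along time (default 64).
#' @param featureDim feature channels per plane (default 48).
#' @param mlpLayers hidden MLP layers (default 3).
#' @param mlpWidth neurons per hidden layer (default 64).
#' @param outChannels 1 for a delta-only field, 2 for delta + beta.
#' @param fusionMode `"concat"` or `"paired-product"`.
#' @param activation `"softplus"` (default, enforces non-negative delta/beta)
#'   or `"linear"`.
#' @param seed integer seed for parameter initialization.
#' @return a [SceneConfig-class].
#' @examples
#' cfg <- newSceneConfig(spatialGrid = 16, temporalGrid = 8, featureDim = 4,
#'                       mlpLayers = 2, mlpWidth = 16, seed = 1)
#' @export
newSceneConfig <- function(spatialGrid = 64, temporalGrid = 64,
                           featureDim = 48, mlpLayers = 3, mlpWidth = 64,
                           outChannels = 1, fusionMode = "concat",
                           activation = "softplus", seed = 1) {
  for (nm in c("spatialGrid", "temporalGrid", "featureDim", "mlpLayers",
               "mlpWidth", "outChannels", "seed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v))
      stop("configuration error: field '", nm, "' must be a single integer")
  }
  obj <- new("SceneConfig",
             spatialGrid = as.integer(spatialGrid),
             temporalGrid = as.integer(temporalGrid),
             featureDim = as.integer(featureDim),
             mlpLayers = as.integer(mlpLayers),
             mlpWidth = as.integer(mlpWidth),
             outChannels = as.integer(outChannels),
             fusionMode = fusionMode, activation = activation,
             seed = as.integer(seed))
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) stop("configuration error: ", paste(ok, collapse = "; "))
  obj
}

# descriptor length fed to the MLP
.descriptorDim <- function(config) {
  F <- config@featureDim
  if (config@fusionMode == "concat") 6L * F else 3L * F
}

#' Initialize a hexplane scene
#'
#' Allocates the six feature planes and the MLP and fills them from the
#' configuration seed: plane features uniform on `(-0.1, 0.1) / sqrt(F)`,
#' MLP weights with uniform fan-in scaling, biases zero. Two calls with equal
#' configurations produce bitwise-identical parameters.
#'
#' @param config a [SceneConfig-class] (see [newSceneConfig()]).
#' @return a [HexplaneScene-class].
#' @examples
#' sc <- initScene(newSceneConfig(spatialGrid = 8, temporalGrid = 4,
#'                                featureDim = 2, mlpLayers = 1,
#'                                mlpWidth = 8, seed = 7))
#' parameterCount(sc)
#' @export
initScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  S <- config@spatialGrid; Tg <- config@temporalGrid; F <- config@featureDim
  shapes <- list(xy = c(S, S), zt = c(S, Tg), xz = c(S, S),
                 yt = c(S, Tg), yz = c(S, S), xt = c(S, Tg))
  withSeed(config@seed, {
    planes <- lapply(shapes, function(sh) {
      array(stats::runif(prod(sh) * F, -0.1, 0.1) / sqrt(F), dim = c(sh, F))
    })
    dims <- c(.descriptorDim(config),
              rep(config@mlpWidth, config@mlpLayers), config@outChannels)
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      fanIn <- dims[l]
      W[[l]] <- matrix(stats::runif(dims[l + 1L] * fanIn, -1, 1) / sqrt(fanIn),
                       nrow = dims[l + 1L], ncol = fanIn)
      b[[l]] <- numeric(dims[l + 1L])
    }
    new("HexplaneScene", config = config, planes = planes,
        mlpWeights = W, mlpBiases = b, history = NULL)
  })
}

#' @describeIn parameterCount total learnable parameters of a scene
#' @export
setMethod("parameterCount", "HexplaneScene", function(object) {
  sum(vapply(object@planes, length, 0L)) +
    sum(vapply(object@mlpWeights, length, 0L)) +
    sum(vapply(object@mlpBiases, length, 0L))
})

#' @describeIn parameterCount parameter count implied by a configuration
#' @export
setMethod("parameterCount", "SceneConfig", function(object) {
  parameterCount(initScene(object))
})

#' @rdname trainHistory
#' @export
setMethod("trainHistory", "HexplaneScene", function(object) object@history)

#' @rdname sceneConfig
#' @export
setMethod("sceneConfig", "HexplaneScene", function(object) object@config)

#' @rdname featurePlanes
#' @export
setMethod("featurePlanes", "HexplaneScene", function(object) object@planes)

setMethod("show", "HexplaneScene", function(object) {
  cfg <- object@config
  cat("HexplaneScene\n")
  cat(sprintf("  planes: spatial %dx%d, spatiotemporal %dx%d, F = %d\n",
              cfg@spatialGrid, cfg@spatialGrid, cfg@spatialGrid,
              cfg@temporalGrid, cfg@featureDim))
  cat(sprintf("  MLP: %d x %d -> %d channel(s), fusion '%s', activation '%s'\n",
              cfg@mlpLayers, cfg@mlpWidth, cfg@outChannels, cfg@fusionMode,
              cfg@activation))
  cat(sprintf("  parameters: %d; %s\n", parameterCount(object),
              if (is.null(object@history)) "unfitted"
              else sprintf("fitted (%d logged steps)", nrow(object@history))))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: grids %d/%d, F = %d, MLP %dx%d, out %d, fusion '%s'\n",
    object@spatialGrid, object@temporalGrid, object@featureDim,
    object@mlpLayers, object@mlpWidth, object@outChannels, object@fusionMode))
})

# validate an n x 4 matrix of normalized spacetime points
.checkPoints <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 4L)
  points <- as.matrix(points)
  if (ncol(points) != 4L)
    stop("points must be an n x 4 matrix of (x, y, z, t)")
  storage.mode(points) <- "double"
  points
}

#' Query fused plane features at spacetime points
#'
#' Projects each normalized point onto the six coordinate-pair planes,
#' bilinearly interpolates a feature vector from each, and fuses them into a
#' descriptor: concatenation (length 6F) under `fusionMode = "concat"`, or
#' the elementwise product of the paired planes (xy*zt, xz*yt, yz*xt; length
#' 3F) under `"paired-product"`. Coordinates are clamped to the plane edges
#' at the boundary of the normalized cube.
#'
#' @param scene a [HexplaneScene-class].
#' @param points numeric matrix (n x 4) of normalized (x, y, z, t).
#' @return numeric matrix (n x D) of descriptors; 0-row input gives a 0-row
#'   result.
#' @export
queryFeatures <- function(scene, points) {
  stopifnot(is(scene, "HexplaneScene"))
  points <- .checkPoints(points)
  if (nrow(points) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = .descriptorDim(scene@config)))
  cpp_scene_features(unname(scene@planes),
                     .FUSION_CODE[[scene@config@fusionMode]], points,
                     scene@config@featureDim)
}

#' Decode descriptors into refractive-index values
#'
#' Applies the scene's MLP and output activation to feature descriptors.
#' Column 1 is the refractive-index decrement delta; column 2 (when
#' `outChannels = 2`) is the attenuation index beta.
#'
#' @param scene a [HexplaneScene-class].
#' @param descriptors numeric matrix (n x D) as returned by [queryFeatures()].
#' @return numeric matrix (n x outChannels).
#' @export
decodeFeatures <- function(scene, descriptors) {
  stopifnot(is(scene, "HexplaneScene"))
  descriptors <- as.matrix(descriptors)
  D <- .descriptorDim(scene@config)
  if (ncol(descriptors) != D)
    stop(sprintf("descriptor width %d does not match MLP input width %d",
                 ncol(descriptors), D))
  if (nrow(descriptors) == 0L)
    return(matrix(numeric(0), 0L, scene@config@outChannels))
  storage.mode(descriptors) <- "double"
  out <- cpp_mlp_decode(unname(scene@mlpWeights), unname(scene@mlpBiases),
                        descriptors, .ACT_CODE[[scene@config@activation]])
  colnames(out) <- c("delta", "beta")[seq_len(ncol(out))]
  out
}

#' Evaluate the field at spacetime points
#'
#' Convenience composition of [queryFeatures()] and [decodeFeatures()].
#'
#' @inheritParams queryFeatures
#' @return numeric matrix (n x outChannels) of delta (and beta) values.
#' @export
evaluatePoints <- function(scene, points) {
  stopifnot(is(scene, "HexplaneScene"))
  points <- .checkPoints(points)
  if (nrow(points) == 0L)
    return(matrix(numeric(0), 0L, scene@config@outChannels))
  out <- cpp_scene_eval(unname(scene@planes), unname(scene@mlpWeights),
                        unname(scene@mlpBiases),
                        .FUSION_CODE[[scene@config@fusionMode]],
                        .ACT_CODE[[scene@config@activation]], points)
  colnames(out) <- c("delta", "beta")[seq_len(ncol(out))]
  out
}

# cell-centred voxel coordinates on [-1, 1]
.voxelCenters <- function(n) -1 + (seq_len(n) - 0.5) * 2 / n

#' Densely evaluate the field on a voxel grid at one time
#'
#' Evaluates the scene at the centers of an `n^3` voxel grid spanning the
#' normalized cube, at normalized time `t`. Equivalent to pointwise
#' [evaluatePoints()] at every voxel center.
#'
#' @param scene a [HexplaneScene-class].
#' @param gridSize voxels per axis.
#' @param t normalized time in `[-1, 1]` (values outside are edge-clamped).
#' @return list with `delta` (3D array) and `beta` (3D array or NULL).
#' @export
evaluateField <- function(scene, gridSize, t = 0) {
  stopifnot(is(scene, "HexplaneScene"), gridSize >= 1)
  g <- .voxelCenters(gridSize)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- cbind(pts, t = t)
  vals <- evaluatePoints(scene, pts)
  delta <- array(vals[, 1L], dim = rep(gridSize, 3L))
  beta <- if (ncol(vals) > 1L) array(vals[, 2L], dim = rep(gridSize, 3L))
          else NULL
  list(delta = delta, beta = beta)
}

#' Save / load a scene checkpoint
#'
#' Checkpoints are written with [saveRDS()]; the round-trip is bit-exact for
#' all parameters.
#'
#' @param scene a [HexplaneScene-class].
#' @param path file path (conventionally `.rds`).
#' @return `saveScene` returns `path` invisibly; `loadScene` returns the
#'   scene.
#' @export
saveScene <- function(scene, path) {
  stopifnot(is(scene, "HexplaneScene"))
  saveRDS(scene, path)
  invisible(path)
}

#' @rdname saveScene
#' @export
loadScene <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "HexplaneScene")) stop("checkpoint does not hold a HexplaneScene")
  validObject(obj)
  obj
}
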