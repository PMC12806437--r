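# Self-supervised optimization of the scene against measured radiographs:
# MSE data term plus TV/L1 plane regularizers, random ray batching, Adam.

#' Create a training configuration
#'
#' @param iterations optimizer steps; the reference configuration uses
#'   50,000 (one step = one random ray batch).
#' @param raysPerBatch rays per step.
#' @param nSamplesPerRay quadrature points per ray (`NA`: spatial plane
#'   resolution).
#' @param lrPlanes,lrMLP Adam learning rates for planes and MLP.
#' @param cosineDecay cosine learning-rate decay to a tenth over the run.
#' @param lambdaReg weight of the plane regularizer.
#' @param tvWeight,l1Weight relative TV / L1 weights inside the regularizer.
#' @param seed integer seed (frame choice, ray choice, jitter).
#' @param logEvery logging stride.
#' @return a [TrainConfig-class].
#' @export
newTrainConfig <- function(iterations = 50000, raysPerBatch = 256,
                           nSamplesPerRay = NA, lrPlanes = 2e-2,
                           lrMLP = 1e-3, cosineDecay = TRUE,
                           lambdaReg = 1e-4, tvWeight = 0.5, l1Weight = 0.5,
                           seed = 1, logEvery = 100) {
  obj <- new("TrainConfig", iterations = as.integer(iterations),
             raysPerBatch = as.integer(raysPerBatch),
             nSamplesPerRay = as.integer(nSamplesPerRay),
             lrPlanes = lrPlanes, lrMLP = lrMLP,
             cosineDecay = isTRUE(cosineDecay), lambdaReg = lambdaReg,
             tvWeight = tvWeight, l1Weight = l1Weight,
             seed = as.integer(seed), logEvery = as.integer(logEvery))
  validObject(obj)
  obj
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d iterations, %d rays/batch, lr %.3g/%.3g, lambda %.3g\n",
    object@iterations, object@raysPerBatch, object@lrPlanes, object@lrMLP,
    object@lambdaReg))
})

#' Plane regularizer: total variation plus L1
#'
#' `TV` is the mean over the six planes of the mean squared forward
#' difference (both plane axes, all channels); `L1` is the mean over planes
#' of the mean absolute feature value. The combined value is
#' `tvWeight * TV + l1Weight * L1`. Constant planes have zero TV; all-zero
#' planes give zero for both terms.
#'
#' @param planes a [HexplaneScene-class] or a list of six plane arrays.
#' @param tvWeight,l1Weight relative weights.
#' @return list with components `tv`, `l1` and `value`.
#' @export
planeRegularizer <- function(planes, tvWeight = 0.5, l1Weight = 0.5) {
  if (is(planes, "HexplaneScene")) planes <- planes@planes
  stopifnot(is.list(planes), length(planes) == 6L)
  perPlane <- vapply(planes, function(p) {
    stopifnot(all(is.finite(p)))
    d1 <- p[-1, , , drop = FALSE] - p[-dim(p)[1], , , drop = FALSE]
    d2 <- p[, -1, , drop = FALSE] - p[, -dim(p)[2], , drop = FALSE]
    c(tv = (sum(d1^2) + sum(d2^2)) / (length(d1) + length(d2)),
      l1 = mean(abs(p)))
  }, c(tv = 0, l1 = 0))
  tv <- mean(perPlane["tv", ])
  l1 <- mean(perPlane["l1", ])
  list(tv = tv, l1 = l1, value = tvWeight * tv + l1Weight * l1)
}

#' Training loss: data term plus regularizer
#'
#' The data term is the mean squared pixel difference between predicted and
#' target radiograph batches (matrices, radiographs, or equal-shaped
#' arrays); the total adds `lambdaReg` times the plane regularizer.
#'
#' @param pred,target numeric arrays of equal shape (or
#'   [Radiograph-class]es).
#' @param planes a [HexplaneScene-class] or plane list (omit for the bare
#'   data term).
#' @param lambdaReg regularizer weight.
#' @param tvWeight,l1Weight relative weights inside the regularizer.
#' @return list with `data`, `reg` and `total`.
#' @export
sceneLoss <- function(pred, target, planes = NULL, lambdaReg = 0,
                     tvWeight = 0.5, l1Weight = 0.5) {
  if (is(pred, "Radiograph")) pred <- pred@pixels
  if (is(target, "Radiograph")) target <- target@pixels
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("shape mismatch between predicted and target batches")
  data <- mean((pred - target)^2)
  reg <- if (is.null(planes)) 0
         else planeRegularizer(planes, tvWeight, l1Weight)$value
  list(data = data, reg = reg, total = data + lambdaReg * reg)
}

# loss and analytic gradients on an explicit ray set (deterministic midpoint
# quadrature); used by the finite-difference gradient checks
.lossGrad <- function(scene, origins, directions, tnorm, targets, channel = 1L,
                      nSamples = 16L, lambdaReg = 0, tvWeight = 0.5,
                      l1Weight = 0.5) {
  cpp_loss_grad(unname(scene@planes), unname(scene@mlpWeights),
                unname(scene@mlpBiases),
                .FUSION_CODE[[scene@config@fusionMode]],
                .ACT_CODE[[scene@config@activation]],
                origins, directions, tnorm, targets,
                as.integer(channel) - 1L, as.integer(nSamples),
                lambdaReg, tvWeight, l1Weight)
}

#' Fit a scene to measured radiographs
#'
#' Self-supervised optimization: each step draws one frame uniformly at
#' random, a without-replacement batch of its detector rays, renders them
#' with stratified quadrature, and takes one Adam step on the MSE data term
#' plus `lambdaReg` times the TV/L1 plane regularizer. Deterministic given
#' the configuration seed. Training compares the rendered channel matching
#' the stack's contrast domain (`delta_line_integral` -> delta,
#' `beta_line_integral` -> beta).
#'
#' @param scene an initialized [HexplaneScene-class].
#' @param projections a [ProjectionSet-class] in a line-integral contrast
#'   domain, with per-frame angles and normalized times.
#' @param config a [TrainConfig-class].
#' @return the fitted [HexplaneScene-class]; the loss log is available via
#'   [trainHistory()].
#' @export
fitScene <- function(scene, projections, config = newTrainConfig()) {
  stopifnot(is(scene, "HexplaneScene"), is(projections, "ProjectionSet"),
            is(config, "TrainConfig"))
  validObject(config)
  channel <- switch(projections@contrastDomain,
                    delta_line_integral = 0L,
                    beta_line_integral = 1L,
                    stop("train on line-integral projections; convert ",
                         "intensity data first (lineIntegralsFromIntensity)"))
  if (channel == 1L && scene@config@outChannels < 2L)
    stop("beta-domain projections need a two-channel scene")
  nSamp <- config@nSamplesPerRay
  if (is.na(nSamp)) nSamp <- scene@config@spatialGrid
  geom <- projections@geometry
  fit <- cpp_fit(unname(scene@planes), unname(scene@mlpWeights),
                 unname(scene@mlpBiases),
                 .FUSION_CODE[[scene@config@fusionMode]],
                 .ACT_CODE[[scene@config@activation]],
                 projections@data, projections@thetaDeg * pi / 180,
                 projections@time, channel,
                 geom@pixelSize, geom@pixelSize,
                 config@iterations, config@raysPerBatch, as.integer(nSamp),
                 config@lrPlanes, config@lrMLP, config@cosineDecay,
                 config@lambdaReg, config@tvWeight, config@l1Weight,
                 as.numeric(config@seed), config@logEvery)
  out <- scene
  out@planes <- stats::setNames(fit$planes, names(scene@planes))
  out@mlpWeights <- fit$W
  out@mlpBiases <- fit$b
  out@history <- fit$history
  out
}

#' Reconstruct a time series of volumes from a fitted scene
#'
#' Stacks [evaluateField()] over the requested normalized times into a
#' [Volume4D-class]. Times outside `[-1, 1]` are produced by plane edge
#' clamping and flag the result as extrapolated.
#'
#' @param scene a fitted [HexplaneScene-class].
#' @param gridSize voxels per axis.
#' @param times numeric vector of normalized times.
#' @param voxelSize physical voxel size stored in the metadata.
#' @return a [Volume4D-class].
#' @export
reconstructSeries <- function(scene, gridSize, times, voxelSize = 1) {
  stopifnot(is(scene, "HexplaneScene"), length(times) >= 1)
  Tn <- length(times)
  delta <- array(0, dim = c(gridSize, gridSize, gridSize, Tn))
  beta <- if (scene@config@outChannels > 1L)
            array(0, dim = c(gridSize, gridSize, gridSize, Tn)) else NULL
  for (i in seq_len(Tn)) {
    f <- evaluateField(scene, gridSize, times[i])
    delta[, , , i] <- f$delta
    if (!is.null(beta)) beta[, , , i] <- f$beta
  }
  new("Volume4D", delta = delta, beta = beta, voxelSize = voxelSize,
      timeStamps = as.numeric(times),
      extrapolated = any(times < -1 | times > 1))
}

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "Volume4D", function(object) dim(object@delta)[4])

#' @rdname volumeAt
#' @export
setMethod("volumeAt", "Volume4D", function(object, i, channel = "delta") {
  arr <- if (channel == "delta") object@delta else object@beta
  if (is.null(arr)) stop("volume has no beta channel")
  arr[, , , i]
})

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@delta)
  cat(sprintf("Volume4D: %d x %d x %d voxels, %d time point(s)%s%s\n",
              d[1], d[2], d[3], d[4],
              if (!is.null(object@beta)) ", delta+beta" else ", delta only",
              if (object@extrapolated) " [extrapolated]" else ""))
})
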