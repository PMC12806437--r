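# Synthetic 4D ground truth and virtual tomoscopy acquisition. The phantoms
# stand in for fluid-dynamics simulations and melt-pool experiments so the
# full pipeline is testable without external data.

#' Create a phantom specification
#'
#' Kind-specific parameters (all normalized to the `[-1, 1]` cube), with
#' defaults chosen to emulate the corresponding study conditions:
#' \describe{
#'   \item{merging_droplets}{`radii` (two numbers), `separation` (initial
#'     center distance), `mergeFraction` (fraction of the sequence after
#'     which the centers stop approaching and the merged blob starts
#'     relaxing), `sharpness` (metaball smooth-union sharpness),
#'     `relaxRate` (exponent shaping the post-merge relaxation ramp).
#'     Defaults: 75 time points, 128 voxels per axis.}
#'   \item{melt_pool}{`substrate` (xmin,xmax,ymin,ymax,zmin,zmax box),
#'     `poolAxes` (ellipsoid semi-axes), `poolPath` (start and end x of the
#'     pool center), `poolZ`, `poolRatio` (pool delta relative to the
#'     substrate).}
#'   \item{static_ball}{`radius`.}
#' }
#'
#' @param kind `"merging_droplets"`, `"melt_pool"` or `"static_ball"`.
#' @param gridSize voxels per axis (>= 8).
#' @param nTimepoints number of time points.
#' @param deltaValue object refractive-index decrement level.
#' @param betaValue attenuation level (0 disables the beta channel).
#' @param seed integer seed.
#' @param ... kind-specific overrides, see above.
#' @return a [PhantomSpec-class].
#' @export
newPhantomSpec <- function(kind = c("merging_droplets", "melt_pool",
                                    "static_ball"),
                           gridSize = NULL, nTimepoints = NULL,
                           deltaValue = 1, betaValue = 0, seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    merging_droplets = list(gridSize = 128L, nTimepoints = 75L,
      params = list(radii = c(0.25, 0.2), separation = 1.0,
                    mergeFraction = 0.45, sharpness = 16, relaxRate = 1)),
    melt_pool = list(gridSize = 48L, nTimepoints = 10L,
      params = list(substrate = c(-0.7, 0.7, -0.7, 0.7, -0.6, 0),
                    poolAxes = c(0.18, 0.12, 0.1),
                    poolPath = c(-0.4, 0.4), poolZ = -0.1, poolRatio = 1.5)),
    static_ball = list(gridSize = 64L, nTimepoints = 1L,
      params = list(radius = 0.6)))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults$params))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults$params, dots)
  obj <- new("PhantomSpec", kind = kind,
             gridSize = as.integer(gridSize %||% defaults$gridSize),
             nTimepoints = as.integer(nTimepoints %||% defaults$nTimepoints),
             deltaValue = deltaValue, betaValue = betaValue,
             params = params, seed = as.integer(seed))
  validObject(obj)
  if (.phantomMinRadius(obj) < 2 * 2 / obj@gridSize)
    stop("gridSize too small to resolve the requested radii")
  obj
}

# smallest characteristic radius of the phantom geometry
.phantomMinRadius <- function(spec) {
  switch(spec@kind,
    static_ball = spec@params$radius,
    merging_droplets = min(spec@params$radii),
    melt_pool = min(spec@params$poolAxes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d^3 voxels, %d time point(s), delta %.3g\n",
              object@kind, object@gridSize, object@nTimepoints,
              object@deltaValue))
})

# smooth union (metaball-style soft minimum) of two signed distances
.smin <- function(d1, d2, k) -log(exp(-k * d1) + exp(-k * d2)) / k

# implicit function of the droplet pair at sequence fraction tau in [0, 1]
.dropletImplicit <- function(X, Y, Z, tau, p) {
  r1 <- p$radii[1]; r2 <- p$radii[2]
  dMerge <- 0.5 * (r1 + r2)
  dist <- if (tau <= p$mergeFraction)
    p$separation + (dMerge - p$separation) * tau / p$mergeFraction
  else dMerge
  d1 <- sqrt((X + dist / 2)^2 + Y^2 + Z^2) - r1
  d2 <- sqrt((X - dist / 2)^2 + Y^2 + Z^2) - r2
  dU <- .smin(d1, d2, p$sharpness)
  if (tau <= p$mergeFraction) return(dU)
  alpha <- ((tau - p$mergeFraction) / (1 - p$mergeFraction))^p$relaxRate
  req <- sum(p$radii^3)^(1 / 3)
  dS <- sqrt(X^2 + Y^2 + Z^2) - req
  (1 - alpha) * dU + alpha * dS
}

# one 3D delta block of the phantom at sequence fraction tau
.phantomFrame <- function(spec, tau) {
  N <- spec@gridSize
  g <- .voxelCenters(N)
  X <- array(rep(g, times = N * N), dim = rep(N, 3))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  p <- spec@params
  switch(spec@kind,
    static_ball = {
      mask <- (X^2 + Y^2 + Z^2) < p$radius^2
      spec@deltaValue * mask
    },
    merging_droplets = {
      mask <- .dropletImplicit(X, Y, Z, tau, p) < 0
      spec@deltaValue * mask
    },
    melt_pool = {
      s <- p$substrate
      sub <- X >= s[1] & X <= s[2] & Y >= s[3] & Y <= s[4] &
             Z >= s[5] & Z <= s[6]
      cx <- p$poolPath[1] + tau * (p$poolPath[2] - p$poolPath[1])
      pool <- ((X - cx) / p$poolAxes[1])^2 + (Y / p$poolAxes[2])^2 +
              ((Z - p$poolZ) / p$poolAxes[3])^2 < 1
      v <- spec@deltaValue * sub
      v[pool] <- spec@deltaValue * p$poolRatio
      v
    })
}

#' Generate a 4D phantom
#'
#' Deterministic, piecewise-constant ground truth: object voxels carry
#' exactly the configured contrast levels, so threshold segmentation of the
#' phantom is exact. `merging_droplets` renders two metaballs whose centers
#' approach linearly, coalesce through a smooth neck, and relax toward the
#' volume-equivalent sphere; `melt_pool` is a static substrate slab with an
#' ellipsoidal molten region translating along a line; `static_ball` repeats
#' a centered ball at every time point.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [Volume4D-class] (beta channel present when `betaValue > 0`,
#'   proportional to the delta channel).
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  N <- spec@gridSize; Tn <- spec@nTimepoints
  if (.phantomMinRadius(spec) < 2 * 2 / N)
    stop("gridSize too small to resolve the requested radii")
  delta <- array(0, dim = c(N, N, N, Tn))
  taus <- if (Tn == 1L) 0 else (seq_len(Tn) - 1) / (Tn - 1)
  for (i in seq_len(Tn)) delta[, , , i] <- .phantomFrame(spec, taus[i])
  beta <- if (spec@betaValue > 0)
    delta * (spec@betaValue / max(spec@deltaValue, .Machine$double.eps))
  else NULL
  new("Volume4D", delta = delta, beta = beta, voxelSize = 2 / N,
      timeStamps = .normalizedTimes(Tn))
}

#' Reference descriptors of a phantom
#'
#' Deterministic per-time summaries used as test fixtures: 6-connected
#' component count, voxel count, and centroid (in normalized coordinates) of
#' the voxels above a threshold.
#'
#' @param phantom a [Volume4D-class].
#' @param threshold segmentation threshold; default half the global maximum.
#' @return data.frame with columns `time`, `nComponents`, `nVoxels`, `cx`,
#'   `cy`, `cz`.
#' @export
referenceDescriptors <- function(phantom, threshold = NULL) {
  stopifnot(is(phantom, "Volume4D"))
  if (is.null(threshold)) threshold <- max(phantom@delta) / 2
  Tn <- nTimepoints(phantom)
  g <- .voxelCenters(dim(phantom@delta)[1])
  out <- data.frame(time = seq_len(Tn), nComponents = 0L, nVoxels = 0L,
                    cx = NA_real_, cy = NA_real_, cz = NA_real_)
  for (i in seq_len(Tn)) {
    v <- volumeAt(phantom, i)
    mask <- v > threshold
    lab <- cpp_label3d(mask, dim(v)[1], dim(v)[2], dim(v)[3])
    out$nComponents[i] <- max(lab)
    out$nVoxels[i] <- sum(mask)
    if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      out$cx[i] <- mean(g[idx[, 1]])
      out$cy[i] <- mean(g[idx[, 2]])
      out$cz[i] <- mean(g[idx[, 3]])
    }
  }
  out
}

#' Count 6-connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @return integer array of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  cpp_label3d(as.logical(mask), dim(mask)[1], dim(mask)[2], dim(mask)[3])
}

#' Simulate a continuous-rotation tomoscopy acquisition
#'
#' Projects the phantom with the dense reference projector while the source
#' rotates continuously: frame j (0-based) is acquired at angle
#' `startAngleDeg + direction * j * 360 / framesPerRotation`. The phantom
#' time axis maps onto the frame sequence by zero-order hold -- each phantom
#' time point spans an equal stretch of frames and the object is static
#' within it (`motion = "hold"`); `motion = "linear"` instead blends
#' neighbouring time points to stress-test intra-wedge motion.
#'
#' @param phantom a [Volume4D-class].
#' @param framesPerRotation frames per 360-degree rotation.
#' @param rotations number of rotations (fractions allowed); the frame count
#'   is `round(rotations * framesPerRotation)`.
#' @param geom a [Geometry-class]; default square detector matching the
#'   phantom grid.
#' @param noise `"none"`, `"gaussian"` (additive, `sigma` in line-integral
#'   units) or `"poisson"` (photon noise at `dose` counts per pixel applied
#'   in the intensity domain).
#' @param sigma gaussian noise level.
#' @param dose mean photon count for poisson noise.
#' @param seed integer seed for the noise.
#' @param startAngleDeg starting angle.
#' @param direction +1 or -1.
#' @param motion `"hold"` (default) or `"linear"`.
#' @return a [ProjectionSet-class] of delta line integrals with true angles
#'   and time stamps.
#' @export
simulateTomoscopy <- function(phantom, framesPerRotation, rotations,
                              geom = NULL,
                              noise = c("none", "gaussian", "poisson"),
                              sigma = 0, dose = 1e4, seed = 1,
                              startAngleDeg = 0, direction = 1,
                              motion = c("hold", "linear")) {
  noise <- match.arg(noise)
  motion <- match.arg(motion)
  stopifnot(is(phantom, "Volume4D"))
  N <- dim(phantom@delta)[1]
  if (is.null(geom)) geom <- newGeometry(N, N)
  nf <- round(rotations * framesPerRotation)
  Tn <- nTimepoints(phantom)
  j <- seq_len(nf) - 1
  theta <- startAngleDeg + direction * j * 360 / framesPerRotation
  frac <- j / nf            # position of each frame in the sequence [0, 1)
  tIdx <- pmin(Tn, floor(frac * Tn) + 1L)
  data <- array(0, dim = c(geom@detectorRows, geom@detectorCols, nf))
  for (f in seq_len(nf)) {
    vol <- if (motion == "hold" || Tn == 1L) {
      volumeAt(phantom, tIdx[f])
    } else {
      # continuous position on the time axis, linear blend of neighbours
      pos <- frac[f] * (Tn - 1) + 1
      lo <- floor(pos); hi <- min(Tn, lo + 1); w <- pos - lo
      (1 - w) * volumeAt(phantom, lo) + w * volumeAt(phantom, hi)
    }
    data[, , f] <- projectVolume(vol, theta[f], geom)
  }
  if (noise == "gaussian" && sigma > 0) {
    data <- data + withSeed(seed, array(stats::rnorm(length(data), 0, sigma),
                                        dim = dim(data)))
  } else if (noise == "poisson") {
    I <- exp(-data)
    counts <- withSeed(seed, array(stats::rpois(length(I), dose * I),
                                   dim = dim(I)))
    data <- -log(pmax(counts, 0.5) / dose)
  }
  new("ProjectionSet", data = data, thetaDeg = theta,
      timeIndex = as.integer(tIdx), time = .normalizedTimes(Tn)[tIdx],
      contrastDomain = "delta_line_integral", geometry = geom)
}
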