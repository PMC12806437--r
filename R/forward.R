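# Parallel-beam forward model: ray generation, stochastic sampling along
# rays, line-integral rendering of the scene, intensity conversions under the
# projection approximation, and the dense reference projector used both as a
# testing oracle and as the phantom acquisition simulator.

#' Create a parallel-beam geometry
#'
#' @param detectorRows,detectorCols detector dimensions.
#' @param pixelSize pixel pitch in normalized volume units; the default
#'   `2 / detectorCols` makes the detector span the `[-1, 1]` cube.
#' @return a [Geometry-class].
#' @export
newGeometry <- function(detectorRows, detectorCols,
                        pixelSize = 2 / detectorCols) {
  obj <- new("Geometry", detectorRows = as.integer(detectorRows),
             detectorCols = as.integer(detectorCols),
             pixelSize = as.numeric(pixelSize))
  validObject(obj)
  obj
}

setMethod("show", "Geometry", function(object) {
  cat(sprintf("Geometry: parallel beam, %d x %d detector, pixel %.4g\n",
              object@detectorRows, object@detectorCols, object@pixelSize))
})

# direction and lateral axis at angle theta (degrees); theta = 0 -> rays
# along +y, CCW rotation about +z
.rayFrame <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  list(dir = c(-sin(th), cos(th), 0), lat = c(cos(th), sin(th), 0))
}

# slab intersection with the [-1,1]^3 cube; returns c(t0, t1) or NULL on miss
.cubeIntersect <- function(origin, direction) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(direction[a]) < 1e-12) {
      if (origin[a] < -1 || origin[a] > 1) return(NULL)
    } else {
      ta <- (-1 - origin[a]) / direction[a]
      tb <- (1 - origin[a]) / direction[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
    }
  }
  if (t1 <= t0) NULL else c(t0, t1)
}

#' Generate detector rays at a rotation angle
#'
#' One ray per detector pixel, all parallel. Detector columns offset the ray
#' laterally (along the rotated +x axis), rows offset it along +z. Origins
#' are placed outside the normalized cube on the source side; `tEntry` /
#' `tExit` give the ray parameters of the cube intersection (NA for rays
#' missing the cube).
#'
#' @param geom a [Geometry-class].
#' @param thetaDeg rotation angle in degrees (CCW about +z; 0 = rays
#'   along +y).
#' @return list with `origins` (n x 3), `directions` (n x 3), `tEntry`,
#'   `tExit`, and the pixel index matrices `row`, `col`. Rays are ordered
#'   with the row index moving fastest (column-major over the detector).
#' @export
generateRays <- function(geom, thetaDeg) {
  stopifnot(is(geom, "Geometry"), is.finite(thetaDeg))
  fr <- .rayFrame(thetaDeg)
  R <- geom@detectorRows; C <- geom@detectorCols; px <- geom@pixelSize
  pr <- rep(seq_len(R), times = C)
  pc <- rep(seq_len(C), each = R)
  sc <- (pc - 1 - (C - 1) / 2) * px
  sz <- (pr - 1 - (R - 1) / 2) * px
  origins <- cbind(sc * fr$lat[1] - 2 * fr$dir[1],
                   sc * fr$lat[2] - 2 * fr$dir[2],
                   sz)
  directions <- matrix(fr$dir, nrow = R * C, ncol = 3, byrow = TRUE)
  tEntry <- rep(NA_real_, R * C); tExit <- rep(NA_real_, R * C)
  for (i in seq_len(R * C)) {
    hit <- .cubeIntersect(origins[i, ], directions[i, ])
    if (!is.null(hit)) { tEntry[i] <- hit[1]; tExit[i] <- hit[2] }
  }
  list(origins = origins, directions = directions,
       tEntry = tEntry, tExit = tExit, row = pr, col = pc)
}

#' Sample quadrature points along a ray
#'
#' Splits the ray's chord through the normalized cube into `nSamples` equal
#' sub-intervals and places one point per interval: at the midpoint
#' (`mode = "uniform"`) or jittered uniformly within the interval
#' (`mode = "stratified"`). Each point carries quadrature weight
#' `chord / nSamples`, so the weights always sum to the chord length.
#'
#' @param origin numeric length-3 ray origin.
#' @param direction numeric length-3 unit direction.
#' @param nSamples number of points (>= 1).
#' @param mode `"stratified"` or `"uniform"`.
#' @param seed integer seed for the stratified jitter.
#' @return list with `points` (n x 3) and `weights` (length n); both empty
#'   when the ray misses the cube.
#' @export
sampleAlongRay <- function(origin, direction, nSamples,
                           mode = c("stratified", "uniform"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(nSamples >= 1)
  hit <- .cubeIntersect(origin, direction)
  if (is.null(hit))
    return(list(points = matrix(numeric(0), 0, 3), weights = numeric(0)))
  chord <- hit[2] - hit[1]
  h <- chord / nSamples
  u <- if (mode == "stratified") withSeed(seed, stats::runif(nSamples))
       else rep(0.5, nSamples)
  tt <- hit[1] + (seq_len(nSamples) - 1 + u) * h
  pts <- cbind(origin[1] + tt * direction[1],
               origin[2] + tt * direction[2],
               origin[3] + tt * direction[3])
  list(points = pts, weights = rep(h, nSamples))
}

#' Render a radiograph from the scene
#'
#' Line-integral rendering under the projection approximation: each detector
#' pixel's value is the quadrature sum of the decoded delta (and beta, when
#' present) along its ray at normalized time `t`, in units of (unitless
#' index) x (normalized length). Deterministic midpoint quadrature by
#' default; stratified jitter is used during training.
#'
#' @param scene a [HexplaneScene-class].
#' @param geom a [Geometry-class].
#' @param thetaDeg rotation angle, degrees.
#' @param t normalized time in `[-1, 1]`.
#' @param nSamples quadrature points per ray; default is the spatial plane
#'   resolution.
#' @param stratified logical, jitter sample positions.
#' @param seed seed for the jitter.
#' @param timeIndex time-point index stored in the output metadata.
#' @return a [Radiograph-class] with the delta line integral, or a list
#'   `list(delta = , beta = )` of two radiographs when the scene has two
#'   output channels.
#' @export
renderProjection <- function(scene, geom, thetaDeg, t = 0, nSamples = NULL,
                             stratified = FALSE, seed = 1, timeIndex = 1L) {
  stopifnot(is(scene, "HexplaneScene"), is(geom, "Geometry"))
  if (is.null(nSamples)) nSamples <- scene@config@spatialGrid
  rays <- generateRays(geom, thetaDeg)
  vals <- cpp_render_rays(unname(scene@planes), unname(scene@mlpWeights),
                          unname(scene@mlpBiases),
                          .FUSION_CODE[[scene@config@fusionMode]],
                          .ACT_CODE[[scene@config@activation]],
                          rays$origins, rays$directions,
                          rep(as.numeric(t), nrow(rays$origins)),
                          as.integer(nSamples), isTRUE(stratified),
                          as.numeric(seed))
  toRad <- function(v, domain) {
    new("Radiograph",
        pixels = matrix(v, geom@detectorRows, geom@detectorCols),
        thetaDeg = thetaDeg, timeIndex = as.integer(timeIndex),
        time = as.numeric(t), contrastDomain = domain)
  }
  if (scene@config@outChannels == 1L) {
    toRad(vals[, 1], "delta_line_integral")
  } else {
    list(delta = toRad(vals[, 1], "delta_line_integral"),
         beta = toRad(vals[, 2], "beta_line_integral"))
  }
}

#' @rdname pixels
#' @export
setMethod("pixels", "Radiograph", function(object) object@pixels)

#' @rdname thetaDeg
#' @export
setMethod("thetaDeg", "Radiograph", function(object) object@thetaDeg)

setMethod("show", "Radiograph", function(object) {
  cat(sprintf("Radiograph %d x %d at theta = %.3f deg, t = %.3f (%s)\n",
              nrow(object@pixels), ncol(object@pixels), object@thetaDeg,
              object@time, object@contrastDomain))
})

#' Convert between attenuation line integrals and intensity
#'
#' Under the projection approximation the transmitted intensity of a unit
#' incident wave is `exp(-2 k int beta dz)` with wavenumber
#' `k = 2 pi / lambda`. `intensityFromLineIntegrals` applies this map
#' pixelwise; `lineIntegralsFromIntensity` inverts it.
#'
#' @param rad a [Radiograph-class] (beta line integrals, resp. intensity).
#' @param k wavenumber `2 pi / lambda`.
#' @return a [Radiograph-class] in the converted contrast domain.
#' @export
intensityFromLineIntegrals <- function(rad, k) {
  stopifnot(is(rad, "Radiograph"))
  if (rad@contrastDomain != "beta_line_integral")
    stop("expected a radiograph in the beta_line_integral domain")
  out <- rad
  out@pixels <- exp(-2 * k * rad@pixels)
  out@contrastDomain <- "intensity"
  out@wavelength <- 2 * pi / k
  out
}

#' @rdname intensityFromLineIntegrals
#' @export
lineIntegralsFromIntensity <- function(rad, k) {
  stopifnot(is(rad, "Radiograph"))
  if (rad@contrastDomain != "intensity")
    stop("expected a radiograph in the intensity domain")
  if (any(rad@pixels <= 0))
    stop("domain error: non-positive intensity cannot be log-transformed")
  out <- rad
  out@pixels <- -log(rad@pixels) / (2 * k)
  out@contrastDomain <- "beta_line_integral"
  out
}

#' Phase from delta line integrals
#'
#' The accumulated phase shift is `phi = -k int delta dz`.
#'
#' @param rad a [Radiograph-class] holding delta line integrals.
#' @param k wavenumber.
#' @return a [Radiograph-class] in the phase domain.
#' @export
phaseFromLineIntegrals <- function(rad, k) {
  stopifnot(is(rad, "Radiograph"))
  if (rad@contrastDomain != "delta_line_integral")
    stop("expected a radiograph in the delta_line_integral domain")
  out <- rad
  out@pixels <- -k * rad@pixels
  out@contrastDomain <- "phase"
  out@wavelength <- 2 * pi / k
  out
}

#' Dense reference projection of a voxel volume
#'
#' Brute-force discrete line integrals of a voxel grid: the volume is
#' trilinearly interpolated (cell-centred on the normalized cube, zero
#' outside) at fine fixed midpoint steps along every detector ray. No
#' randomness. Serves as the independent reference for the scene renderer
#' and as the projection simulator for phantom acquisitions.
#'
#' @param volume numeric 3D array over `[-1, 1]^3`.
#' @param thetaDeg rotation angle, degrees.
#' @param geom a [Geometry-class].
#' @param step sampling step in normalized units; default half a voxel.
#' @param boundary `"zero"` (vacuum outside the grid; right for compact
#'   phantoms) or `"clamp"` (edge extension, matching the scene renderer's
#'   clamping when projecting densely evaluated fields).
#' @return numeric matrix (detectorRows x detectorCols) of line integrals.
#' @export
projectVolume <- function(volume, thetaDeg, geom, step = NULL,
                          boundary = c("zero", "clamp")) {
  boundary <- match.arg(boundary)
  stopifnot(length(dim(volume)) == 3L, is(geom, "Geometry"),
            all(is.finite(volume)))
  if (is.null(step)) step <- 1 / dim(volume)[1]
  cpp_project_volume(volume, thetaDeg * pi / 180,
                     geom@detectorRows, geom@detectorCols,
                     geom@pixelSize, geom@pixelSize, step,
                     boundary == "clamp")
}
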