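# Wedge scheduling and extraction of wedge datasets from continuous-rotation
# tomoscopy stacks.

#' Temporal enhancement of a wedge width
#'
#' The factor by which a wedge acquisition shortens the per-volume
#' acquisition relative to a conventional 0-180 degree scan:
#' `180 / wedgeDeg`. A 3 degree wedge gives 60x, 18 degrees gives 10x, a
#' 180 degree wedge is the tomoscopy baseline (1x).
#'
#' @param wedgeDeg wedge width per time point, degrees (> 0).
#' @return numeric enhancement factor.
#' @examples
#' temporalEnhancement(3)   # 60
#' temporalEnhancement(0.9) # 200
#' @export
temporalEnhancement <- function(wedgeDeg) {
  if (any(!is.finite(wedgeDeg)) || any(wedgeDeg <= 0))
    stop("domain error: wedgeDeg must be positive")
  180 / wedgeDeg
}

#' Build a wedge acquisition schedule
#'
#' Window i (0-based) covers the unwrapped angular interval
#' `[start + i * wedge, start + (i+1) * wedge)` degrees. Under per-rotation
#' extraction from repeated 360-degree tomoscopy rotations, window i is drawn
#' from rotation `floor(i * wedge / 360) + 1`. The total unwrapped coverage
#' is `nTimepoints * wedgeDeg` (not reduced modulo 360).
#'
#' @param nTimepoints number of time points (>= 1).
#' @param wedgeDeg wedge width per time point, degrees (> 0).
#' @param framesPerRotation frames per 360-degree rotation (>= 1).
#' @param startAngleDeg starting angle, degrees.
#' @param rotationDirection +1 (CCW) or -1.
#' @return an [AcquisitionSchedule-class].
#' @examples
#' sch <- buildSchedule(75, 3, 400)
#' totalCoverage(sch)  # 225
#' @export
buildSchedule <- function(nTimepoints, wedgeDeg, framesPerRotation,
                          startAngleDeg = 0, rotationDirection = 1) {
  stopifnot(nTimepoints >= 1, wedgeDeg > 0, framesPerRotation >= 1)
  i <- seq_len(nTimepoints) - 1
  windows <- cbind(start = startAngleDeg + i * wedgeDeg,
                   end = startAngleDeg + (i + 1) * wedgeDeg)
  rotationIndex <- as.integer(floor(i * wedgeDeg / 360) + 1)
  framesPerWedge <- wedgeDeg * framesPerRotation / 360
  obj <- new("AcquisitionSchedule",
             nTimepoints = as.integer(nTimepoints),
             wedgeDeg = as.numeric(wedgeDeg),
             framesPerRotation = as.integer(framesPerRotation),
             rotationDirection = as.integer(sign(rotationDirection)),
             startAngleDeg = as.numeric(startAngleDeg),
             windows = windows, rotationIndex = rotationIndex,
             singleFrame = framesPerWedge < 1)
  validObject(obj)
  obj
}

#' @rdname scheduleWindows
#' @export
setMethod("scheduleWindows", "AcquisitionSchedule",
          function(object) object@windows)

#' @rdname totalCoverage
#' @export
setMethod("totalCoverage", "AcquisitionSchedule",
          function(object) object@nTimepoints * object@wedgeDeg)

setMethod("show", "AcquisitionSchedule", function(object) {
  cat(sprintf(
    "AcquisitionSchedule: %d wedges of %.3g deg (TE %.3gx), %d frames/rev\n",
    object@nTimepoints, object@wedgeDeg, temporalEnhancement(object@wedgeDeg),
    object@framesPerRotation))
  cat(sprintf("  total unwrapped coverage %.6g deg%s\n", totalCoverage(object),
              if (object@singleFrame) " [single-frame wedges]" else ""))
})

#' Revisit period of a wedge schedule
#'
#' Number of time steps after which a wedge window starts again at the same
#' angle modulo 360 degrees: `360 / wedgeDeg` when that ratio is an integer,
#' `NA` otherwise. For 18 degree wedges the same viewing angle recurs every
#' 20 time steps.
#'
#' @param wedgeDeg wedge width, degrees (> 0).
#' @param tol tolerance for integrality of `360 / wedgeDeg`.
#' @return integer period, or NA when the windows never realign.
#' @export
revisitPeriod <- function(wedgeDeg, tol = 1e-9) {
  if (!is.finite(wedgeDeg) || wedgeDeg <= 0)
    stop("domain error: wedgeDeg must be positive")
  p <- 360 / wedgeDeg
  if (abs(p - round(p)) < tol) as.integer(round(p)) else NA_integer_
}

# normalized mid-wedge times for n time points, linearly scaled to [-1, 1]
.normalizedTimes <- function(n) {
  if (n == 1L) 0 else -1 + 2 * (seq_len(n) - 1) / (n - 1)
}

#' Extract a wedge dataset from a continuous-rotation stack
#'
#' Carves per-time-point angular wedges out of a tomoscopy
#' [ProjectionSet-class] whose frames were acquired under continuous
#' rotation. Two modes:
#' \describe{
#'   \item{streaming}{(default) consecutive frames: window i takes the frames
#'     whose unwrapped angle falls in `[start + i*wedge, start + (i+1)*wedge)`
#'     -- every continuous frame is used, no rotation skipping. This is the
#'     native wedge acquisition.}
#'   \item{per-rotation}{benchmarking emulation against repeated-rotation
#'     tomoscopy: window i is drawn from rotation `floor(i*wedge/360) + 1`,
#'     selecting frames whose angle modulo 360 lies in the window modulo 360.}
#' }
#' Extraction is a pure selection -- pixels are untouched; only the time
#' stamps are rewritten so that all frames of window i share time index i and
#' the normalized mid-wedge time.
#'
#' @param stack a [ProjectionSet-class] with monotone unwrapped angles.
#' @param schedule an [AcquisitionSchedule-class].
#' @param mode `"streaming"` or `"per-rotation"`.
#' @return a [ProjectionSet-class] of the selected, re-stamped frames.
#' @export
extractWedges <- function(stack, schedule, mode = c("streaming", "per-rotation")) {
  mode <- match.arg(mode)
  stopifnot(is(stack, "ProjectionSet"), is(schedule, "AcquisitionSchedule"))
  theta <- stack@thetaDeg
  n <- schedule@nTimepoints
  wedge <- schedule@wedgeDeg
  start <- schedule@startAngleDeg
  times <- .normalizedTimes(n)
  keep <- integer(0)
  newIdx <- integer(0)
  for (i in seq_len(n)) {
    eps <- 1e-9   # half-open windows, robust to angle rounding
    if (mode == "streaming") {
      lo <- start + (i - 1) * wedge
      hi <- start + i * wedge
      sel <- which(theta >= lo - eps & theta < hi - eps)
      if (length(sel) == 0L && max(theta) < hi - wedge / 2)
        stop(sprintf(
          "data exhausted: stack ends before window %d; last valid time point %d",
          i, i - 1L))
    } else {
      rot <- schedule@rotationIndex[i]
      if (max(theta) < (rot - 1) * 360)
        stop(sprintf(
          "data exhausted: stack holds too few rotations for window %d; last valid time point %d",
          i, i - 1L))
      inRot <- theta >= (rot - 1) * 360 & theta < rot * 360
      lo <- (start + (i - 1) * wedge) %% 360
      hi <- lo + wedge
      thMod <- theta %% 360
      inWin <- if (hi <= 360) thMod >= lo - eps & thMod < hi - eps
               else thMod >= lo - eps | thMod < (hi - 360) - eps
      sel <- which(inRot & inWin)
    }
    keep <- c(keep, sel)
    newIdx <- c(newIdx, rep(i, length(sel)))
  }
  new("ProjectionSet",
      data = stack@data[, , keep, drop = FALSE],
      thetaDeg = stack@thetaDeg[keep],
      timeIndex = as.integer(newIdx),
      time = times[newIdx],
      contrastDomain = stack@contrastDomain,
      geometry = stack@geometry)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "ProjectionSet", function(object) dim(object@data)[3])

#' @rdname thetaDeg
#' @export
setMethod("thetaDeg", "ProjectionSet", function(object) object@thetaDeg)

#' @rdname pixels
#' @export
setMethod("pixels", "ProjectionSet", function(object) object@data)

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ProjectionSet: %d frames of %d x %d (%s), %d time point(s), theta %.6g..%.6g deg\n",
    d[3], d[1], d[2], object@contrastDomain,
    length(unique(object@timeIndex)),
    min(object@thetaDeg), max(object@thetaDeg)))
})

#' Subset frames of a projection stack
#'
#' @param x a [ProjectionSet-class].
#' @param i frame indices.
#' @param j,...,drop ignored.
#' @return a [ProjectionSet-class] holding the selected frames.
#' @export
setMethod("[", "ProjectionSet", function(x, i, j, ..., drop = FALSE) {
  new("ProjectionSet", data = x@data[, , i, drop = FALSE],
      thetaDeg = x@thetaDeg[i], timeIndex = x@timeIndex[i],
      time = x@time[i], contrastDomain = x@contrastDomain,
      geometry = x@geometry)
})
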