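# Array interchange. Pixel payloads travel as multi-page 32-bit float TIFF
# with CSV/JSON sidecars carrying angles, time stamps and geometry; scene
# checkpoints use RDS (bit-exact). TIFF round-trips preserve pixel values at
# 32-bit float precision.

# affine map of an array into [0, 1] for 32-bit float TIFF storage; the
# range travels in the JSON sidecar
.toUnit <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) list(x = array(0, dim(x)), lo = lo, hi = hi)
  else list(x = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

.fromUnit <- function(x, lo, hi) {
  if (hi == lo) array(lo, dim(x)) else lo + x * (hi - lo)
}

.sidecarPaths <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  list(tif = paste0(base, ".tif"), csv = paste0(base, ".csv"),
       json = paste0(base, ".json"))
}

#' Write / read a projection stack
#'
#' Pixels go to a multi-page 32-bit float TIFF; per-frame angle and time
#' metadata to a CSV sidecar (`frame`, `theta_deg`, `time_index`, `time`);
#' contrast domain and geometry to a JSON sidecar. All three share the base
#' name of `path`.
#'
#' @param ps a [ProjectionSet-class].
#' @param path output path (`.tif` appended to the base name).
#' @return `writeProjectionSet` returns the TIFF path invisibly;
#'   `readProjectionSet` returns the [ProjectionSet-class].
#' @export
writeProjectionSet <- function(ps, path) {
  stopifnot(is(ps, "ProjectionSet"))
  p <- .sidecarPaths(path)
  u <- .toUnit(ps@data)
  pages <- lapply(seq_len(nFrames(ps)), function(i) u$x[, , i])
  tiff::writeTIFF(pages, p$tif, bits.per.sample = 32L)
  utils::write.csv(data.frame(frame = seq_len(nFrames(ps)),
                              theta_deg = ps@thetaDeg,
                              time_index = ps@timeIndex, time = ps@time),
                   p$csv, row.names = FALSE)
  jsonlite::write_json(list(contrast_domain = ps@contrastDomain,
                            detector_rows = ps@geometry@detectorRows,
                            detector_cols = ps@geometry@detectorCols,
                            pixel_size = ps@geometry@pixelSize,
                            value_range = c(u$lo, u$hi)),
                       p$json, auto_unbox = TRUE, digits = NA)
  invisible(p$tif)
}

#' @rdname writeProjectionSet
#' @export
readProjectionSet <- function(path) {
  p <- .sidecarPaths(path)
  pages <- tiff::readTIFF(p$tif, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- utils::read.csv(p$csv)
  side <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  data <- .fromUnit(data, side$value_range[1], side$value_range[2])
  new("ProjectionSet", data = data, thetaDeg = as.numeric(meta$theta_deg),
      timeIndex = as.integer(meta$time_index), time = as.numeric(meta$time),
      contrastDomain = side$contrast_domain,
      geometry = newGeometry(side$detector_rows, side$detector_cols,
                             side$pixel_size))
}

#' Write / read a 4D volume
#'
#' The delta (and optional beta) channel is written as a multi-page 32-bit
#' float TIFF, one page per z-slice, time-major; shape, voxel size and time
#' stamps go to a JSON sidecar.
#'
#' @param vol a [Volume4D-class].
#' @param path output path.
#' @return `writeVolume4D` returns the TIFF path invisibly; `readVolume4D`
#'   the [Volume4D-class].
#' @export
writeVolume4D <- function(vol, path) {
  stopifnot(is(vol, "Volume4D"))
  p <- .sidecarPaths(path)
  d <- dim(vol@delta)
  ud <- .toUnit(vol@delta)
  ub <- if (!is.null(vol@beta)) .toUnit(vol@beta)
  pages <- list()
  for (i in seq_len(d[4])) for (k in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- ud$x[, , k, i]
  if (!is.null(vol@beta))
    for (i in seq_len(d[4])) for (k in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- ub$x[, , k, i]
  tiff::writeTIFF(pages, p$tif, bits.per.sample = 32L)
  jsonlite::write_json(list(dim = d, has_beta = !is.null(vol@beta),
                            delta_range = c(ud$lo, ud$hi),
                            beta_range = if (!is.null(vol@beta))
                              c(ub$lo, ub$hi),
                            voxel_size = vol@voxelSize,
                            time_stamps = vol@timeStamps,
                            extrapolated = vol@extrapolated),
                       p$json, auto_unbox = TRUE, digits = NA)
  invisible(p$tif)
}

#' @rdname writeVolume4D
#' @export
readVolume4D <- function(path) {
  p <- .sidecarPaths(path)
  side <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  pages <- tiff::readTIFF(p$tif, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(side$dim)
  fill <- function(offset) {
    arr <- array(0, dim = d)
    m <- offset
    for (i in seq_len(d[4])) for (k in seq_len(d[3])) {
      m <- m + 1L
      arr[, , k, i] <- pages[[m]]
    }
    arr
  }
  delta <- .fromUnit(fill(0L), side$delta_range[1], side$delta_range[2])
  beta <- if (isTRUE(side$has_beta))
    .fromUnit(fill(d[3] * d[4]), side$beta_range[1], side$beta_range[2])
  else NULL
  new("Volume4D", delta = delta, beta = beta,
      voxelSize = as.numeric(side$voxel_size),
      timeStamps = as.numeric(side$time_stamps),
      extrapolated = isTRUE(side$extrapolated))
}

#' Write / read an acquisition schedule as JSON
#'
#' @param schedule an [AcquisitionSchedule-class].
#' @param path JSON file path.
#' @return `writeSchedule` returns `path` invisibly; `readSchedule` the
#'   schedule.
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "AcquisitionSchedule"))
  jsonlite::write_json(list(n_timepoints = schedule@nTimepoints,
                            wedge_deg = schedule@wedgeDeg,
                            frames_per_rotation = schedule@framesPerRotation,
                            rotation_direction = schedule@rotationDirection,
                            start_angle_deg = schedule@startAngleDeg),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  buildSchedule(s$n_timepoints, s$wedge_deg, s$frames_per_rotation,
                s$start_angle_deg, s$rotation_direction)
}
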