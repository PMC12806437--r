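# Scoring of reconstructions: Fourier shell correlation with the half-bit
# criterion, PSNR/SSIM/NRMSE, a filtered-back-projection baseline, and
# threshold-based volume measurement.

# zero-pad a 3D array to an n^3 cube (n = max dimension)
.padToCube <- function(v) {
  d <- dim(v)
  n <- max(d)
  if (all(d == n)) return(v)
  out <- array(0, dim = rep(n, 3))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
  out
}

#' Fourier shell correlation of two volumes
#'
#' Per spherical shell in frequency space,
#' `Re(sum(F_A * Conj(F_B))) / sqrt(sum|F_A|^2 * sum|F_B|^2)` over the
#' voxels whose radial frequency falls in the shell (full-sphere counts,
#' shell width one frequency bin). Non-cubic volumes are zero-padded to
#' cubes. The half-bit threshold and the derived resolution are attached to
#' the returned curve.
#'
#' @param volA,volB numeric 3D arrays of equal shape.
#' @return an [FSCCurve-class].
#' @export
fsc <- function(volA, volB) {
  stopifnot(length(dim(volA)) == 3L, identical(dim(volA), dim(volB)))
  if (all(volA == 0) || all(volB == 0))
    stop("undefined correlation: all-zero volume")
  volA <- .padToCube(volA); volB <- .padToCube(volB)
  n <- dim(volA)[1]
  FA <- stats::fft(volA); FB <- stats::fft(volB)
  f1 <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  fx <- array(rep(f1, times = n * n), dim = rep(n, 3))
  fy <- aperm(fx, c(2, 1, 3))
  fz <- aperm(fx, c(3, 2, 1))
  r <- sqrt(fx^2 + fy^2 + fz^2)
  shell <- as.integer(round(r * n))          # bin index; center freq j/n
  maxShell <- floor(n / 2)
  keep <- shell <= maxShell
  num <- Re(FA * Conj(FB))
  pa <- Mod(FA)^2
  pb <- Mod(FB)^2
  sNum <- tapply(num[keep], shell[keep], sum)
  sPa <- tapply(pa[keep], shell[keep], sum)
  sPb <- tapply(pb[keep], shell[keep], sum)
  sN <- tapply(rep(1, sum(keep)), shell[keep], sum)
  j <- as.integer(names(sNum))
  corr <- as.numeric(sNum / sqrt(sPa * sPb))
  corr[!is.finite(corr)] <- 0
  curve <- new("FSCCurve", freq = j / n, fsc = corr,
               nVoxels = as.numeric(sN),
               threshold = halfbitThreshold(as.numeric(sN)),
               crossing = NA_real_, resolutionVoxels = NA_real_)
  .attachResolution(curve)
}

#' Half-bit information threshold
#'
#' The shell-dependent criterion
#' `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))`,
#' where `n` is the number of voxels in the shell. Strictly decreasing in
#' `n`, with asymptote `0.2071 / 1.2071 ~ 0.1716`.
#'
#' @param n voxel counts per shell (>= 1).
#' @return threshold values in (0, 1].
#' @export
halfbitThreshold <- function(n) {
  stopifnot(all(n >= 1))
  (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))
}

# locate the first downward threshold crossing and attach the resolution;
# the DC shell (one voxel, threshold exactly 1) is degenerate and excluded
# from the scan
.attachResolution <- function(curve) {
  f <- curve@freq; c0 <- curve@fsc; thr <- curve@threshold
  ok <- f > 0
  below <- c0 < thr & ok
  crossing <- NA_real_
  i <- which(below)[1]
  if (!is.na(i)) {
    first <- which(ok)[1]
    if (i == first) {
      crossing <- f[i]
    } else {
      d1 <- c0[i - 1] - thr[i - 1]   # >= 0
      d2 <- c0[i] - thr[i]           # < 0
      w <- d1 / (d1 - d2)
      crossing <- f[i - 1] + w * (f[i] - f[i - 1])
    }
  }
  res <- if (is.na(crossing) || crossing <= 0) 2 else max(2, 1 / crossing)
  curve@crossing <- crossing
  curve@resolutionVoxels <- res
  curve
}

#' Resolution from an FSC curve
#'
#' The first shell (scanning from low frequency upward) where the
#' correlation drops below the half-bit threshold defines the crossing
#' frequency by linear interpolation between neighbouring shells; the
#' resolution is its reciprocal in voxels. A curve that never crosses is at
#' the two-voxel Nyquist limit, and the estimate is never reported below
#' two voxels.
#'
#' @param curve an [FSCCurve-class].
#' @return resolution in voxels.
#' @export
resolutionFromFSC <- function(curve) {
  stopifnot(is(curve, "FSCCurve"))
  .attachResolution(curve)@resolutionVoxels
}

#' @rdname resolutionVoxels
#' @export
setMethod("resolutionVoxels", "FSCCurve",
          function(object) object@resolutionVoxels)

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf(
    "FSCCurve: %d shells, crossing %s, resolution %.3g voxels\n",
    length(object@freq),
    if (is.na(object@crossing)) "none (Nyquist-limited)"
    else sprintf("%.4g cycles/voxel", object@crossing),
    object@resolutionVoxels))
})

# separable uniform box filter, 'valid' region, via cumulative sums
.boxValid <- function(v, w) {
  for (ax in 1:3) {
    d <- dim(v)
    m <- matrix(aperm(v, c(ax, setdiff(1:3, ax))), nrow = d[ax])
    cs <- rbind(0, apply(m, 2, cumsum))
    out <- (cs[(w + 1):(d[ax] + 1), , drop = FALSE] -
            cs[1:(d[ax] - w + 1), , drop = FALSE]) / w
    nd <- d; nd[ax] <- d[ax] - w + 1
    v <- aperm(array(out, dim = c(nd[ax], nd[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  v
}

# mean 3D SSIM with a uniform window and standard constants
.ssim3d <- function(x, y, dataRange, win = 7L) {
  if (any(dim(x) < win)) win <- min(dim(x)) - (min(dim(x)) %% 2 == 0)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  NP <- win^3
  covNorm <- NP / (NP - 1)
  ux <- .boxValid(x, win); uy <- .boxValid(y, win)
  uxx <- .boxValid(x * x, win); uyy <- .boxValid(y * y, win)
  uxy <- .boxValid(x * y, win)
  vx <- covNorm * (uxx - ux^2); vy <- covNorm * (uyy - uy^2)
  cxy <- covNorm * (uxy - ux * uy)
  ssimMap <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(ssimMap)
}

#' Per-time image-quality metrics
#'
#' PSNR (on the ground truth's value range, capped at `psnrCap` when the
#' error vanishes), SSIM (uniform 7-voxel window, standard constants, valid
#' region), and NRMSE (RMSE divided by the truth's range), per time point
#' plus mean and standard deviation over time.
#'
#' @param recon,truth [Volume4D-class]es (or 3D arrays, treated as one time
#'   point) of matching shape.
#' @param psnrCap sentinel PSNR (dB) reported for an exact match.
#' @return data.frame with one row per time point (`time`, `psnr`, `ssim`,
#'   `nrmse`) and a `"summary"` attribute holding means and standard
#'   deviations.
#' @export
imageMetrics <- function(recon, truth, psnrCap = 100) {
  as4 <- function(v) {
    if (is(v, "Volume4D")) v@delta
    else if (length(dim(v)) == 3L) array(v, dim = c(dim(v), 1L))
    else v
  }
  r <- as4(recon); g <- as4(truth)
  if (!identical(dim(r), dim(g))) stop("shape mismatch")
  Tn <- dim(r)[4]
  out <- data.frame(time = seq_len(Tn), psnr = NA_real_, ssim = NA_real_,
                    nrmse = NA_real_)
  for (i in seq_len(Tn)) {
    ri <- r[, , , i]; gi <- g[, , , i]
    rng <- max(gi) - min(gi)
    if (rng == 0) stop("PSNR undefined for a constant truth volume")
    mse <- mean((ri - gi)^2)
    out$psnr[i] <- if (mse == 0) psnrCap
                   else min(psnrCap, 10 * log10(rng^2 / mse))
    out$ssim[i] <- .ssim3d(ri, gi, rng)
    out$nrmse[i] <- sqrt(mse) / rng
  }
  attr(out, "summary") <- data.frame(
    metric = c("psnr", "ssim", "nrmse"),
    mean = c(mean(out$psnr), mean(out$ssim), mean(out$nrmse)),
    sd = c(stats::sd(out$psnr), stats::sd(out$ssim), stats::sd(out$nrmse)))
  out
}

# ramp-filter a rows x cols frame along the column (lateral) axis
.rampFilter <- function(P, pixelSize) {
  C <- ncol(P)
  np <- 2L * 2^ceiling(log2(max(C, 2L)))
  pad <- matrix(0, nrow(P), np)
  pad[, seq_len(C)] <- P
  f <- abs(.fftFreq(np, pixelSize))
  Ft <- t(stats::mvfft(t(pad)))
  Ft <- sweep(Ft, 2, f, `*`)
  q <- Re(t(stats::mvfft(t(Ft), inverse = TRUE))) / np
  q[, seq_len(C), drop = FALSE]
}

#' Filtered back projection
#'
#' Slice-wise parallel-beam FBP: each frame is ramp-filtered along the
#' detector columns, then backprojected with `pi / nAngles` weighting; the
#' rotation axis (detector rows) indexes the slices. This is the package's
#' desk-scale ground-truth reconstructor, a surrogate for Fourier-regridding
#' implementations -- not a clone of them. Spans under 180 degrees produce a
#' warning (limited-angle artifacts expected), not an error.
#'
#' @param projections a [ProjectionSet-class] (all frames are used; subset
#'   by time before calling for per-time reconstructions).
#' @param gridSize output voxels per axis in x and y (default: detector
#'   columns). Slices along z equal the detector rows.
#' @return numeric 3D array (gridSize x gridSize x detectorRows).
#' @export
fbpReconstruct <- function(projections, gridSize = NULL) {
  stopifnot(is(projections, "ProjectionSet"))
  nf <- nFrames(projections)
  if (nf < 2L) warning("fewer than 2 angles: reconstruction is degenerate")
  span <- max(projections@thetaDeg) - min(projections@thetaDeg)
  if (nf > 1L) span <- span + span / (nf - 1L)   # half-open angular grid
  if (span < 180 - 1e-9 && nf > 1L)
    warning(sprintf(
      "angular span %.3g deg < 180 deg: limited-angle artifacts expected",
      span))
  geom <- projections@geometry
  if (is.null(gridSize)) gridSize <- geom@detectorCols
  R <- geom@detectorRows
  filt <- array(0, dim = dim(projections@data))
  for (f in seq_len(nf))
    filt[, , f] <- .rampFilter(projections@data[, , f], geom@pixelSize)
  vol <- array(0, dim = c(gridSize, gridSize, R))
  th <- projections@thetaDeg * pi / 180
  for (r in seq_len(R)) {
    sino <- t(filt[r, , , drop = TRUE])
    if (is.null(dim(sino))) sino <- matrix(sino, nrow = nf)
    vol[, , r] <- cpp_backproject(sino, th, as.integer(gridSize),
                                  geom@pixelSize)
  }
  vol
}

#' Threshold-based volume measurement
#'
#' Counts the voxels above (or below) a threshold and converts the count to
#' a physical volume with the voxel size. Used to track e.g. the molten
#' phase in melt-pool reconstructions.
#'
#' @param volume numeric 3D array (or [Volume4D-class]; then a per-time
#'   vector is returned).
#' @param threshold segmentation threshold.
#' @param voxelSize physical voxel edge length.
#' @param above logical; count voxels above (default) or below threshold.
#' @return physical volume (voxel count times voxelSize^3).
#' @export
moltenVolume <- function(volume, threshold, voxelSize = 1, above = TRUE) {
  if (is(volume, "Volume4D")) {
    vs <- volume@voxelSize
    return(vapply(seq_len(nTimepoints(volume)), function(i)
      moltenVolume(volumeAt(volume, i), threshold, vs, above), 0))
  }
  cnt <- if (above) sum(volume > threshold) else sum(volume < threshold)
  cnt * voxelSize^3
}
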