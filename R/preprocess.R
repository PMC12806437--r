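# Radiograph conditioning before reconstruction: flat-field correction,
# single-distance transport-of-intensity phase retrieval for homogeneous
# objects, Radon-sum consistency normalization, and rebinning of half-turn
# blocks into full rotations.

#' Create phase-retrieval parameters
#'
#' @param deltaOverBeta material delta/beta ratio (> 0).
#' @param distance propagation (sample-detector) distance, length units.
#' @param wavelength X-ray wavelength, same units.
#' @param pixelSize detector pixel size, same units.
#' @return a [PhaseRetrievalParams-class]. The linear attenuation
#'   coefficient convention is `mu = 4 pi beta / lambda`; since the filter
#'   only needs delta/beta, `mu` enters the output scale through
#'   `-log(.)/mu` with beta implied by `deltaOverBeta`.
#' @export
newPhaseRetrievalParams <- function(deltaOverBeta, distance, wavelength,
                                    pixelSize) {
  obj <- new("PhaseRetrievalParams", deltaOverBeta = deltaOverBeta,
             distance = distance, wavelength = wavelength,
             pixelSize = pixelSize)
  validObject(obj)
  obj
}

#' Flat-field correction
#'
#' Transmission = `(raw - dark) / (flat - dark)`, with `dark` defaulting to
#' zero and the output clipped below at a small positive floor so later log
#' transforms stay finite.
#'
#' @param raw,flat,dark numeric matrices of equal shape (`dark` optional).
#' @param floor lower clip value.
#' @return transmission matrix.
#' @examples
#' flatFieldCorrect(matrix(0.5, 2, 2), matrix(1, 2, 2))
#' @export
flatFieldCorrect <- function(raw, flat, dark = NULL, floor = 1e-9) {
  if (is.null(dark)) dark <- array(0, dim(raw))
  if (!identical(dim(raw), dim(flat)) || !identical(dim(raw), dim(dark)))
    stop("raw, flat and dark must share a shape")
  den <- flat - dark
  nbad <- sum(den <= 0)
  if (nbad > 0)
    stop(sprintf("flat - dark is non-positive at %d pixel(s)", nbad))
  pmax((raw - dark) / den, floor)
}

# symmetric padding of a matrix to the next powers of two
.padSymmetric <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  p1 <- 2^ceiling(log2(n1)); p2 <- 2^ceiling(log2(n2))
  if (p1 == n1 && p2 == n2) return(list(x = x, n1 = n1, n2 = n2))
  ri <- c(seq_len(n1), rev(seq_len(n1)))[(seq_len(p1) - 1L) %% (2L * n1) + 1L]
  ci <- c(seq_len(n2), rev(seq_len(n2)))[(seq_len(p2) - 1L) %% (2L * n2) + 1L]
  list(x = x[ri, ci, drop = FALSE], n1 = n1, n2 = n2)
}

# FFT sample frequencies in cycles per physical unit
.fftFreq <- function(n, d) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

#' Single-distance phase retrieval for homogeneous objects
#'
#' Transport-of-intensity retrieval: the measured transmission is low-pass
#' filtered in Fourier space with
#' `1 / (1 + R * (delta/beta) * lambda / (4 pi) * |2 pi f|^2)`
#' (`f` in cycles per length, from the pixel size), then log-transformed to
#' a thickness map `-log(.) / mu`. With `distance = 0` the filter collapses
#' to 1 and the output is the pure absorption thickness `-log(I) / mu`.
#'
#' @param transmission numeric matrix of strictly positive transmission
#'   values (see [flatFieldCorrect()]).
#' @param params a [PhaseRetrievalParams-class].
#' @param pad symmetric-pad to the next power of two before the FFT
#'   (suppresses wrap-around; default TRUE).
#' @param floor clip for non-positive filtered intensities (a warning
#'   reports the clipped count).
#' @return thickness map (same shape as the input), proportional to the
#'   retrieved projected thickness of the homogeneous object.
#' @export
paganinRetrieve <- function(transmission, params, pad = TRUE, floor = 1e-9) {
  stopifnot(is(params, "PhaseRetrievalParams"))
  if (any(transmission <= 0)) stop("transmission must be strictly positive")
  mu <- 4 * pi / params@wavelength   # mu / beta; beta folded into delta/beta
  x <- if (pad) .padSymmetric(transmission) else
    list(x = transmission, n1 = nrow(transmission), n2 = ncol(transmission))
  fx <- .fftFreq(nrow(x$x), params@pixelSize)
  fy <- .fftFreq(ncol(x$x), params@pixelSize)
  f2 <- outer(fx^2, fy^2, `+`)                      # |f|^2
  filt <- 1 + params@distance * params@deltaOverBeta *
    (params@wavelength / (4 * pi)) * (4 * pi^2) * f2
  sm <- Re(stats::fft(stats::fft(x$x) / filt, inverse = TRUE)) / length(x$x)
  sm <- sm[seq_len(x$n1), seq_len(x$n2), drop = FALSE]
  nbad <- sum(sm <= 0)
  if (nbad > 0) {
    warning(sprintf("clipped %d non-positive filtered pixel(s)", nbad))
    sm <- pmax(sm, floor)
  }
  -log(sm) / mu
}

#' Radon-sum consistency normalization
#'
#' For parallel-beam data the total integral of every projection of a
#' contained object is the same at a fixed time point. Each frame is scaled
#' multiplicatively so its pixel sum matches the mean pixel sum of its time
#' group; the scale factors are returned for audit. The operation is
#' idempotent.
#'
#' @param stack a [ProjectionSet-class], grouped by its `timeIndex`.
#' @return list with the normalized `stack` and the per-frame `factors`.
#' @export
radonSumNormalize <- function(stack) {
  stopifnot(is(stack, "ProjectionSet"))
  sums <- apply(stack@data, 3, sum)
  if (any(sums == 0)) {
    bad <- which(sums == 0)[1]
    stop(sprintf("frame %d has zero pixel sum and cannot be normalized", bad))
  }
  groups <- split(seq_along(sums), stack@timeIndex)
  factors <- numeric(length(sums))
  for (g in groups) factors[g] <- mean(sums[g]) / sums[g]
  out <- stack
  for (i in seq_along(factors)) out@data[, , i] <- out@data[, , i] * factors[i]
  list(stack = out, factors = factors)
}

#' Rebin half-turn blocks into full rotations
#'
#' A continuous-rotation stack stored as 2T blocks of P frames over 0-180
#' degrees each is reshaped to T blocks of 2P frames over 0-360 degrees:
#' consecutive block pairs are concatenated, halving the time points and
#' doubling the projections per time point while preserving every frame.
#'
#' @param stack numeric 4D array shaped (2T, P, H, W), or a
#'   [ProjectionSet-class] whose frames form 2T such blocks in order.
#' @param anglesDeg optional per-frame angles of one 360-degree pair
#'   (length 2P); defaults to an even 0-360 grid.
#' @return for an array input, a list with the reshaped `data`
#'   (T, 2P, H, W) and `anglesDeg` (length 2P); for a
#'   [ProjectionSet-class], a rebinned `ProjectionSet`.
#' @export
rebinHalfToFullRotation <- function(stack, anglesDeg = NULL) {
  if (is(stack, "ProjectionSet")) {
    Tn <- length(unique(stack@timeIndex))
    if (Tn %% 2L != 0L) stop("odd number of half-turn blocks cannot be paired")
    P <- nFrames(stack) / Tn
    newIdx <- (stack@timeIndex + 1L) %/% 2L
    out <- stack
    out@timeIndex <- as.integer(newIdx)
    out@time <- .normalizedTimes(Tn / 2L)[newIdx]
    return(out)
  }
  d <- dim(stack)
  if (length(d) != 4L) stop("stack must be a (2T, P, H, W) array")
  if (d[1] %% 2L != 0L) stop("odd number of half-turn blocks cannot be paired")
  Tn <- d[1] / 2L; P <- d[2]
  out <- array(0, dim = c(Tn, 2L * P, d[3], d[4]))
  for (i in seq_len(Tn)) {
    out[i, seq_len(P), , ] <- stack[2L * i - 1L, , , ]
    out[i, P + seq_len(P), , ] <- stack[2L * i, , , ]
  }
  if (is.null(anglesDeg)) anglesDeg <- (seq_len(2L * P) - 1L) * 360 / (2L * P)
  if (length(anglesDeg) != 2L * P)
    stop("anglesDeg must cover one full rotation (length 2P)")
  list(data = out, anglesDeg = anglesDeg)
}
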