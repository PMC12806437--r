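# Radiograph conditioning: flat field, phase retrieval, Radon-sum
# normalization, half-to-full rotation rebinning.

test_that("flat-field correction follows (raw - dark) / (flat - dark)", {
  flat <- matrix(2, 4, 4)
  expect_true(all(flatFieldCorrect(flat, flat) == 1))
  expect_true(all(flatFieldCorrect(0.5 * flat, flat) == 0.5))
  dark <- 0.1 * flat
  got <- flatFieldCorrect(0.55 * flat, flat, dark)
  expect_equal(as.numeric(got), rep(0.5, 16), tolerance = 1e-12)
  bad <- flat; bad[1, 1:2] <- 0.05
  expect_error(flatFieldCorrect(flat, bad, dark), "2 pixel")
})

test_that("flat fielding a noiseless acquisition recovers exp(-2k int beta)", {
  vol <- ballVolume(16, 0.5, level = 1e-6)     # beta field
  geom <- newGeometry(16, 16)
  k <- 2 * pi / 1e-4
  betaLI <- projectVolume(vol, 40, geom)
  I <- exp(-2 * k * betaLI)                    # unit incident intensity
  flat <- matrix(1500, 16, 16)                 # detector counts, beam only
  raw <- flat * I
  trans <- flatFieldCorrect(raw, flat)
  expect_equal(trans, I, tolerance = 1e-12)
})

test_that("phase retrieval collapses to -log(I)/mu at zero distance", {
  set.seed(31)
  I <- matrix(runif(48, 0.3, 1), 6, 8)
  prm <- newPhaseRetrievalParams(deltaOverBeta = 500, distance = 0,
                                 wavelength = 1e-4, pixelSize = 6.5e-4)
  mu <- 4 * pi / 1e-4
  expect_lt(max(abs(paganinRetrieve(I, prm) - (-log(I) / mu))), 1e-10)

  # unit transmission has a DC-only spectrum: zero thickness, any params
  prmR <- newPhaseRetrievalParams(500, 0.1, 1e-4, 6.5e-4)
  expect_lt(max(abs(paganinRetrieve(matrix(1, 8, 8), prmR))), 1e-12)
})

test_that("the retrieval filter is linear and shift-invariant", {
  set.seed(14)
  I <- matrix(runif(64, 0.4, 1), 8, 8)
  prm <- newPhaseRetrievalParams(300, 0.05, 1e-4, 1e-3)
  out <- paganinRetrieve(I, prm, pad = FALSE)
  shI <- I[c(4:8, 1:3), c(7:8, 1:6)]           # cyclic shift
  shOut <- paganinRetrieve(shI, prm, pad = FALSE)
  expect_equal(shOut, out[c(4:8, 1:3), c(7:8, 1:6)], tolerance = 1e-9)
})

test_that("the Fourier filter matches a direct DFT quadrature oracle", {
  # smooth Gaussian-blob intensity on a small grid; evaluate the filtered
  # spectrum by explicit double sums
  n <- 8
  g <- outer(seq_len(n), seq_len(n), function(i, j)
    exp(-((i - 4.2)^2 + (j - 5.1)^2) / 6))
  I <- 1 - 0.5 * g / max(g)
  prm <- newPhaseRetrievalParams(200, 0.08, 1e-4, 2e-3)
  got <- paganinRetrieve(I, prm, pad = FALSE)
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * prm@pixelSize)
  Ff <- matrix(0 + 0i, n, n)
  for (u in 1:n) for (v in 1:n)
    for (a in 1:n) for (b in 1:n)
      Ff[u, v] <- Ff[u, v] + I[a, b] *
        exp(-2i * pi * ((u - 1) * (a - 1) / n + (v - 1) * (b - 1) / n))
  filt <- 1 + prm@distance * prm@deltaOverBeta * (prm@wavelength / (4 * pi)) *
    (2 * pi)^2 * outer(f^2, f^2, `+`)
  sm <- matrix(0 + 0i, n, n)
  for (a in 1:n) for (b in 1:n)
    for (u in 1:n) for (v in 1:n)
      sm[a, b] <- sm[a, b] + Ff[u, v] / filt[u, v] *
        exp(2i * pi * ((u - 1) * (a - 1) / n + (v - 1) * (b - 1) / n))
  want <- -log(Re(sm) / n^2) / (4 * pi / prm@wavelength)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("Radon-sum normalization equalizes per-frame sums and is idempotent", {
  geom <- newGeometry(2, 2)
  mkframe <- function(s) matrix(s / 4, 2, 2)
  data <- array(0, c(2, 2, 5))
  sums <- c(10, 12, 14, 8, 8)
  for (i in 1:5) data[, , i] <- mkframe(sums[i])
  ps <- new("ProjectionSet", data = data, thetaDeg = 1:5,
            timeIndex = as.integer(c(1, 1, 1, 2, 2)),
            time = c(-1, -1, -1, 1, 1),
            contrastDomain = "delta_line_integral", geometry = geom)
  out <- radonSumNormalize(ps)
  expect_equal(out$factors, c(1.2, 1, 6 / 7, 1, 1), tolerance = 1e-12)
  newSums <- apply(out$stack@data, 3, sum)
  expect_equal(newSums, c(12, 12, 12, 8, 8), tolerance = 1e-12)
  again <- radonSumNormalize(out$stack)
  expect_equal(again$factors, rep(1, 5), tolerance = 1e-12)

  zero <- ps; zero@data[, , 2] <- 0
  expect_error(radonSumNormalize(zero), "frame 2")
})

test_that("half-turn blocks rebin to full rotations preserving every frame", {
  # (2T, P, H, W) = (4, 3, 2, 2): two full rotations out of four half-turns
  set.seed(77)
  stack <- array(rnorm(4 * 3 * 2 * 2), c(4, 3, 2, 2))
  out <- rebinHalfToFullRotation(stack)
  expect_identical(dim(out$data), c(2L, 6L, 2L, 2L))
  expect_equal(out$data[1, 1:3, , ], stack[1, , , ])
  expect_equal(out$data[1, 4:6, , ], stack[2, , , ])
  expect_equal(out$data[2, 1:3, , ], stack[3, , , ])
  expect_equal(out$anglesDeg, (0:5) * 60)
  expect_equal(sum(out$data), sum(stack))

  expect_error(rebinHalfToFullRotation(array(0, c(3, 2, 2, 2))), "odd")

  # shape bookkeeping of the reference protocol: (400, 200, H, W) halves the
  # time points and doubles the frames per block
  big <- array(0, c(400, 2, 1, 1))
  expect_identical(dim(rebinHalfToFullRotation(big)$data)[1:2], c(200L, 4L))
})

test_that("rebinning a ProjectionSet pairs its time blocks", {
  geom <- newGeometry(2, 2)
  data <- array(seq_len(2 * 2 * 8), c(2, 2, 8))
  ps <- new("ProjectionSet", data = data, thetaDeg = (0:7) * 45,
            timeIndex = as.integer(rep(1:4, each = 2)),
            time = rep(c(-1, -1 / 3, 1 / 3, 1), each = 2),
            contrastDomain = "delta_line_integral", geometry = geom)
  out <- rebinHalfToFullRotation(ps)
  expect_identical(unique(out@timeIndex), c(1L, 2L))
  expect_identical(out@data, ps@data)   # frame identity
  odd <- ps[1:6]
  expect_error(rebinHalfToFullRotation(odd), "odd")
})
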