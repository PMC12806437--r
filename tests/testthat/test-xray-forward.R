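# Parallel-beam forward model: rays, sampling, rendering, conversions, and
# the dense reference projector.

test_that("ray generation follows the parallel-beam angle convention", {
  geom <- newGeometry(2, 2, pixelSize = 0.5)
  r0 <- generateRays(geom, 0)
  # all four rays point along +y, laterally offset by the pixel size
  expect_true(all(abs(sweep(r0$directions, 2, c(0, 1, 0))) < 1e-12))
  expect_equal(sort(unique(r0$origins[, 1])), c(-0.25, 0.25))
  expect_equal(sort(unique(r0$origins[, 3])), c(-0.25, 0.25))

  r180 <- generateRays(geom, 180)
  expect_equal(r180$directions, -r0$directions, tolerance = 1e-12)

  # arbitrary angle: direction equals the rotation matrix applied to +y
  th <- 37.3 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  want <- as.numeric(Rz %*% c(0, 1, 0))
  r <- generateRays(geom, 37.3)
  expect_equal(as.numeric(r$directions[1, ]), want, tolerance = 1e-12)

  # a full turn reproduces the identical ray set
  r360 <- generateRays(geom, 360)
  expect_equal(r360$origins, r0$origins, tolerance = 1e-12)
  expect_equal(r360$directions, r0$directions, tolerance = 1e-12)
})

test_that("quadrature weights sum to the ray's cube chord", {
  through <- sampleAlongRay(c(0, -3, 0), c(0, 1, 0), 4, mode = "uniform")
  expect_equal(sum(through$weights), 2, tolerance = 1e-12)
  expect_equal(nrow(through$points), 4L)

  # corner-grazing ray: chord strictly shorter than the full diameter
  o <- c(-1.5, -1.5 + 0.9, 0)
  d <- c(1, 1, 0) / sqrt(2)
  graze <- sampleAlongRay(o, d, 8, mode = "uniform")
  expect_lt(sum(graze$weights), 2)
  # analytic chord of the [-1,1]^2 slab cut by the diagonal line
  chord <- sqrt(2) * (2 - 0.9)
  expect_equal(sum(graze$weights), chord, tolerance = 1e-9)

  a <- sampleAlongRay(c(0, -3, 0.2), c(0, 1, 0), 6, "stratified", seed = 4)
  b <- sampleAlongRay(c(0, -3, 0.2), c(0, 1, 0), 6, "stratified", seed = 4)
  expect_identical(a, b)
  expect_equal(sum(a$weights), 2, tolerance = 1e-12)

  miss <- sampleAlongRay(c(5, 0, 0), c(0, 0, 1), 4)
  expect_identical(nrow(miss$points), 0L)
  expect_length(miss$weights, 0)
})

test_that("a zero field renders all-zero radiographs at any angle and time", {
  sc <- tinyScene(seed = 1, activation = "linear")
  sc@mlpWeights <- lapply(sc@mlpWeights, function(w) w * 0)
  sc@mlpBiases <- lapply(sc@mlpBiases, function(b) b * 0)
  geom <- newGeometry(6, 6)
  for (th in c(0, 41, 200)) {
    r <- renderProjection(sc, geom, th, t = 0.4)
    expect_true(all(r@pixels == 0))
  }
})

test_that("rendering is linear in the decoded field", {
  sc <- tinyScene(spatial = 6, temporal = 4, F = 2, activation = "linear",
                  seed = 31)
  geom <- newGeometry(8, 8)
  r1 <- pixels(renderProjection(sc, geom, 25, 0.1))
  # doubling the output layer doubles the decoded field pointwise
  sc2 <- sc
  L <- length(sc2@mlpWeights)
  sc2@mlpWeights[[L]] <- 2 * sc2@mlpWeights[[L]]
  sc2@mlpBiases[[L]] <- 2 * sc2@mlpBiases[[L]]
  r2 <- pixels(renderProjection(sc2, geom, 25, 0.1))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("renderer converges to the dense projector of its own field", {
  sc <- tinyScene(spatial = 8, temporal = 4, F = 4, layers = 2, width = 16,
                  seed = 9)
  f <- evaluateField(sc, 32, 0.3)$delta     # 4x the plane resolution
  geom <- newGeometry(24, 24)
  for (th in c(17, 113)) {
    a <- pixels(renderProjection(sc, geom, th, 0.3, nSamples = 256))
    b <- projectVolume(f, th, geom, step = 1 / 64, boundary = "clamp")
    expect_lt(sqrt(sum((a - b)^2) / sum(b^2)), 0.01)
  }
})

test_that("dense projector sifts an impulse into the matching pixel", {
  N <- 16
  vol <- array(0, rep(N, 3))
  vol[N / 2, N / 2, N / 2] <- 1   # half a voxel off-centre
  geom <- newGeometry(N, N)
  for (th in c(0, 45, 131)) {
    p <- projectVolume(vol, th, geom)
    hot <- which(p == max(p), arr.ind = TRUE)
    # impulse at voxel N/2 lies half a voxel below centre in z
    expect_equal(unname(hot[1, 1]), N / 2)
    expect_gt(max(p), 0)
    # energy confined near one detector column
    cols <- which(colSums(p) > 1e-3 * max(p))
    expect_lt(max(cols) - min(cols), 4)
  }
})

test_that("projection conserves mass for contained objects at any angle", {
  set.seed(5)
  N <- 32
  vol <- array(0, rep(N, 3))
  core <- 9:24
  vol[core, core, core] <- array(runif(16^3), rep(16, 3))
  geom <- newGeometry(N, N)
  pixArea <- geom@pixelSize^2
  voxVol <- (2 / N)^3
  for (th in c(0, 30.5, 77, 142)) {
    p <- projectVolume(vol, th, geom, step = 1 / (2 * N))
    expect_equal(sum(p) * pixArea, sum(vol) * voxVol, tolerance = 0.01)
    expect_true(all(p >= 0))   # non-negative field, non-negative projection
  }
})

test_that("axis-aligned projection of a uniform cube equals its thickness", {
  N <- 32
  vol <- array(0, rep(N, 3))
  vol[9:24, 9:24, 9:24] <- 1      # cube of side 1 in normalized units
  geom <- newGeometry(N, N)
  p <- projectVolume(vol, 0, geom, step = 1 / 128)
  inner <- p[13:20, 13:20]        # well inside the footprint
  expect_true(all(abs(inner - 1) < 0.02))
  expect_true(all(p[1:2, ] < 0.02))
})

test_that("projector respects full-turn periodicity and half-turn mirroring", {
  set.seed(8)
  N <- 32
  vol <- array(0, rep(N, 3))
  core <- 7:26
  vol[core, core, core] <- array(runif(20^3), rep(20, 3))
  geom <- newGeometry(N, N)
  for (th in c(12.5, 63)) {
    a <- projectVolume(vol, th, geom)
    b <- projectVolume(vol, th + 360, geom)
    expect_equal(a, b, tolerance = 1e-10)
    m <- projectVolume(vol, th + 180, geom)
    expect_equal(m, a[, ncol(a):1], tolerance = 0.05)
    expect_lt(sqrt(sum((m - a[, ncol(a):1])^2) / sum(a^2)), 0.01)
  }
})

test_that("ball projections match the analytic chord law", {
  N <- 48
  vol <- ballVolume(N, 0.6)
  geom <- newGeometry(N, N)
  p <- projectVolume(vol, 28, geom, step = 1 / 256)
  s <- (seq_len(N) - 1 - (N - 1) / 2) * geom@pixelSize
  d2 <- outer(s^2, s^2, `+`)          # squared ray-centre distance
  want <- 2 * sqrt(pmax(0.6^2 - d2, 0))
  # voxelization blurs the rim; compare away from the boundary shell
  interior <- d2 < (0.6 - 3 * 2 / N)^2
  expect_lt(max(abs(p - want)[interior]), 0.06)
  expect_lt(sqrt(sum((p - want)^2) / sum(want^2)), 0.04)
})

test_that("attenuation line integrals convert to intensity and back", {
  geom <- newGeometry(3, 3)
  mk <- function(v) new("Radiograph", pixels = matrix(v, 3, 3),
                        thetaDeg = 0, contrastDomain = "beta_line_integral")
  k <- 2 * pi / 1e-4
  vac <- intensityFromLineIntegrals(mk(0), k)
  expect_true(all(vac@pixels == 1))
  # 2 k int beta dz = ln 2 halves the intensity
  half <- intensityFromLineIntegrals(mk(log(2) / (2 * k)), k)
  expect_equal(as.numeric(half@pixels), rep(0.5, 9), tolerance = 1e-12)

  set.seed(3)
  li <- mk(runif(9) * 1e-5)   # keep 2 k int beta dz of order one
  rt <- lineIntegralsFromIntensity(intensityFromLineIntegrals(li, k), k)
  expect_equal(rt@pixels, li@pixels, tolerance = 1e-12)

  bad <- intensityFromLineIntegrals(mk(0), k)
  bad@pixels[1, 1] <- -0.5
  expect_error(lineIntegralsFromIntensity(bad, k), "non-positive")
  # phase conversion: phi = -k int delta dz
  dl <- new("Radiograph", pixels = matrix(2, 3, 3), thetaDeg = 0,
            contrastDomain = "delta_line_integral")
  expect_equal(as.numeric(phaseFromLineIntegrals(dl, k)@pixels),
               rep(-2 * k, 9))
})
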