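# FSC, half-bit criterion, image metrics, FBP baseline, volume measurement.

test_that("FSC is 1 for identical volumes and invariant to scale and order", {
  v <- ballVolume(16, 0.5) + 0.01 * array(stats::rnorm(16^3), rep(16, 3))
  cv <- fsc(v, v)
  expect_true(all(abs(cv@fsc - 1) < 1e-9))
  expect_equal(resolutionVoxels(cv), 2)        # no crossing: Nyquist floor
  cs <- fsc(v, 2 * v)
  expect_true(all(abs(cs@fsc - 1) < 1e-9))
  ab <- fsc(v, v^2)
  ba <- fsc(v^2, v)
  expect_equal(ab@fsc, ba@fsc, tolerance = 1e-12)
  expect_error(fsc(array(0, rep(8, 3)), v[1:8, 1:8, 1:8]), "all-zero")
})

test_that("FSC shells match a scalar-loop oracle and noise decorrelates", {
  set.seed(61)
  a <- array(stats::rnorm(8^3), rep(8, 3))
  b <- a + 0.5 * array(stats::rnorm(8^3), rep(8, 3))
  got <- fsc(a, b)
  want <- rFSC(a, b)
  expect_equal(got@freq, want$freq, tolerance = 1e-12)
  expect_equal(got@fsc, want$fsc, tolerance = 1e-5)
  expect_equal(got@nVoxels, want$n)

  # independent white noise: shell correlations within 3 / sqrt(n_r) of zero
  set.seed(62)
  n1 <- array(stats::rnorm(16^3), rep(16, 3))
  n2 <- array(stats::rnorm(16^3), rep(16, 3))
  cv <- fsc(n1, n2)
  big <- cv@nVoxels >= 50
  expect_true(all(abs(cv@fsc[big]) <= 3 / sqrt(cv@nVoxels[big])))
})

test_that("half-bit threshold has the stated values and monotonicity", {
  expect_equal(halfbitThreshold(1), (0.2071 + 1.9102) / (1.2071 + 0.9102),
               tolerance = 1e-12)
  expect_equal(halfbitThreshold(1e12), 0.2071 / 1.2071, tolerance = 1e-5)
  n <- c(1, 2, 5, 10, 100, 1e4, 1e6)
  expect_true(all(diff(halfbitThreshold(n)) < 0))
  expect_true(all(halfbitThreshold(n) > 0 & halfbitThreshold(n) <= 1))
})

test_that("resolution extraction interpolates the first downward crossing", {
  mkCurve <- function(freq, corr, n) {
    methods::new("FSCCurve", freq = freq, fsc = corr, nVoxels = n,
                 threshold = halfbitThreshold(n),
                 crossing = NA_real_, resolutionVoxels = NA_real_)
  }
  # large shells: threshold ~ 0.1716; drop from 1 to 0 across 0.25
  freq <- c(0, 0.15, 0.2, 0.25, 0.3, 0.35)
  n <- c(1, rep(1e6, 5))
  thr <- halfbitThreshold(1e6)
  corr <- c(1, 1, 1, 1, -1, -1)
  # crossing between 0.25 (corr 1) and 0.30 (corr -1):
  # f = 0.25 + (1 - thr)/(2) * 0.05 -> resolution 1/f
  want <- 0.25 + (1 - thr) / 2 * 0.05
  got <- resolutionFromFSC(mkCurve(freq, corr, n))
  expect_equal(got, 1 / want, tolerance = 1e-10)

  # curve crossing essentially at 0.25 cycles/voxel gives 4 voxels
  curve2 <- mkCurve(c(0, 0.15, 0.2, 0.25, 0.3, 0.35),
                    c(1, 1, 1, thr * 1.0000001, -1, -1), n)
  expect_equal(resolutionFromFSC(curve2), 4, tolerance = 1e-4)

  # no crossing: Nyquist-limited two voxels
  expect_equal(resolutionFromFSC(mkCurve(freq, rep(1, 6), n)), 2)

  # band-limited pair: compare against a brute-force discrete shell scan
  set.seed(63)
  a <- array(stats::rnorm(16^3), rep(16, 3))
  Fa <- stats::fft(a)
  f1 <- c(0:7, -8:-1) / 16
  r <- sqrt(outer(outer(f1^2, f1^2, `+`), f1^2, `+`))
  Fb <- Fa * (r <= 0.27)                    # kill everything above cutoff
  b <- Re(stats::fft(Fb, inverse = TRUE)) / 16^3 +
    1e-3 * array(stats::rnorm(16^3), rep(16, 3))
  cv <- fsc(a, b)
  # brute-force shell scan brackets the interpolated crossing
  firstBelow <- which(cv@fsc < cv@threshold & cv@freq > 0)[1]
  expect_false(is.na(firstBelow))
  expect_gte(resolutionVoxels(cv), 1 / cv@freq[firstBelow])
  expect_lte(resolutionVoxels(cv), 1 / cv@freq[firstBelow - 1])
  # and the reported crossing sits near the constructed band limit
  expect_lt(abs(cv@crossing - 0.27), 0.07)
})

test_that("image metrics have the stated exact limits", {
  truth <- array(stats::runif(10^3), rep(10, 3))
  truth <- (truth - min(truth)) / (max(truth) - min(truth))  # range 1
  t4 <- array(truth, c(10, 10, 10, 1))
  same <- imageMetrics(t4, t4)
  expect_equal(same$nrmse, 0)
  expect_equal(same$ssim, 1, tolerance = 1e-9)
  expect_equal(same$psnr, 100)       # capped sentinel for an exact match

  off <- imageMetrics(array(truth + 0.2, c(10, 10, 10, 1)), t4)
  expect_equal(off$nrmse, 0.2, tolerance = 1e-12)

  expect_error(imageMetrics(t4, array(1, c(10, 10, 10, 1))), "constant")
})

test_that("PSNR/SSIM/NRMSE match scalar-loop implementations", {
  set.seed(64)
  truth <- array(stats::runif(9^3, 0, 2), rep(9, 3))
  recon <- truth + array(stats::rnorm(9^3, 0, 0.1), rep(9, 3))
  m <- imageMetrics(recon, truth)
  rng <- max(truth) - min(truth)
  mse <- mean((recon - truth)^2)
  expect_equal(m$psnr, 10 * log10(rng^2 / mse), tolerance = 1e-10)
  expect_equal(m$nrmse, sqrt(mse) / rng, tolerance = 1e-10)
  expect_equal(m$ssim, rSSIM(recon, truth, rng), tolerance = 1e-6)
  # per-time curves have length T and aggregate into the summary
  r4 <- array(c(recon, truth), c(9, 9, 9, 2))
  t4 <- array(c(truth, truth), c(9, 9, 9, 2))
  m2 <- imageMetrics(r4, t4)
  expect_identical(nrow(m2), 2L)
  sm <- attr(m2, "summary")
  expect_equal(sm$mean[sm$metric == "nrmse"], mean(m2$nrmse))
})

test_that("FBP recovers a ball phantom and is linear", {
  vol <- ballVolume(64, 0.6)
  geom <- newGeometry(64, 64)
  th <- (0:179) * 1
  ps <- projectStack(vol, th, geom)
  rec <- fbpReconstruct(ps)
  expect_lt(sqrt(mean((rec - vol)^2)) / (max(vol) - min(vol)), 0.05)

  zero <- ps
  zero@data[] <- 0
  expect_true(all(fbpReconstruct(zero) == 0))

  dbl <- ps
  dbl@data <- 2 * dbl@data
  expect_equal(fbpReconstruct(dbl), 2 * rec, tolerance = 1e-10)
})

test_that("FBP error shrinks monotonically with angular sampling", {
  vol <- ballVolume(32, 0.6)
  geom <- newGeometry(32, 32)
  errs <- vapply(c(16, 32, 64, 180), function(na) {
    ps <- projectStack(vol, seq(0, 180, length.out = na + 1)[1:na], geom)
    rec <- suppressWarnings(fbpReconstruct(ps))
    sqrt(mean((rec - vol)^2))
  }, 0)
  # non-increasing up to the voxelization floor of the discrete phantom
  expect_true(all(diff(errs) <= 1e-3))
  # under-180-degree spans warn instead of erroring
  wps <- projectStack(vol, seq(0, 18, length.out = 10), geom)
  expect_warning(fbpReconstruct(wps), "limited-angle")
})

test_that("threshold segmentation measures volumes", {
  vol <- array(0, c(4, 4, 4))
  vol[1:2, , ] <- 5                       # half the voxels
  expect_equal(moltenVolume(vol, 1, voxelSize = 0.5), 32 * 0.5^3)
  expect_equal(moltenVolume(vol, -1), 64) # threshold below min: whole grid
  expect_equal(moltenVolume(vol, 1, above = FALSE), 32)

  # ellipsoidal pool against the analytic volume
  spec <- newPhantomSpec("melt_pool", gridSize = 48, nTimepoints = 1)
  ph <- makePhantom(spec)
  vs <- ph@voxelSize
  pool <- moltenVolume(volumeAt(ph, 1), 1.2 * spec@deltaValue, vs)
  axes <- spec@params$poolAxes
  analytic <- 4 / 3 * pi * prod(axes)
  # one-voxel-shell tolerance on the ellipsoid surface
  shell <- 4 / 3 * pi * (prod(axes + vs) - prod(axes - vs))
  expect_lt(abs(pool - analytic), shell)
})
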