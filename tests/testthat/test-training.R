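# Loss, regularizers, gradients and the fitting loop.

test_that("plane regularizer matches hand-computed TV and L1 values", {
  zeros <- replicate(6, array(0, c(3, 3, 2)), simplify = FALSE)
  r0 <- planeRegularizer(zeros)
  expect_equal(r0$value, 0)

  const <- replicate(6, array(0.7, c(3, 3, 2)), simplify = FALSE)
  rc <- planeRegularizer(const, tvWeight = 1, l1Weight = 1)
  expect_equal(rc$tv, 0)
  expect_equal(rc$l1, 0.7)

  # 2x2 single-channel plane [[0,1],[0,1]]: column-axis diffs (1,1),
  # row-axis diffs (0,0) -> TV mean 0.5; mean |value| 0.5
  p <- array(c(0, 0, 1, 1), c(2, 2, 1))
  r <- planeRegularizer(replicate(6, p, simplify = FALSE),
                        tvWeight = 1, l1Weight = 0)
  expect_equal(r$tv, 0.5)
  expect_equal(planeRegularizer(replicate(6, p, simplify = FALSE),
                                tvWeight = 0, l1Weight = 1)$l1, 0.5)
})

test_that("loss equals a scalar-loop MSE plus weighted regularizer", {
  set.seed(12)
  pred <- matrix(rnorm(8), 2, 4)
  targ <- matrix(rnorm(8), 2, 4)
  sc <- tinyScene(seed = 41)
  got <- sceneLoss(pred, targ, sc, lambdaReg = 0.3)
  mse <- 0
  for (i in 1:2) for (j in 1:4) mse <- mse + (pred[i, j] - targ[i, j])^2
  mse <- mse / 8
  expect_equal(got$data, mse, tolerance = 1e-12)
  expect_equal(got$total, got$data + 0.3 * got$reg, tolerance = 1e-12)

  expect_equal(sceneLoss(targ, targ)$total, 0)
  expect_equal(sceneLoss(targ + 0.25, targ)$data, 0.25^2, tolerance = 1e-12)
  expect_error(sceneLoss(matrix(0, 2, 2), matrix(0, 3, 2)), "mismatch")
})

test_that("analytic gradients agree with central finite differences", {
  sc <- tinyScene(spatial = 6, temporal = 4, F = 3, layers = 2, width = 8,
                  seed = 11)
  geom <- newGeometry(4, 4)
  rays <- generateRays(geom, 30)
  tn <- rep(0.2, 16)
  set.seed(2)
  tg <- runif(16)
  args <- list(origins = rays$origins, directions = rays$directions,
               tnorm = tn, targets = tg, nSamples = 8, lambdaReg = 0.01)
  g <- do.call(hextomo:::.lossGrad, c(list(sc), args))
  fd <- function(mutate) {
    eps <- 1e-6
    lp <- do.call(hextomo:::.lossGrad, c(list(mutate(sc, eps)), args))$total
    lm <- do.call(hextomo:::.lossGrad, c(list(mutate(sc, -eps)), args))$total
    (lp - lm) / (2 * eps)
  }
  checks <- list(
    list(function(s, e) { s@planes$xy[3, 4, 2] <- s@planes$xy[3, 4, 2] + e; s },
         g$grad_planes[[1]][3, 4, 2]),
    list(function(s, e) { s@planes$zt[2, 2, 1] <- s@planes$zt[2, 2, 1] + e; s },
         g$grad_planes[[2]][2, 2, 1]),
    list(function(s, e) { s@planes$xt[5, 3, 3] <- s@planes$xt[5, 3, 3] + e; s },
         g$grad_planes[[6]][5, 3, 3]),
    list(function(s, e) { s@mlpWeights[[1]][2, 5] <- s@mlpWeights[[1]][2, 5] + e; s },
         g$grad_W[[1]][2, 5]),
    list(function(s, e) { s@mlpWeights[[3]][1, 4] <- s@mlpWeights[[3]][1, 4] + e; s },
         g$grad_W[[3]][1, 4]),
    list(function(s, e) { s@mlpBiases[[2]][3] <- s@mlpBiases[[2]][3] + e; s },
         g$grad_b[[2]][3]))
  for (ch in checks) {
    num <- fd(ch[[1]])
    expect_equal(num, ch[[2]], tolerance = 1e-3)
  }
})

staticBallStack <- function() {
  spec <- newPhantomSpec("static_ball", gridSize = 16, nTimepoints = 1,
                         radius = 0.6)
  simulateTomoscopy(makePhantom(spec), framesPerRotation = 40,
                    rotations = 0.5, geom = newGeometry(16, 16))
}

test_that("fitting reduces the loss and is seed-deterministic", {
  stack <- staticBallStack()
  sc <- tinyScene(spatial = 12, temporal = 4, F = 4, layers = 2, width = 16,
                  seed = 6)
  cfg <- newTrainConfig(iterations = 300, raysPerBatch = 64,
                        nSamplesPerRay = 16, seed = 9, logEvery = 50)
  f1 <- fitScene(sc, stack, cfg)
  h <- trainHistory(f1)
  expect_lt(utils::tail(h$data_loss, 1), h$data_loss[1] / 10)
  # total = data + lambda * reg at every logged step
  expect_equal(h$total_loss, h$data_loss + cfg@lambdaReg * h$reg_loss,
               tolerance = 1e-10)
  # identical seeds give identical runs, parameters included
  f2 <- fitScene(sc, stack, cfg)
  expect_identical(f1@planes, f2@planes)
  expect_identical(trainHistory(f1)$total_loss, trainHistory(f2)$total_loss)
  # trailing-window convergence on full-coverage noiseless data
  expect_lt(stats::median(utils::tail(h$data_loss, 3)),
            stats::median(utils::head(h$data_loss, 3)))
})

test_that("a dominant regularizer shrinks the planes toward zero", {
  stack <- staticBallStack()
  sc <- tinyScene(spatial = 8, temporal = 4, F = 2, layers = 1, width = 8,
                  seed = 4)
  big <- fitScene(sc, stack, newTrainConfig(iterations = 200,
                                            raysPerBatch = 32,
                                            nSamplesPerRay = 8,
                                            lambdaReg = 1e4, seed = 2,
                                            logEvery = 100))
  before <- mean(abs(unlist(featurePlanes(sc))))
  after <- mean(abs(unlist(featurePlanes(big))))
  expect_lt(after, before / 3)
})

test_that("non-finite losses abort with the failing iteration", {
  stack <- staticBallStack()
  stack@data[1, 1, 1] <- NaN
  sc <- tinyScene(spatial = 8, temporal = 4, F = 2, layers = 1, width = 8,
                  seed = 1)
  expect_error(
    fitScene(sc, stack, newTrainConfig(iterations = 2000, raysPerBatch = 256,
                                       nSamplesPerRay = 8, logEvery = 500)),
    "non-finite loss at iteration")
})

test_that("reconstructSeries stacks dense evaluations with metadata", {
  sc <- tinyScene(seed = 3)
  one <- reconstructSeries(sc, 6, times = 0.25)
  expect_identical(nTimepoints(one), 1L)
  expect_equal(volumeAt(one, 1), evaluateField(sc, 6, 0.25)$delta)
  expect_false(one@extrapolated)

  three <- reconstructSeries(sc, 5, times = c(-0.5, 0, 1.4))
  expect_identical(nTimepoints(three), 3L)
  expect_true(three@extrapolated)
  # beyond t = 1 the temporal planes clamp to their edge
  expect_equal(volumeAt(reconstructSeries(sc, 5, 1.4), 1),
               volumeAt(reconstructSeries(sc, 5, 1), 1), tolerance = 1e-12)
})
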