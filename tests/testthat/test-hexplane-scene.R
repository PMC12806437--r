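# Six-plane scene: initialization, querying, decoding, dense evaluation.

test_that("initialization is seed-deterministic and validates its config", {
  a <- tinyScene(seed = 7)
  b <- tinyScene(seed = 7)
  expect_identical(a@planes, b@planes)
  expect_identical(a@mlpWeights, b@mlpWeights)
  expect_false(identical(a@planes, tinyScene(seed = 8)@planes))

  expect_error(newSceneConfig(outChannels = 3), "outChannels")
  expect_error(newSceneConfig(spatialGrid = 1), "spatialGrid")
  expect_error(newSceneConfig(featureDim = 0), "featureDim")
  expect_error(newSceneConfig(fusionMode = "sum"), "fusionMode")
})

test_that("parameter count matches the closed-form plane + MLP audit", {
  # reference configuration: grids 64, F = 48, MLP 3 x 64, one output
  cfg <- newSceneConfig(spatialGrid = 64, temporalGrid = 64, featureDim = 48,
                        mlpLayers = 3, mlpWidth = 64, outChannels = 1)
  planes <- 3 * 64 * 64 * 48 + 3 * 64 * 64 * 48
  mlp <- (6 * 48) * 64 + 64 + 64 * 64 + 64 + 64 * 64 + 64 + 64 * 1 + 1
  expect_identical(parameterCount(cfg), as.integer(planes + mlp))

  # plane storage grows as N^2 F + N T F, never as N^3 T
  for (N in c(8, 16, 32)) {
    Tg <- 6; F <- 4
    cfgN <- newSceneConfig(spatialGrid = N, temporalGrid = Tg, featureDim = F,
                           mlpLayers = 1, mlpWidth = 4)
    sc <- initScene(cfgN)
    planeParams <- sum(vapply(featurePlanes(sc), length, 0L))
    expect_identical(planeParams, as.integer(3 * N * N * F + 3 * N * Tg * F))
    expect_lt(planeParams, N^3 * Tg)
  }
})

test_that("fused descriptors equal a scalar-loop bilinear oracle", {
  for (fusion in c("concat", "paired-product")) {
    sc <- tinyScene(spatial = 7, temporal = 5, F = 3, fusionMode = fusion,
                    seed = 21)
    set.seed(42)
    pts <- matrix(runif(4 * 40, -1, 1), ncol = 4)
    got <- queryFeatures(sc, pts)
    want <- t(vapply(seq_len(nrow(pts)),
                     function(i) rQueryOne(sc, pts[i, ]),
                     numeric(ncol(got))))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("interpolation at grid nodes reproduces stored features exactly", {
  # node coordinates are exact dyadics (grid - 1 a power of two), so the
  # collapse of the bilinear weights is exact in floating point
  sc <- tinyScene(spatial = 9, temporal = 5, F = 3, seed = 2)
  gs <- -1 + 2 * (0:8) / 8
  gt <- -1 + 2 * (0:4) / 4
  p <- c(gs[3], gs[6], gs[2], gt[4])
  d <- queryFeatures(sc, matrix(p, 1))
  expect_identical(as.numeric(d[1, 1:3]), as.numeric(sc@planes$xy[3, 6, ]))
  expect_identical(as.numeric(d[1, 4:6]), as.numeric(sc@planes$zt[2, 4, ]))
  expect_identical(as.numeric(d[1, 13:15]), as.numeric(sc@planes$yz[6, 2, ]))
})

test_that("diagonal points query the three spatial planes at one location", {
  sc <- tinyScene(spatial = 9, temporal = 5, F = 2, seed = 3)
  u <- 0.37
  d <- queryFeatures(sc, matrix(c(u, u, u, u), 1))
  # xy, xz, yz slices all read location (u, u)
  loc <- rBilinear(sc@planes$xy, u, u)
  expect_equal(as.numeric(d[1, 1:2]), loc, tolerance = 1e-12)
  expect_equal(as.numeric(d[1, 5:6]), rBilinear(sc@planes$xz, u, u),
               tolerance = 1e-12)
  expect_equal(as.numeric(d[1, 9:10]), rBilinear(sc@planes$yz, u, u),
               tolerance = 1e-12)
})

test_that("empty point sets give empty results, bad widths give shape errors", {
  sc <- tinyScene()
  expect_identical(nrow(queryFeatures(sc, matrix(numeric(0), 0, 4))), 0L)
  expect_identical(nrow(evaluatePoints(sc, matrix(numeric(0), 0, 4))), 0L)
  expect_error(decodeFeatures(sc, matrix(0, 2, 5)), "width")
})

test_that("decoding matches a scalar-loop MLP and batching is invariant", {
  sc <- tinyScene(spatial = 6, temporal = 4, F = 2, layers = 2, width = 6,
                  seed = 13)
  set.seed(7)
  D <- matrix(rnorm(12 * 10), 10, 12)
  got <- decodeFeatures(sc, D)
  want <- vapply(seq_len(10), function(i) rDecodeOne(sc, D[i, ])[1], 0)
  expect_equal(as.numeric(got[, 1]), want, tolerance = 1e-12)
  # a batch of copies decodes to identical rows
  rep5 <- decodeFeatures(sc, D[rep(2, 5), ])
  expect_true(all(rep5 == rep5[1, 1]))
})

test_that("zero MLP weights force a constant softplus(0) field", {
  sc <- tinyScene(seed = 5)
  sc@mlpWeights <- lapply(sc@mlpWeights, function(w) w * 0)
  sc@mlpBiases <- lapply(sc@mlpBiases, function(b) b * 0)
  set.seed(11)
  v <- evaluatePoints(sc, matrix(runif(20, -1, 1), 5, 4))
  expect_equal(as.numeric(v), rep(log(2), 5), tolerance = 1e-12)
  f <- evaluateField(sc, 4, 0.2)
  expect_true(all(abs(f$delta - log(2)) < 1e-12))
})

test_that("hand-set single-layer MLP reproduces affine + activation", {
  sc <- tinyScene(spatial = 4, temporal = 4, F = 1, layers = 1, width = 2,
                  seed = 1)
  # hidden: relu(W1 d + b1); output: softplus(W2 h + b2)
  sc@mlpWeights <- list(matrix(c(1, -1, 0.5, 0, 0, 2,
                                 0, 0, 0, 1, -2, 0), 2, 6, byrow = TRUE),
                        matrix(c(1, 3), 1, 2))
  sc@mlpBiases <- list(c(0.1, -0.2), 0.25)
  d <- c(0.2, -0.4, 0.1, 0.3, 0.5, -0.1)
  h <- pmax(sc@mlpWeights[[1]] %*% d + sc@mlpBiases[[1]], 0)
  want <- log1p(exp(sc@mlpWeights[[2]] %*% h + 0.25))
  expect_equal(as.numeric(decodeFeatures(sc, matrix(d, 1))),
               as.numeric(want), tolerance = 1e-12)
})

test_that("dense field evaluation equals pointwise queries", {
  sc <- tinyScene(seed = 17)
  f <- evaluateField(sc, 4, t = -0.3)
  g <- -1 + (seq_len(4) - 0.5) * 2 / 4
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  want <- evaluatePoints(sc, cbind(pts, -0.3))
  expect_equal(as.numeric(f$delta), as.numeric(want[, 1]), tolerance = 1e-12)
})

test_that("time-constant planes give time-invariant fields", {
  sc <- tinyScene(spatial = 6, temporal = 4, F = 2, seed = 19)
  for (nm in c("zt", "yt", "xt")) {
    p <- sc@planes[[nm]]
    for (k in seq_len(dim(p)[3])) p[, , k] <- p[, 1, k]  # constant along T
    sc@planes[[nm]] <- p
  }
  expect_equal(evaluateField(sc, 5, -0.8)$delta,
               evaluateField(sc, 5, 0.6)$delta, tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-exactly", {
  sc <- tinyScene(seed = 23)
  path <- tempfile(fileext = ".rds")
  saveScene(sc, path)
  back <- loadScene(path)
  expect_identical(back@planes, sc@planes)
  expect_identical(back@mlpWeights, sc@mlpWeights)
  expect_identical(back@mlpBiases, sc@mlpBiases)
  expect_identical(back@config, sc@config)
})
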