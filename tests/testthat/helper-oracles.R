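# Scalar-loop reference implementations and small builders shared across
# tests. The oracles deliberately avoid the package's vectorized/compiled
# code paths.

tinyScene <- function(spatial = 8, temporal = 4, F = 3, layers = 2,
                      width = 8, seed = 1, ...) {
  initScene(newSceneConfig(spatialGrid = spatial, temporalGrid = temporal,
                           featureDim = F, mlpLayers = layers,
                           mlpWidth = width, seed = seed, ...))
}

# bilinear interpolation of one plane at one (u, v), clamped, scalar loops
rBilinear <- function(plane, u, v) {
  n1 <- dim(plane)[1]; n2 <- dim(plane)[2]; F <- dim(plane)[3]
  g1 <- min(max((u + 1) / 2 * (n1 - 1), 0), n1 - 1)
  g2 <- min(max((v + 1) / 2 * (n2 - 1), 0), n2 - 1)
  i0 <- min(floor(g1), n1 - 2); j0 <- min(floor(g2), n2 - 2)
  fi <- g1 - i0; fj <- g2 - j0
  out <- numeric(F)
  for (k in seq_len(F)) {
    out[k] <- (1 - fi) * (1 - fj) * plane[i0 + 1, j0 + 1, k] +
      fi * (1 - fj) * plane[i0 + 2, j0 + 1, k] +
      (1 - fi) * fj * plane[i0 + 1, j0 + 2, k] +
      fi * fj * plane[i0 + 2, j0 + 2, k]
  }
  out
}

# full descriptor at one point, scalar loops
rQueryOne <- function(scene, p) {
  pl <- featurePlanes(scene)
  coords <- list(c(p[1], p[2]), c(p[3], p[4]), c(p[1], p[3]),
                 c(p[2], p[4]), c(p[2], p[3]), c(p[1], p[4]))
  feats <- lapply(seq_len(6), function(i)
    rBilinear(pl[[i]], coords[[i]][1], coords[[i]][2]))
  if (sceneConfig(scene)@fusionMode == "concat") unlist(feats)
  else c(feats[[1]] * feats[[2]], feats[[3]] * feats[[4]],
         feats[[5]] * feats[[6]])
}

rSoftplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))

# MLP decode of one descriptor, scalar loops
rDecodeOne <- function(scene, d) {
  W <- scene@mlpWeights; b <- scene@mlpBiases
  a <- d
  for (l in seq_len(length(W) - 1L)) a <- pmax(W[[l]] %*% a + b[[l]], 0)
  u <- W[[length(W)]] %*% a + b[[length(b)]]
  if (sceneConfig(scene)@activation == "softplus") rSoftplus(u) else u
}

# shell-wise FSC, scalar loops over voxels (cubic volumes only)
rFSC <- function(volA, volB) {
  n <- dim(volA)[1]
  FA <- fft(volA); FB <- fft(volB)
  f1 <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  maxShell <- floor(n / 2)
  num <- pa <- pb <- cnt <- numeric(maxShell + 1)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    r <- sqrt(f1[i]^2 + f1[j]^2 + f1[k]^2)
    s <- round(r * n)
    if (s > maxShell) next
    num[s + 1] <- num[s + 1] + Re(FA[i, j, k] * Conj(FB[i, j, k]))
    pa[s + 1] <- pa[s + 1] + Mod(FA[i, j, k])^2
    pb[s + 1] <- pb[s + 1] + Mod(FB[i, j, k])^2
    cnt[s + 1] <- cnt[s + 1] + 1
  }
  list(freq = (0:maxShell) / n, fsc = num / sqrt(pa * pb), n = cnt)
}

# uniform-window SSIM, scalar loops (valid region)
rSSIM <- function(x, y, dataRange, win = 7L) {
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  d <- dim(x); NP <- win^3; cn <- NP / (NP - 1)
  vals <- c()
  for (i in seq_len(d[1] - win + 1)) for (j in seq_len(d[2] - win + 1))
    for (k in seq_len(d[3] - win + 1)) {
      xw <- x[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
      yw <- y[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
      ux <- mean(xw); uy <- mean(yw)
      vx <- cn * (mean(xw^2) - ux^2); vy <- cn * (mean(yw^2) - uy^2)
      cxy <- cn * (mean(xw * yw) - ux * uy)
      vals <- c(vals, ((2 * ux * uy + C1) * (2 * cxy + C2)) /
                  ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# centred ball mask on an N-cube of cell-centred voxels
ballVolume <- function(N, radius, level = 1) {
  g <- -1 + (seq_len(N) - 0.5) * 2 / N
  X <- array(rep(g, times = N * N), dim = rep(N, 3))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  level * ((X^2 + Y^2 + Z^2) < radius^2)
}

# projections of a phantom over an angle grid, wrapped as a ProjectionSet
projectStack <- function(vol, thetas, geom, time = 0, timeIndex = 1L) {
  data <- array(0, c(geom@detectorRows, geom@detectorCols, length(thetas)))
  for (i in seq_along(thetas)) data[, , i] <- projectVolume(vol, thetas[i], geom)
  new("ProjectionSet", data = data, thetaDeg = thetas,
      timeIndex = rep(as.integer(timeIndex), length(thetas)),
      time = rep(time, length(thetas)),
      contrastDomain = "delta_line_integral", geometry = geom)
}
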