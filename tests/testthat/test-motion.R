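grid <- gridSpec(0.45, 12)

test_that("channel direction follows s = [sin(theta), -cos(theta)]", {
  expect_equal(channelDirection(0), c(0, -1))
  expect_equal(channelDirection(pi / 2), c(1, 0))
  th <- seq(0, 2 * pi, length.out = 33)
  norms <- sqrt(rowSums(channelDirection(th)^2))
  expect_equal(norms, rep(1, 33))
})

test_that("reconstruction weights normalize and taper as specified", {
  expect_equal(reconstructionWeights(c(0, 0.5, 1, 1.5)), rep(0.25, 4))
  ang <- seq(0, pi, length.out = 64)
  w <- reconstructionWeights(ang, "smooth-transition")
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  expect_lt(w[1], w[32])
  expect_lt(w[64], w[32])
  expect_error(reconstructionWeights(numeric(0)), "empty")
})

test_that("effective temporal resolution follows the span/source/segment formula", {
  expect_equal(effectiveTemporalResolution(acquisitionGeometry(0.33)), 165)
  expect_equal(effectiveTemporalResolution(acquisitionGeometry(0.33, 2)),
               82.5)
  expect_equal(effectiveTemporalResolution(acquisitionGeometry(0.33, 1, 2)),
               effectiveTemporalResolution(acquisitionGeometry(0.33, 2, 1)))
})

test_that("zero velocity yields a discrete delta at the origin", {
  k <- synthesizeMpsf(motionState(0), acquisitionGeometry(0.33), grid)
  v <- as.matrix(k)
  ctr <- (dim(v) + 1) / 2
  expect_equal(v[ctr[1], ctr[2]], 1)
  expect_equal(sum(v), 1)
})

test_that("kernel support is bounded by speed times acquisition duration", {
  geom <- acquisitionGeometry(0.5)  # 0.25 s half-scan window
  k <- synthesizeMpsf(motionState(30, 0.8, 2.1), geom, gridSpec(0.45, 18),
                      nAngleSamples = 4096)
  v <- as.matrix(k)
  ctr <- (dim(v) + 1) / 2
  nz <- which(v > 0, arr.ind = TRUE)
  dmax <- max(sqrt((nz[, 1] - ctr[1])^2 + (nz[, 2] - ctr[2])^2)) *
    pixelSize(k)
  expect_lte(dmax, 30 * 0.25 + 2 * pixelSize(k))
  expect_true(all(v >= 0))
  expect_lt(abs(sum(v) - 1), 1e-9)
})

test_that("dual-source kernels are spatially tighter than single-source", {
  m <- motionState(30, 1.0, 0.4)
  extent <- function(geom) {
    v <- as.matrix(synthesizeMpsf(m, geom, grid, 2048))
    nz <- which(v > 1e-12, arr.ind = TRUE)
    max(dist(nz))
  }
  expect_lt(extent(acquisitionGeometry(0.33, 2)),
            extent(acquisitionGeometry(0.33, 1)))
})

test_that("kernel matches an independent dense point-cloud accumulation", {
  geom <- acquisitionGeometry(0.33)
  m <- motionState(28, 2.2, 5.1)
  k <- synthesizeMpsf(m, geom, grid, 1024)
  v <- as.matrix(k)
  half <- (nrow(v) - 1) / 2
  hp <- pixelSize(k)
  ## independent oracle: dense accumulation from first principles
  n <- 1e5
  u <- (seq_len(n) - 0.5) / n
  theta <- 5.1 + u * pi          # cw start angle + span position
  tloc <- u * 0.165              # single source: time over the full window
  vx <- 28 * cos(2.2); vy <- 28 * sin(2.2)
  sx <- sin(theta); sy <- -cos(theta)
  proj <- (vx * sx + vy * sy) * tloc
  gx <- proj * sx / hp + half + 1
  gy <- proj * sy / hp + half + 1
  ix <- floor(gx); iy <- floor(gy); fx <- gx - ix; fy <- gy - iy
  K <- nrow(v)
  acc <- numeric(K * K)
  idx <- c((iy - 1) * K + ix, (iy - 1) * K + ix + 1,
           iy * K + ix, iy * K + ix + 1)
  wts <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  for (p in seq_along(idx)) acc[idx[p]] <- acc[idx[p]] + wts[p]
  acc <- acc / sum(acc)
  expect_lt(sum(abs(v - matrix(acc, K, K))), 0.01)
})

test_that("a vanishing reconstruction span degenerates to a delta", {
  geom <- acquisitionGeometry(0.33, reconSpan = 1e-4)
  k <- synthesizeMpsf(motionState(35, 1.3, 0.2), geom, grid)
  v <- as.matrix(k)
  ctr <- (dim(v) + 1) / 2
  expect_gt(v[ctr[1], ctr[2]], 0.99)
})

test_that("motion ensembles are seeded, reproducible and mix directions", {
  geom <- acquisitionGeometry(0.33, 2)
  e1 <- sampleMpsfEnsemble(20, geom, grid, 5, seed = 9, nAngleSamples = 256)
  e2 <- sampleMpsfEnsemble(20, geom, grid, 5, seed = 9, nAngleSamples = 256)
  expect_identical(lapply(e1, as.matrix), lapply(e2, as.matrix))
  e0 <- sampleMpsfEnsemble(0, geom, grid, 3, seed = 9, nAngleSamples = 256)
  expect_identical(as.matrix(e0[[1]]), as.matrix(e0[[3]]))
  ## the ensemble-mean kernel approaches circular symmetry with n
  aniso <- function(n) {
    ks <- sampleMpsfEnsemble(25, geom, grid, n, seed = 4,
                             nAngleSamples = 256)
    half <- max(vapply(ks, function(k) (nrow(as.matrix(k)) - 1L) %/% 2L,
                       integer(1)))
    K <- 2L * half + 1L
    acc <- matrix(0, K, K)
    for (k in ks) {
      h <- (nrow(as.matrix(k)) - 1L) %/% 2L
      idx <- (half + 1L - h):(half + 1L + h)
      acc[idx, idx] <- acc[idx, idx] + as.matrix(k)
    }
    acc <- acc / sum(acc)
    xy <- expand.grid(x = seq_len(K) - half - 1L, y = seq_len(K) - half - 1L)
    cx <- sum(acc * xy$x); cy <- sum(acc * xy$y)
    cov <- matrix(c(sum(acc * (xy$x - cx)^2), sum(acc * (xy$x - cx) * (xy$y - cy)),
                    sum(acc * (xy$x - cx) * (xy$y - cy)), sum(acc * (xy$y - cy)^2)), 2)
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    ev[1] / ev[2]
  }
  expect_lt(abs(aniso(400) - 1), abs(aniso(25) - 1))
})

test_that("segment velocity is bounded, monotone in heart rate, and affine", {
  tab <- defaultVelocityTable()
  for (i in seq_len(nrow(tab)))
    for (hr in c(50, 75, 100)) {
      v <- segmentVelocity(hr, tab$sex[i], tab$segment_id[i])
      expect_gte(v, 15); expect_lte(v, 35)
    }
  expect_lte(segmentVelocity(60, "F", "RCA_mid"),
             segmentVelocity(90, "F", "RCA_mid"))
  custom <- data.frame(sex = "M", segment_id = "X", v_at_60bpm_mm_s = 20,
                       slope_mm_s_per_bpm = 0.1)
  expect_equal(segmentVelocity(70, "M", "X", custom), 21)
  expect_error(segmentVelocity(70, "F", "nope"), "valid segments")
})
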