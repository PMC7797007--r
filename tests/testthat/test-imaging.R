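grid <- gridSpec(0.45, 8)

test_that("parametric TTF families hit their defining values", {
  for (shape in c("gaussian", "logistic")) {
    ttf <- parametricTtf(0.40, shape)
    expect_equal(ttf@mtf[which(ttf@freq == 0.40)], 0.5)
    expect_equal(ttf@mtf[1], 1)
  }
  f <- seq(0.05, 1, by = 0.05)
  lo <- ctaEprime:::mtfAt(parametricTtf(0.32), f)
  hi <- ctaEprime:::mtfAt(parametricTtf(0.52), f)
  expect_true(all(hi > lo))
})

test_that("TTF discretization round-trips through the kernel within 2%", {
  ttf <- parametricTtf(0.40)
  psf <- ttfToPsf(ttf, grid)
  expect_equal(sum(psf), 1)
  K <- nrow(psf)
  hp <- attr(psf, "pixelSize")
  M <- Re(fft(ctaEprime:::embedKernel(psf, K, K)))
  fr <- ctaEprime:::radialFreqGrid(K, K, hp)
  nyq <- 1 / (2 * grid@clinicalPixel)
  sel <- fr <= nyq
  expect_lt(max(abs(M[sel] - ctaEprime:::mtfAt(ttf, fr[sel]))), 0.02)
  ## ideal system: delta kernel
  expect_equal(dim(ttfToPsf(parametricTtf(Inf), grid)), c(1L, 1L))
  ## sharper system: smaller kernel FWHM
  fwhm <- function(f50) {
    p <- ttfToPsf(parametricTtf(f50), grid)
    ctr <- (nrow(p) + 1) / 2
    sum(p[ctr, ] > max(p) / 2)
  }
  expect_lt(fwhm(0.52), fwhm(0.32))
})

test_that("blur is linear, mean-preserving and commutative", {
  ph <- renderCrossSection(vesselSpec(3, 0.5, lumenHu = 450), grid)
  expect_equal(as.matrix(applyBlur(ph, matrix(1, 1, 1))), as.matrix(ph))
  k1 <- ttfToPsf(parametricTtf(0.45), grid)
  k2 <- ttfToPsf(parametricTtf(0.35), grid)
  b1 <- applyBlur(ph, k1)
  expect_equal(mean(as.matrix(b1)), mean(as.matrix(ph)), tolerance = 1e-6)
  ab <- as.matrix(applyBlur(b1, k2))
  ba <- as.matrix(applyBlur(applyBlur(ph, k2), k1))
  ## compare away from the replicate-padded border, where the two
  ## orderings see slightly different padding content
  core <- 61:120
  expect_equal(ab[core, core], ba[core, core], tolerance = 1e-6)
})

test_that("downsampling block-averages exactly", {
  expect_equal(downsample(matrix(7, 6, 6), 3L), matrix(7, 2, 2))
  x <- matrix(rnorm(16), 4, 4)
  expect_equal(downsample(x, 1L), x)
  chk <- matrix(c(1, 0), 4, 4)  # checkerboard columns by recycling
  expect_equal(downsample(chk, 2L), matrix(0.5, 2, 2))
  hand <- matrix(1:16, 4, 4)
  expect_equal(downsample(hand, 2L)[1, 1], mean(c(1, 2, 5, 6)))
  expect_error(downsample(matrix(0, 5, 5), 2L), "divisible")
})

test_that("correlated noise fields have the exact requested magnitude", {
  nps <- parametricNps(12, 0.25)
  set.seed(1)
  y <- generateCorrelatedNoise(nps, 32L, 0.45)
  expect_equal(sd(y), 12, tolerance = 1e-12)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_identical(generateCorrelatedNoise(parametricNps(0, 0.25), 32L, 0.45),
                   matrix(0, 32, 32))
})

test_that("a flat spectrum produces white fields", {
  nps <- parametricNps(10, 0)  # white
  set.seed(7)
  num <- 0; den <- 0; n <- 0
  for (i in 1:200) {
    y <- generateCorrelatedNoise(nps, 32L, 0.45)
    num <- num + sum(y[-1, ] * y[-32, ])
    den <- den + sum(y^2)
    n <- n + 31 * 32
  }
  rho <- num / den
  expect_lt(abs(rho), 3 / sqrt(n))
})

test_that("the empirical spectrum follows the band-pass target shape", {
  nps <- parametricNps(20, 0.3)
  n <- 32L; d <- 0.45
  set.seed(11)
  P <- matrix(0, n, n)
  for (i in 1:200) {
    y <- generateCorrelatedNoise(nps, n, d)
    P <- P + Mod(fft(y))^2
  }
  fr <- ctaEprime:::radialFreqGrid(n, n, d)
  emp <- ctaEprime:::radialProfile(P, fr, nbins = 12)
  tgt <- stats::approx(nps@freq, nps@density, emp$r, rule = 2)$y
  empN <- emp$value / sum(emp$value)
  tgtN <- tgt / sum(tgt)
  expect_lt(sum(abs(empN - tgtN)), 0.10)
})

test_that("the identity chain reproduces the downsampled phantom", {
  ph <- renderCrossSection(vesselSpec(3, 0.5, lumenHu = 450), grid)
  inst <- composeInstance(ph, parametricTtf(Inf), NULL,
                          parametricNps(0, 0), grid)
  expect_equal(as.matrix(inst), downsample(ph, grid@hyperFactor),
               tolerance = 1e-9)
})

test_that("instances are bit-identical under a fixed seed", {
  ph <- renderCrossSection(vesselSpec(3, 0.5, lumenHu = 450), grid)
  k <- synthesizeMpsf(motionState(15, 0.3, 1.2), acquisitionGeometry(0.28, 2),
                      grid, 256)
  mk <- function() composeInstance(ph, parametricTtf(0.4), k,
                                   parametricNps(20, 0.25), grid, seed = 33)
  expect_identical(as.matrix(mk()), as.matrix(mk()))
})

test_that("a noise-only instance has standard deviation sigma exactly", {
  flat <- new("PhantomImage", values = matrix(100, 160, 160),
              pixelSize = 0.045)
  inst <- composeInstance(flat, parametricTtf(0.4), NULL,
                          parametricNps(17, 0.25), gridSpec(0.45, 7),
                          seed = 2)
  expect_equal(sd(as.matrix(inst)), 17, tolerance = 1e-12)
})

test_that("the deterministic chain is linear in the phantom", {
  g <- gridSpec(0.45, 7)
  mk <- function() new("PhantomImage",
                       values = matrix(rnorm(160 * 160, 100, 50), 160),
                       pixelSize = 0.045)
  set.seed(5)
  p1 <- mk(); p2 <- mk()
  k <- synthesizeMpsf(motionState(12, 1, 2), acquisitionGeometry(0.28, 2),
                      g, 256)
  chain <- function(p) as.matrix(composeInstance(p, parametricTtf(0.4), k,
                                                 parametricNps(0, 0.25), g))
  comb <- new("PhantomImage", values = 2 * p1@values - 0.5 * p2@values,
              pixelSize = 0.045)
  expect_equal(chain(comb), 2 * chain(p1) - 0.5 * chain(p2),
               tolerance = 1e-6)
})

test_that("noise fields from disjoint seeds are uncorrelated", {
  nps <- parametricNps(10, 0.25)
  set.seed(21); a <- generateCorrelatedNoise(nps, 32L, 0.45)
  set.seed(22); b <- generateCorrelatedNoise(nps, 32L, 0.45)
  expect_lt(abs(cor(as.vector(a), as.vector(b))), 3 / sqrt(length(a)))
})

test_that("tabulated curves read back from CSV", {
  f <- seq(0, 1.2, by = 0.02)
  path <- file.path(tempdir(), "ttf.csv")
  write.csv(data.frame(freq = f, mtf = exp(-f^2 / (2 * 0.3^2))), path,
            row.names = FALSE)
  ttf <- readCurveCsv(path, "ttf")
  expect_equal(ttf@mtf[1], 1)
  expect_equal(ctaEprime:::mtfAt(ttf, ttf@f50), 0.5, tolerance = 1e-3)
  pathN <- file.path(tempdir(), "nps.csv")
  write.csv(data.frame(freq = f, nps = f * exp(-f / 0.3)), pathN,
            row.names = FALSE)
  nps <- readCurveCsv(pathN, "nps", sigma = 20)
  expect_equal(nps@sigma, 20)
  expect_true(all(nps@density >= 0))
})
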