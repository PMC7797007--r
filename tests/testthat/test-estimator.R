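test_that("the default bank spans 71 distinct templates consistent with the chain", {
  cs <- diagCase()
  g <- caseGrid(cs)
  bank <- buildTemplateBank(cs, grid = g)
  expect_identical(ncol(bank@templates), 71L)
  expect_equal(bank@stenosis, seq(0.15, 0.85, by = 0.01))
  ## pairwise non-identical templates
  expect_identical(anyDuplicated(split(bank@templates,
                                       col(bank@templates))), 0L)
  ## template at the case's true parameters equals the noise-free
  ## motion-free composed instance
  ph <- renderCrossSection(ctaEprime:::caseVessel(cs, g), g)
  inst <- composeInstance(ph, parametricTtf(cs@f50), NULL,
                          parametricNps(0, 0.25), g)
  i <- which(abs(bank@stenosis - 0.5) < 1e-9)
  expect_equal(bank@templates[, i], as.vector(as.matrix(inst)),
               tolerance = 1e-8)
})

test_that("the squared-difference estimator picks the residual argmin", {
  ## 3-template toy: brute-force residuals decide
  tm <- cbind(c(sqrt(5), 0, 0, 0), c(sqrt(1.2), 0, 0, 0),
              c(sqrt(4.8), 0, 0, 0))
  bank <- new("TemplateBank", templates = tm, stenosis = c(0.2, 0.5, 0.8),
              velocity = rep(0, 3), dim = c(2L, 2L), pixelSize = 0.45,
              mode = "none", caseId = "toy")
  x <- matrix(0, 2, 2)
  res <- colSums((tm - as.vector(x))^2)
  cat(sprintf("\ntoy residual sums: %.1f %.1f %.1f\n", res[1], res[2], res[3]))
  expect_identical(which.min(res), 2L)
  expect_equal(mleEstimate(x, bank), 0.5)
  ## an exact bank template returns its own stenosis
  expect_equal(mleEstimate(matrix(tm[, 3], 2, 2), bank), 0.8)
  ## residual ties average the tied stenosis values
  tie <- new("TemplateBank", templates = tm[, c(1, 1, 3)],
             stenosis = c(0.2, 0.6, 0.8), velocity = rep(0, 3),
             dim = c(2L, 2L), pixelSize = 0.45, mode = "none",
             caseId = "toy")
  expect_equal(mleEstimate(matrix(tm[, 1], 2, 2), tie), 0.4)
})

test_that("noise-free motion-free estimation on the grid is exact", {
  cs <- diagCase(sigma = 0, velocity = 0)
  d <- estimateDistribution(cs, nInstances = 5, seed = 3)
  expect_true(all(estimates(d) == 0.5))
  res <- estimabilityIndex(d, cs)
  expect_identical(res@bias, 0)
  expect_identical(res@sdFraction, 0)
  expect_true(degeneracyFlags(res)[["zero_variance"]])
  expect_identical(ePrime(res), Inf)
})

test_that("estimate ensembles are reproducible and refuse n < 2", {
  cs <- diagCase(sigma = 25)
  g <- caseGrid(cs)
  bank <- buildTemplateBank(cs, grid = g)
  d1 <- estimateDistribution(cs, 25, seed = 8, bank = bank, grid = g)
  d2 <- estimateDistribution(cs, 25, seed = 8, bank = bank, grid = g)
  expect_identical(estimates(d1), estimates(d2))
  expect_error(estimateDistribution(cs, 1, seed = 8), "SD undefined")
})

test_that("the closed-form white-noise e' scales as a matched filter", {
  cs <- whiteNoiseCase()
  bank <- buildTemplateBank(cs, grid = caseGrid(cs))
  e1 <- closedFormEprimeWhiteNoise(bank, 20, 0.5)
  expect_equal(closedFormEprimeWhiteNoise(bank, 40, 0.5), e1 / 2)
  twice <- new("TemplateBank", templates = 2 * bank@templates,
               stenosis = bank@stenosis, velocity = bank@velocity,
               dim = bank@dim, pixelSize = bank@pixelSize,
               mode = bank@mode, caseId = bank@caseId)
  expect_equal(closedFormEprimeWhiteNoise(twice, 20, 0.5), 2 * e1)
})

test_that("e' is the reciprocal ensemble SD on the fractional scale", {
  cs <- diagCase()
  mkdist <- function(a) new("EstimateDistribution",
                            estimates = c(0.5 - a, 0.5 + a), truth = 0.5,
                            nClipped = 0L, seed = 1L)
  r <- estimabilityIndex(mkdist(0.25 / sqrt(2)), cs)
  expect_equal(ePrime(r), 4)
  r2 <- estimabilityIndex(mkdist(0.0391 / sqrt(2)), cs)
  expect_equal(round(ePrime(r2), 2), 25.58)
  expect_equal(precisionPct(r2), 3.91)
})

test_that("degenerate conditions are flagged and report e' = 0", {
  lowCnr <- diagCase(sigma = 60, contrast = 170)  # mixed plaque, CNR ~ 0.4
  expect_lte(caseCnr(lowCnr), 1)
  r <- computeEprime(lowCnr, nInstances = 10, seed = 1)
  expect_true(degeneracyFlags(r)[["degenerate_cnr"]])
  expect_identical(ePrime(r), 0)
  fast <- diagCase(velocity = 40)
  r2 <- computeEprime(fast, nInstances = 10, seed = 1)
  expect_true(degeneracyFlags(r2)[["degenerate_velocity"]])
  expect_identical(ePrime(r2), 0)
})

test_that("ensembles pinned at the bank edge are flagged saturated", {
  ## heavy motion on a slow single-source scanner drives every estimate
  ## to the template-grid edge
  cs <- diagCase(velocity = 35, nSources = 1L, rotation = 0.35)
  r <- suppressWarnings(computeEprime(cs, nInstances = 40, seed = 2))
  expect_true(degeneracyFlags(r)[["saturated"]])
  expect_identical(ePrime(r), 0)
})

test_that("nominal and velocity-axis banks build and estimate", {
  cs <- diagCase(sigma = 20)
  g <- caseGrid(cs)
  bnom <- buildTemplateBank(cs, grid = g, motionMode = "nominal")
  expect_identical(unique(bnom@velocity), 20)
  baxis <- buildTemplateBank(cs, stenosisGrid = seq(0.3, 0.7, 0.05),
                             grid = g, motionMode = "axis",
                             velocityLevels = c(15, 25, 35))
  expect_identical(ncol(baxis@templates), 27L)
  d <- suppressWarnings(
    estimateDistribution(cs, 20, seed = 5, bank = baxis, grid = g))
  expect_true(all(estimates(d) >= 0.3 & estimates(d) <= 0.7))
})
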