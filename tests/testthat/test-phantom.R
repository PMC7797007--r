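grid <- gridSpec(0.45, 8)

test_that("disease-free vessel renders no plaque and the analytic lumen area", {
  spec <- vesselSpec(3, 0, "calcified", lumenHu = 450)
  ph <- renderCrossSection(spec, grid)
  v <- as.matrix(ph)
  ## nothing at the calcified plaque value anywhere
  expect_false(any(abs(v - 500) < 1))
  ## lumen area by integrating the anti-aliased lumen coverage
  cov <- pmin(pmax((v - 50) / (450 - 50), 0), 1)
  area <- sum(cov) * pixelSize(ph)^2
  expect_lt(abs(area / (pi * 1.5^2) - 1), 0.005)
})

test_that("plaque annulus carries the material HU exactly at region interiors", {
  for (mat in c("noncalcified", "mixed", "calcified")) {
    ph <- renderCrossSection(vesselSpec(3, 0.5, mat, lumenHu = 450), grid)
    v <- as.matrix(ph)
    n <- nrow(v)
    ## sample mid-annulus along the +x axis: radius (0.75 + 1.5) / 2 mm
    r <- (0.75 + 1.5) / 2
    i <- n / 2  # row just below center (center offset half hyper pixel)
    j <- round(n / 2 + r / pixelSize(ph))
    expect_identical(v[i, j],
                     c(noncalcified = -40, mixed = 150, calcified = 500)[[mat]])
    expect_identical(v[2, 2], -90)   # background corner
    expect_identical(v[i, n / 2 + 2], 450)  # lumen interior
  }
})

test_that("minimal lumen diameter across the center matches the stenosed diameter", {
  ph <- renderCrossSection(vesselSpec(3, 0.5, "mixed", lumenHu = 450), grid)
  v <- as.matrix(ph)
  row <- v[nrow(v) / 2, ]
  lumPix <- sum(row > (450 + 150) / 2)
  expect_lt(abs(lumPix * pixelSize(ph) - 1.5), pixelSize(ph) + 1e-12)
})

test_that("rendered region areas match analytic circle/annulus areas", {
  spec <- vesselSpec(3.3, 0.4, "mixed", lumenHu = 400)
  ph <- renderCrossSection(spec, grid)
  v <- as.matrix(ph)
  px2 <- pixelSize(ph)^2
  rl <- 0.6 * 3.3 / 2; rr <- 3.3 / 2; rw <- rr + 0.5
  tol <- 2 / grid@hyperFactor
  lum <- sum(v > (400 + 150) / 2) * px2
  expect_lt(abs(lum / (pi * rl^2) - 1), tol)
  wallPlus <- sum(v > (50 - 90) / 2) * px2  # everything inside outer wall
  expect_lt(abs(wallPlus / (pi * rw^2) - 1), tol)
  plaque <- sum(v > (150 + 50) / 2) * px2 - lum  # annulus between lumen and wall
  expect_lt(abs(plaque / (pi * (rr^2 - rl^2)) - 1), tol)
})

test_that("concentric phantom is invariant under 90-degree grid rotations", {
  ph <- renderCrossSection(vesselSpec(3, 0.5, "mixed", lumenHu = 450), grid)
  v <- as.matrix(ph)
  r90 <- t(v[nrow(v):1, ])
  expect_equal(v, r90, tolerance = 0)
})

test_that("a vessel larger than the field of view is a geometry error", {
  expect_error(renderCrossSection(vesselSpec(9, 0.5), grid),
               "exceeds field of view")
})

test_that("segment diameter lookup is pure, bounded and validates segments", {
  tab <- defaultSegmentTable()
  for (i in seq_len(nrow(tab))) {
    d <- lumenReferenceDiameter(tab$sex[i], tab$segment_id[i])
    expect_gte(d, 1.5); expect_lte(d, 5.0)
    expect_identical(d, lumenReferenceDiameter(tab$sex[i], tab$segment_id[i]))
  }
  custom <- data.frame(sex = "F", segment_id = "proximal-LAD",
                       diameter_mm = 3.7)
  expect_identical(lumenReferenceDiameter("F", "proximal-LAD", custom), 3.7)
  expect_error(lumenReferenceDiameter("F", "no-such-segment"), "LAD_prox")
})

test_that("volume-averaging adjustment reproduces the area-fraction oracle", {
  ## large lumen: unchanged
  expect_identical(adjustedLumenHu(500, 0.1, 5, grid, -40), 500)
  ## stenosed lumen exactly one clinical pixel across
  d <- 3; s <- 1 - 0.45 / d  # stenosed diameter = 0.45 mm = 1 pixel
  frac <- pi * (0.45 / 2)^2 / 0.45^2
  oracle <- frac * 500 + (1 - frac) * 150
  got <- adjustedLumenHu(500, s, d, grid, 150)
  expect_lt(got, 500)
  expect_equal(got, oracle, tolerance = 1e-12)
  ## monotone in stenosis severity
  expect_lte(adjustedLumenHu(500, 0.85, 3, grid, -40),
             adjustedLumenHu(500, 0.15, 3, grid, -40))
  expect_error(adjustedLumenHu(-5, 0.5, 3, grid), "aortaContrast")
})

test_that("eccentric plaque shifts the lumen without changing its area", {
  conc <- renderCrossSection(vesselSpec(3, 0.5, "mixed", lumenHu = 450),
                             grid)
  ecc <- renderCrossSection(vesselSpec(3, 0.5, "mixed", lumenHu = 450,
                                       eccentricity = 1), grid)
  lum <- function(ph) as.matrix(ph) > (450 + 150) / 2
  expect_lt(abs(sum(lum(ecc)) / sum(lum(conc)) - 1), 0.01)
  ## lumen centroid moves off center by eccentricity * (rRef - rLum)
  n <- nrow(as.matrix(ecc))
  rowc <- (seq_len(n) - 0.5) * pixelSize(ecc) - grid@fov / 2
  cm <- sum(rowc * rowSums(lum(ecc))) / sum(lum(ecc))
  expect_equal(cm, 1.5 - 0.75, tolerance = 0.02)
  expect_error(vesselSpec(3, 0.5, eccentricity = 2), "eccentricity")
})

test_that("phantom dump writes a binary array with a JSON sidecar", {
  ph <- renderCrossSection(vesselSpec(3, 0.5), gridSpec(0.5, 6))
  path <- file.path(tempdir(), "ph.bin")
  writePhantom(ph, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(meta$shape, dim(ph))
  back <- matrix(readBin(path, "double", prod(dim(ph))), dim(ph)[1])
  expect_equal(back, as.matrix(ph), tolerance = 0)
})
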