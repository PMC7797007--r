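## Estimator module: the ideal maximum-likelihood stenosis estimator
## (squared-difference template matching without prewhitening), its
## estimate ensemble, and the estimability index e'.

## Direction-averaged motion kernel for a nominal velocity: mean of mPSF
## instances over a deterministic direction x start-angle grid, padded to
## a common (odd) size.
averagedMotionKernel <- function(speed, geom, grid, nDirections = 16L,
                                 nStarts = 8L, nAngleSamples = 512L) {
  dirs <- (seq_len(nDirections) - 0.5) / nDirections * 2 * pi
  starts <- (seq_len(nStarts) - 0.5) / nStarts * 2 * pi
  ks <- lapply(dirs, function(d) lapply(starts, function(s)
    synthesizeMpsf(motionState(speed, d, s), geom, grid, nAngleSamples,
                   checkExtent = FALSE)))
  ks <- unlist(ks, recursive = FALSE)
  half <- max(vapply(ks, function(k) (nrow(k@values) - 1L) %/% 2L,
                     integer(1)))
  K <- 2L * half + 1L
  acc <- matrix(0, K, K)
  for (k in ks) {
    h <- (nrow(k@values) - 1L) %/% 2L
    idx <- (half + 1L - h):(half + 1L + h)
    acc[idx, idx] <- acc[idx, idx] + k@values
  }
  new("MotionKernel", values = acc / sum(acc), pixelSize = ks[[1]]@pixelSize,
      temporalResolutionMs = ks[[1]]@temporalResolutionMs)
}

#' Build a bank of noise-free stenosis templates
#'
#' Each template is the deterministic chain (phantom at a grid stenosis
#' value, system TTF blur, optional nominal motion blur, downsampling)
#' with no noise. The default bank is motion-free: the motion direction
#' is stochastic and unknown to the observer, so its asymmetric blur
#' cannot be prewhitened into the templates. \code{motionMode =
#' "nominal"} adds a direction-averaged motion blur at the case velocity;
#' \code{motionMode = "axis"} spans a velocity axis of direction-averaged
#' blurs (the estimate remains the stenosis coordinate of the global
#' minimizer).
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param stenosisGrid sorted stenosis fractions (default 0.15 to 0.85 in
#'   steps of 0.01, 71 templates).
#' @param grid optional \linkS4class{GridSpec}; default
#'   \code{caseGrid(case)}.
#' @param motionMode \code{"none"}, \code{"nominal"} or \code{"axis"}.
#' @param velocityLevels velocity axis (mm/s) for \code{"axis"} mode.
#' @return a \linkS4class{TemplateBank}.
#' @export
buildTemplateBank <- function(case, stenosisGrid = seq(0.15, 0.85, by = 0.01),
                              grid = NULL,
                              motionMode = c("none", "nominal", "axis"),
                              velocityLevels = seq(15, 35, by = 5)) {
  motionMode <- match.arg(motionMode)
  stopIfNot(length(stenosisGrid) >= 1L && !is.unsorted(stenosisGrid),
            "stenosisGrid must be non-empty and sorted")
  grid <- grid %||% caseGrid(case)
  ttf <- caseTtf(case)
  kernels <- switch(motionMode,
    none = list(NULL),
    nominal = list(averagedMotionKernel(caseVelocity(case), case@geometry,
                                        grid)),
    axis = lapply(velocityLevels, averagedMotionKernel,
                  geom = case@geometry, grid = grid))
  vels <- switch(motionMode, none = 0, nominal = caseVelocity(case),
                 axis = velocityLevels)
  mHalf <- max(vapply(kernels, function(k)
    if (is.null(k)) 0L else (nrow(k@values) - 1L) %/% 2L, integer(1)))

  ## shared frequency-domain setup across templates (same N for all)
  nH <- gridHyperN(grid)
  hp <- pixelSize(grid)
  psfHalf <- if (is.infinite(ttf@f50)) 0L else
    (max(dim(ttfToPsf(ttf, grid))) - 1L) %/% 2L
  N <- goodFFTSize(nH + 2L * (psfHalf + mHalf + 2L))
  p1 <- (N - nH) %/% 2L
  M2 <- mtfAt(ttf, radialFreqGrid(N, N, hp))
  Khats <- lapply(kernels, function(k)
    if (is.null(k)) 1 else fft(embedKernel(k@values, N, N)))

  nClin <- gridClinN(grid)
  nT <- length(stenosisGrid) * length(kernels)
  sOut <- numeric(nT); vOut <- numeric(nT)

  ## render all stenosis levels cheaply: only the lumen disk changes
  ## across templates, so render the fully occluded vessel once and add
  ## the (anti-aliased) lumen disk coverage per level
  r2 <- renderRadius2(grid, 4L)
  ord <- order(r2)
  rsort <- sqrt(r2[ord])
  d <- caseDiameter(case)
  baseVals <- renderValues(caseVessel(case, grid, 1), grid, 4L, r2 = r2)
  fine <- matrix(0, nrow(r2), ncol(r2))
  pads <- array(0, dim = c(N, N, length(stenosisGrid)))
  for (si in seq_along(stenosisGrid)) {
    s <- stenosisGrid[si]
    k <- findInterval((1 - s) * d / 2, rsort, left.open = TRUE)
    lumIdx <- ord[seq_len(k)]
    fine[lumIdx] <- 1
    vals <- baseVals + blockAverage(fine, 4L) *
      (caseLumenHu(case, grid, s) - casePlaqueHu(case))
    fine[lumIdx] <- 0
    pads[, , si] <- padReplicate2(vals, p1, N - nH - p1)
  }
  tmpl <- matrix(0, nClin * nClin, nT)
  j <- 0L
  for (vi in seq_along(kernels)) {
    filt <- if (identical(Khats[[vi]], 1)) M2 + 0i else M2 * Khats[[vi]]
    cols <- j + seq_along(stenosisGrid)
    tmpl[, cols] <- cpp_ttf_chain(pads, filt, p1, nH, grid@hyperFactor)
    sOut[cols] <- stenosisGrid
    vOut[cols] <- vels[vi]
    j <- j + length(stenosisGrid)
  }
  new("TemplateBank", templates = tmpl, stenosis = sOut, velocity = vOut,
      dim = c(nClin, nClin), pixelSize = grid@clinicalPixel,
      mode = motionMode, caseId = case@id)
}

#' Maximum-likelihood stenosis estimate for one image instance
#'
#' Returns the stenosis coordinate of the global minimizer of the
#' pixel-wise squared difference between the instance and the bank
#' templates. Residual ties (within 1e-9 relative) average the tied
#' stenosis values.
#'
#' @param instance an \linkS4class{ImageInstance}, or a matrix matching
#'   the template shape.
#' @param bank a \linkS4class{TemplateBank}.
#' @return estimated stenosis fraction.
#' @export
mleEstimate <- function(instance, bank) {
  stopIfNot(ncol(bank@templates) >= 1L, "empty template bank")
  x <- as.vector(if (is(instance, "ImageInstance")) instance@values
                 else instance)
  stopIfNot(length(x) == nrow(bank@templates),
            "instance shape does not match bank templates")
  res <- colSums((bank@templates - x)^2)
  rmin <- min(res)
  mean(bank@stenosis[res <= rmin + 1e-9 * max(rmin, 1)])
}

#' Simulate the ensemble of maximum-likelihood estimates for a case
#'
#' Synthesizes \code{nInstances} stochastic image instances (independent
#' uniform motion direction and start angle, independent NPS-correlated
#' noise) of the case, estimates stenosis for each against the template
#' bank, and returns the estimate ensemble. Per-instance seeds are
#' derived deterministically from the root seed.
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param nInstances ensemble size (>= 2; default 2300).
#' @param seed root seed.
#' @param bank optional precomputed \linkS4class{TemplateBank}.
#' @param grid optional \linkS4class{GridSpec}.
#' @param nAngleSamples projection-angle samples per motion PSF.
#' @param motionMode template bank motion handling (used when
#'   \code{bank} is NULL).
#' @return an \linkS4class{EstimateDistribution}.
#' @export
estimateDistribution <- function(case, nInstances = 2300L, seed = 1L,
                                 bank = NULL, grid = NULL,
                                 nAngleSamples = 512L,
                                 motionMode = "none") {
  stopIfNot(nInstances >= 2L, "nInstances must be >= 2 (SD undefined)")
  grid <- grid %||% caseGrid(case)
  if (is.null(bank))
    bank <- buildTemplateBank(case, grid = grid, motionMode = motionMode)
  truth <- case@stenosisPct / 100
  speed <- caseVelocity(case)
  geom <- case@geometry
  nps <- caseNps(case)
  hp <- pixelSize(grid)
  nClin <- gridClinN(grid)
  tEff <- geom@rotationTime * geom@reconSpan / (2 * pi) /
    (geom@nSources * geom@nSegments)
  mHalf <- ceiling(speed * tEff / hp) + 1L

  ph <- renderCrossSection(caseVessel(case, grid), grid)
  setup <- chainSetup(ph, caseTtf(case), grid, mHalf)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  n <- as.integer(nInstances)
  noise <- matrix(0, nClin * nClin, n)
  H <- if (nps@sigma > 0) npsFilter(nps, nClin, grid@clinicalPixel) else NULL

  if (speed > 0) {
    ptsList <- vector("list", n)
    for (i in seq_len(n)) {
      set.seed(deriveSeed(seed, i))
      u <- runif(2, 0, 2 * pi)
      pts <- mpsfPoints(motionState(speed, u[1], u[2]), geom, nAngleSamples)
      ptsList[[i]] <- list(xy = pts$xy / hp, w = pts$w)
      if (!is.null(H)) noise[, i] <- rnorm(nClin * nClin)
    }
    allPts <- do.call(rbind, lapply(ptsList, `[[`, "xy"))
    allW <- unlist(lapply(ptsList, `[[`, "w"))
    starts <- c(0L, cumsum(vapply(ptsList, function(p) nrow(p$xy),
                                  integer(1))))
    Cbox <- boxMeans(ifft2r(setup$Bhat), setup$hf)
    D <- cpp_motion_gather(Cbox, setup$off, setup$hf, nClin,
                           allPts, allW, starts)
  } else {
    base <- as.vector(deterministicImage(setup))
    D <- matrix(base, nClin * nClin, n)
    if (!is.null(H))
      for (i in seq_len(n)) {
        set.seed(deriveSeed(seed, i))
        runif(2)
        noise[, i] <- rnorm(nClin * nClin)
      }
  }

  if (!is.null(H)) {
    for (i in seq_len(n)) {
      y <- ifft2r(fft(matrix(noise[, i], nClin, nClin)) * H)
      y <- y - mean(y)
      D[, i] <- D[, i] + as.vector(y) * (nps@sigma / sd(y))
    }
  }

  ## squared-difference residuals against all templates at once
  Tm <- bank@templates
  res <- outer(colSums(Tm^2), colSums(D^2), "+") - 2 * crossprod(Tm, D)
  est <- numeric(n)
  for (i in seq_len(n)) {
    r <- res[, i]
    rmin <- min(r)
    est[i] <- mean(bank@stenosis[r <= rmin + 1e-9 * max(rmin, 1)])
  }
  sRange <- range(bank@stenosis)
  nClipped <- sum(est <= sRange[1] + 1e-12 | est >= sRange[2] - 1e-12)
  if (nClipped > 0)
    warning(sprintf("%d estimate(s) clipped at the template grid edge",
                    nClipped), call. = FALSE)
  new("EstimateDistribution", estimates = est, truth = truth,
      nClipped = as.integer(nClipped), seed = as.integer(seed))
}

.degeneracyFlags <- function(case, grid = NULL, sdv = NA_real_,
                             saturated = FALSE) {
  c(degenerate_cnr = caseCnr(case, grid) <= 1,
    degenerate_velocity = caseVelocity(case) >= 40,
    zero_variance = !is.na(sdv) && sdv == 0,
    saturated = saturated)
}

#' Estimability index from an estimate ensemble
#'
#' e' is the reciprocal of the ensemble standard deviation on the
#' fractional stenosis scale. Degenerate (nondiagnostic) conditions
#' report e' = 0 with the corresponding flag:
#' \itemize{
#'   \item local plaque CNR at or below 1 (\code{degenerate_cnr});
#'   \item vessel speed at or above 40 mm/s (\code{degenerate_velocity});
#'   \item a saturated ensemble -- at least half of the estimates pinned
#'     at the template-grid edge (\code{saturated}): the truncated SD no
#'     longer measures estimation ability, and a degradation severe
#'     enough to drive the estimator to the bank boundary is
#'     nondiagnostic in the same sense as the CNR/velocity rules.
#' }
#' A zero-variance ensemble with no clipping (exact noise-free recovery)
#' reports an infinite e' sentinel flagged \code{zero_variance}.
#'
#' @param dist an \linkS4class{EstimateDistribution}.
#' @param case the \linkS4class{CaseSpec} the ensemble was simulated for.
#' @param grid optional \linkS4class{GridSpec} (CNR evaluation).
#' @return an \linkS4class{EstimabilityResult}.
#' @export
estimabilityIndex <- function(dist, case, grid = NULL) {
  est <- dist@estimates
  sdv <- sd(est)
  saturated <- dist@nClipped >= length(est) / 2
  flags <- .degeneracyFlags(case, grid, sdv, saturated)
  ep <- if (flags[["degenerate_cnr"]] || flags[["degenerate_velocity"]] ||
            saturated) 0
        else if (sdv == 0) Inf
        else 1 / sdv
  new("EstimabilityResult", ePrime = ep, sdFraction = sdv,
      precisionPct = 100 * sdv, meanEstimate = mean(est),
      bias = mean(est) - dist@truth, flags = flags,
      n = length(est))
}

#' Compute the estimability index of a case
#'
#' End-to-end convenience wrapper: builds the grid and template bank,
#' simulates the estimate ensemble, and summarizes it as e'. Cases that
#' are degenerate a priori (CNR <= 1 or speed >= 40 mm/s) are flagged
#' and reported as e' = 0 without simulation unless
#' \code{skipDegenerate = FALSE}.
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param nInstances ensemble size.
#' @param seed root seed.
#' @param grid,bank optional precomputed grid and template bank.
#' @param nAngleSamples projection-angle samples per motion PSF.
#' @param motionMode template-bank motion handling.
#' @param skipDegenerate skip the simulation for degenerate cases.
#' @return an \linkS4class{EstimabilityResult}.
#' @examples
#' \donttest{
#' cs <- caseSpec("demo", sigma = 25, lumenEnhancement = 500)
#' computeEprime(cs, nInstances = 100, seed = 7)
#' }
#' @export
computeEprime <- function(case, nInstances = 2300L, seed = 1L, grid = NULL,
                          bank = NULL, nAngleSamples = 512L,
                          motionMode = "none", skipDegenerate = TRUE) {
  grid <- grid %||% caseGrid(case)
  flags <- .degeneracyFlags(case, grid)
  if (skipDegenerate &&
      (flags[["degenerate_cnr"]] || flags[["degenerate_velocity"]])) {
    return(new("EstimabilityResult", ePrime = 0, sdFraction = NA_real_,
               precisionPct = NA_real_, meanEstimate = NA_real_,
               bias = NA_real_, flags = flags, n = 0L))
  }
  dist <- estimateDistribution(case, nInstances, seed, bank = bank,
                               grid = grid, nAngleSamples = nAngleSamples,
                               motionMode = motionMode)
  estimabilityIndex(dist, case, grid)
}

#' Closed-form e' under white noise (analytic cross-check)
#'
#' Local-linearization matched-filter variance: for a locally linear
#' template bank and white Gaussian noise of standard deviation sigma,
#' the estimate SD is \code{sigma / ||dT/ds||}, so
#' \code{e' = ||dT/ds|| / sigma} with the gradient taken as the central
#' finite difference of the templates at the true stenosis.
#'
#' @param bank a single-velocity \linkS4class{TemplateBank}.
#' @param sigma white noise standard deviation (HU).
#' @param truth stenosis fraction at which to linearize.
#' @return the analytic e'.
#' @export
closedFormEprimeWhiteNoise <- function(bank, sigma, truth) {
  stopIfNot(length(unique(bank@velocity)) == 1L,
            "closed form requires a single-velocity bank")
  s <- bank@stenosis
  i <- which.min(abs(s - truth))
  stopIfNot(i > 1L && i < length(s),
            "truth must lie strictly inside the stenosis grid")
  g <- (bank@templates[, i + 1L] - bank@templates[, i - 1L]) /
    (s[i + 1L] - s[i - 1L])
  sqrt(sum(g^2)) / sigma
}

#' Precision conversions for the estimability index
#'
#' \code{precisionPctFromEprime} converts e' to the stenosis estimation
#' precision (ensemble SD) in percent stenosis; \code{ci95WidthPct} is
#' the width of the +/- 2 SD (95\%) interval in percent.
#'
#' @param ePrime estimability index value(s).
#' @return percent-stenosis precision or interval width.
#' @examples
#' precisionPctFromEprime(25.58)  # 3.91
#' ci95WidthPct(25.58)            # 15.6
#' @export
precisionPctFromEprime <- function(ePrime) 100 / ePrime

#' @rdname precisionPctFromEprime
#' @export
ci95WidthPct <- function(ePrime) 400 / ePrime
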