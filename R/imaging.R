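## Imaging module: TTF blur, downsampling to clinical resolution, and
## NPS-correlated noise. The deterministic chain is linear and
## shift-invariant; blurs are applied in the frequency domain on a
## replicate-padded grid whose margin exceeds the blur support.

fftshift2 <- function(m) {
  k1 <- nrow(m); k2 <- ncol(m)
  o1 <- ((seq_len(k1) - 1 + ceiling(k1 / 2)) %% k1) + 1
  o2 <- ((seq_len(k2) - 1 + ceiling(k2 / 2)) %% k2) + 1
  m[o1, o2]
}

ifft2r <- function(X) Re(fft(X, inverse = TRUE)) / length(X)

padReplicate2 <- function(x, p1, p2) {
  n <- dim(x)
  ri <- pmin(pmax(seq_len(n[1] + p1 + p2) - p1, 1L), n[1])
  x[ri, ri]
}

#' Parametric task transfer function
#'
#' Radially symmetric MTF families parameterized by the 50\% frequency:
#' \code{"gaussian"} (\code{exp(-f^2 / (2 s^2))} with \code{s} set so that
#' the value at \code{f50} is exactly 0.5) and \code{"logistic"}
#' (\code{1 / (1 + (f/f50)^4)}, a heavier-tailed kernel family). An
#' infinite \code{f50} yields the ideal (all-pass) system.
#'
#' @param f50 frequency at 50\% modulation (1/mm).
#' @param shape \code{"gaussian"} or \code{"logistic"}.
#' @return a \linkS4class{TTFCurve}; the tabulated frequency axis
#'   includes \code{f50} so the defining value is exact.
#' @examples
#' parametricTtf(0.4)
#' @export
parametricTtf <- function(f50, shape = c("gaussian", "logistic")) {
  shape <- match.arg(shape)
  if (is.infinite(f50))
    return(new("TTFCurve", freq = c(0, 1e3), mtf = c(1, 1), f50 = Inf))
  fmax <- if (shape == "gaussian") 4 * f50 else 10 * f50
  freq <- sort(unique(c(seq(0, fmax, length.out = 1024L), f50)))
  mtf <- switch(shape,
    gaussian = exp(-freq^2 / (2 * (f50 / sqrt(2 * log(2)))^2)),
    logistic = 1 / (1 + (freq / f50)^4))
  new("TTFCurve", freq = freq, mtf = mtf, f50 = f50)
}

#' Read a tabulated TTF or NPS curve from a two-column CSV
#'
#' @param path CSV with columns frequency (1/mm) and value.
#' @param type \code{"ttf"} or \code{"nps"}.
#' @param sigma noise magnitude (HU) attached to an NPS curve.
#' @return a \linkS4class{TTFCurve} or \linkS4class{NPSCurve}.
#' @export
readCurveCsv <- function(path, type = c("ttf", "nps"), sigma = NA_real_) {
  type <- match.arg(type)
  tab <- read.csv(path)
  stopIfNot(ncol(tab) >= 2, "curve CSV needs two columns (freq, value)")
  f <- tab[[1]]; v <- tab[[2]]
  o <- order(f); f <- f[o]; v <- v[o]
  if (type == "ttf") {
    ov <- order(v)
    f50 <- stats::approx(v[ov], f[ov], 0.5, ties = "ordered")$y
    if (is.na(f50))
      stop("tabulated TTF never crosses 0.5; cannot locate f50",
           call. = FALSE)
    new("TTFCurve", freq = f, mtf = v / v[1], f50 = f50)
  } else {
    area <- sum(2 * pi * f * v) * mean(diff(f))
    new("NPSCurve", freq = f, density = v / area, sigma = sigma)
  }
}

## Evaluate the MTF curve at arbitrary (radial) frequency.
mtfAt <- function(ttf, f) {
  if (is.infinite(ttf@f50)) return(array(1, dim = dim(f) %||% length(f)))
  out <- stats::approx(ttf@freq, ttf@mtf, pmin(as.vector(abs(f)),
                                               max(ttf@freq)),
                       rule = 2)$y
  if (!is.null(dim(f))) dim(out) <- dim(f)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discretize a TTF into a spatial blur kernel
#'
#' Samples the radially symmetric MTF on the hyper-resolution frequency
#' grid, inverse-transforms, and trims the kernel to the smallest odd box
#' holding all but 1e-7 of its absolute mass.
#'
#' @param ttf a \linkS4class{TTFCurve}.
#' @param grid a \linkS4class{GridSpec}.
#' @return an odd-sized 2D kernel summing to 1 with a
#'   \code{"pixelSize"} attribute.
#' @export
ttfToPsf <- function(ttf, grid) {
  hp <- pixelSize(grid)
  if (is.infinite(ttf@f50)) {
    k <- matrix(1, 1, 1)
    attr(k, "pixelSize") <- hp
    return(k)
  }
  if (mtfAt(ttf, 1 / (2 * hp)) > 0.5)
    stop("TTF support extends beyond the hyper-grid Nyquist frequency",
         call. = FALSE)
  half <- min(ceiling(4 / (ttf@f50 * hp)), (gridHyperN(grid) - 1L) %/% 2L)
  K <- 2L * as.integer(half) + 1L
  M <- mtfAt(ttf, radialFreqGrid(K, K, hp))
  psf <- fftshift2(ifft2r(M))
  psf <- psf / sum(psf)
  ## trim to effective support
  ctr <- half + 1L
  tot <- sum(abs(psf))
  for (h in 0:half) {
    idx <- (ctr - h):(ctr + h)
    if (sum(abs(psf[idx, idx])) >= (1 - 1e-7) * tot) break
  }
  psf <- psf[idx, idx]
  psf <- psf / sum(psf)
  attr(psf, "pixelSize") <- hp
  psf
}

#' Convolve an image with a blur kernel
#'
#' Linear shift-invariant convolution in the frequency domain on a
#' replicate-padded canvas (margin equal to the kernel half-width,
#' trimmed after), preserving the image mean for unit-sum kernels.
#'
#' @param image a \linkS4class{PhantomImage} or plain matrix.
#' @param kernel odd-sized kernel matrix (e.g. from
#'   \code{\link{ttfToPsf}} or a \linkS4class{MotionKernel}).
#' @return blurred image of the same class and size as the input.
#' @export
applyBlur <- function(image, kernel) {
  px <- NULL
  if (is(image, "PhantomImage")) px <- image@pixelSize
  kpx <- if (is(kernel, "MotionKernel")) kernel@pixelSize else
    attr(kernel, "pixelSize")
  if (!is.null(px) && !is.null(kpx) && abs(px - kpx) > 1e-9 * px)
    stop("image and kernel pixel sizes differ", call. = FALSE)
  A <- if (is(image, "PhantomImage")) image@values else image
  k <- if (is(kernel, "MotionKernel")) kernel@values else kernel
  p <- (max(dim(k)) - 1L) %/% 2L
  Ap <- padReplicate(A, p)
  out <- ifft2r(fft(Ap) * fft(embedKernel(k, nrow(Ap), ncol(Ap))))
  out <- out[(p + 1):(p + nrow(A)), (p + 1):(p + ncol(A))]
  if (is(image, "PhantomImage"))
    new("PhantomImage", values = out, pixelSize = px)
  else out
}

#' Downsample a hyper-resolution image to the clinical grid
#'
#' Block averaging (area integration) over \code{hyperFactor} x
#' \code{hyperFactor} pixel blocks; the image mean is preserved.
#'
#' @param image a \linkS4class{PhantomImage} or matrix whose shape is
#'   divisible by \code{hyperFactor}.
#' @param hyperFactor integer block factor.
#' @return clinical-resolution matrix.
#' @export
downsample <- function(image, hyperFactor) {
  A <- if (is(image, "PhantomImage")) image@values else image
  blockAverage(A, as.integer(hyperFactor))
}

#' Parametric noise power spectrum
#'
#' Radial NPS families with noise magnitude \code{sigma}: a flat (white)
#' spectrum for \code{peak = 0}, or the band-pass ramp-type spectrum
#' \code{(f/peak) * exp(1 - f/peak)} characteristic of filtered
#' backprojection, peaking at \code{peak}. The density is normalized to
#' unit integral over the 2D frequency plane.
#'
#' @param sigma noise magnitude (HU standard deviation).
#' @param peak peak radial frequency (1/mm); 0 selects a flat spectrum.
#' @param fmax tabulation limit (1/mm).
#' @return an \linkS4class{NPSCurve}.
#' @export
parametricNps <- function(sigma, peak = 0, fmax = NULL) {
  if (peak <= 0) {
    fmax <- fmax %||% 8
    freq <- seq(0, fmax, length.out = 512L)
    dens <- rep(1 / (pi * fmax^2), length(freq))
  } else {
    fmax <- fmax %||% max(8 * peak, 3)
    freq <- seq(0, fmax, length.out = 1024L)
    g <- (freq / peak) * exp(1 - freq / peak)
    area <- sum(2 * pi * freq * g) * (freq[2] - freq[1])
    dens <- g / area
  }
  new("NPSCurve", freq = freq, density = dens, sigma = sigma)
}

## sqrt-NPS frequency-domain filter for an n x n field with pixel size d.
npsFilter <- function(nps, n, d) {
  r <- radialFreqGrid(n, n, d)
  S <- stats::approx(nps@freq, nps@density, pmin(as.vector(r),
                                                 max(nps@freq)),
                     rule = 2)$y
  dim(S) <- dim(r)
  sqrt(S)
}

#' Generate a correlated noise field
#'
#' Filters a zero-mean white Gaussian field with the square root of the
#' NPS in the frequency domain, then rescales so the sample standard
#' deviation equals \code{sigma} exactly (the per-case noise-magnitude
#' matching rule). Consumes the current RNG stream.
#'
#' @param nps an \linkS4class{NPSCurve}.
#' @param n field side length in pixels (>= 16).
#' @param pixel pixel size (mm).
#' @return an \code{n} x \code{n} zero-mean noise matrix with sample SD
#'   equal to \code{nps@sigma}.
#' @export
generateCorrelatedNoise <- function(nps, n, pixel) {
  stopIfNot(n >= 16L, "noise field must be at least 16 x 16")
  if (nps@sigma == 0) return(matrix(0, n, n))
  w <- matrix(rnorm(n * n), n, n)
  y <- ifft2r(fft(w) * npsFilter(nps, n, pixel))
  y <- y - mean(y)
  y * nps@sigma / sd(y)
}

## ---- deterministic chain shared by compose_instance and the estimator ----

## Precompute the frequency-domain representation of the system-blurred,
## replicate-padded phantom. motionHalfPx bounds the motion-kernel
## support the margin must additionally absorb.
chainSetup <- function(phantom, ttf, grid, motionHalfPx = 0L) {
  nH <- gridHyperN(grid)
  stopIfNot(all(dim(phantom@values) == nH),
            "phantom shape inconsistent with grid")
  hp <- pixelSize(grid)
  psfHalf <- if (is.infinite(ttf@f50)) 0L else
    (max(dim(ttfToPsf(ttf, grid))) - 1L) %/% 2L
  margin <- psfHalf + as.integer(motionHalfPx) + 2L
  N <- goodFFTSize(nH + 2L * margin)
  p1 <- (N - nH) %/% 2L
  Ap <- padReplicate2(phantom@values, p1, N - nH - p1)
  M <- mtfAt(ttf, radialFreqGrid(N, N, hp))
  list(Bhat = fft(Ap) * M, N = N, off = p1, nH = nH,
       hf = grid@hyperFactor, hp = hp)
}

## Noise-free clinical-resolution image for one motion kernel (or none).
deterministicImage <- function(setup, motionKernel = NULL) {
  Khat <- if (is.null(motionKernel)) 1 else
    fft(embedKernel(if (is(motionKernel, "MotionKernel"))
      motionKernel@values else motionKernel, setup$N, setup$N))
  field <- ifft2r(setup$Bhat * Khat)
  idx <- (setup$off + 1):(setup$off + setup$nH)
  blockAverage(field[idx, idx], setup$hf)
}

#' Compose one stochastic image instance
#'
#' Applies the deterministic chain (system TTF blur, then motion blur,
#' then downsampling to the clinical grid) and adds one instance of
#' NPS-correlated noise.
#'
#' @param phantom a \linkS4class{PhantomImage} on the grid's hyper
#'   resolution.
#' @param ttf a \linkS4class{TTFCurve}.
#' @param motionKernel a \linkS4class{MotionKernel}, or NULL for a
#'   motion-free instance.
#' @param nps an \linkS4class{NPSCurve}.
#' @param grid the \linkS4class{GridSpec} the phantom was rendered on.
#' @param seed optional seed for the noise draw (RNG state is restored).
#' @param caseId,drawIndex provenance annotations.
#' @return an \linkS4class{ImageInstance}.
#' @export
composeInstance <- function(phantom, ttf, motionKernel, nps, grid,
                            seed = NULL, caseId = "", drawIndex = NA_integer_) {
  mHalf <- if (is.null(motionKernel)) 0L else
    (max(dim(motionKernel@values)) - 1L) %/% 2L
  setup <- chainSetup(phantom, ttf, grid, mHalf)
  img <- deterministicImage(setup, motionKernel)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (nps@sigma > 0)
    img <- img + generateCorrelatedNoise(nps, nrow(img), grid@clinicalPixel)
  new("ImageInstance", values = img, pixelSize = grid@clinicalPixel,
      provenance = list(case_id = caseId, seed = seed, draw = drawIndex))
}
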