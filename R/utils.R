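## Internal numerical helpers shared across modules.

#' @useDynLib ctaEprime, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats fft rnorm runif sd lm predict coef aggregate quantile
#' @importFrom utils read.csv write.csv modifyList
NULL

## FFT sample frequencies (cycles/mm) for n samples spaced d apart,
## in standard DFT (wrap-around) order.
fftFreq <- function(n, d = 1) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * d)
}

## 2D radial frequency grid in DFT order.
radialFreqGrid <- function(nr, nc, d) {
  fr <- fftFreq(nr, d)
  fc <- fftFreq(nc, d)
  sqrt(outer(fr^2, fc^2, "+"))
}

## Embed a small odd-sized kernel at the DFT origin of an N1 x N2 array,
## wrapping negative offsets.
embedKernel <- function(kernel, n1, n2) {
  m <- dim(kernel)
  if (any(m %% 2L == 0L)) stop("kernel dimensions must be odd")
  h <- (m - 1L) %/% 2L
  out <- matrix(0, n1, n2)
  ri <- ((seq_len(m[1]) - 1L - h[1]) %% n1) + 1L
  ci <- ((seq_len(m[2]) - 1L - h[2]) %% n2) + 1L
  out[ri, ci] <- kernel
  out
}

## Replicate-edge padding by `p` pixels on every side.
padReplicate <- function(x, p) {
  n <- dim(x)
  ri <- pmin(pmax(seq_len(n[1] + 2L * p) - p, 1L), n[1])
  ci <- pmin(pmax(seq_len(n[2] + 2L * p) - p, 1L), n[2])
  x[ri, ci]
}

## Smallest highly-composite FFT size >= n (factors 2,3,5).
goodFFTSize <- function(n) {
  m <- n
  repeat {
    k <- m
    for (f in c(2L, 3L, 5L)) while (k %% f == 0L) k <- k %/% f
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

## Deterministic per-instance RNG seed derived from a root seed; keeps
## ensembles reproducible and independent of evaluation order.
deriveSeed <- function(root, i) {
  as.integer((abs(as.numeric(root)) * 48271 + 1009 * as.numeric(i)) %%
               2147483629)
}

## Truncated-normal draws by inverse-CDF on the truncated interval.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

## Radially averaged profile of a 2D array given a matching radius array.
## Returns data.frame(r = bin center, value = mean within bin).
radialProfile <- function(x, r, nbins = 32, rmax = max(r)) {
  br <- seq(0, rmax, length.out = nbins + 1)
  bin <- findInterval(r, br, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nbins
  v <- tapply(x[keep], bin[keep], mean)
  idx <- as.integer(names(v))
  data.frame(r = (br[idx] + br[idx + 1L]) / 2, value = as.numeric(v))
}

## Sliding block means: out[a, b] = mean of x[a:(a+h-1), b:(b+h-1)],
## computed by 2D cumulative sums.
boxMeans <- function(x, h) {
  n <- nrow(x)
  S <- matrix(0, n + 1L, n + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # transposed
  S[-1L, -1L] <- t(S[-1L, -1L])
  m <- n - h + 1L
  i1 <- (h + 1L):(n + 1L); i0 <- 1L:m
  (S[i1, i1] - S[i0, i1] - S[i1, i0] + S[i0, i0]) / h^2
}

## Atomic write: render to a sibling temp file, then rename into place.
atomicWrite <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

writeJsonAtomic <- function(x, path) {
  atomicWrite(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
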