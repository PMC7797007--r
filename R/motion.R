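## Motion module: stochastic 2D image-domain asymmetric motion PSFs
## induced by half-scan acquisition of a moving vessel.

#' Construct an acquisition geometry
#'
#' @param rotationTime gantry rotation time (s).
#' @param nSources 1 (single source) or 2 (dual source).
#' @param nSegments number of multisegment acquisition segments.
#' @param reconSpan angular reconstruction span (rad); defaults to pi
#'   (half-scan, parallel-beam approximation).
#' @param rotationSense \code{"cw"} (default) or \code{"ccw"}.
#' @param weighting projection weighting scheme, \code{"uniform"} or
#'   \code{"smooth-transition"}.
#' @return an \linkS4class{AcquisitionGeometry}.
#' @examples
#' acquisitionGeometry(0.33, nSources = 2)
#' @export
acquisitionGeometry <- function(rotationTime, nSources = 1L, nSegments = 1L,
                                reconSpan = pi, rotationSense = "cw",
                                weighting = "uniform") {
  new("AcquisitionGeometry", rotationTime = rotationTime,
      nSources = as.integer(nSources), nSegments = as.integer(nSegments),
      reconSpan = reconSpan, rotationSense = rotationSense,
      weighting = weighting)
}

#' Construct a motion state
#'
#' @param speed vessel speed (mm/s).
#' @param direction in-plane motion direction (rad).
#' @param startAngle source projection angle at the start of the
#'   acquisition window (rad).
#' @return a \linkS4class{MotionState}.
#' @export
motionState <- function(speed, direction = 0, startAngle = 0) {
  new("MotionState", speed = speed, direction = direction,
      startAngle = startAngle)
}

#' Detector channel direction for a projection angle
#'
#' The channel direction is perpendicular to the source-to-detector axis;
#' for a clockwise source rotation seen from the isocenter it is
#' \code{s = c(sin(theta), -cos(theta))}.
#'
#' @param theta source projection angle (rad); vectorized.
#' @return a length-2 unit vector, or a 2-column matrix for vector input.
#' @examples
#' channelDirection(0)      # c(0, -1)
#' channelDirection(pi / 2) # c(1, 0)
#' @export
channelDirection <- function(theta) {
  out <- cbind(sin(theta), -cos(theta))
  if (length(theta) == 1L) as.vector(out) else out
}

#' Projection-angle reconstruction weights
#'
#' @param angles projection angles spanning the reconstruction window.
#' @param scheme \code{"uniform"} for equal weights, or
#'   \code{"smooth-transition"} for a cosine taper over the first and last
#'   quarter of the span (suppressing data-transition artifacts).
#' @return non-negative weights summing to 1, one per angle.
#' @export
reconstructionWeights <- function(angles, scheme = "uniform") {
  n <- length(angles)
  stopIfNot(n >= 1L, "empty angle set")
  if (scheme == "uniform") return(rep(1 / n, n))
  stopIfNot(scheme == "smooth-transition",
            sprintf("unknown weighting scheme '%s'", scheme))
  span <- max(angles) - min(angles)
  u <- if (span > 0) (angles - min(angles)) / span else rep(0.5, n)
  a <- 0.5  # tapered fraction of the span (Tukey window)
  w <- rep(1, n)
  lo <- u < a / 2
  hi <- u > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / a - 1)))
  w / sum(w)
}

#' Effective temporal resolution of an acquisition geometry
#'
#' The acquisition window of the reconstruction span divided among
#' sources and segments:
#' \code{rotationTime * reconSpan / (2 pi) / (nSources * nSegments)}.
#'
#' @param geom an \linkS4class{AcquisitionGeometry}.
#' @return effective temporal resolution in milliseconds.
#' @examples
#' effectiveTemporalResolution(acquisitionGeometry(0.33)) # 82.5 ms
#' @export
effectiveTemporalResolution <- function(geom) {
  1000 * geom@rotationTime * geom@reconSpan / (2 * pi) /
    (geom@nSources * geom@nSegments)
}

## Splat points (mm) for one motion draw: per sampled projection angle,
## the vessel displacement projected onto (and laid along) the channel
## direction, plus the reconstruction weight of that angle.
## Dual-source / multisegment acquisitions partition the span into
## nSources*nSegments contiguous angular subsets, each acquired over the
## (shorter) effective temporal window with its own time origin.
mpsfPoints <- function(motion, geom, nAngleSamples) {
  n <- as.integer(nAngleSamples)
  u <- (seq_len(n) - 0.5) / n                       # position within span
  sense <- if (geom@rotationSense == "cw") 1 else -1
  theta <- motion@startAngle + sense * u * geom@reconSpan
  nsub <- geom@nSources * geom@nSegments
  tEff <- geom@rotationTime * geom@reconSpan / (2 * pi) / nsub
  sub <- pmin(floor(u * nsub), nsub - 1)
  tloc <- (u - sub / nsub) * nsub * tEff            # time within subset [0, tEff)
  v <- motion@speed * c(cos(motion@direction), sin(motion@direction))
  s <- cbind(sin(theta), -cos(theta))
  proj <- (v[1] * s[, 1] + v[2] * s[, 2]) * tloc    # (v t) . s
  list(xy = s * proj, w = reconstructionWeights(theta, geom@weighting),
       tEff = tEff)
}

## Bilinear splat of weighted points (mm) onto an odd-sized kernel grid
## centered at the origin.
splatKernel <- function(xy, w, pixel, halfWidth) {
  k <- 2L * as.integer(halfWidth) + 1L
  c0 <- as.integer(halfWidth) + 1L
  gx <- xy[, 1] / pixel + c0
  gy <- xy[, 2] / pixel + c0
  ix <- floor(gx); iy <- floor(gy)
  fx <- gx - ix; fy <- gy - iy
  idx <- c((iy - 1) * k + ix, (iy - 1) * k + ix + 1,
           iy * k + ix, iy * k + ix + 1)
  wts <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
           w * (1 - fx) * fy, w * fx * fy)
  if (any(idx < 1 | idx > k * k))
    stop("motion kernel support exceeds grid extent", call. = FALSE)
  acc <- rowsum(wts, idx)
  out <- matrix(0, k, k)
  out[as.integer(rownames(acc))] <- acc
  out / sum(out)
}

#' Synthesize one asymmetric motion PSF instance
#'
#' For every sampled projection angle the vessel motion vector, integrated
#' to the angle's acquisition time, is projected onto the channel
#' direction and deposited (sub-pixel bilinear splatting, weighted by the
#' reconstruction weights) along that direction. Dual-source and
#' multisegment geometries partition the span into contiguous angular
#' subsets each acquired over the shorter effective temporal window.
#'
#' @param motion a \linkS4class{MotionState}.
#' @param geom an \linkS4class{AcquisitionGeometry}.
#' @param grid a \linkS4class{GridSpec}; the kernel is sampled at the
#'   hyper pixel size.
#' @param nAngleSamples number of sampled projection angles (>= 64).
#' @param checkExtent fail when the kernel support exceeds the grid field
#'   of view (disable for internal use on padded canvases).
#' @return a \linkS4class{MotionKernel} normalized to unit sum, anchored
#'   so the zero-time vessel position is at the kernel center.
#' @examples
#' g <- gridSpec(0.45, 8)
#' synthesizeMpsf(motionState(25, pi / 3), acquisitionGeometry(0.33), g)
#' @export
synthesizeMpsf <- function(motion, geom, grid, nAngleSamples = 1024L,
                           checkExtent = TRUE) {
  stopIfNot(nAngleSamples >= 64L, "nAngleSamples must be >= 64")
  hp <- pixelSize(grid)
  pts <- mpsfPoints(motion, geom, nAngleSamples)
  half <- ceiling(motion@speed * pts$tEff / hp) + 1L
  if (checkExtent && (2L * half + 1L) * hp > grid@fov)
    stop("motion kernel support exceeds the grid field of view",
         call. = FALSE)
  new("MotionKernel", values = splatKernel(pts$xy, pts$w, hp, half),
      pixelSize = hp, temporalResolutionMs = 1000 * pts$tEff)
}

#' Draw an ensemble of motion PSF instances
#'
#' Motion direction and start angle are drawn independently and uniformly
#' on [0, 2 pi) per instance; per-instance seeds are derived
#' deterministically from the root seed, so the ensemble is reproducible
#' and order-independent.
#'
#' @param speed vessel speed (mm/s).
#' @param geom an \linkS4class{AcquisitionGeometry}.
#' @param grid a \linkS4class{GridSpec}.
#' @param n ensemble size.
#' @param seed root seed.
#' @param nAngleSamples sampled projection angles per kernel.
#' @return list of \linkS4class{MotionKernel} objects.
#' @export
sampleMpsfEnsemble <- function(speed, geom, grid, n, seed,
                               nAngleSamples = 1024L) {
  stopIfNot(n >= 1L, "n must be >= 1")
  lapply(seq_len(n), function(i) {
    dr <- mpsfDraw(seed, i)
    synthesizeMpsf(motionState(speed, dr[1], dr[2]), geom, grid,
                   nAngleSamples)
  })
}

## The (direction, start angle) pair of draw i under root seed `seed`.
mpsfDraw <- function(seed, i) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(deriveSeed(seed, i))
  runif(2, 0, 2 * pi)
}

#' Default segment velocity lookup table
#'
#' Per sex/segment affine velocity model
#' \code{v = v_at_60bpm + slope * (HR - 60)}, clamped to the configured
#' physiologic range. The shipped coefficients are editable defaults
#' spanning 15 to 35 mm/s over resting heart rates 50 to 100 bpm.
#'
#' @return data.frame with columns \code{sex}, \code{segment_id},
#'   \code{v_at_60bpm_mm_s}, \code{slope_mm_s_per_bpm}.
#' @export
defaultVelocityTable <- function() .readLookup(NULL, "segment_velocity.csv")

#' Vessel speed from heart rate, sex and segment
#'
#' @param heartRate resting heart rate (bpm), > 0.
#' @param sex \code{"F"} or \code{"M"}.
#' @param ahaSegment coronary segment identifier.
#' @param table lookup data.frame (see \code{\link{defaultVelocityTable}}).
#' @param range allowed velocity range (mm/s) the affine model is clamped
#'   to.
#' @return vessel speed (mm/s), monotone non-decreasing in heart rate.
#' @export
segmentVelocity <- function(heartRate, sex, ahaSegment, table = NULL,
                            range = c(15, 35)) {
  stopIfNot(heartRate > 0, "heartRate must be > 0")
  table <- .readLookup(table, "segment_velocity.csv")
  hit <- table$sex == sex & table$segment_id == ahaSegment
  if (!any(hit))
    stop(sprintf("unknown segment '%s' for sex '%s'; valid segments: %s",
                 ahaSegment, sex,
                 paste(sort(unique(table$segment_id)), collapse = ", ")),
         call. = FALSE)
  row <- table[which(hit)[1], ]
  v <- row$v_at_60bpm_mm_s + row$slope_mm_s_per_bpm * (heartRate - 60)
  min(max(v, range[1]), range[2])
}
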