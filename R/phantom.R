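## Phantom module: hyper-resolution ground-truth cross-sections of
## contrast-enhanced coronary lumens narrowed by concentric plaque.

## Default plaque attenuation by material class at 120 kV.
.plaqueHuTable <- c(noncalcified = -40, mixed = 150, calcified = 500)

#' Construct a sampling grid
#'
#' @param clinicalPixel reconstructed in-plane pixel size (mm).
#' @param fov requested square field of view (mm); rounded up to a whole,
#'   even number of clinical pixels so block downsampling is exact.
#' @param hyperFactor integer hyper-resolution oversampling factor
#'   (default 10, the minimum).
#' @return a \linkS4class{GridSpec}.
#' @examples
#' gridSpec(0.45, fov = 8)
#' @export
gridSpec <- function(clinicalPixel, fov, hyperFactor = 10L) {
  nClin <- ceiling(fov / clinicalPixel)
  if (nClin %% 2L == 1L) nClin <- nClin + 1L
  new("GridSpec", clinicalPixel = clinicalPixel,
      hyperFactor = as.integer(hyperFactor), fov = nClin * clinicalPixel)
}

gridClinN <- function(grid) as.integer(round(grid@fov / grid@clinicalPixel))
gridHyperN <- function(grid) gridClinN(grid) * grid@hyperFactor

#' Construct a stenosed-vessel specification
#'
#' @param referenceDiameter normal reference lumen diameter (mm).
#' @param stenosisFraction fractional diameter narrowing in [0, 1]; the
#'   stenosed lumen diameter is \code{(1 - stenosisFraction) *
#'   referenceDiameter}.
#' @param material plaque material class (\code{"noncalcified"},
#'   \code{"mixed"}, \code{"calcified"}).
#' @param plaqueHu plaque attenuation (HU); defaults by material to
#'   -40 / 150 / 500 HU.
#' @param lumenHu contrast-enhanced lumen attenuation (HU).
#' @param wallHu vessel wall attenuation (HU).
#' @param backgroundHu uniform background attenuation (HU), an epicardial
#'   fat surrogate.
#' @param wallThickness concentric wall thickness (mm).
#' @param eccentricity plaque eccentricity in [0, 1]; 0 (default) is a
#'   concentric annulus, larger values shift the residual lumen off
#'   center into a crescent-shaped plaque.
#' @return a \linkS4class{VesselSpec}.
#' @examples
#' vesselSpec(3, 0.5, "calcified", lumenHu = 450)
#' @export
vesselSpec <- function(referenceDiameter, stenosisFraction,
                       material = "noncalcified", plaqueHu = NULL,
                       lumenHu = 450, wallHu = 50, backgroundHu = -90,
                       wallThickness = 0.5, eccentricity = 0) {
  if (is.null(plaqueHu)) {
    stopIfNot(material %in% names(.plaqueHuTable),
              sprintf("unknown plaque material '%s'", material))
    plaqueHu <- unname(.plaqueHuTable[material])
  }
  new("VesselSpec", referenceDiameter = referenceDiameter,
      wallThickness = wallThickness, stenosisFraction = stenosisFraction,
      material = material, plaqueHu = plaqueHu, lumenHu = lumenHu,
      wallHu = wallHu, backgroundHu = backgroundHu,
      eccentricity = eccentricity)
}

## Block average over f x f pixel blocks (grouped row sums, twice).
blockAverage <- function(x, f) {
  if (f == 1L) return(x)
  n <- dim(x)
  stopIfNot(all(n %% f == 0L), "array shape not divisible by block factor")
  g1 <- rep(seq_len(n[1] %/% f), each = f)
  g2 <- rep(seq_len(n[2] %/% f), each = f)
  out <- t(rowsum(t(rowsum(x, g1, reorder = FALSE)), g2,
                  reorder = FALSE)) / f^2
  dimnames(out) <- NULL
  out
}

#' Render a stenosed-vessel cross-section phantom
#'
#' Renders concentric disks (stenosed lumen, plaque annulus between the
#' stenosed and reference lumen boundaries, vessel wall annulus, uniform
#' background) on the hyper-resolution grid. Material boundaries are
#' anti-aliased by area-weighted sub-sampling (rendering at
#' \code{subsample}-fold finer resolution and block-averaging), which
#' suppresses discretization artifacts of the continuous-to-discrete
#' model.
#'
#' @param spec a \linkS4class{VesselSpec}.
#' @param grid a \linkS4class{GridSpec}; the field of view must contain
#'   the outer wall.
#' @param subsample anti-aliasing sub-sampling factor per hyper pixel.
#' @return a \linkS4class{PhantomImage} at hyper resolution.
#' @examples
#' ph <- renderCrossSection(vesselSpec(3, 0.5), gridSpec(0.45, 8))
#' @export
renderCrossSection <- function(spec, grid, subsample = 4L) {
  new("PhantomImage",
      values = renderValues(spec, grid, as.integer(subsample)),
      pixelSize = grid@fov / gridHyperN(grid))
}

## Squared-radius map of the sub-sampled rendering grid (cacheable
## across templates sharing a grid).
renderRadius2 <- function(grid, subsample) {
  nF <- gridHyperN(grid) * subsample
  x <- (seq_len(nF) - 0.5) * grid@fov / nF - grid@fov / 2
  outer(x^2, x^2, "+")
}

renderValues <- function(spec, grid, subsample, r2 = NULL) {
  rLum <- (1 - spec@stenosisFraction) * spec@referenceDiameter / 2
  rRef <- spec@referenceDiameter / 2
  rWall <- rRef + spec@wallThickness
  if (2 * rWall > grid@fov)
    stop(sprintf("vessel outer diameter %.2f mm exceeds field of view %.2f mm",
                 2 * rWall, grid@fov), call. = FALSE)
  if (is.null(r2)) r2 <- renderRadius2(grid, subsample)
  vals <- matrix(spec@backgroundHu, nrow(r2), ncol(r2))
  vals[r2 < rWall^2] <- spec@wallHu
  vals[r2 < rRef^2] <- spec@plaqueHu
  if (spec@eccentricity == 0) {
    vals[r2 < rLum^2] <- spec@lumenHu
  } else {
    ## crescent plaque: residual lumen offset toward the reference
    ## boundary by eccentricity * (rRef - rLum)
    nF <- nrow(r2)
    x <- (seq_len(nF) - 0.5) * grid@fov / nF - grid@fov / 2
    cx <- spec@eccentricity * (rRef - rLum)
    vals[outer((x - cx)^2, x^2, "+") < rLum^2] <- spec@lumenHu
  }
  blockAverage(vals, subsample)
}

.readLookup <- function(table, file) {
  if (is.null(table))
    table <- read.csv(system.file("extdata", file, package = "ctaEprime"),
                      stringsAsFactors = FALSE)
  table
}

#' Default segment reference-diameter lookup table
#'
#' Reference lumen diameters (mm) by sex and AHA-style coronary segment,
#' assuming a right-dominant arterial system. The shipped values are
#' editable, plausible defaults spanning 1.5 to 5.0 mm.
#'
#' @return data.frame with columns \code{sex}, \code{segment_id},
#'   \code{diameter_mm}.
#' @export
defaultSegmentTable <- function() .readLookup(NULL, "segment_diameters.csv")

#' Look up the reference lumen diameter for a sex/segment combination
#'
#' @param sex \code{"F"} or \code{"M"}.
#' @param ahaSegment coronary segment identifier.
#' @param table lookup data.frame (columns \code{sex}, \code{segment_id},
#'   \code{diameter_mm}); default the shipped table.
#' @return reference lumen diameter (mm).
#' @export
lumenReferenceDiameter <- function(sex, ahaSegment, table = NULL) {
  table <- .readLookup(table, "segment_diameters.csv")
  hit <- table$sex == sex & table$segment_id == ahaSegment
  if (!any(hit))
    stop(sprintf("unknown segment '%s' for sex '%s'; valid segments: %s",
                 ahaSegment, sex,
                 paste(sort(unique(table$segment_id)), collapse = ", ")),
         call. = FALSE)
  table$diameter_mm[which(hit)[1]]
}

#' Volume-averaging adjustment of the luminal enhancement
#'
#' The rendered lumen attenuation is reduced relative to the aortic
#' enhancement when the stenosed lumen becomes small relative to the
#' reconstructed pixel: the lumen value is the area-weighted mixture of
#' contrast and plaque material within one clinical pixel footprint.
#'
#' @param aortaContrast measured aortic enhancement (HU), >= 0.
#' @param stenosisFraction fractional diameter narrowing.
#' @param diameterMm reference lumen diameter (mm).
#' @param grid a \linkS4class{GridSpec} (supplies the clinical pixel size).
#' @param plaqueHu attenuation of the surrounding plaque (HU).
#' @return adjusted lumen attenuation (HU).
#' @export
adjustedLumenHu <- function(aortaContrast, stenosisFraction, diameterMm,
                            grid, plaqueHu = -40) {
  stopIfNot(aortaContrast >= 0, "aortaContrast must be >= 0")
  dS <- (1 - stenosisFraction) * diameterMm
  frac <- min(1, pi * (dS / 2)^2 / grid@clinicalPixel^2)
  frac * aortaContrast + (1 - frac) * plaqueHu
}

#' Write a phantom to a flat binary file with a JSON sidecar
#'
#' @param phantom a \linkS4class{PhantomImage}.
#' @param path output path for the binary (double, column-major); a
#'   \code{.json} sidecar with shape and pixel size is written alongside.
#' @return invisibly, the binary path.
#' @export
writePhantom <- function(phantom, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(phantom@values), con, size = 8)
  writeJsonAtomic(list(shape = dim(phantom@values), order = "column-major",
                       dtype = "float64",
                       pixel_size_mm = phantom@pixelSize),
                  paste0(path, ".json"))
  invisible(path)
}
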