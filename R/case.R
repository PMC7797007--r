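## Case specifications: everything needed to simulate one patient-scanner
## acquisition condition, plus derived case quantities.

#' Construct a patient-scanner case specification
#'
#' @param id case identifier.
#' @param sex \code{"F"} or \code{"M"}.
#' @param heartRate resting heart rate (bpm).
#' @param ahaSegment involved coronary segment identifier.
#' @param stenosisPct stenosis severity, percent diameter narrowing.
#' @param material plaque material class.
#' @param lumenEnhancement aortic contrast enhancement (HU).
#' @param rotationTime,nSources,nSegments scanner geometry (used when
#'   \code{geometry} is NULL).
#' @param geometry an \linkS4class{AcquisitionGeometry}, overriding the
#'   three scalar geometry arguments.
#' @param pixelSize reconstructed in-plane pixel size (mm).
#' @param sliceThickness,sliceInterval through-plane metadata (mm).
#' @param f50 TTF 50\% frequency (1/mm); the default maps the plaque
#'   material to the curve matched to the case's primary contrast edge
#'   (sharper effective TTF for higher-contrast calcified edges).
#' @param npsPeak NPS peak frequency (1/mm); 0 selects a white spectrum.
#' @param sigma local noise magnitude (HU).
#' @param diameterMm explicit reference diameter (mm); NA looks it up
#'   from sex and segment.
#' @param velocityMmS explicit vessel speed (mm/s); NA derives it from
#'   sex, heart rate and segment.
#' @param qualityLabel \code{"high"}, \code{"low"} or \code{"unknown"}.
#' @return a \linkS4class{CaseSpec}.
#' @examples
#' cs <- caseSpec("demo", "F", 64, "LAD_prox", 50, "calcified", 500)
#' @export
caseSpec <- function(id = "case", sex = "F", heartRate = 65,
                     ahaSegment = "LAD_prox", stenosisPct = 50,
                     material = "noncalcified", lumenEnhancement = 450,
                     rotationTime = 0.33, nSources = 1L, nSegments = 1L,
                     geometry = NULL, pixelSize = 0.45,
                     sliceThickness = 0.625, sliceInterval = 0.5,
                     f50 = NULL, npsPeak = 0.25, sigma = 30,
                     diameterMm = NA_real_, velocityMmS = NA_real_,
                     qualityLabel = "unknown") {
  if (is.null(geometry))
    geometry <- acquisitionGeometry(rotationTime, nSources, nSegments)
  if (is.null(f50))
    f50 <- c(noncalcified = 0.38, mixed = 0.42, calcified = 0.46)[[material]]
  new("CaseSpec", id = id, sex = sex, heartRate = heartRate,
      ahaSegment = ahaSegment, stenosisPct = stenosisPct,
      material = material, lumenEnhancement = lumenEnhancement,
      geometry = geometry, pixelSize = pixelSize,
      sliceThickness = sliceThickness, sliceInterval = sliceInterval,
      f50 = f50, npsPeak = npsPeak, sigma = sigma,
      diameterMm = diameterMm, velocityMmS = velocityMmS,
      qualityLabel = qualityLabel)
}

#' Reference lumen diameter of a case
#' @param case a \linkS4class{CaseSpec}.
#' @param table optional segment-diameter lookup table.
#' @return diameter in mm (explicit value, or sex/segment lookup).
#' @export
caseDiameter <- function(case, table = NULL) {
  if (!is.na(case@diameterMm)) return(case@diameterMm)
  lumenReferenceDiameter(case@sex, case@ahaSegment, table)
}

#' Vessel speed of a case
#' @param case a \linkS4class{CaseSpec}.
#' @param table optional segment-velocity lookup table.
#' @return speed in mm/s (explicit value, or heart-rate model).
#' @export
caseVelocity <- function(case, table = NULL) {
  if (!is.na(case@velocityMmS)) return(case@velocityMmS)
  segmentVelocity(case@heartRate, case@sex, case@ahaSegment, table)
}

## Plaque HU of a case (material default).
casePlaqueHu <- function(case) unname(.plaqueHuTable[case@material])

## Volume-averaged lumen HU at an arbitrary stenosis fraction (defaults
## to the case's own severity).
caseLumenHu <- function(case, grid, stenosisFraction = case@stenosisPct / 100) {
  adjustedLumenHu(case@lumenEnhancement, stenosisFraction,
                  caseDiameter(case), grid, casePlaqueHu(case))
}

#' Local plaque contrast-to-noise ratio of a case
#'
#' Absolute lumen/plaque contrast (after volume-averaging adjustment of
#' the lumen enhancement) divided by the case noise magnitude.
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param grid optional \linkS4class{GridSpec}; defaults to
#'   \code{caseGrid(case)}.
#' @return the CNR (HU/sigma); Inf for a noise-free case.
#' @export
caseCnr <- function(case, grid = NULL) {
  grid <- grid %||% caseGrid(case)
  contrast <- abs(caseLumenHu(case, grid) - casePlaqueHu(case))
  if (case@sigma == 0) return(Inf)
  contrast / case@sigma
}

#' Default sampling grid for a case
#'
#' Field of view = vessel outer diameter plus a symmetric margin, with at
#' least \code{minClinPx} clinical pixels a side.
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param marginMm margin beyond the outer wall on each side (mm).
#' @param minClinPx minimum clinical-grid side length (pixels).
#' @param hyperFactor hyper-resolution factor.
#' @return a \linkS4class{GridSpec}.
#' @export
caseGrid <- function(case, marginMm = 1.5, minClinPx = 16L,
                     hyperFactor = 10L) {
  outer <- caseDiameter(case) + 2 * 0.5
  fov <- max(outer + 2 * marginMm, minClinPx * case@pixelSize)
  gridSpec(case@pixelSize, fov, hyperFactor)
}

## Vessel spec of a case at an arbitrary stenosis fraction, with the
## volume-averaging lumen adjustment applied.
caseVessel <- function(case, grid, stenosisFraction = case@stenosisPct / 100) {
  vesselSpec(caseDiameter(case), stenosisFraction, case@material,
             lumenHu = caseLumenHu(case, grid, stenosisFraction))
}

caseTtf <- function(case) parametricTtf(case@f50)
caseNps <- function(case) parametricNps(case@sigma, case@npsPeak)

#' Serialize / deserialize a case specification as JSON
#'
#' @param case a \linkS4class{CaseSpec}.
#' @param path file path.
#' @return \code{writeCaseJson} the path, invisibly; \code{readCaseJson}
#'   a \linkS4class{CaseSpec}.
#' @export
writeCaseJson <- function(case, path) {
  g <- case@geometry
  writeJsonAtomic(list(
    id = case@id, sex = case@sex, heart_rate_bpm = case@heartRate,
    aha_segment = case@ahaSegment, stenosis_pct = case@stenosisPct,
    material = case@material, lumen_enhancement_hu = case@lumenEnhancement,
    rotation_time_s = g@rotationTime, n_sources = g@nSources,
    n_segments = g@nSegments, recon_span_deg = g@reconSpan * 180 / pi,
    weighting = g@weighting, pixel_size_mm = case@pixelSize,
    slice_thickness_mm = case@sliceThickness,
    slice_interval_mm = case@sliceInterval, ttf_f50_mm1 = case@f50,
    nps_peak_mm1 = case@npsPeak, noise_sigma_hu = case@sigma,
    diameter_mm = case@diameterMm, velocity_mm_s = case@velocityMmS,
    quality_label = case@qualityLabel), path)
  invisible(path)
}

#' @rdname writeCaseJson
#' @export
readCaseJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sex", "heart_rate_bpm", "aha_segment", "stenosis_pct",
            "material", "lumen_enhancement_hu", "noise_sigma_hu")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("case JSON missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  caseSpec(id = x$id %||% "case", sex = x$sex,
           heartRate = x$heart_rate_bpm, ahaSegment = x$aha_segment,
           stenosisPct = x$stenosis_pct, material = x$material,
           lumenEnhancement = x$lumen_enhancement_hu,
           rotationTime = x$rotation_time_s %||% 0.33,
           nSources = x$n_sources %||% 1L,
           nSegments = x$n_segments %||% 1L,
           pixelSize = x$pixel_size_mm %||% 0.45,
           sliceThickness = x$slice_thickness_mm %||% 0.625,
           sliceInterval = x$slice_interval_mm %||% 0.5,
           f50 = x$ttf_f50_mm1, npsPeak = x$nps_peak_mm1 %||% 0.25,
           sigma = x$noise_sigma_hu,
           diameterMm = x$diameter_mm %||% NA_real_,
           velocityMmS = x$velocity_mm_s %||% NA_real_,
           qualityLabel = x$quality_label %||% "unknown")
}
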