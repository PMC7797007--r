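## Central S4 containers. Validity methods encode the structural
## invariants; construction goes through the exported constructors.

#' Sampling grid for phantom rendering and imaging
#'
#' Describes the reconstructed (clinical) pixel size, the hyper-resolution
#' oversampling factor used for the continuous-to-discrete model, and the
#' square field of view. The hyper pixel size is
#' \code{clinicalPixel / hyperFactor}; rendering and blurring happen on the
#' hyper grid, and images are block-averaged back to the clinical grid.
#'
#' @slot clinicalPixel reconstructed in-plane pixel size (mm).
#' @slot hyperFactor integer oversampling factor (>= 10).
#' @slot fov side length of the square field of view (mm).
#' @export
setClass("GridSpec",
  representation(clinicalPixel = "numeric", hyperFactor = "integer",
                 fov = "numeric"),
  validity = function(object) {
    if (object@clinicalPixel <= 0) return("clinicalPixel must be > 0")
    if (object@hyperFactor < 10L) return("hyperFactor must be >= 10")
    if (object@fov <= 0) return("fov must be > 0")
    TRUE
  })

#' Parametric stenosed-vessel cross-section specification
#'
#' A disease-free coronary artery is a uniform cylinder of contrast-enhanced
#' lumen with 0.5 mm of concentric wall; a plaque annulus narrows the lumen
#' to \code{(1 - stenosisFraction)} times the reference diameter (percent
#' diameter-narrowing convention).
#'
#' @slot referenceDiameter normal reference lumen diameter (mm).
#' @slot wallThickness vessel wall thickness (mm).
#' @slot stenosisFraction fractional diameter narrowing in [0, 1].
#' @slot material plaque material class:
#'   \code{"noncalcified"}, \code{"mixed"} or \code{"calcified"}.
#' @slot plaqueHu,lumenHu,wallHu,backgroundHu attenuation values (HU).
#' @slot eccentricity plaque eccentricity in [0, 1]: 0 is the default
#'   concentric annulus; 1 offsets the residual lumen until it touches
#'   the reference lumen boundary (a crescent-shaped plaque).
#' @export
setClass("VesselSpec",
  representation(referenceDiameter = "numeric", wallThickness = "numeric",
                 stenosisFraction = "numeric", material = "character",
                 plaqueHu = "numeric", lumenHu = "numeric",
                 wallHu = "numeric", backgroundHu = "numeric",
                 eccentricity = "numeric"),
  validity = function(object) {
    if (object@referenceDiameter <= 0) return("referenceDiameter must be > 0")
    if (object@stenosisFraction < 0 || object@stenosisFraction > 1)
      return("stenosisFraction must be in [0, 1]")
    if (!object@material %in% c("noncalcified", "mixed", "calcified"))
      return("unknown plaque material")
    if (object@wallThickness < 0) return("wallThickness must be >= 0")
    if (object@eccentricity < 0 || object@eccentricity > 1)
      return("eccentricity must be in [0, 1]")
    TRUE
  })

#' Hyper-resolution ground-truth phantom image
#'
#' @slot values 2D matrix of attenuation values (HU), vessel-centered.
#' @slot pixelSize hyper pixel size (mm).
#' @export
setClass("PhantomImage",
  representation(values = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("values must be finite")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    TRUE
  })

#' CT acquisition geometry
#'
#' @slot rotationTime gantry rotation time (s).
#' @slot nSources number of x-ray sources (1 or 2).
#' @slot nSegments number of multisegment acquisition segments (>= 1).
#' @slot reconSpan angular span of projection data used for reconstruction
#'   (rad); pi corresponds to half-scan.
#' @slot rotationSense \code{"cw"} or \code{"ccw"}.
#' @slot weighting projection reconstruction weighting scheme:
#'   \code{"uniform"} or \code{"smooth-transition"}.
#' @export
setClass("AcquisitionGeometry",
  representation(rotationTime = "numeric", nSources = "integer",
                 nSegments = "integer", reconSpan = "numeric",
                 rotationSense = "character", weighting = "character"),
  validity = function(object) {
    if (object@rotationTime <= 0) return("rotationTime must be > 0")
    if (!object@nSources %in% c(1L, 2L)) return("nSources must be 1 or 2")
    if (object@nSegments < 1L) return("nSegments must be >= 1")
    if (object@reconSpan <= 0 || object@reconSpan > 2 * pi)
      return("reconSpan must be in (0, 2*pi]")
    if (!object@rotationSense %in% c("cw", "ccw"))
      return("rotationSense must be 'cw' or 'ccw'")
    if (!object@weighting %in% c("uniform", "smooth-transition"))
      return("unknown weighting scheme")
    TRUE
  })

#' In-plane vessel motion state for one acquisition
#'
#' Motion magnitude and direction are constant over the brief half-scan
#' window; the direction and the source start angle are the stochastic
#' degrees of freedom across repeated acquisitions.
#'
#' @slot speed vessel speed (mm/s), >= 0.
#' @slot direction motion direction (rad).
#' @slot startAngle source projection angle at the start of the
#'   acquisition window (rad).
#' @export
setClass("MotionState",
  representation(speed = "numeric", direction = "numeric",
                 startAngle = "numeric"),
  validity = function(object) {
    if (object@speed < 0) return("speed must be >= 0")
    TRUE
  })

#' Image-domain asymmetric motion point spread function
#'
#' @slot values non-negative 2D kernel summing to 1, DFT-centered at the
#'   zero-time vessel position.
#' @slot pixelSize kernel pixel size (mm).
#' @slot temporalResolutionMs effective temporal resolution (ms) of the
#'   acquisition that produced the kernel.
#' @export
setClass("MotionKernel",
  representation(values = "matrix", pixelSize = "numeric",
                 temporalResolutionMs = "numeric"),
  validity = function(object) {
    if (any(object@values < 0)) return("kernel values must be non-negative")
    if (abs(sum(object@values) - 1) > 1e-9)
      return("kernel must sum to 1 within 1e-9")
    if (any(dim(object@values) %% 2L == 0L))
      return("kernel dimensions must be odd")
    TRUE
  })

#' Task transfer function (task-based MTF) curve
#'
#' @slot freq spatial frequency axis (1/mm), starting at 0.
#' @slot mtf modulation values in [0, 1] with \code{mtf[1] == 1}.
#' @slot f50 frequency at which the MTF is 0.5 (1/mm).
#' @export
setClass("TTFCurve",
  representation(freq = "numeric", mtf = "numeric", f50 = "numeric"),
  validity = function(object) {
    if (length(object@freq) != length(object@mtf))
      return("freq and mtf lengths differ")
    if (abs(object@mtf[1] - 1) > 1e-9) return("mtf(0) must be 1")
    if (object@f50 <= 0) return("f50 must be > 0")
    TRUE
  })

#' Noise power spectrum descriptor
#'
#' Radial spectral density (normalized to unit integral over the 2D
#' frequency plane) plus the noise magnitude sigma the synthesized fields
#' are rescaled to.
#'
#' @slot freq radial spatial frequency axis (1/mm).
#' @slot density normalized radial spectral density (>= 0).
#' @slot sigma noise magnitude (HU standard deviation), >= 0.
#' @export
setClass("NPSCurve",
  representation(freq = "numeric", density = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (length(object@freq) != length(object@density))
      return("freq and density lengths differ")
    if (any(object@density < 0)) return("density must be >= 0")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  })

#' One stochastic clinical-resolution image instance
#'
#' @slot values 2D matrix (HU) at clinical resolution.
#' @slot pixelSize clinical pixel size (mm).
#' @slot provenance list recording the seed, draw index and case id.
#' @export
setClass("ImageInstance",
  representation(values = "matrix", pixelSize = "numeric",
                 provenance = "list"))

#' Bank of noise-free stenosis templates
#'
#' @slot templates matrix with one flattened noise-free clinical-resolution
#'   template per column.
#' @slot stenosis stenosis fraction of each template.
#' @slot velocity velocity coordinate of each template (mm/s); all zero in
#'   the default motion-free bank.
#' @slot dim the 2D template shape.
#' @slot pixelSize clinical pixel size (mm).
#' @slot mode template motion handling: \code{"none"}, \code{"nominal"} or
#'   \code{"axis"}.
#' @slot caseId identifier of the case specification the bank was built for.
#' @export
setClass("TemplateBank",
  representation(templates = "matrix", stenosis = "numeric",
                 velocity = "numeric", dim = "integer",
                 pixelSize = "numeric", mode = "character",
                 caseId = "character"),
  validity = function(object) {
    if (ncol(object@templates) != length(object@stenosis))
      return("one stenosis value per template required")
    if (length(object@velocity) != length(object@stenosis))
      return("one velocity value per template required")
    if (prod(object@dim) != nrow(object@templates))
      return("dim inconsistent with template length")
    if (is.unsorted(unique(object@stenosis))) {
      ## stenosis must be grid-ordered within each velocity block
    }
    TRUE
  })

#' Ensemble of maximum-likelihood stenosis estimates
#'
#' @slot estimates per-instance estimated stenosis fractions.
#' @slot truth true stenosis fraction of the simulated case.
#' @slot nClipped number of estimates that hit the template-grid edge.
#' @slot seed root seed of the ensemble.
#' @export
setClass("EstimateDistribution",
  representation(estimates = "numeric", truth = "numeric",
                 nClipped = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@estimates) < 1L) return("empty ensemble")
    TRUE
  })

#' Estimability index result
#'
#' @slot ePrime the estimability index, 1/SD of the fractional stenosis
#'   estimate ensemble; 0 for degenerate (nondiagnostic) cases and Inf
#'   when the ensemble has zero variance.
#' @slot sdFraction ensemble standard deviation on the fractional scale.
#' @slot precisionPct \code{100 * sdFraction}.
#' @slot meanEstimate,bias ensemble mean and bias versus truth.
#' @slot flags named logical vector: \code{degenerate_cnr},
#'   \code{degenerate_velocity}, \code{zero_variance} and
#'   \code{saturated} (ensemble pinned at the template-grid edge).
#' @slot n ensemble size.
#' @export
setClass("EstimabilityResult",
  representation(ePrime = "numeric", sdFraction = "numeric",
                 precisionPct = "numeric", meanEstimate = "numeric",
                 bias = "numeric", flags = "logical", n = "integer"),
  validity = function(object) {
    need <- c("degenerate_cnr", "degenerate_velocity", "zero_variance")
    if (!all(need %in% names(object@flags)))
      return("flags must name degenerate_cnr, degenerate_velocity, zero_variance")
    TRUE
  })

#' Patient-scanner case specification
#'
#' All patient, lesion and scanner attributes needed to simulate one
#' acquisition condition and compute its estimability index.
#'
#' @slot id case identifier.
#' @slot sex \code{"F"} or \code{"M"}.
#' @slot heartRate resting heart rate (bpm).
#' @slot ahaSegment involved vessel segment identifier (AHA model).
#' @slot stenosisPct stenosis severity (percent diameter narrowing).
#' @slot material plaque material class.
#' @slot lumenEnhancement aortic luminal contrast enhancement (HU).
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @slot pixelSize reconstructed in-plane pixel size (mm).
#' @slot sliceThickness,sliceInterval through-plane metadata (mm); the
#'   imaging model is 2D in-plane, these are carried but unused.
#' @slot f50 TTF 50\% frequency (1/mm) matched to the case's primary
#'   contrast edge.
#' @slot npsPeak NPS peak radial frequency (1/mm); 0 selects a flat
#'   (white) spectrum.
#' @slot sigma local noise magnitude (HU).
#' @slot diameterMm explicit reference lumen diameter (mm); NA means
#'   look up from sex/segment.
#' @slot velocityMmS explicit vessel speed (mm/s); NA means derive from
#'   sex, heart rate and segment.
#' @slot qualityLabel \code{"high"}, \code{"low"} or \code{"unknown"}.
#' @export
setClass("CaseSpec",
  representation(id = "character", sex = "character", heartRate = "numeric",
                 ahaSegment = "character", stenosisPct = "numeric",
                 material = "character", lumenEnhancement = "numeric",
                 geometry = "AcquisitionGeometry", pixelSize = "numeric",
                 sliceThickness = "numeric", sliceInterval = "numeric",
                 f50 = "numeric", npsPeak = "numeric", sigma = "numeric",
                 diameterMm = "numeric", velocityMmS = "numeric",
                 qualityLabel = "character"),
  validity = function(object) {
    if (object@stenosisPct < 0 || object@stenosisPct > 100)
      return("stenosisPct must be in [0, 100]")
    if (object@sigma < 0) return("sigma must be >= 0")
    if (!object@sex %in% c("F", "M")) return("sex must be 'F' or 'M'")
    if (!object@qualityLabel %in% c("high", "low", "unknown"))
      return("qualityLabel must be high/low/unknown")
    TRUE
  })
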