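# Shared fixtures: a well-conditioned dual-source reference protocol
# (diagnostic regime: CNR well above 1, moderate motion) used as the
# base point for trend and estimator tests.

diagCase <- function(sigma = 30, velocity = 20, contrast = 450,
                     diameter = 3.0, nSources = 2L, rotation = 0.28,
                     material = "mixed", stenosisPct = 50, ...) {
  caseSpec(id = "ref", sex = "F", heartRate = 64, ahaSegment = "LAD_prox",
           stenosisPct = stenosisPct, material = material,
           lumenEnhancement = contrast, sigma = sigma,
           velocityMmS = velocity, diameterMm = diameter,
           rotationTime = rotation, nSources = nSources, ...)
}

# Motion-free white-noise case for closed-form comparisons.
whiteNoiseCase <- function(sigma = 25)
  diagCase(sigma = sigma, velocity = 0, contrast = 500, npsPeak = 0)

# Brute-force pairwise-concordance AUC oracle (ties count 1/2).
aucPairOracle <- function(scores, labels) {
  hi <- scores[labels == "high"]
  lo <- scores[labels == "low"]
  tot <- 0
  for (h in hi) for (l in lo)
    tot <- tot + (h > l) + 0.5 * (h == l)
  tot / (length(hi) * length(lo))
}
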