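## Protocol-optimization module: full factorial e' sweeps over
## patient/protocol factors, quadratic response-surface fitting, partial
## dependence and slice predictions.

#' Default sweep factor configuration
#'
#' The protocol-harmonization factor space: vessel diameter, stenosis,
#' vessel velocity, plaque material, lumen contrast, reconstructed pixel
#' size, noise magnitude, rotation time, dual-source acquisition, and
#' spatial resolution (MTF f50), each at three levels (two for the
#' on/off factor) across its clinically relevant range.
#'
#' @param nLevels levels per continuous factor.
#' @return named list of factor level vectors.
#' @export
defaultFactorConfig <- function(nLevels = 3L) {
  lv <- function(a, b) seq(a, b, length.out = nLevels)
  list(contrast_hu = lv(300, 600),
       diameter_mm = lv(1.5, 5.0),
       dual_source = c(0, 1),
       f50_mm1 = lv(0.32, 0.52),
       material = c("noncalcified", "mixed", "calcified"),
       pixel_mm = lv(0.35, 0.55),
       rotation_s = lv(0.25, 0.35),
       sigma_hu = lv(15, 45),
       stenosis_pct = lv(30, 70),
       velocity_mm_s = lv(15, 35))
}

#' Build a full factorial design
#'
#' @param factorConfig named list; each element the level vector of one
#'   factor (numeric or character).
#' @return list of class \code{factorGrid} with the factor definitions
#'   and the \code{design} data.frame (Cartesian product, rows ordered
#'   lexicographically by factor name then level).
#' @examples
#' factorialGrid(list(a = 1:2, b = c("x", "y", "z")))
#' @export
factorialGrid <- function(factorConfig) {
  stopIfNot(length(factorConfig) >= 1L &&
              all(lengths(factorConfig) >= 1L),
            "every factor needs at least one level")
  nm <- sort(names(factorConfig))
  ## expand.grid varies the first factor fastest; reverse so the first
  ## name is the most significant (lexicographic) axis
  design <- expand.grid(rev(factorConfig[nm]), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, nm, drop = FALSE]
  rownames(design) <- NULL
  structure(list(factors = factorConfig[nm], design = design),
            class = "factorGrid")
}

#' @export
print.factorGrid <- function(x, ...) {
  cat(sprintf("factorGrid: %d factors, %d design rows\n",
              length(x$factors), nrow(x$design)))
  invisible(x)
}

## Map one design row to a CaseSpec; unknown factor names error.
.sweepCase <- function(row, engine) {
  known <- c("contrast_hu", "diameter_mm", "dual_source", "f50_mm1",
             "material", "pixel_mm", "rotation_s", "sigma_hu",
             "stenosis_pct", "velocity_mm_s")
  bad <- setdiff(names(row), known)
  if (length(bad))
    stop("unknown sweep factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  g <- function(nm, def) if (nm %in% names(row)) row[[nm]] else def
  caseSpec(id = "sweep", sex = engine$sex %||% "F",
           heartRate = engine$heartRate %||% 65,
           ahaSegment = engine$ahaSegment %||% "LAD_prox",
           stenosisPct = g("stenosis_pct", 50),
           material = as.character(g("material", "mixed")),
           lumenEnhancement = g("contrast_hu", 450),
           rotationTime = g("rotation_s", 0.30),
           nSources = if (g("dual_source", 0) > 0) 2L else 1L,
           pixelSize = g("pixel_mm", 0.45),
           f50 = g("f50_mm1", NULL), npsPeak = engine$npsPeak %||% 0.25,
           sigma = g("sigma_hu", 30),
           diameterMm = g("diameter_mm", NA_real_),
           velocityMmS = g("velocity_mm_s", NA_real_))
}

#' Run an e' sweep over a factorial design
#'
#' Computes e' (and precision = 1/e') for every design row with a
#' per-row derived seed. Degenerate rows are flagged, not dropped.
#'
#' @param grid a \code{factorGrid}.
#' @param engineConfig list of engine defaults for factors not in the
#'   design (sex, heartRate, ahaSegment, npsPeak).
#' @param nInstances ensemble size per row (sweep default 500).
#' @param seed root seed.
#' @param checkpoint optional CSV path; completed rows are appended as
#'   the sweep runs.
#' @param verbose print one line per row.
#' @return data.frame: the design plus \code{e_prime}, \code{precision},
#'   \code{degenerate} and \code{seed}.
#' @export
runSweep <- function(grid, engineConfig = list(), nInstances = 500L,
                     seed = 1L, checkpoint = NULL, verbose = FALSE) {
  design <- grid$design
  out <- design
  out$e_prime <- NA_real_
  out$precision <- NA_real_
  out$degenerate <- FALSE
  out$seed <- vapply(seq_len(nrow(design)), function(i) deriveSeed(seed, i),
                     integer(1))
  for (i in seq_len(nrow(design))) {
    cs <- .sweepCase(design[i, , drop = FALSE], engineConfig)
    res <- suppressWarnings(
      computeEprime(cs, nInstances = nInstances, seed = out$seed[i]))
    fl <- degeneracyFlags(res)
    out$e_prime[i] <- ePrime(res)
    out$precision[i] <- if (ePrime(res) > 0) 1 / ePrime(res) else NA_real_
    out$degenerate[i] <- fl[["degenerate_cnr"]] ||
      fl[["degenerate_velocity"]] || fl[["saturated"]]
    if (verbose)
      message(sprintf("row %d/%d: e' = %.2f", i, nrow(design),
                      out$e_prime[i]))
    if (!is.null(checkpoint))
      write.csv(out[seq_len(i), ], checkpoint, row.names = FALSE)
  }
  out
}

## Quadratic response-surface formula: linear + squared terms for
## continuous factors, main effects for categoricals, all pairwise
## interactions.
.rsFormula <- function(factorNames, data, response) {
  cont <- factorNames[vapply(data[factorNames], is.numeric, logical(1))]
  terms <- c(factorNames,
             if (length(cont)) paste0("I(", cont, "^2)"),
             if (length(factorNames) > 1L)
               combn(factorNames, 2L, paste, collapse = ":"))
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit a quadratic response-surface model to a sweep table
#'
#' Least-squares fit of the response (stenosis precision, fractional SD,
#' by default) on intercept, linear, squared (continuous) and pairwise
#' interaction terms, optionally pruned by a coefficient significance
#' rule and refit.
#'
#' @param table a sweep response table (see \code{\link{runSweep}});
#'   rows with missing response are dropped.
#' @param response response column name.
#' @param factorNames model predictors; default every design column.
#' @param prunePvalue drop terms whose coefficients all have p at or
#'   above this value, then refit; NULL disables pruning. Pruning is
#'   also skipped for (near-)exact fits, where p-values are undefined.
#' @return list of class \code{fittedResponseModel}: \code{fit} (the
#'   \code{lm}), \code{terms}, \code{coefficients}, \code{rmse},
#'   \code{r_squared}, \code{ranges}.
#' @export
fitResponseModel <- function(table, response = "precision",
                             factorNames = NULL, prunePvalue = 0.01) {
  if (is.null(factorNames))
    factorNames <- setdiff(names(table),
                           c("e_prime", "precision", "degenerate", "seed",
                             response))
  dat <- table[!is.na(table[[response]]), , drop = FALSE]
  for (nm in factorNames)
    if (!is.numeric(dat[[nm]])) dat[[nm]] <- factor(dat[[nm]])
  fml <- .rsFormula(factorNames, dat, response)
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient response-surface fit; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  exact <- sqrt(mean(residuals(fit)^2)) <=
    1e-8 * max(abs(dat[[response]]), 1e-12)
  if (!is.null(prunePvalue) && !exact && fit$df.residual > 0) {
    pv <- suppressWarnings(summary(fit))$coefficients[, 4]
    labs <- attr(stats::terms(fit), "term.labels")
    asg <- attr(stats::model.matrix(fit), "assign")
    keep <- labs[vapply(seq_along(labs), function(t)
      any(pv[asg == t] < prunePvalue, na.rm = TRUE), logical(1))]
    if (length(keep) == 0L) keep <- "1"
    fit <- lm(stats::reformulate(keep, response = response), data = dat)
  }
  structure(list(fit = fit, terms = names(coef(fit)),
                 coefficients = coef(fit),
                 rmse = sqrt(mean(residuals(fit)^2)),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 ranges = lapply(dat[factorNames], function(x)
                   if (is.numeric(x)) range(x) else levels(x))),
            class = "fittedResponseModel")
}

#' @export
print.fittedResponseModel <- function(x, ...) {
  cat(sprintf("Response-surface model: %d terms, RMSE %.4g, R^2 %.3f\n",
              length(x$coefficients), x$rmse, x$r_squared))
  invisible(x)
}

#' Partial dependence of the sweep response on one factor
#'
#' Mean response per factor level, averaged over all other factors'
#' design points (the full factorial design is balanced, so the simple
#' group mean is the marginal model response).
#'
#' @param table sweep response table.
#' @param factor factor column name.
#' @param response response column name.
#' @return data.frame with the factor level and the mean response.
#' @export
partialDependence <- function(table, factor, response = "precision") {
  stopIfNot(factor %in% names(table),
            sprintf("factor '%s' not in table", factor))
  out <- aggregate(table[[response]], list(table[[factor]]),
                   mean, na.rm = TRUE)
  names(out) <- c(factor, response)
  out
}

#' Predicted precision along one factor with 95\% confidence bounds
#'
#' Slice through the fitted response surface: all factors held at
#' \code{at}, the named factor varied over its design range.
#'
#' @param model a \code{fittedResponseModel}.
#' @param at named list of factor values held constant.
#' @param varyFactor factor to vary.
#' @param n number of evaluation points (continuous factors).
#' @return data.frame with the factor value, \code{fit}, \code{lwr},
#'   \code{upr}.
#' @export
predictSlice <- function(model, at, varyFactor, n = 41L) {
  rng <- model$ranges[[varyFactor]]
  stopIfNot(!is.null(rng), sprintf("unknown factor '%s'", varyFactor))
  xs <- if (is.numeric(rng)) seq(rng[1], rng[2], length.out = n) else rng
  miss <- setdiff(names(model$ranges), c(varyFactor, names(at)))
  stopIfNot(length(miss) == 0L,
            paste("at-values missing factor(s):",
                  paste(miss, collapse = ", ")))
  for (nm in names(at)) {
    r <- model$ranges[[nm]]
    if (is.numeric(r) && (at[[nm]] < r[1] || at[[nm]] > r[2]))
      warning(sprintf("'%s' = %g extrapolates beyond the design range",
                      nm, at[[nm]]), call. = FALSE)
  }
  nd <- as.data.frame(at[names(at) != varyFactor], stringsAsFactors = FALSE)
  nd <- nd[rep(1L, length(xs)), , drop = FALSE]
  nd[[varyFactor]] <- xs
  for (nm in names(model$ranges))
    if (!is.numeric(model$ranges[[nm]]))
      nd[[nm]] <- factor(nd[[nm]], levels = model$ranges[[nm]])
  pr <- predict(model$fit, newdata = nd, interval = "confidence")
  out <- data.frame(xs, pr)
  names(out) <- c(varyFactor, "fit", "lwr", "upr")
  rownames(out) <- NULL
  out
}
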