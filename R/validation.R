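## Validation module: lesion/series selection rules, a synthetic
## two-class cohort generator, and the ROC / bootstrap /
## cross-validation classifier harness.

#' Select the representative lesion from two readers' stenosis readings
#'
#' The lesion with the highest percentage stenosis represents the
#' clinical decision. If the two readers agree on the maximum, ties
#' between lesions at that level are broken by the largest
#' reference-diameter vessel segment (right-dominant ordering); if they
#' disagree on the maximum, their maximum readings are averaged.
#'
#' @param readings data.frame with columns \code{lesion}, \code{segment},
#'   \code{site_pct}, \code{core_pct}.
#' @param sex patient sex, for the diameter lookup used in tie-breaks.
#' @param table optional segment-diameter table.
#' @return list with \code{lesion}, \code{segment} and
#'   \code{stenosis_pct}.
#' @export
selectRepresentativeLesion <- function(readings, sex = "F", table = NULL) {
  stopIfNot(nrow(readings) >= 1L, "no lesion readings supplied")
  siteMax <- max(readings$site_pct)
  coreMax <- max(readings$core_pct)
  if (siteMax == coreMax) {
    cand <- readings[readings$site_pct == siteMax |
                       readings$core_pct == coreMax, , drop = FALSE]
    if (nrow(cand) > 1L) {
      d <- vapply(cand$segment, function(sg)
        lumenReferenceDiameter(sex, sg, table), numeric(1))
      cand <- cand[order(-d), , drop = FALSE]
    }
    list(lesion = cand$lesion[1], segment = cand$segment[1],
         stenosis_pct = siteMax)
  } else {
    i <- which.max(pmax(readings$site_pct, readings$core_pct))
    list(lesion = readings$lesion[i], segment = readings$segment[i],
         stenosis_pct = mean(c(siteMax, coreMax)))
  }
}

#' Select the best image series by estimability
#'
#' For a patient with multiple reconstructed series, the series with the
#' highest e' represents the interpreted clinical read. Ties pick the
#' first series and emit a warning.
#'
#' @param ePrimes numeric vector of per-series e' values.
#' @return index of the selected series.
#' @export
selectBestSeries <- function(ePrimes) {
  stopIfNot(length(ePrimes) >= 1L, "no series supplied")
  i <- which.max(ePrimes)
  if (sum(ePrimes == ePrimes[i]) > 1L)
    warning("e' tie between series; selecting the first", call. = FALSE)
  i
}

#' Class-conditional cohort profile
#'
#' Default per-class distributions emulating the clinical two-cohort
#' benchmark: heart rate, aortic contrast, noise magnitude and stenosis
#' severity as truncated normals, plaque material and sex as categorical
#' frequencies (lesions without a reported plaque are treated as
#' noncalcified), and scanner geometry drawn from the shipped scanner
#' catalogue.
#'
#' @return nested list with \code{high} and \code{low} class profiles.
#' @export
defaultCohortProfile <- function() {
  list(
    high = list(hr = c(64, 9), contrast = c(578, 154), sigma = c(32, 11),
                stenosis = c(33.6, 16),
                material = c(noncalcified = 72, mixed = 15, calcified = 1),
                sexF = 52 / 85),
    low = list(hr = c(69, 11), contrast = c(230, 192), sigma = c(41, 16),
               stenosis = c(38.3, 10.5),
               material = c(noncalcified = 9, mixed = 13, calcified = 22),
               sexF = 22 / 39))
}

#' Generate a synthetic two-class cohort
#'
#' Draws per-case patient and scanner attributes from the
#' class-conditional profile; quality labels are assigned by construction
#' (the generating class). Reproducible for a fixed seed.
#'
#' @param nHigh,nLow class sizes (default 88 and 44, a 2:1 ratio).
#' @param seed root seed.
#' @param profile class profile, see \code{\link{defaultCohortProfile}}.
#' @param pixelRange uniform range for the reconstructed pixel size (mm).
#' @return data.frame (one row per case) mirroring
#'   \linkS4class{CaseSpec} fields plus \code{label}.
#' @export
generateSyntheticCohort <- function(nHigh = 88L, nLow = 44L, seed = 1L,
                                    profile = defaultCohortProfile(),
                                    pixelRange = c(0.40, 0.50)) {
  stopIfNot(nHigh >= 1L && nLow >= 1L, "both classes need at least 1 case")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cat <- read.csv(system.file("extdata", "scanner_catalogue.csv",
                              package = "ctaEprime"))
  segs <- unique(defaultSegmentTable()$segment_id)
  drawClass <- function(n, p, label) {
    sc <- cat[sample(nrow(cat), n, replace = TRUE, prob = cat$weight), ]
    data.frame(
      case_id = paste0(label, "_", seq_len(n)),
      sex = ifelse(runif(n) < p$sexF, "F", "M"),
      heart_rate_bpm = rtruncnorm(n, p$hr[1], p$hr[2], lower = 30),
      aha_segment = sample(segs, n, replace = TRUE),
      stenosis_pct = rtruncnorm(n, p$stenosis[1], p$stenosis[2],
                                lower = 15, upper = 85),
      material = sample(names(p$material), n, replace = TRUE,
                        prob = p$material),
      lumen_enhancement_hu = rtruncnorm(n, p$contrast[1], p$contrast[2],
                                        lower = 0),
      noise_sigma_hu = rtruncnorm(n, p$sigma[1], p$sigma[2], lower = 1),
      rotation_time_s = sc$rotation_time_s,
      n_sources = sc$n_sources,
      n_segments = ifelse(sc$multisegment == 1, 2L, 1L),
      pixel_size_mm = round(runif(n, pixelRange[1], pixelRange[2]), 3),
      label = label,
      row.names = NULL)
  }
  rbind(drawClass(as.integer(nHigh), profile$high, "high"),
        drawClass(as.integer(nLow), profile$low, "low"))
}

## Build a CaseSpec from one cohort table row.
rowToCase <- function(row) {
  caseSpec(id = row$case_id, sex = row$sex,
           heartRate = row$heart_rate_bpm, ahaSegment = row$aha_segment,
           stenosisPct = row$stenosis_pct, material = row$material,
           lumenEnhancement = row$lumen_enhancement_hu,
           rotationTime = row$rotation_time_s,
           nSources = as.integer(row$n_sources),
           nSegments = as.integer(row$n_segments),
           pixelSize = row$pixel_size_mm, sigma = row$noise_sigma_hu,
           qualityLabel = row$label)
}

#' Compute e' for every case of a cohort table
#'
#' @param table cohort data.frame as produced by
#'   \code{\link{generateSyntheticCohort}}.
#' @param nInstances ensemble size per case.
#' @param seed root seed; each case uses a derived sub-seed.
#' @param verbose print one line per case.
#' @return the table with \code{e_prime}, \code{precision_pct} and
#'   \code{degenerate} columns appended.
#' @export
cohortEprime <- function(table, nInstances = 300L, seed = 1L,
                         verbose = FALSE) {
  out <- table
  out$e_prime <- NA_real_
  out$precision_pct <- NA_real_
  out$degenerate <- FALSE
  for (i in seq_len(nrow(table))) {
    cs <- rowToCase(table[i, ])
    res <- suppressWarnings(
      computeEprime(cs, nInstances = nInstances,
                    seed = deriveSeed(seed, i)))
    fl <- degeneracyFlags(res)
    out$e_prime[i] <- if (is.infinite(ePrime(res))) 1e6 else ePrime(res)
    out$precision_pct[i] <- precisionPct(res)
    out$degenerate[i] <- fl[["degenerate_cnr"]] ||
      fl[["degenerate_velocity"]] || fl[["saturated"]]
    if (verbose)
      message(sprintf("%s: e' = %.2f%s", table$case_id[i], out$e_prime[i],
                      if (out$degenerate[i]) " (degenerate)" else ""))
  }
  out
}

#' ROC analysis of e' as a quality classifier
#'
#' AUC is the pairwise concordance statistic (ties count 1/2); the
#' optimal threshold minimizes the Euclidean distance of the ROC point to
#' the ideal classifier (0, 1), breaking ties toward the
#' higher-sensitivity point. Curve thresholds are the midpoints between
#' consecutive observed scores (the standard operating-point
#' convention). Cases with score at or above the threshold classify as
#' high quality.
#'
#' @param scores numeric scores (e' values).
#' @param labels class labels; \code{"high"}/\code{"low"}, or a factor /
#'   logical where TRUE marks the high-quality class.
#' @return list of class \code{rocResult}: \code{auc},
#'   \code{optimal_threshold}, \code{accuracy}, \code{confusion},
#'   \code{curve} (data.frame fpr/tpr/threshold).
#' @export
rocAnalysis <- function(scores, labels) {
  pos <- .asHighLogical(labels)
  stopIfNot(any(pos) && any(!pos), "both classes must be present")
  nP <- sum(pos); nN <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  ## candidate thresholds at midpoints between consecutive observed
  ## scores (the standard operating-point convention), plus the extremes
  su <- sort(unique(scores))
  thr <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  d2 <- fpr^2 + (1 - tpr)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1L) best <- best[which.max(tpr[best])]
  pred <- scores >= thr[best]
  conf <- c(tp = sum(pred & pos), fp = sum(pred & !pos),
            fn = sum(!pred & pos), tn = sum(!pred & !pos))
  structure(list(auc = auc, optimal_threshold = thr[best],
                 accuracy = mean(pred == pos), confusion = conf,
                 curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr)),
            class = "rocResult")
}

.asHighLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    stopIfNot(all(labels %in% c("high", "low")),
              "character labels must be 'high' or 'low'")
    return(labels == "high")
  }
  labels > 0
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f, optimal threshold %.2f, accuracy %.3f\n",
              x$auc, x$optimal_threshold, x$accuracy))
  invisible(x)
}

#' Bootstrap the ROC summaries with within-class case replacement
#'
#' Resamples each class with replacement to its original size (keeping
#' the dataset size and class ratio) and recomputes the ROC per
#' replicate.
#'
#' @param scores,labels as in \code{\link{rocAnalysis}}.
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed seed.
#' @return data.frame with mean and sd of \code{auc}, \code{accuracy}
#'   and \code{threshold} over replicates.
#' @export
bootstrapRoc <- function(scores, labels, nBoot = 1000L, seed = 1L) {
  stopIfNot(nBoot >= 100L, "nBoot must be >= 100")
  pos <- .asHighLogical(labels)
  iP <- which(pos); iN <- which(!pos)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(iP, length(iP), replace = TRUE),
             sample(iN, length(iN), replace = TRUE))
    rc <- rocAnalysis(scores[idx], pos[idx])
    c(rc$auc, rc$accuracy, rc$optimal_threshold)
  }, numeric(3))
  data.frame(metric = c("auc", "accuracy", "threshold"),
             mean = rowMeans(reps), sd = apply(reps, 1, sd))
}

#' Stratified k-fold cross-validation of the e' threshold classifier
#'
#' Folds are stratified by class; the threshold is fit on the training
#' folds and evaluated on the held-out fold.
#'
#' @param scores,labels as in \code{\link{rocAnalysis}}.
#' @param k number of folds (default 4).
#' @param seed seed for fold assignment.
#' @return list with per-fold data.frame \code{folds} and summary
#'   data.frame \code{summary} (mean/sd of test auc, accuracy and the
#'   training thresholds).
#' @export
kfoldCv <- function(scores, labels, k = 4L, seed = 1L) {
  pos <- .asHighLogical(labels)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(scores))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(pos == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(seq_len(k), function(f)
    length(unique(pos[fold != f])) < 2L, logical(1))))
    stop("a training fold lost one of the classes; reduce k", call. = FALSE)
  rows <- lapply(seq_len(k), function(f) {
    train <- rocAnalysis(scores[fold != f], pos[fold != f])
    te <- fold == f
    pred <- scores[te] >= train$optimal_threshold
    acc <- mean(pred == pos[te])
    auc <- if (length(unique(pos[te])) == 2L)
      rocAnalysis(scores[te], pos[te])$auc else NA_real_
    data.frame(fold = f, threshold = train$optimal_threshold,
               test_accuracy = acc, test_auc = auc)
  })
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("auc", "accuracy", "threshold"),
    mean = c(mean(folds$test_auc, na.rm = TRUE), mean(folds$test_accuracy),
             mean(folds$threshold)),
    sd = c(sd(folds$test_auc, na.rm = TRUE), sd(folds$test_accuracy),
           sd(folds$threshold)))
  list(folds = folds, summary = summ)
}
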