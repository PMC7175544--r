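# Segmental Z-scores against a healthy reference panel, loss/gain calls at
# |Z| >= 3, the CPA (copy number profile abnormality) tumor-burden score,
# and control-based calibration of a 1%-FDR abnormality cutoff.

#' Segmental Z-score
#'
#' Standardized deviation of a segment's weighted mean ratio from its
#' distribution across the reference panel:
#' \deqn{Z = \frac{\mu_w(R_n..R_m) - \mu(\mu_w(r_{1,n..m}),..,\mu_w(r_{p,n..m}))}
#'               {sd(\mu_w(r_{1,n..m}),..,\mu_w(r_{p,n..m}))}}
#' where \eqn{\mu_w} is the bin mean weighted by the panel-derived weights
#' (shared between case and controls) and the spread across controls is the
#' population (divide by p) standard deviation, matching the weight
#' definition in [panelBinWeights()].
#'
#' @param profile A [CopyNumberProfile].
#' @param panel A [ReferencePanel] on the same grid.
#' @param idx Bin indices (global grid indices) of the segment.
#' @param weights Per-bin weights; defaults to the grid weights.
#' @return The Z-score, or `NA` (with a warning suppressed at this level)
#'   when the control spread is zero: such segments are undeterminable and
#'   are excluded from the CPA score.
#' @export
segmentZscore <- function(profile, panel, idx,
                          weights = binWeights(profile@grid)) {
  contrib <- idx[weights[idx] > 0 & !profile@missing[idx]]
  if (!length(contrib)) stop(undeterminableSegment("no usable bins in segment"))
  w <- weights[contrib]
  caseMean <- sum(w * ratios(profile)[contrib]) / sum(w)
  ctrl <- as.numeric(panel@ratios[, contrib, drop = FALSE] %*% w) / sum(w)
  # two-pass population sd: one-pass moment form cancels catastrophically
  # when the control means sit far from zero
  s <- sqrt(mean((ctrl - mean(ctrl))^2))
  if (!is.finite(s) || s <= 0) return(NA_real_)
  (caseMean - mean(ctrl)) / s
}

#' Loss/neutral/gain call from a Z-score
#'
#' Aberrations are called once a segment has an absolute Z-score of 3 or
#' more: gain if `z >= 3`, loss if `z <= -3`, neutral otherwise.
#'
#' @param z Finite Z-score(s).
#' @return Character vector of calls.
#' @export
callSegment <- function(z) {
  ifelse(is.na(z), NA_character_,
         ifelse(z >= 3, "gain", ifelse(z <= -3, "loss", "neutral")))
}

#' Score a segmentation against a panel
#'
#' Fills `z` and `call` for every segment. Segments whose control spread is
#' zero get `z = NA` and are excluded from the CPA score.
#'
#' @param segset A [SegmentSet].
#' @param profile The matching [CopyNumberProfile].
#' @param panel A [ReferencePanel].
#' @return The scored [SegmentSet].
#' @export
scoreSegments <- function(segset, profile, panel) {
  seg <- segset@segments
  w <- binWeights(profile@grid)
  mask <- binMask(segset@grid)
  for (k in seq_len(nrow(seg))) {
    idx <- seg$startBin[k]:seg$endBin[k]
    idx <- idx[mask[idx]]
    seg$z[k] <- segmentZscore(profile, panel, idx, w)
  }
  seg$call <- callSegment(seg$z)
  new("SegmentSet", sampleId = segset@sampleId, segments = seg,
      grid = segset@grid)
}

#' CPA score
#'
#' Copy number profile abnormality: the segment-length-weighted sum of
#' absolute segmental Z-scores divided by the segment count,
#' \deqn{CPA = \sum_i |Z_i| \, l_i / n,}
#' with segment lengths \eqn{l_i} in units of 100 Mb (the score is expressed
#' per 100 Mb). A flat diploid profile scores near 0; highly aberrant
#' samples reach values of several units. Undeterminable segments (`z = NA`)
#' are dropped from both the sum and `n`.
#'
#' @param segset A scored [SegmentSet] (see [scoreSegments()]).
#' @return The CPA score (nonnegative).
#' @export
cpaScore <- function(segset) {
  seg <- segset@segments
  keep <- !is.na(seg$z)
  if (!any(keep)) stop(undeterminableSegment("no determinable segments"))
  sum(abs(seg$z[keep]) * seg$lengthBp[keep] / 1e8) / sum(keep)
}

#' Calibrate the abnormality cutoff from control CPA scores
#'
#' Fits a normal distribution (mean, sd) to the controls' CPA scores and
#' places the abnormality cutoff at its `1 - fdr` quantile,
#' `cutoff = mu + qnorm(1 - fdr) * sigma`, so that samples crossing the
#' cutoff are abnormal at the configured false-discovery rate. The adequacy
#' of the normal assumption is recorded as a Monte-Carlo Lilliefors p-value.
#' Calibrate separately per modality (plasma vs FFPE) since their noise
#' levels differ.
#'
#' @param controlCpa Numeric CPA scores of controls (>= 20 recommended).
#' @param fdr Target type-I error rate (default 0.01).
#' @param modality Modality tag stored with the calibration (default "LB").
#' @param lillieforsMc Monte-Carlo replicates for the normality check
#'   (default 2000; set 0 to skip).
#' @param seed Seed for the normality check.
#' @return A [CutoffCalibration].
#' @export
calibrateCutoff <- function(controlCpa, fdr = 0.01, modality = "LB",
                            lillieforsMc = 2000, seed = 1L) {
  stopifnot(length(controlCpa) >= 2, all(is.finite(controlCpa)))
  mu <- mean(controlCpa)
  sigma <- sd(controlCpa)
  if (sigma == 0) {
    warning("degenerate control CPA distribution (sigma = 0); cutoff = mu")
    cutoff <- mu
  } else {
    cutoff <- mu + qnorm(1 - fdr) * sigma
  }
  lp <- if (lillieforsMc > 0 && sigma > 0)
    lillieforsNormality(controlCpa, nMc = lillieforsMc, seed = seed)$p
  else NA_real_
  new("CutoffCalibration", mu = mu, sigma = sigma, fdr = fdr,
      cutoff = cutoff, lillieforsP = lp, modality = modality)
}

#' @rdname CutoffCalibration-class
#' @export
setMethod("cutoff", "CutoffCalibration", function(x) x@cutoff)

#' @rdname CutoffCalibration-class
#' @export
setMethod("show", "CutoffCalibration", function(object) {
  cat(sprintf(
    "CutoffCalibration [%s]: mu = %.4g, sigma = %.4g, fdr = %.3g -> cutoff = %.4g (Lilliefors p = %.3g)\n",
    object@modality, object@mu, object@sigma, object@fdr, object@cutoff,
    object@lillieforsP))
})

#' Monte-Carlo Lilliefors normality test
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and the normal CDF
#' with mean and sd estimated from the data; the null distribution accounts
#' for the estimation by re-estimating both parameters in every Monte-Carlo
#' replicate (Lilliefors' correction).
#'
#' @param x Numeric sample (n >= 5, non-constant).
#' @param nMc Monte-Carlo replicates (default 10000).
#' @param seed Seed.
#' @return List with `stat` (the KS distance) and `p`.
#' @export
lillieforsNormality <- function(x, nMc = 10000, seed = 1L) {
  n <- length(x)
  stopifnot(n >= 5)
  if (sd(x) == 0) stop("constant input: normality test undefined")
  dStat <- function(v) {
    z <- sort((v - mean(v)) / sd(v))
    pz <- pnorm(z)
    max(seq_len(n) / n - pz, pz - (seq_len(n) - 1) / n)
  }
  d0 <- dStat(x)
  exceed <- withSeed(seed, {
    sum(replicate(nMc, dStat(rnorm(n)) >= d0))
  })
  list(stat = d0, p = (1 + exceed) / (nMc + 1))
}

#' Flag abnormal samples
#'
#' A sample is abnormal when its CPA score is strictly greater than the
#' calibrated cutoff ("crosses the limit"); a CPA equal to the cutoff is
#' not flagged.
#'
#' @param cpa Data frame with at least `sampleId` and `cpa` columns
#'   (and optionally `modality`), e.g. from [cpaReport()].
#' @param calibration A [CutoffCalibration].
#' @return The data frame with `cutoff` and `abnormal` columns added.
#' @export
classifyAbnormal <- function(cpa, calibration) {
  if (!is.null(cpa$modality) &&
      any(cpa$modality != calibration@modality))
    warning("modality mismatch between samples and calibration")
  cpa$cutoff <- calibration@cutoff
  cpa$abnormal <- cpa$cpa > calibration@cutoff
  cpa
}

#' Per-sample CPA table
#'
#' Convenience wrapper assembling the tab-delimited CPA report rows from
#' scored segment sets.
#'
#' @param segsets List of scored [SegmentSet]s.
#' @param modality Modality tag for all rows (default "LB").
#' @return `data.frame` with `sampleId`, `modality`, `nSegments`, `cpa`.
#' @export
cpaReport <- function(segsets, modality = "LB") {
  do.call(rbind, lapply(segsets, function(s) data.frame(
    sampleId = sampleId(s), modality = modality,
    nSegments = nSegments(s), cpa = cpaScore(s))))
}
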