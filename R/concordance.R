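# Paired solid/liquid profile comparison (smoothing, Pearson correlation,
# total-least-squares slope, interval-weighted group summaries) and
# cohort-level aberration-frequency waves with complete-linkage clustering
# on Pearson distances d = (1 - r) / 2.

#' Smooth a profile with a centered sliding window
#'
#' Centered moving average over the usable bins of each chromosome
#' (default window 100 bins), interpolating the window mean to the central
#' position. The window shrinks at chromosome edges and never crosses a
#' chromosome boundary; masked/missing bins stay undefined (NA).
#'
#' @param profile A [CopyNumberProfile].
#' @param window Window size in bins (>= 1; 1 is the identity).
#' @return A [CopyNumberProfile] with smoothed ratios.
#' @export
smoothProfile <- function(profile, window = 100) {
  stopifnot(window >= 1)
  grid <- profile@grid
  use <- informativeBins(profile)
  ch <- binChrom(grid)
  r <- ratios(profile)
  out <- rep(NA_real_, length(r))
  half <- floor(window / 2)
  for (cn in unique(ch)) {
    ix <- which(ch == cn & use)
    m <- length(ix)
    if (!m) next
    v <- r[ix]
    cs <- cumsum(c(0, v))
    lo <- pmax(1, seq_len(m) - half)
    hi <- pmin(m, seq_len(m) + half)
    out[ix] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  copyNumberProfile(profile@sampleId, out, grid, missing = !use)
}

#' Pearson correlation of two (smoothed) profiles
#'
#' @param a,b [CopyNumberProfile]s on the same grid (typically smoothed;
#'   see [smoothProfile()]).
#' @param minBins Minimum number of common informative bins (default 30).
#' @return Pearson r over the common bins.
#' @export
profilePearson <- function(a, b, minBins = 30) {
  common <- informativeBins(a) & informativeBins(b)
  if (sum(common) < minBins) stop("fewer than ", minBins, " common bins")
  x <- ratios(a)[common]; y <- ratios(b)[common]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Total-least-squares slope between two profiles
#'
#' Slope of the first principal axis of the centered scatter (b on the
#' y-axis, a on the x-axis); orthogonal residuals, so neither profile is
#' privileged. A slope > 1 means b's amplitudes exceed a's (e.g. a higher
#' tumor fraction in b).
#'
#' @param a,b [CopyNumberProfile]s on the same grid.
#' @param minBins Minimum common bins (default 30).
#' @return The TLS slope.
#' @export
tlsSlope <- function(a, b, minBins = 30) {
  common <- informativeBins(a) & informativeBins(b)
  if (sum(common) < minBins) stop("fewer than ", minBins, " common bins")
  x <- ratios(a)[common]; y <- ratios(b)[common]
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxx == 0 && syy == 0) stop("degenerate scatter: slope undefined")
  if (sxy == 0) return(if (syy > sxx) Inf else 0)
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' Weighted group mean with 95% CI
#'
#' Weighted mean and a normal-approximation 95% confidence interval using
#' the effective sample size `(sum w)^2 / sum(w^2)` -- the summary used when
#' dots (samples) carry unequal reliability, e.g. down-weighting pairs with
#' long between-biopsy intervals via [intervalWeights()].
#'
#' @param values Numeric values.
#' @param weights Nonnegative weights, not all zero.
#' @return List with `mean`, `lo`, `hi`, `effN`, and `degenerate` (TRUE when
#'   the effective sample size is too small for a spread estimate).
#' @export
weightedGroupSummary <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (all(weights == 0)) stop("all-zero weights")
  w <- weights / sum(weights)
  m <- sum(w * values)
  effN <- 1 / sum(w^2)
  if (effN <= 1 + 1e-9) {
    return(list(mean = m, lo = m, hi = m, effN = effN, degenerate = TRUE))
  }
  v <- sum(w * (values - m)^2) * effN / (effN - 1)
  se <- sqrt(v / effN)
  list(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se, effN = effN,
       degenerate = FALSE)
}

#' Interval-time dot weights
#'
#' Quadratically scaled down-weighting of sample pairs by the number of days
#' between the two biopsies: `1 / (1 + days)^2`. Long intervals make the
#' pair less informative about concordance, hence the reciprocal reading.
#'
#' @param days Nonnegative interval lengths in days.
#' @return Weights in (0, 1].
#' @export
intervalWeights <- function(days) {
  stopifnot(all(days >= 0))
  1 / (1 + days)^2
}

#' Aberration-frequency waves
#'
#' Per-bin percentage of samples called gain and loss within a group, plus
#' the signed combination %gain - %loss used for clustering.
#'
#' @param segsets List of scored [SegmentSet]s (one group).
#' @param grid The shared [BinGrid].
#' @return List with numeric per-bin `gainPct`, `lossPct`, `signed`
#'   (NA at masked bins).
#' @export
aberrationFrequencyWaves <- function(segsets, grid) {
  stopifnot(length(segsets) >= 1)
  n <- nBins(grid)
  gain <- loss <- rep(0, n)
  for (s in segsets) {
    seg <- s@segments
    for (k in seq_len(nrow(seg))) {
      if (is.na(seg$call[k]) || seg$call[k] == "neutral") next
      idx <- seg$startBin[k]:seg$endBin[k]
      if (seg$call[k] == "gain") gain[idx] <- gain[idx] + 1
      else loss[idx] <- loss[idx] + 1
    }
  }
  gainPct <- 100 * gain / length(segsets)
  lossPct <- 100 * loss / length(segsets)
  mask <- binMask(grid)
  gainPct[!mask] <- NA; lossPct[!mask] <- NA
  list(gainPct = gainPct, lossPct = lossPct, signed = gainPct - lossPct)
}

#' Cluster groups by their aberration waves
#'
#' Agglomerative complete-linkage clustering of group-level signed waves
#' (%gains - %losses) on the Pearson distance d = (1 - r) / 2. Groups with a
#' constant wave have undefined correlation and are dropped with a warning.
#'
#' @param waves Named list of wave objects (see
#'   [aberrationFrequencyWaves()]) or of numeric signed vectors.
#' @return An [stats::hclust] tree.
#' @export
clusterGroups <- function(waves) {
  stopifnot(length(waves) >= 2)
  sig <- lapply(waves, function(w) if (is.list(w)) w$signed else w)
  ok <- vapply(sig, function(v) sd(v, na.rm = TRUE) > 0, logical(1))
  if (any(!ok)) {
    warning("dropping constant wave(s): ",
            paste(names(sig)[!ok], collapse = ", "))
    sig <- sig[ok]
  }
  if (length(sig) < 2) stop("fewer than 2 non-constant waves")
  m <- do.call(cbind, sig)
  r <- cor(m, use = "pairwise.complete.obs")
  d <- stats::as.dist((1 - r) / 2)
  stats::hclust(d, method = "complete")
}
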