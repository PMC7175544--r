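# Synthetic cfDNA cohort generator: reference panels, subtype-fingerprinted
# tumor profiles, array-style training tables and fragment-size-annotated
# reads, with the statistical structure the analysis assumes (Gaussian
# bin noise with bin-specific variances, tumor-fraction-scaled amplitudes,
# two-component fragment-length mixture).

# GRCh38 autosome lengths (Mb), used only as relative proportions when
# scaling the synthetic genome
.autosomeMb <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135,
                 133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51)

#' Reduced synthetic genome
#'
#' Builds a 22-autosome bin grid whose chromosome sizes are proportional to
#' the human autosomes, scaled to a configurable total bin count so tests
#' and simulations stay fast. A centromere-like run of masked bins is placed
#' at the p/q arm boundary of each chromosome (40% of its length), so that
#' arm-level events and masked-locus handling are both exercised.
#'
#' @param totalBins Approximate total number of bins (default 3000).
#' @param binWidth Bin width in bp (default 100 kb).
#' @param centromereFraction Fraction of each chromosome masked as its
#'   centromere (default 0.03).
#' @param nChrom Number of autosomes to keep, from chr1 down (default 22).
#' @return A [BinGrid] with unit weights on usable bins.
#' @export
syntheticGenome <- function(totalBins = 3000, binWidth = 100000L,
                            centromereFraction = 0.03, nChrom = 22) {
  mb <- .autosomeMb[seq_len(nChrom)]
  nb <- pmax(10L, round(mb / sum(mb) * totalBins))
  lens <- setNames(as.numeric(nb) * binWidth, paste0("chr", seq_len(nChrom)))
  grid <- binGrid(lens, binWidth = binWidth)
  ch <- binChrom(grid)
  mask <- rep(TRUE, nBins(grid))
  for (cn in names(lens)) {
    ix <- which(ch == cn)
    ncen <- max(1L, round(length(ix) * centromereFraction))
    mid <- floor(length(ix) * 0.4)
    lo <- max(1L, mid - floor(ncen / 2))
    mask[ix[seq(lo, min(length(ix), lo + ncen - 1L))]] <- FALSE
  }
  setGridWeights(grid, mask = mask, weights = ifelse(mask, 1, 0))
}

#' Chromosome-arm label of each bin
#'
#' Bins before the 40% point of their chromosome are assigned to the p arm,
#' the rest to the q arm, matching the centromere placement of
#' [syntheticGenome()].
#'
#' @param grid A [BinGrid].
#' @return Character vector like `"1p"`, `"1q"` per bin.
#' @export
binArms <- function(grid) {
  ch <- binChrom(grid)
  out <- character(nBins(grid))
  for (cn in unique(ch)) {
    ix <- which(ch == cn)
    cut <- floor(length(ix) * 0.4)
    num <- sub("^chr", "", cn)
    out[ix] <- paste0(num, ifelse(seq_along(ix) <= cut, "p", "q"))
  }
  out
}

#' Default histology fingerprints
#'
#' Qualitative arm-level aberration fingerprints for LUAD, LUSC and SCLC:
#' 5p gains shared by all lung cancers; 1p and 9p gained in SCLC but lost in
#' NSCLC; 3p lost in LUSC and (most often) SCLC; 3q gains typical of LUSC;
#' 19p and 1q/14q events separating LUAD. Penetrances are this package's
#' choices, set so that classes overlap but remain separable.
#'
#' @param penetrance Optional scalar in (0, 1] overriding every event's
#'   penetrance (e.g. 0.9 for a high-signal cohort).
#' @return Named list of fingerprints, each a `data.frame` with columns
#'   `arm`, `direction` ("gain"/"loss"), `penetrance`.
#' @export
defaultFingerprints <- function(penetrance = NULL) {
  fp <- list(
    LUAD = data.frame(
      arm = c("1p", "1q", "5p", "9p", "14q", "19p"),
      direction = c("loss", "gain", "gain", "loss", "loss", "loss"),
      penetrance = c(0.7, 0.6, 0.7, 0.7, 0.5, 0.6)),
    LUSC = data.frame(
      arm = c("1p", "3p", "3q", "5p", "9p", "22q"),
      direction = c("loss", "loss", "gain", "gain", "loss", "loss"),
      penetrance = c(0.6, 0.8, 0.8, 0.7, 0.6, 0.5)),
    SCLC = data.frame(
      arm = c("1p", "3p", "5p", "9p", "13q", "16q", "17p"),
      direction = c("gain", "loss", "gain", "gain", "loss", "loss", "loss"),
      penetrance = c(0.8, 0.9, 0.8, 0.7, 0.7, 0.7, 0.8))
  )
  if (!is.null(penetrance)) {
    stopifnot(penetrance > 0, penetrance <= 1)
    fp <- lapply(fp, function(f) { f$penetrance <- penetrance; f })
  }
  fp
}

#' Two-component cfDNA fragment-length model
#'
#' Gaussian insert-size components for normal-cell and tumor-derived cfDNA.
#' Tumor fragments are shorter on average, which is what insert-size
#' filtering exploits.
#'
#' @param normalMean,normalSd Normal-component mean/sd in bp (167, 12).
#' @param tumorMean,tumorSd Tumor-component mean/sd in bp (145, 25).
#' @return A `fragmentModel` list.
#' @export
fragmentModel <- function(normalMean = 167, normalSd = 12,
                          tumorMean = 145, tumorSd = 25) {
  stopifnot(normalMean > 0, normalSd > 0, tumorMean > 0, tumorSd > 0)
  structure(list(normalMean = normalMean, normalSd = normalSd,
                 tumorMean = tumorMean, tumorSd = tumorSd),
            class = "fragmentModel")
}

#' Cohort simulation configuration
#'
#' Bundles the knobs of the synthetic cohort: control count, per-class case
#' count, tumor-fraction distribution, per-bin noise range, fragment model
#' and master seed. Per-bin noise standard deviations are drawn once (from
#' the master seed) and shared by the panel and every sample, emulating
#' locus-specific technical variability.
#'
#' @param nControls Controls in the reference panel (default 50).
#' @param nCasesPerClass Cases per histology class (default 20).
#' @param tumorFraction Either a length-2 numeric range for a uniform draw
#'   (default `c(0.05, 0.5)`) or a list `list(dist = "beta", shape1, shape2)`.
#' @param binNoiseSdRange Range the per-bin noise sd is drawn from
#'   (default `c(0.05, 0.2)` log2 units, typical of shallow WGS 100 kb bins).
#' @param seed Master seed.
#' @param fragModel A [fragmentModel()].
#' @return A `cohortConfig` list.
#' @export
cohortConfig <- function(nControls = 50, nCasesPerClass = 20,
                         tumorFraction = c(0.05, 0.5),
                         binNoiseSdRange = c(0.05, 0.2),
                         seed = 1L, fragModel = fragmentModel()) {
  stopifnot(binNoiseSdRange[1] > 0, binNoiseSdRange[2] >= binNoiseSdRange[1])
  structure(list(nControls = as.integer(nControls),
                 nCasesPerClass = as.integer(nCasesPerClass),
                 tumorFraction = tumorFraction,
                 binNoiseSdRange = binNoiseSdRange,
                 seed = as.integer(seed), fragModel = fragModel),
            class = "cohortConfig")
}

# per-bin generating noise sd, deterministic in (grid, config$seed)
binNoiseSd <- function(grid, config) {
  withSeed(childSeed(config$seed, 1L),
           runif(nBins(grid), config$binNoiseSdRange[1], config$binNoiseSdRange[2]))
}

drawTumorFraction <- function(config, n = 1) {
  tf <- config$tumorFraction
  if (is.list(tf) && identical(tf$dist, "beta"))
    rbeta(n, tf$shape1, tf$shape2)
  else
    runif(n, tf[1], tf[2])
}

#' Expected log2 ratio of an aberration
#'
#' For tumor fraction `f` and tumor copy number `copies` (diploid background),
#' the expected bin-wise log2 ratio is `log2((2 * (1 - f) + copies * f) / 2)`.
#' This ties aberration amplitude to tumor fraction: amplitudes shrink toward
#' 0 as `f` does.
#'
#' @param f Tumor fraction in \[0, 1\].
#' @param copies Tumor copy number (integer >= 0).
#' @return Expected log2 ratio; `-Inf` (with a warning) for a complete loss
#'   (`copies = 0`, `f = 1`).
#' @examples
#' expectedLog2Ratio(0.5, 3)  # log2(1.25)
#' @export
expectedLog2Ratio <- function(f, copies) {
  stopifnot(all(f >= 0 & f <= 1), all(copies >= 0))
  out <- log2((2 * (1 - f) + copies * f) / 2)
  if (any(out == -Inf)) warning("complete loss: expected ratio is -Inf")
  out
}

#' Simulate a reference panel
#'
#' Per-bin control ratios are Normal(0, sd_i) with sd_i drawn once per bin
#' from the configured range; all controls share the bin-specific sds.
#'
#' @param grid A [BinGrid].
#' @param config A [cohortConfig()].
#' @param drawSeed Seed for the Gaussian draws; the default ties it to the
#'   master seed. Supply a different value to generate an independent
#'   control cohort that still shares the config's per-bin noise sds (e.g.
#'   held-out controls for cutoff validation).
#' @return A [ReferencePanel]; masked bins are NA.
#' @export
simulatePanel <- function(grid, config = cohortConfig(),
                          drawSeed = childSeed(config$seed, 2L)) {
  sds <- binNoiseSd(grid, config)
  n <- nBins(grid)
  p <- config$nControls
  m <- withSeed(drawSeed,
                matrix(rnorm(p * n, 0, rep(sds, each = p)), nrow = p))
  m[, !binMask(grid)] <- NA
  referencePanel(m, grid)
}

# per-bin tumor copy number implied by a fingerprint realization
realizeCopyState <- function(grid, fingerprint, gainCopies = 3,
                             lossCopies = 1) {
  arms <- binArms(grid)
  copies <- rep(2, nBins(grid))
  if (!is.null(fingerprint) && nrow(fingerprint)) {
    on <- runif(nrow(fingerprint)) < fingerprint$penetrance
    for (k in which(on)) {
      tgt <- if (fingerprint$direction[k] == "gain") gainCopies else lossCopies
      copies[arms == fingerprint$arm[k]] <- tgt
    }
  }
  copies
}

#' Simulate a case (or control) profile with its truth segmentation
#'
#' Each fingerprint event is realized with its penetrance; realized arms get
#' the tumor copy number (3 for gains, 1 for losses by default; set
#' `gainCopies = 5` for amplification-like events), the expected log2 ratio
#' follows [expectedLog2Ratio()], and Normal(0, sd_i) bin noise is added.
#' A tumor fraction of 0 (a control) yields neutral expectation everywhere.
#'
#' @param grid A [BinGrid].
#' @param fingerprint A fingerprint `data.frame` (see
#'   [defaultFingerprints()]) or `NULL` for a control.
#' @param tumorFraction Tumor fraction in \[0, 1\].
#' @param config A [cohortConfig()] (source of the shared per-bin noise sds).
#' @param sampleId Sample identifier.
#' @param seed Per-sample seed (event realization + noise).
#' @param gainCopies,lossCopies Tumor copy numbers used for gains/losses.
#' @return List with `profile` ([CopyNumberProfile]), `truth` ([SegmentSet]
#'   of the generating states, meanRatio = expected log2 ratio) and
#'   `copyState` (per-bin tumor copies).
#' @export
simulateCase <- function(grid, fingerprint, tumorFraction,
                         config = cohortConfig(), sampleId = "case",
                         seed = config$seed, gainCopies = 3, lossCopies = 1) {
  sds <- binNoiseSd(grid, config)
  n <- nBins(grid)
  withSeed(seed, {
    # events are realized even at f = 0 (amplitude scaling zeroes them), so
    # profiles simulated across a tumor-fraction grid under one seed share
    # both the realized events and the noise draws exactly
    copies <- realizeCopyState(grid, fingerprint, gainCopies, lossCopies)
    expected <- expectedLog2Ratio(tumorFraction, copies)
    r <- expected + rnorm(n, 0, sds)
    r[!binMask(grid)] <- NA
    prof <- copyNumberProfile(sampleId, r, grid)
    truth <- truthSegments(sampleId, expected, grid)
    list(profile = prof, truth = truth, copyState = copies)
  })
}

# SegmentSet from runs of equal expected value over usable bins
truthSegments <- function(sampleId, expected, grid) {
  mask <- binMask(grid)
  ch <- binChrom(grid)
  rows <- list()
  for (cn in unique(ch)) {
    ix <- which(ch == cn & mask)
    if (!length(ix)) next
    runId <- cumsum(c(1, diff(expected[ix]) != 0))
    for (rid in unique(runId)) {
      jx <- ix[runId == rid]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, startBin = min(jx), endBin = max(jx),
        nBins = length(jx),
        lengthBp = length(jx) * grid@binWidth,
        meanRatio = expected[jx[1]], z = NA_real_, call = NA_character_)
    }
  }
  new("SegmentSet", sampleId = as.character(sampleId),
      segments = do.call(rbind, rows), grid = grid)
}

#' Simulate an array-style training table
#'
#' Emulates a public tumor-tissue copy-number resource: per-sample segmental
#' continuous states (expected log2 ratio of each realized event at the
#' sample's tumor fraction, plus a small per-segment jitter) with class
#' labels, ready for [discretizeFeatures()].
#'
#' @param grid A [BinGrid].
#' @param fingerprints Named list of class fingerprints.
#' @param nPerClass Samples per class (default 68, giving the class-balanced
#'   n = 204 design with three classes).
#' @param config A [cohortConfig()].
#' @param tumorFraction Range of tumor fractions for the tissue samples
#'   (default `c(0.3, 0.9)`; tissue purity is high compared to plasma).
#' @param segmentJitterSd Per-segment continuous-state jitter (default 0.05).
#' @return List with `states` (samples x usable-bins continuous matrix),
#'   `labels` (factor) and `binIndex` (grid bin indices of the columns).
#' @export
simulateTrainingTable <- function(grid, fingerprints = defaultFingerprints(),
                                  nPerClass = 68, config = cohortConfig(),
                                  tumorFraction = c(0.3, 0.9),
                                  segmentJitterSd = 0.05) {
  mask <- binMask(grid)
  usable <- which(mask)
  arms <- binArms(grid)
  labels <- rep(names(fingerprints), each = nPerClass)
  withSeed(childSeed(config$seed, 3L), {
    states <- matrix(0, nrow = length(labels), ncol = length(usable))
    for (s in seq_along(labels)) {
      fp <- fingerprints[[labels[s]]]
      f <- runif(1, tumorFraction[1], tumorFraction[2])
      copies <- realizeCopyState(grid, fp)
      expected <- expectedLog2Ratio(f, copies)
      # segment-level jitter: one draw per constant-state run
      runId <- cumsum(c(1, diff(copies[usable]) != 0 |
                          diff(match(binChrom(grid)[usable],
                                     unique(binChrom(grid)))) != 0))
      jit <- rnorm(max(runId), 0, segmentJitterSd)
      states[s, ] <- expected[usable] + jit[runId]
    }
    list(states = states, labels = factor(labels), binIndex = usable)
  })
}

#' Simulate fragment-size-annotated reads
#'
#' Reads are assigned to usable bins with probability proportional to the
#' expected local coverage `2(1 - f) + f * copies`; each read is tumor-origin
#' with the local conditional probability `f * copies / (2(1 - f) + f *
#' copies)` and draws its insert size from the matching Gaussian component
#' of the fragment model. Origins are retained so truth-based enrichment
#' tests are possible.
#'
#' @param nReads Number of reads.
#' @param tumorFraction Tumor fraction f.
#' @param copyState Per-bin tumor copy number (length `nBins(grid)`).
#' @param grid A [BinGrid].
#' @param model A [fragmentModel()].
#' @param seed Seed.
#' @return `data.frame` with columns `bin` (grid bin index), `insertSize`
#'   (bp, >= 1) and `origin` ("tumor"/"normal").
#' @export
simulateFragments <- function(nReads, tumorFraction, copyState, grid,
                              model = fragmentModel(), seed = 1L) {
  stopifnot(nReads > 0, length(copyState) == nBins(grid))
  usable <- which(binMask(grid))
  f <- tumorFraction
  cov <- 2 * (1 - f) + f * copyState[usable]
  withSeed(seed, {
    bin <- usable[sample.int(length(usable), nReads, replace = TRUE,
                             prob = cov)]
    pTum <- f * copyState[bin] / (2 * (1 - f) + f * copyState[bin])
    tumor <- runif(nReads) < pTum
    is <- ifelse(tumor,
                 rnorm(nReads, model$tumorMean, model$tumorSd),
                 rnorm(nReads, model$normalMean, model$normalSd))
    data.frame(bin = bin, insertSize = as.integer(pmax(1, round(is))),
               origin = ifelse(tumor, "tumor", "normal"))
  })
}
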