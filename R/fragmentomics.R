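# In-silico tumor enrichment by insert-size filtering: three parallel arms
# (raw reads, 90-135 bp filtered reads, and a random downsample matched to
# the filtered read count as a negative control), profile derivation from
# binned read counts, and closed-form enrichment expectations.

#' Insert-size filter
#'
#' @param lo,hi Inclusive bounds in bp (defaults 90 and 135).
#' @return A `sizeFilter` list.
#' @export
sizeFilter <- function(lo = 90, hi = 135) {
  stopifnot(lo > 0, lo <= hi)
  structure(list(lo = lo, hi = hi), class = "sizeFilter")
}

#' Filter reads by insert size
#'
#' Keeps reads with `lo <= insertSize <= hi` (both bounds inclusive).
#'
#' @param reads Read records (`data.frame` with `insertSize`).
#' @param filter A [sizeFilter()].
#' @return The retained reads.
#' @export
filterByInsertSize <- function(reads, filter = sizeFilter()) {
  reads[reads$insertSize >= filter$lo & reads$insertSize <= filter$hi, ,
        drop = FALSE]
}

#' Randomly downsample reads
#'
#' Uniform sample without replacement to a target count; reproducible.
#'
#' @param reads Read records.
#' @param targetCount Number of reads to keep (<= nrow(reads)).
#' @param seed Seed.
#' @return The sampled reads (original order preserved).
#' @export
randomDownsample <- function(reads, targetCount, seed = 1L) {
  if (targetCount > nrow(reads))
    stop("target count exceeds available reads")
  keep <- withSeed(seed, sort(sample.int(nrow(reads), targetCount)))
  reads[keep, , drop = FALSE]
}

#' Derive a copy-number profile from binned reads
#'
#' Per-bin `log2(observed / expected)` after total-count scaling of both
#' vectors, so profiles from arms with different read counts are comparable.
#' Bins with zero expected count are masked; usable bins with zero observed
#' count are flagged missing.
#'
#' @param reads Read records with a `bin` column of grid bin indices.
#' @param grid A [BinGrid].
#' @param expected Per-bin expected counts (e.g. the synthetic truth or a
#'   control-derived expectation); default uniform over usable bins.
#' @param sampleId Sample identifier.
#' @return A [CopyNumberProfile].
#' @export
readsToProfile <- function(reads, grid, expected = NULL,
                           sampleId = "reads") {
  n <- nBins(grid)
  mask <- binMask(grid)
  if (is.null(expected)) expected <- ifelse(mask, 1, 0)
  stopifnot(length(expected) == n)
  obs <- tabulate(reads$bin, nbins = n)
  ok <- mask & expected > 0
  ratio <- rep(NA_real_, n)
  ratio[ok] <- log2((obs[ok] / sum(obs[ok])) / (expected[ok] / sum(expected[ok])))
  miss <- !ok | obs == 0
  ratio[ratio == -Inf] <- NA
  copyNumberProfile(sampleId, ratio, grid, missing = miss)
}

#' Closed-form enriched tumor fraction
#'
#' If a filter passes tumor reads with probability `passTumor` and normal
#' reads with `passNormal`, the tumor fraction after filtering is
#' `f' = f * passTumor / (f * passTumor + (1 - f) * passNormal)`.
#'
#' @param f Tumor fraction before filtering.
#' @param passTumor,passNormal Pass probabilities in \[0, 1\].
#' @return The enriched fraction f'.
#' @export
enrichedTumorFraction <- function(f, passTumor, passNormal) {
  stopifnot(f >= 0, f <= 1, passTumor >= 0, passTumor <= 1,
            passNormal >= 0, passNormal <= 1)
  den <- f * passTumor + (1 - f) * passNormal
  if (den == 0) stop("degenerate filter: no reads pass")
  f * passTumor / den
}

#' Component pass rates of a size filter
#'
#' Gaussian-component probabilities of falling inside the filter window,
#' for the closed-form enrichment expectation.
#'
#' @param model A [fragmentModel()].
#' @param filter A [sizeFilter()].
#' @return List with `tumor` and `normal` pass probabilities.
#' @export
fragmentPassRates <- function(model = fragmentModel(),
                              filter = sizeFilter()) {
  list(
    tumor = pnorm(filter$hi, model$tumorMean, model$tumorSd) -
      pnorm(filter$lo, model$tumorMean, model$tumorSd),
    normal = pnorm(filter$hi, model$normalMean, model$normalSd) -
      pnorm(filter$lo, model$normalMean, model$normalSd))
}

#' Run the three-arm enrichment pipeline
#'
#' From one sample's reads: (1) raw profile, (2) insert-size-filtered
#' profile, (3) random-downsample profile matched to the filtered read
#' count (the negative control ruling out downsampling noise as the cause
#' of new aberrations).
#'
#' @param reads Read records.
#' @param grid A [BinGrid].
#' @param expected Per-bin expected counts (see [readsToProfile()]).
#' @param filter A [sizeFilter()].
#' @param seed Seed for the downsampling arm.
#' @return List with profiles `raw`, `filtered`, `downsampled` and the
#'   per-arm read `counts`.
#' @export
fragmentPipeline <- function(reads, grid, expected = NULL,
                             filter = sizeFilter(), seed = 1L) {
  fil <- filterByInsertSize(reads, filter)
  if (!nrow(fil)) stop("no reads pass the insert-size filter")
  dwn <- randomDownsample(reads, nrow(fil), seed = seed)
  list(raw = readsToProfile(reads, grid, expected, "raw"),
       filtered = readsToProfile(fil, grid, expected, "filtered"),
       downsampled = readsToProfile(dwn, grid, expected, "downsampled"),
       counts = c(raw = nrow(reads), filtered = nrow(fil),
                  downsampled = nrow(dwn)))
}

#' Segmental amplitude shifts across pipeline arms
#'
#' Measures each raw-arm segment's amplitude (|mean log2 ratio|) on all
#' three arms and summarises the deltas filtered - raw (the enrichment
#' effect) and downsampled - raw (the negative control, expected to center
#' on zero), each with a 95% CI. Only segments with a raw amplitude of at
#' least `minAmplitude` enter the summaries: near-zero (neutral) segments
#' would otherwise inflate the lower-coverage arms, because the absolute
#' value of a noisy zero is biased upward.
#'
#' @param triple Output of [fragmentPipeline()].
#' @param segset Segments called on the raw arm ([segmentProfile()]).
#' @param minAmplitude Raw-amplitude floor for the delta summaries
#'   (default 0.1, aberration scale).
#' @return List with the per-segment `table` (all segments, plus `kept`)
#'   and `filteredDelta` / `downsampledDelta` summaries (`mean`, `lo`,
#'   `hi`).
#' @export
amplitudeShift <- function(triple, segset, minAmplitude = 0.1) {
  seg <- segset@segments
  mask <- binMask(segset@grid)
  amp <- function(profile, k) {
    idx <- seg$startBin[k]:seg$endBin[k]
    idx <- idx[mask[idx] & !profile@missing[idx]]
    if (!length(idx)) return(NA_real_)
    abs(mean(ratios(profile)[idx]))
  }
  tab <- data.frame(
    chrom = seg$chrom, startBin = seg$startBin, endBin = seg$endBin,
    raw = vapply(seq_len(nrow(seg)), function(k) amp(triple$raw, k), 1),
    filtered = vapply(seq_len(nrow(seg)), function(k) amp(triple$filtered, k), 1),
    downsampled = vapply(seq_len(nrow(seg)), function(k) amp(triple$downsampled, k), 1))
  tab$kept <- is.finite(tab$raw) & tab$raw >= minAmplitude
  summ <- function(delta) {
    delta <- delta[tab$kept & is.finite(delta)]
    if (!length(delta)) return(list(mean = NA_real_, lo = NA_real_,
                                    hi = NA_real_))
    se <- if (length(delta) > 1) sd(delta) / sqrt(length(delta)) else 0
    list(mean = mean(delta), lo = mean(delta) - 1.96 * se,
         hi = mean(delta) + 1.96 * se)
  }
  list(table = tab,
       filteredDelta = summ(tab$filtered - tab$raw),
       downsampledDelta = summ(tab$downsampled - tab$raw))
}
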