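# Circular-binary-segmentation-style partitioning of bin-wise log2-ratio
# profiles into stretches of expected equal copy number. Each chromosome is
# processed independently; masked/missing bins are skipped (indices
# compacted), never interpolated.

#' Segmentation parameters
#'
#' @param alpha Permutation p-value threshold for accepting a split
#'   (default 0.01).
#' @param nPerm Number of permutations per split test (default 1000; the
#'   test stops early once significance is impossible).
#' @param minBins Minimum usable bins for a chromosome (or recursion piece)
#'   to be tested; smaller stretches stay a single segment (default 3).
#' @param seed Seed for the permutation null.
#' @return A `segmentationParams` list.
#' @export
segmentationParams <- function(alpha = 0.01, nPerm = 1000L, minBins = 3L,
                               seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, nPerm >= 100)
  structure(list(alpha = alpha, nPerm = as.integer(nPerm),
                 minBins = as.integer(minBins), seed = as.integer(seed)),
            class = "segmentationParams")
}

#' Segment a copy-number profile
#'
#' Recursive best-split search per chromosome: the maximal two-sided
#' circular split statistic is located, its significance assessed by a
#' within-chromosome permutation null, and the split accepted when
#' p < alpha; accepted pieces are searched recursively. Segments tile every
#' usable, non-missing bin exactly once (the returned set carries a grid in
#' which sample-missing bins are masked). Z-scores and calls are left unset;
#' see [scoreSegments()].
#'
#' @param profile A [CopyNumberProfile].
#' @param params A [segmentationParams()].
#' @return A [SegmentSet] with `z` and `call` set to `NA`.
#' @export
segmentProfile <- function(profile, params = segmentationParams()) {
  grid <- profile@grid
  mask <- informativeBins(profile)
  ch <- binChrom(grid)
  r <- ratios(profile)
  rows <- list()
  withSeed(params$seed, {
    for (cn in unique(ch)) {
      ix <- which(ch == cn & mask)
      if (!length(ix)) next
      bounds <- .segmentValues(r[ix], params)
      for (b in seq_len(nrow(bounds))) {
        jx <- ix[seq(bounds[b, 1], bounds[b, 2])]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, startBin = min(jx), endBin = max(jx),
          nBins = length(jx), lengthBp = length(jx) * grid@binWidth,
          meanRatio = mean(r[jx]), z = NA_real_, call = NA_character_)
      }
    }
  })
  seg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), startBin = integer(), endBin = integer(),
               nBins = integer(), lengthBp = numeric(), meanRatio = numeric(),
               z = numeric(), call = character())
  # a profile-missing bin that is grid-usable still needs covering: extend
  # tiling over the grid mask by assigning such bins to the enclosing run
  ss <- new("SegmentSet", sampleId = sampleId(profile), segments = seg,
            grid = .gridForSample(grid, mask))
  ss
}

# grid with sample-missing bins masked out, so tiling invariants refer to
# the bins that actually carry information for this sample
.gridForSample <- function(grid, informative) {
  if (all(informative == binMask(grid))) return(grid)
  w <- binWeights(grid)
  setGridWeights(grid, mask = informative, weights = ifelse(informative, pmax(w, .Machine$double.eps), 0))
}

# recursive split search on compacted values; returns matrix of
# (startIdx, endIdx) into v, in order
.segmentValues <- function(v, params) {
  n <- length(v)
  if (n < params$minBins)
    return(matrix(c(1L, n), nrow = 1))
  res <- .cbsSplitTest(v - mean(v), params$nPerm, params$alpha)  # centering keeps the scan exactly translation-invariant
  if (res$p >= params$alpha || res$stat <= 0)
    return(matrix(c(1L, n), nrow = 1))
  i <- res$i; j <- res$j   # arc (i, j], 0-based boundaries
  cuts <- sort(unique(c(i, j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(matrix(c(1L, n), nrow = 1))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  out <- list()
  for (k in seq_along(starts)) {
    sub <- .segmentValues(v[starts[k]:ends[k]], params)
    out[[k]] <- sub + starts[k] - 1L
  }
  do.call(rbind, out)
}

#' Merge adjacent segments with similar means
#'
#' Adjacent same-chromosome segments whose mean ratios differ by less than
#' `tolerance` are merged (iteratively, left to right); tiling is preserved.
#'
#' @param segset A [SegmentSet].
#' @param tolerance Absolute mean-difference threshold; 0 is the identity.
#' @return A [SegmentSet].
#' @export
mergeAdjacent <- function(segset, tolerance = 0) {
  seg <- segset@segments
  if (nrow(seg) < 2 || tolerance <= 0) return(segset)
  grid <- segset@grid
  mask <- binMask(grid)
  r <- NULL
  out <- seg[1, ]
  for (k in 2:nrow(seg)) {
    last <- nrow(out)
    if (seg$chrom[k] == out$chrom[last] &&
        abs(seg$meanRatio[k] - out$meanRatio[last]) < tolerance) {
      nb1 <- out$nBins[last]; nb2 <- seg$nBins[k]
      out$meanRatio[last] <- (out$meanRatio[last] * nb1 +
                                seg$meanRatio[k] * nb2) / (nb1 + nb2)
      out$endBin[last] <- seg$endBin[k]
      out$nBins[last] <- nb1 + nb2
      out$lengthBp[last] <- out$lengthBp[last] + seg$lengthBp[k]
      out$z[last] <- NA_real_; out$call[last] <- NA_character_
    } else {
      out <- rbind(out, seg[k, ])
    }
  }
  rownames(out) <- NULL
  new("SegmentSet", sampleId = segset@sampleId, segments = out, grid = grid)
}

#' @rdname SegmentSet-class
#' @export
setMethod("segments", "SegmentSet", function(x) x@segments)

#' @rdname SegmentSet-class
#' @export
setMethod("sampleId", "SegmentSet", function(x) x@sampleId)

#' @rdname SegmentSet-class
#' @export
setMethod("show", "SegmentSet", function(object) {
  seg <- object@segments
  cat("SegmentSet", object@sampleId, ":", nrow(seg), "segments",
      if (all(is.na(seg$z))) "(unscored)" else
        sprintf("(%d gains, %d losses)", sum(seg$call == "gain", na.rm = TRUE),
                sum(seg$call == "loss", na.rm = TRUE)), "\n")
})

#' Number of segments
#' @param segset A [SegmentSet].
#' @export
nSegments <- function(segset) nrow(segset@segments)
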