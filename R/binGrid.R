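#' Construct a bin grid
#'
#' Partitions a set of chromosomes into fixed-width, 0-based half-open bins.
#' The final bin of each chromosome is truncated to the chromosome length.
#'
#' @param chromLengths Named integer vector of chromosome lengths in bp, in
#'   the desired chromosome order.
#' @param binWidth Bin width in bp (default 100 kb).
#' @param mask Optional logical vector over the resulting bins (`TRUE` =
#'   usable). Defaults to all usable.
#' @param weights Optional nonnegative weights over the bins; defaults to 1
#'   on usable bins, 0 on masked bins.
#' @return A [BinGrid].
#' @examples
#' g <- binGrid(c(chrA = 450e3, chrB = 300e3), binWidth = 1e5)
#' nBins(g)
#' @export
binGrid <- function(chromLengths, binWidth = 100000L, mask = NULL, weights = NULL) {
  stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
            binWidth >= 1)
  binWidth <- as.integer(binWidth)
  pieces <- lapply(names(chromLengths), function(ch) {
    len <- as.numeric(chromLengths[[ch]])
    starts <- seq(0, len - 1, by = binWidth)
    ends <- pmin(starts + binWidth, len)
    # GRanges is 1-based closed; store 0-based half-open [start, end) as
    # start+1 .. end
    GRanges(ch, IRanges(start = starts + 1, end = ends))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  n <- length(gr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(weights)) weights <- ifelse(mask, 1, 0)
  mcols(gr)$mask <- mask
  mcols(gr)$weight <- weights
  new("BinGrid", bins = gr, binWidth = binWidth)
}

#' @rdname BinGrid-class
#' @export
setMethod("nBins", "BinGrid", function(x) length(x@bins))

#' @rdname BinGrid-class
#' @export
setMethod("binMask", "BinGrid", function(x) mcols(x@bins)$mask)

#' @rdname BinGrid-class
#' @export
setMethod("binWeights", "BinGrid", function(x) mcols(x@bins)$weight)

#' @rdname BinGrid-class
#' @export
setMethod("bins", "BinGrid", function(x) x@bins)

#' @rdname BinGrid-class
#' @export
setMethod("show", "BinGrid", function(object) {
  ch <- unique(as.character(seqnames(object@bins)))
  cat("BinGrid:", length(object@bins), "bins of", object@binWidth, "bp on",
      length(ch), "chromosomes;", sum(binMask(object)), "usable\n")
})

#' Chromosome of each bin
#' @param grid A [BinGrid].
#' @return Character vector of per-bin chromosome names.
#' @export
binChrom <- function(grid) as.character(seqnames(grid@bins))

#' Replace grid mask and weights
#'
#' Returns a copy of `grid` with the given mask/weights (masked bins are
#' forced to weight 0).
#' @param grid A [BinGrid].
#' @param mask Logical per-bin usability.
#' @param weights Nonnegative per-bin weights.
#' @return A [BinGrid].
#' @export
setGridWeights <- function(grid, mask = binMask(grid), weights) {
  weights[!mask] <- 0
  mcols(grid@bins)$mask <- mask
  mcols(grid@bins)$weight <- weights
  validObject(grid)
  grid
}

#' Weighted mean over a bin range
#'
#' The weighted average of per-bin values over the usable, non-missing bins
#' of a range, the building block of the segmental Z-score: segment means of
#' both the case and each control are taken with the same panel-derived
#' weights so that noisy bins contribute less.
#'
#' @param values Per-bin numeric values.
#' @param weights Per-bin nonnegative weights (0 at masked bins).
#' @param idx Indices of the bins in the range (default: all).
#' @param missing Optional logical, bins to exclude (e.g. sample-missing).
#' @return The weighted mean `sum(w*v)/sum(w)` over contributing bins.
#'   Signals an error of class `"undeterminableSegment"` when no bin
#'   contributes.
#' @examples
#' weightedMean(c(0.1, 0.3), c(3, 1))  # 0.15
#' @export
weightedMean <- function(values, weights, idx = seq_along(values),
                         missing = NULL) {
  v <- values[idx]
  w <- weights[idx]
  drop <- w <= 0 | is.na(v)
  if (!is.null(missing)) drop <- drop | missing[idx]
  v <- v[!drop]; w <- w[!drop]
  if (!length(v))
    stop(undeterminableSegment("no usable bins in range"))
  sum(w * v) / sum(w)
}

undeterminableSegment <- function(msg) {
  structure(class = c("undeterminableSegment", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Panel-derived bin weights
#'
#' Per-bin weights as the reciprocal of the per-bin variability of the
#' reference panel (population standard deviation across controls), so that
#' bins that fluctuate more in healthy samples are down-weighted. Bins with
#' zero spread across controls are uninformative and are masked.
#'
#' @param panel A [ReferencePanel].
#' @return A list with `weights` (numeric per-bin; 0 at masked bins) and
#'   `mask` (updated usability).
#' @seealso [applyPanelWeights()] to stamp the result onto the grid.
#' @export
panelBinWeights <- function(panel) {
  stopifnot(is(panel, "ReferencePanel"))
  m <- panel@ratios
  sds <- popSd(m)
  mask <- binMask(panel@grid) & !is.na(sds) & sds > 0
  w <- ifelse(mask, 1 / sds, 0)
  w[is.na(w)] <- 0
  list(weights = w, mask = mask)
}

# population (divide by p) sd per column
popSd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(m^2) - mu^2)
}

#' Stamp panel-derived weights onto a grid
#'
#' @param grid A [BinGrid].
#' @param panel A [ReferencePanel] on the same grid.
#' @return The grid with weights from [panelBinWeights()] and zero-spread
#'   bins masked out.
#' @export
applyPanelWeights <- function(grid, panel) {
  pw <- panelBinWeights(panel)
  setGridWeights(grid, mask = pw$mask, weights = pw$weights)
}
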