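#' Construct a copy-number profile
#'
#' @param sampleId Sample identifier.
#' @param ratios Per-bin log2 ratios aligned to `grid` (NA allowed at bins
#'   flagged missing or masked).
#' @param grid A [BinGrid].
#' @param missing Optional logical per-bin missingness; defaults to
#'   `is.na(ratios)`.
#' @return A [CopyNumberProfile].
#' @export
copyNumberProfile <- function(sampleId, ratios, grid, missing = NULL) {
  if (is.null(missing)) missing <- is.na(ratios)
  new("CopyNumberProfile", sampleId = as.character(sampleId),
      ratios = as.numeric(ratios), missing = missing, grid = grid)
}

#' @rdname CopyNumberProfile-class
#' @export
setMethod("ratios", "CopyNumberProfile", function(x) x@ratios)

#' @rdname CopyNumberProfile-class
#' @export
setMethod("sampleId", "CopyNumberProfile", function(x) x@sampleId)

#' @rdname CopyNumberProfile-class
#' @export
setMethod("nBins", "CopyNumberProfile", function(x) nBins(x@grid))

#' @rdname CopyNumberProfile-class
#' @export
setMethod("show", "CopyNumberProfile", function(object) {
  use <- binMask(object@grid) & !object@missing
  cat("CopyNumberProfile", object@sampleId, ":", nBins(object@grid), "bins,",
      sum(use), "informative; median ratio",
      signif(median(object@ratios[use]), 3), "\n")
})

# bins contributing for this sample: grid mask minus sample-missing
informativeBins <- function(profile) {
  binMask(profile@grid) & !profile@missing
}

#' Construct a reference panel
#'
#' @param ratioMatrix p x nBins matrix of control log2 ratios.
#' @param grid A [BinGrid].
#' @return A [ReferencePanel].
#' @export
referencePanel <- function(ratioMatrix, grid) {
  new("ReferencePanel", grid = grid, ratios = as.matrix(ratioMatrix))
}

#' @rdname ReferencePanel-class
#' @export
setMethod("nBins", "ReferencePanel", function(x) nBins(x@grid))

#' Number of controls in a panel
#' @param panel A [ReferencePanel].
#' @export
nControls <- function(panel) nrow(panel@ratios)

#' @rdname ReferencePanel-class
#' @export
setMethod("ratios", "ReferencePanel", function(x) x@ratios)

#' @rdname ReferencePanel-class
#' @export
setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", nrow(object@ratios), "controls x",
      ncol(object@ratios), "bins\n")
})
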