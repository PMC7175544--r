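#' @import methods
#' @importFrom stats sd rnorm runif qnorm pnorm cor var median quantile
#'   setNames predict ecdf rbinom rpois
#' @importFrom utils head read.delim write.table
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle runValue
#' @useDynLib plasmaCNA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Genome bin grid
#'
#' Partition of a genome into fixed-width, 0-based half-open bins with a
#' per-bin usability mask and nonnegative per-bin weights. Masked bins
#' (centromere-like loci of undeterminable copy number) carry weight 0 and
#' are ignored by every downstream operation; usable bins carry weight > 0.
#' The weights are typically derived from a reference panel with
#' [panelBinWeights()] and enter the weighted segment means that feed the
#' segmental Z-score.
#'
#' @slot bins A [GenomicRanges::GRanges] of the bins, sorted by chromosome
#'   then start, with metadata columns `mask` (logical, `TRUE` = usable) and
#'   `weight` (numeric, >= 0).
#' @slot binWidth Integer bin width in bp (the final bin of a chromosome may
#'   be truncated).
#'
#' @seealso [binGrid()], [syntheticGenome()], [panelBinWeights()]
#' @export
setClass("BinGrid",
  representation(bins = "GRanges", binWidth = "integer"))

setValidity("BinGrid", function(object) {
  gr <- object@bins
  msg <- character()
  mc <- mcols(gr)
  if (!all(c("mask", "weight") %in% colnames(mc)))
    return("bins must carry 'mask' and 'weight' metadata columns")
  mask <- mc$mask
  w <- mc$weight
  if (anyNA(mask) || !is.logical(mask)) msg <- c(msg, "mask must be logical without NA")
  if (anyNA(w) || any(w < 0)) msg <- c(msg, "weights must be nonnegative and non-NA")
  if (any(!mask & w != 0)) msg <- c(msg, "masked-out bins must have weight 0")
  if (any(mask & w <= 0)) msg <- c(msg, "usable bins must have weight > 0")
  ch <- as.character(seqnames(gr))
  s <- start(gr)
  ord <- order(match(ch, unique(ch)), s)
  if (!identical(ord, seq_along(gr))) msg <- c(msg, "bins must be sorted by (chromosome, start)")
  sp <- split(seq_along(gr), ch)
  for (ix in sp) {
    if (length(ix) > 1 && any(start(gr)[ix][-1] < end(gr)[ix][-length(ix)] + 1))
      msg <- c(msg, "bins overlap within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample copy-number profile
#'
#' Bin-wise log2 ratios (observed/expected coverage) for one sample, aligned
#' to a [BinGrid]. Ratios at masked or missing bins are ignored downstream.
#'
#' @slot sampleId Sample identifier.
#' @slot ratios Numeric vector of per-bin log2 ratios, length `nBins(grid)`.
#' @slot missing Logical vector flagging bins without information in this
#'   sample (in addition to the grid mask).
#' @slot grid The [BinGrid] the profile is aligned to.
#' @export
setClass("CopyNumberProfile",
  representation(sampleId = "character", ratios = "numeric",
                 missing = "logical", grid = "BinGrid"))

setValidity("CopyNumberProfile", function(object) {
  n <- length(object@grid@bins)
  msg <- character()
  if (length(object@ratios) != n) msg <- c(msg, "ratios length must equal grid bin count")
  if (length(object@missing) != n) msg <- c(msg, "missing length must equal grid bin count")
  use <- binMask(object@grid) & !object@missing
  if (length(object@ratios) == n && any(!is.finite(object@ratios[use])))
    msg <- c(msg, "ratios must be finite on usable, non-missing bins")
  if (length(msg)) msg else TRUE
})

#' Reference panel of control profiles
#'
#' Per-bin log2 ratios of p healthy control samples on a shared [BinGrid].
#' The panel supplies the denominator of the segmental Z-score (spread of
#' control segment means) and the per-bin weights (reciprocal of the per-bin
#' control variability).
#'
#' @slot grid The shared [BinGrid].
#' @slot ratios p x nBins numeric matrix of control log2 ratios (rows =
#'   controls).
#' @export
setClass("ReferencePanel",
  representation(grid = "BinGrid", ratios = "matrix"))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (nrow(object@ratios) < 2) msg <- c(msg, "a panel needs p >= 2 controls")
  if (ncol(object@ratios) != length(object@grid@bins))
    msg <- c(msg, "panel columns must match grid bins")
  use <- binMask(object@grid)
  if (ncol(object@ratios) == length(object@grid@bins) &&
      any(!is.finite(object@ratios[, use, drop = FALSE])))
    msg <- c(msg, "panel ratios must be finite on usable bins")
  if (length(msg)) msg else TRUE
})

#' Segmentation of one profile
#'
#' An ordered set of segments tiling every usable bin of the grid exactly
#' once. Bin indices are global grid indices (1-based, inclusive); `nBins`
#' counts usable bins only and `lengthBp` is the usable-bin span
#' (`nBins * binWidth`). `z` and `call` are `NA` until scored with
#' [scoreSegments()].
#'
#' @slot sampleId Sample identifier.
#' @slot segments `data.frame` with columns `chrom`, `startBin`, `endBin`,
#'   `nBins`, `lengthBp`, `meanRatio`, `z`, `call`.
#' @slot grid The [BinGrid] the bin indices refer to.
#' @export
setClass("SegmentSet",
  representation(sampleId = "character", segments = "data.frame",
                 grid = "BinGrid"))

setValidity("SegmentSet", function(object) {
  seg <- object@segments
  need <- c("chrom", "startBin", "endBin", "nBins", "lengthBp", "meanRatio", "z", "call")
  if (!all(need %in% names(seg))) return("segments is missing required columns")
  msg <- character()
  if (nrow(seg)) {
    if (any(seg$startBin > seg$endBin)) msg <- c(msg, "startBin must be <= endBin")
    gridChrom <- as.character(seqnames(object@grid@bins))
    if (any(gridChrom[seg$startBin] != seg$chrom | gridChrom[seg$endBin] != seg$chrom))
      msg <- c(msg, "a segment must not cross a chromosome boundary")
    mask <- binMask(object@grid)
    covered <- unlist(mapply(seq, seg$startBin, seg$endBin, SIMPLIFY = FALSE))
    usableCovered <- covered[mask[covered]]
    if (anyDuplicated(usableCovered) || !setequal(usableCovered, which(mask)))
      msg <- c(msg, "segments must tile every usable bin exactly once")
    bad <- !seg$call %in% c("loss", "neutral", "gain", NA)
    if (any(bad)) msg <- c(msg, "call must be loss/neutral/gain or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Abnormality cutoff calibration
#'
#' Normal fit to control CPA scores and the resulting abnormality cutoff at
#' the (1 - fdr) quantile of that fit: `cutoff = mu + qnorm(1 - fdr) * sigma`.
#' Samples with CPA strictly above the cutoff are abnormal at the configured
#' false-discovery rate. Calibration is performed per modality (e.g. liquid
#' plasma vs FFPE tissue) because noise levels differ.
#'
#' @slot mu,sigma Mean and standard deviation of the control CPA fit.
#' @slot fdr Target type-I error rate (default 0.01).
#' @slot cutoff The abnormality cutoff.
#' @slot lillieforsP Monte-Carlo Lilliefors p-value of the normality check
#'   on the control CPA scores (NA if not computed).
#' @slot modality Free-text modality tag (e.g. "LB", "SB").
#' @export
setClass("CutoffCalibration",
  representation(mu = "numeric", sigma = "numeric", fdr = "numeric",
                 cutoff = "numeric", lillieforsP = "numeric",
                 modality = "character"))

setValidity("CutoffCalibration", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@fdr <= 0 || object@fdr >= 1) msg <- c(msg, "fdr must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Discrete per-bin copy-number feature matrix
#'
#' Samples x usable-bins matrix of discrete copy-number states (-1 loss,
#' 0 neutral, +1 gain) with per-sample class labels, the feature space of the
#' histology classifier. `binIndex` maps columns back to grid bins.
#'
#' @slot states Integer matrix, samples x bins, entries in {-1, 0, 1}.
#' @slot labels Factor of per-sample classes (may be empty for unlabelled
#'   prediction sets).
#' @slot binIndex Integer vector of grid bin indices for the columns.
#' @export
setClass("FeatureMatrix",
  representation(states = "matrix", labels = "factor", binIndex = "integer"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!all(object@states %in% c(-1L, 0L, 1L))) msg <- c(msg, "states must be -1/0/+1")
  if (ncol(object@states) != length(object@binIndex))
    msg <- c(msg, "binIndex must map every column")
  if (length(object@labels) && length(object@labels) != nrow(object@states))
    msg <- c(msg, "labels must match sample count")
  if (length(msg)) msg else TRUE
})

#' Trained histology classifier
#'
#' A fitted multiclass model over discrete per-bin states, by default
#' multinomial logistic regression with ridge penalty (glmnet), with the
#' penalty strength chosen by inner cross-validation.
#'
#' @slot fit The underlying fitted model object.
#' @slot family One of "ridge", "lasso", "enet", "rf", "svm".
#' @slot lambda Selected regularization strength (glmnet families; NA else).
#' @slot classes Class labels in model order.
#' @slot binIndex Grid bin indices of the feature columns.
#' @slot seed Seed used for inner CV fold assignment.
#' @export
setClass("TrainedModel",
  representation(fit = "ANY", family = "character", lambda = "numeric",
                 classes = "character", binIndex = "integer", seed = "integer"))

#' Classifier evaluation report
#'
#' Pooled held-out predictions from leave-one-out cross-validation together
#' with one-vs-all ROC AUCs per class, their mean (mAUC) and argmax accuracy.
#'
#' @slot classAUC Named numeric of per-class one-vs-all AUCs.
#' @slot mAUC Mean of the per-class AUCs.
#' @slot accuracy Fraction of samples whose argmax class matches the label.
#' @slot predictions `data.frame` with one row per sample: `label`,
#'   `predicted`, `flat` and one probability column per class.
#' @export
setClass("EvalReport",
  representation(classAUC = "numeric", mAUC = "numeric", accuracy = "numeric",
                 predictions = "data.frame"))
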