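# Readers/writers for the package's tab-delimited table dialects. All
# formats round-trip losslessly; malformed input is rejected with the
# offending detail.

.checkHeader <- function(path, expected) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, expected))
    stop("unexpected header in ", path, ": got '",
         paste(hdr, collapse = " "), "', expected '",
         paste(expected, collapse = " "), "'")
}

#' Write / read a bin-ratio table
#'
#' Dialect: tab-delimited `chrom start end ratio` (0-based half-open
#' coordinates), one file per sample; masked or missing bins are emitted
#' with an empty ratio field.
#'
#' @param profile A [CopyNumberProfile].
#' @param path Output file.
#' @export
writeBinRatios <- function(profile, path) {
  grid <- profile@grid
  gr <- grid@bins
  r <- ratios(profile)
  r[!informativeBins(profile)] <- NA
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
                   end = end(gr), ratio = sprintf("%.17g", r))
  df$ratio[is.na(r)] <- ""
  writeLines(c("chrom\tstart\tend\tratio",
               sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end, df$ratio)),
             path)
  invisible(path)
}

#' @rdname writeBinRatios
#' @param grid The [BinGrid] the table is aligned to.
#' @param sampleId Sample identifier for the returned profile.
#' @return `readBinRatios()` returns a [CopyNumberProfile].
#' @export
readBinRatios <- function(path, grid, sampleId = basename(path)) {
  .checkHeader(path, c("chrom", "start", "end", "ratio"))
  df <- read.delim(path, colClasses = c("character", "integer", "integer",
                                        "character"))
  if (nrow(df) != nBins(grid)) stop("row count does not match grid")
  gr <- grid@bins
  if (!identical(df$chrom, as.character(seqnames(gr))) ||
      !identical(df$start, start(gr) - 1L) || !identical(df$end, end(gr)))
    stop("bin coordinates do not match grid")
  r <- suppressWarnings(as.numeric(df$ratio))
  bad <- which(df$ratio != "" & is.na(r))
  if (length(bad)) stop("malformed ratio at line ", bad[1] + 1)
  copyNumberProfile(sampleId, r, grid)
}

#' Write / read a grid file
#'
#' Dialect: tab-delimited `chrom start end mask weight` (0-based half-open).
#'
#' @param grid A [BinGrid].
#' @param path File path.
#' @export
writeGridFile <- function(grid, path) {
  gr <- grid@bins
  writeLines(c("chrom\tstart\tend\tmask\tweight",
               sprintf("%s\t%d\t%d\t%d\t%.17g", as.character(seqnames(gr)),
                       start(gr) - 1, end(gr), as.integer(binMask(grid)),
                       binWeights(grid))),
             path)
  invisible(path)
}

#' @rdname writeGridFile
#' @param binWidth Bin width of the stored grid (bp).
#' @return `readGridFile()` returns a [BinGrid].
#' @export
readGridFile <- function(path, binWidth = 100000L) {
  .checkHeader(path, c("chrom", "start", "end", "mask", "weight"))
  df <- read.delim(path, colClasses = c("character", "integer", "integer",
                                        "integer", "numeric"))
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  mcols(gr)$mask <- df$mask == 1
  mcols(gr)$weight <- df$weight
  new("BinGrid", bins = gr, binWidth = as.integer(binWidth))
}

#' Write / read a segment table
#'
#' BED-like dialect with header: `chrom start end start_bin end_bin n_bins
#' mean_ratio z call` (0-based half-open genomic coordinates; empty z/call
#' for unscored segments).
#'
#' @param segset A [SegmentSet].
#' @param path File path.
#' @export
writeSegments <- function(segset, path) {
  seg <- segset@segments
  gr <- segset@grid@bins
  z <- ifelse(is.na(seg$z), "", sprintf("%.17g", seg$z))
  cl <- ifelse(is.na(seg$call), "", seg$call)
  writeLines(c("chrom\tstart\tend\tstart_bin\tend_bin\tn_bins\tmean_ratio\tz\tcall",
               sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%.17g\t%s\t%s",
                       seg$chrom, start(gr)[seg$startBin] - 1,
                       end(gr)[seg$endBin], seg$startBin, seg$endBin,
                       seg$nBins, seg$meanRatio, z, cl)),
             path)
  invisible(path)
}

#' @rdname writeSegments
#' @param grid The [BinGrid] the bin indices refer to.
#' @param sampleId Sample identifier.
#' @return `readSegments()` returns a [SegmentSet].
#' @export
readSegments <- function(path, grid, sampleId = basename(path)) {
  .checkHeader(path, c("chrom", "start", "end", "start_bin", "end_bin",
                       "n_bins", "mean_ratio", "z", "call"))
  df <- read.delim(path, colClasses = c("character", "integer", "integer",
                                        "integer", "integer", "integer",
                                        "numeric", "character", "character"))
  seg <- data.frame(
    chrom = df$chrom, startBin = df$start_bin, endBin = df$end_bin,
    nBins = df$n_bins, lengthBp = df$n_bins * grid@binWidth,
    meanRatio = df$mean_ratio,
    z = suppressWarnings(ifelse(df$z == "", NA_real_, as.numeric(df$z))),
    call = ifelse(df$call == "", NA_character_, df$call))
  new("SegmentSet", sampleId = sampleId, segments = seg, grid = grid)
}

#' Write / read fragment read records
#'
#' Dialect: tab-delimited `bin_index insert_size origin`.
#'
#' @param reads Read records `data.frame`.
#' @param path File path.
#' @export
writeReadRecords <- function(reads, path) {
  writeLines(c("bin_index\tinsert_size\torigin",
               sprintf("%d\t%d\t%s", reads$bin, as.integer(reads$insertSize),
                       reads$origin)),
             path)
  invisible(path)
}

#' @rdname writeReadRecords
#' @return `readReadRecords()` returns the read records `data.frame`.
#' @export
readReadRecords <- function(path) {
  .checkHeader(path, c("bin_index", "insert_size", "origin"))
  df <- read.delim(path, colClasses = c("integer", "integer", "character"))
  data.frame(bin = df$bin_index, insertSize = df$insert_size,
             origin = df$origin)
}

#' Write / read a feature matrix with its label sidecar
#'
#' Dialect: tab-delimited samples x bins table whose first column is the
#' sample index and whose header names the grid bin indices; labels go to a
#' `<path>.labels` sidecar (`sample label` pairs).
#'
#' @param fm A [FeatureMatrix].
#' @param path File path.
#' @export
writeFeatureMatrix <- function(fm, path) {
  hdr <- paste(c("sample", paste0("bin", fm@binIndex)), collapse = "\t")
  body <- vapply(seq_len(nrow(fm@states)), function(i)
    paste(c(i, fm@states[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  if (length(fm@labels))
    writeLines(c("sample\tlabel",
                 sprintf("%d\t%s", seq_along(fm@labels),
                         as.character(fm@labels))),
               paste0(path, ".labels"))
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @return `readFeatureMatrix()` returns a [FeatureMatrix].
#' @export
readFeatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (names(df)[1] != "sample") stop("unexpected header in ", path)
  binIndex <- as.integer(sub("^bin", "", names(df)[-1]))
  st <- as.matrix(df[, -1, drop = FALSE])
  dimnames(st) <- NULL
  storage.mode(st) <- "integer"
  labPath <- paste0(path, ".labels")
  labels <- if (file.exists(labPath))
    factor(read.delim(labPath)$label)
  else factor(character())
  new("FeatureMatrix", states = st, labels = labels, binIndex = binIndex)
}

#' Write a CPA report table
#'
#' Dialect: tab-delimited `sample_id modality n_segments cpa cutoff
#' abnormal`.
#'
#' @param report Data frame from [classifyAbnormal()].
#' @param path File path.
#' @export
writeCpaReport <- function(report, path) {
  writeLines(c("sample_id\tmodality\tn_segments\tcpa\tcutoff\tabnormal",
               sprintf("%s\t%s\t%d\t%.17g\t%.17g\t%d", report$sampleId,
                       report$modality, report$nSegments, report$cpa,
                       report$cutoff, as.integer(report$abnormal))),
             path)
  invisible(path)
}
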