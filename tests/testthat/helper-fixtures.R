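# Small in-code fixtures shared across tests.

# tiny two-chromosome grid with explicit mask
tinyGrid <- function(nA = 6, nB = 4, binWidth = 1e5, mask = NULL) {
  g <- binGrid(c(chrA = nA * binWidth, chrB = nB * binWidth),
               binWidth = binWidth)
  if (!is.null(mask)) g <- setGridWeights(g, mask = mask,
                                          weights = ifelse(mask, 1, 0))
  g
}

# panel with prescribed per-bin control values (p x n matrix)
tinyPanel <- function(m, grid) referencePanel(m, grid)

# profile from a plain ratio vector
tinyProfile <- function(r, grid, id = "s") copyNumberProfile(id, r, grid)

# a scored-segment data.frame row
segRow <- function(chrom, startBin, endBin, nBins, lengthBp, meanRatio = 0,
                   z = NA_real_, call = NA_character_) {
  data.frame(chrom = chrom, startBin = startBin, endBin = endBin,
             nBins = nBins, lengthBp = lengthBp, meanRatio = meanRatio,
             z = z, call = call)
}

# independent direct evaluation of the segmental Z-score formula:
# weighted case mean minus mean of weighted control means, over the
# population sd of the weighted control means (loops, no matrix algebra)
oracleZ <- function(caseRatios, controlMatrix, weights, idx) {
  wm <- function(v) {
    s <- 0; sw <- 0
    for (i in idx) { s <- s + weights[i] * v[i]; sw <- sw + weights[i] }
    s / sw
  }
  caseMean <- wm(caseRatios)
  ctrl <- apply(controlMatrix, 1, wm)
  popSd <- sqrt(sum((ctrl - mean(ctrl))^2) / length(ctrl))
  (caseMean - mean(ctrl)) / popSd
}

# exhaustive circular-split search used as the segmentation oracle on
# small instances: max over all arcs (i, j] of the t-like statistic with
# fixed overall population variance
oracleCbsScan <- function(x) {
  n <- length(x)
  sigma2 <- mean((x - mean(x))^2)
  best <- -Inf; bi <- 0; bj <- n
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k == n) next
    inM <- mean(x[(i + 1):j])
    outM <- mean(x[-((i + 1):j)])
    t <- abs(inM - outM) / sqrt(sigma2 * (1 / k + 1 / (n - k)))
    if (t > best) { best <- t; bi <- i; bj <- j }
  }
  list(stat = best, i = bi, j = bj)
}
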