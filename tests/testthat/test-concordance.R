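test_that("smoothing is a centered mean that shrinks at edges", {
  g <- binGrid(c(chr1 = 100e5), binWidth = 1e5)
  ramp <- tinyProfile(0:99, g)
  sm <- smoothProfile(ramp, window = 3)
  # interior bin i of a linear ramp keeps its value
  expect_equal(ratios(sm)[2:99], as.numeric(1:98))
  expect_equal(ratios(sm)[1], 0.5)     # shrunk window (bins 1,2)
  expect_equal(ratios(sm)[100], 98.5)
  # window = 1 is the identity; constant input is unchanged
  expect_equal(ratios(smoothProfile(ramp, 1)), ratios(ramp))
  const <- tinyProfile(rep(0.4, 100), g)
  expect_equal(ratios(smoothProfile(const, 100)), rep(0.4, 100))
  # smoothing preserves the chromosome mean on these inputs
  expect_equal(mean(ratios(sm)), mean(0:99), tolerance = 1e-9)
})

test_that("smoothing never crosses chromosome boundaries", {
  g <- tinyGrid(nA = 6, nB = 4)
  p <- tinyProfile(c(rep(0, 6), rep(10, 4)), g)
  sm <- smoothProfile(p, window = 5)
  expect_true(all(ratios(sm)[1:6] == 0))
  expect_true(all(ratios(sm)[7:10] == 10))
})

test_that("profile correlation and TLS slope behave on exact inputs", {
  g <- binGrid(c(chr1 = 200e5), binWidth = 1e5)
  set.seed(3)
  a <- tinyProfile(rnorm(200, 0, 0.3), g)
  expect_equal(profilePearson(a, a), 1.0)
  neg <- tinyProfile(-ratios(a), g)
  expect_equal(profilePearson(a, neg), -1.0)
  b2 <- tinyProfile(2 * ratios(a), g)
  expect_equal(tlsSlope(a, b2), 2.0, tolerance = 1e-12)
  expect_equal(tlsSlope(a, a), 1.0)
  # reciprocal property on noiseless proportional inputs
  expect_equal(tlsSlope(a, b2) * tlsSlope(b2, a), 1.0, tolerance = 1e-12)
})

test_that("independent noise decorrelates and symmetric TLS recovers the slope", {
  g <- binGrid(c(chr1 = 3000e5), binWidth = 1e5)
  nOk <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    x <- tinyProfile(rnorm(3000), g)
    y <- tinyProfile(rnorm(3000), g)
    if (abs(profilePearson(x, y)) < 0.1) nOk <- nOk + 1
  }
  expect_gte(nOk, 9)
  # equal symmetric noise on both axes around y = 0.5 x
  set.seed(77)
  base <- rnorm(3000, 0, 1)
  ax <- tinyProfile(base + rnorm(3000, 0, 0.1), g)
  ay <- tinyProfile(0.5 * base + rnorm(3000, 0, 0.1), g)
  # closed-form TLS with equal error variances
  expect_equal(tlsSlope(ax, ay), 0.5, tolerance = 0.05)
})

test_that("weighted group summaries match hand arithmetic", {
  s <- weightedGroupSummary(c(0.6, 0.9), c(1, 3))
  expect_equal(s$mean, 0.825, tolerance = 1e-12)
  u <- weightedGroupSummary(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(u$mean, 2.5)
  expect_equal(u$effN, 4)
  expect_equal(u$hi - u$mean, 1.96 * sd(1:4) / 2, tolerance = 1e-9)
  d <- weightedGroupSummary(c(5, 7), c(2, 0))
  expect_true(d$degenerate)
  expect_equal(d$mean, 5)
  expect_error(weightedGroupSummary(1:3, c(0, 0, 0)), "all-zero")
  expect_equal(intervalWeights(0), 1)
  expect_lt(intervalWeights(504), intervalWeights(50))
})

test_that("aberration waves count gain/loss fractions per bin", {
  g <- tinyGrid(nA = 6, nB = 4)
  mkSeg <- function(id, callA) {
    seg <- rbind(segRow("chrA", 1, 6, 6, 6e5, 0.3, z = 5, call = callA),
                 segRow("chrB", 7, 10, 4, 4e5, 0, z = 0, call = "neutral"))
    new("SegmentSet", sampleId = id, segments = seg, grid = g)
  }
  w1 <- aberrationFrequencyWaves(list(mkSeg("a", "gain")), g)
  expect_equal(w1$gainPct[1:6], rep(100, 6))
  expect_equal(w1$signed[7:10], rep(0, 4))
  w2 <- aberrationFrequencyWaves(list(mkSeg("a", "gain"),
                                      mkSeg("b", "loss")), g)
  expect_equal(w2$signed[1:6], rep(0, 6))
  expect_equal(w2$gainPct[1:6], rep(50, 6))
  w0 <- aberrationFrequencyWaves(list(mkSeg("a", "neutral")), g)
  expect_true(all(w0$signed[binMask(g)] == 0))
})

test_that("penetrance-0.5 events produce ~50% waves at n = 200", {
  g <- syntheticGenome(totalBins = 150)
  arm <- binArms(g)
  target <- which(arm == "2q" & binMask(g))
  n <- 200
  set.seed(90)
  sets <- lapply(seq_len(n), function(i) {
    on <- runif(1) < 0.5
    segs <- list()
    for (cn in unique(binChrom(g))) {
      ix <- which(binChrom(g) == cn & binMask(g))
      if (cn == "chr2" && on) {
        qs <- ix[ix %in% target]
        ps <- setdiff(ix, qs)
        segs[[length(segs) + 1]] <- segRow(cn, min(ps), max(ps), length(ps),
                                           length(ps) * 1e5, 0, 0, "neutral")
        segs[[length(segs) + 1]] <- segRow(cn, min(qs), max(qs), length(qs),
                                           length(qs) * 1e5, 0.3, 5, "gain")
      } else {
        segs[[length(segs) + 1]] <- segRow(cn, min(ix), max(ix), length(ix),
                                           length(ix) * 1e5, 0, 0, "neutral")
      }
    }
    new("SegmentSet", sampleId = paste0("s", i),
        segments = do.call(rbind, segs), grid = g)
  })
  w <- aberrationFrequencyWaves(sets, g)
  expect_lt(abs(mean(w$gainPct[target]) / 100 - 0.5),
            3 * sqrt(0.25 / n))
})

test_that("complete-linkage clustering on d = (1 - r)/2 groups shared fingerprints", {
  set.seed(12)
  base <- rnorm(300)
  waves <- list(luad = base + rnorm(300, 0, 0.2),
                lusc = base + rnorm(300, 0, 0.2),
                sclc = rnorm(300))
  hc <- clusterGroups(waves)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))   # NSCLC pair merges first
  # identical waves -> distance 0; anti-correlated -> distance 1
  h2 <- clusterGroups(list(a = base, b = base, c = -base))
  expect_equal(h2$height[1], 0, tolerance = 1e-12)
  expect_equal(h2$height[2], 1, tolerance = 1e-12)
  expect_warning(clusterGroups(list(a = base, b = base + 1e-3 * rnorm(300),
                                    flat = rep(1, 300))),
                 "constant")
})
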