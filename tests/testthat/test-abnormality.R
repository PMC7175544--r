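test_that("segmental Z-scores match hand arithmetic", {
  g <- tinyGrid(nA = 2, nB = 1)
  # 5 controls constant within sample: control segment means are the
  # constants; population sd of {-0.2,-0.1,0,0.1,0.2} = 0.14142...
  m <- matrix(rep(c(-0.2, -0.1, 0, 0.1, 0.2), 3), nrow = 5)
  pan <- tinyPanel(m, g)
  p <- tinyProfile(c(0.3, 0.3, 0.3), g)
  z <- segmentZscore(p, pan, idx = 1:2, weights = rep(1, 3))
  expect_equal(z, 0.3 / sqrt(0.02), tolerance = 1e-12)
  # case mean equal to control mean of means -> 0
  p0 <- tinyProfile(c(0, 0, 0), g)
  expect_equal(segmentZscore(p0, pan, idx = 1:2, weights = rep(1, 3)), 0)
  # translation invariance
  pShift <- tinyProfile(c(0.3, 0.3, 0.3) + 5, g)
  panShift <- tinyPanel(m + 5, g)
  expect_equal(segmentZscore(pShift, panShift, idx = 1:2, rep(1, 3)), z)
})

test_that("Z-scores agree with direct formula evaluation on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    nb <- sample(2:10, 1)
    p <- sample(3:8, 1)
    g <- binGrid(setNames(nb * 1e5, "chrZ"), binWidth = 1e5)
    w <- runif(nb, 0.2, 5)
    g <- setGridWeights(g, weights = w)
    m <- matrix(rnorm(p * nb, 0, 0.2), nrow = p)
    prof <- tinyProfile(rnorm(nb, 0, 0.3), g)
    idx <- sort(sample(nb, sample(1:nb, 1)))
    z <- segmentZscore(prof, tinyPanel(m, g), idx)
    expect_equal(z, oracleZ(ratios(prof), m, w, idx), tolerance = 1e-12)
  }
})

test_that("aberration calls use the |Z| >= 3 boundary", {
  expect_equal(callSegment(3.0), "gain")
  expect_equal(callSegment(-2.99), "neutral")
  expect_equal(callSegment(-5), "loss")
  expect_equal(callSegment(c(-3, 2.999, 0)), c("loss", "neutral", "neutral"))
})

test_that("CPA matches hand-computed segment sets", {
  g <- binGrid(c(chrA = 500e5, chrB = 2500e5), binWidth = 1e5)
  seg <- rbind(
    segRow("chrA", 1, 500, 500, 50e6, 0.4, z = 4, call = "gain"),
    segRow("chrB", 501, 3000, 2500, 250e6, -0.05, z = 0.5, call = "neutral"))
  ss <- new("SegmentSet", sampleId = "hand", segments = seg, grid = g)
  # (4 * 0.5 + 0.5 * 2.5) / 2 with lengths in 100 Mb units
  expect_equal(cpaScore(ss), 1.625, tolerance = 1e-12)
  # all zero Z -> 0
  seg0 <- seg; seg0$z <- 0; seg0$call <- "neutral"
  expect_equal(cpaScore(new("SegmentSet", sampleId = "z0", segments = seg0,
                            grid = g)), 0)
  # undeterminable segments drop from both numerator and n
  segNA <- rbind(
    segRow("chrA", 1, 500, 500, 50e6, 0.4, z = 4, call = "gain"),
    segRow("chrB", 501, 2000, 1500, 150e6, 0, z = 0.5, call = "neutral"),
    segRow("chrB", 2001, 3000, 1000, 100e6, 0, z = NA))
  ssNA <- new("SegmentSet", sampleId = "na", segments = segNA, grid = g)
  expect_equal(cpaScore(ssNA), (4 * 0.5 + 0.5 * 1.5) / 2, tolerance = 1e-12)
})

test_that("CPA changes under segment duplication unless n is held fixed", {
  g <- binGrid(c(chrA = 1000e5), binWidth = 1e5)
  one <- new("SegmentSet", sampleId = "a", segments =
               segRow("chrA", 1, 1000, 1000, 100e6, 0.3, z = 4, call = "gain"),
             grid = g)
  halves <- new("SegmentSet", sampleId = "b", segments = rbind(
    segRow("chrA", 1, 500, 500, 50e6, 0.3, z = 4, call = "gain"),
    segRow("chrA", 501, 1000, 500, 50e6, 0.3, z = 4, call = "gain")),
    grid = g)
  expect_equal(cpaScore(one), 4)
  expect_equal(cpaScore(halves), 2)   # documented n-sensitivity of the score
})

test_that("cutoff calibration places the 1 - fdr normal quantile", {
  set.seed(8)
  x <- rnorm(500, 0.3, 0.1)
  cal <- calibrateCutoff(x, fdr = 0.01, lillieforsMc = 0)
  expect_equal(cal@cutoff, mean(x) + qnorm(0.99) * sd(x), tolerance = 1e-12)
  expect_equal(cal@cutoff, 0.3 + 2.3263 * 0.1, tolerance = 0.02)
  calHalf <- calibrateCutoff(x, fdr = 0.5, lillieforsMc = 0)
  expect_equal(calHalf@cutoff, mean(x), tolerance = 1e-12)
  expect_warning(cal0 <- calibrateCutoff(rep(0.4, 30), lillieforsMc = 0),
                 "degenerate")
  expect_equal(cal0@cutoff, 0.4)
})

test_that("abnormality uses a strict inequality and warns on modality mismatch", {
  cal <- calibrateCutoff(c(rnorm(100, 0.3, 0.1)), lillieforsMc = 0,
                         modality = "LB")
  df <- data.frame(sampleId = c("a", "b"), modality = "LB",
                   cpa = c(cal@cutoff, cal@cutoff + 1e-9))
  out <- classifyAbnormal(df, cal)
  expect_identical(out$abnormal, c(FALSE, TRUE))
  dfSB <- transform(df, modality = "SB")
  expect_warning(classifyAbnormal(dfSB, cal), "modality mismatch")
})

test_that("Monte-Carlo Lilliefors test behaves like a normality test", {
  # strongly exponential sample rejects
  set.seed(21)
  pExp <- lillieforsNormality(rexp(200), nMc = 1000, seed = 3)$p
  expect_lt(pExp, 0.01)
  # normal samples give (roughly uniform) non-extreme p-values
  ps <- vapply(1:20, function(s) {
    set.seed(400 + s)
    lillieforsNormality(rnorm(80), nMc = 400, seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(max(ps), 0.3)
  # small symmetric sample is not rejected
  expect_gt(lillieforsNormality(c(-2, -1, 0, 1, 2), nMc = 500, seed = 1)$p,
            0.05)
  expect_error(lillieforsNormality(rep(1, 10)), "constant")
})

test_that("Monte-Carlo Lilliefors agrees with the analytic approximation", {
  skip_if_not_installed("nortest")
  set.seed(60)
  x <- rnorm(300, 2, 0.5)
  ours <- lillieforsNormality(x, nMc = 4000, seed = 2)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$stat, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$p.value), 0.12)
})

test_that("CPA is invariant under joint translation of case and panel", {
  g <- syntheticGenome(totalBins = 200)
  cc <- cohortConfig(nControls = 20, seed = 13)
  pan <- simulatePanel(g, cc)
  g2 <- applyPanelWeights(g, pan)
  pan <- referencePanel(ratios(pan), g2)
  sim <- simulateCase(g2, defaultFingerprints(0.9)$LUSC, 0.3, cc, seed = 4)
  sp <- segmentationParams(seed = 6)
  ss <- scoreSegments(segmentProfile(sim$profile, sp), sim$profile, pan)
  shift <- copyNumberProfile("s", ratios(sim$profile) + 0.7, g2)
  panShift <- referencePanel(ratios(pan) + 0.7, g2)
  ssShift <- scoreSegments(segmentProfile(shift, sp), shift, panShift)
  expect_equal(cpaScore(ssShift), cpaScore(ss), tolerance = 1e-9)
})
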