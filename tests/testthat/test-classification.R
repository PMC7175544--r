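test_that("discretization applies the segment call / threshold rules", {
  g <- tinyGrid(nA = 6, nB = 4)
  seg <- rbind(segRow("chrA", 1, 6, 6, 6e5, 0.3, z = 5, call = "gain"),
               segRow("chrB", 7, 10, 4, 4e5, 0, z = 0, call = "neutral"))
  ss <- new("SegmentSet", sampleId = "s", segments = seg, grid = g)
  fm <- discretizeFeatures(list(ss), g, labels = "LUAD")
  expect_equal(as.integer(states(fm)[1, ]), c(rep(1L, 6), rep(0L, 4)))

  # continuous array-style states with the symmetric +-0.1 threshold
  tt <- list(states = matrix(c(0.25, -0.09, 0.09, -0.3, 0, 0.11,
                               rep(0, 4)), nrow = 1),
             labels = factor("SCLC"), binIndex = which(binMask(g)))
  fmc <- discretizeFeatures(tt, g)
  expect_equal(as.integer(states(fmc)[1, 1:6]), c(1L, 0L, 0L, -1L, 0L, 1L))

  # discretization is invariant to monotone amplitude rescaling that
  # preserves call boundaries
  tt2 <- tt; tt2$states <- tt$states * 3
  keep <- abs(tt$states) > 0.1 | abs(tt2$states) <= 0.1
  expect_equal(states(discretizeFeatures(tt2, g))[1, keep],
               states(fmc)[1, keep])
})

test_that("balanced subsampling draws min-class-size samples per class", {
  labels <- factor(rep(c("LUAD", "LUSC", "SCLC"), times = c(424, 351, 68)))
  ix <- balancedSubsample(labels, seed = 4)
  expect_equal(length(ix), 204)
  expect_true(all(table(labels[ix]) == 68))
  expect_identical(ix, balancedSubsample(labels, seed = 4))
  expect_false(identical(ix, balancedSubsample(labels, seed = 5)))
  bal <- factor(rep(c("A", "B"), each = 10))
  expect_equal(sort(balancedSubsample(bal, 1)), 1:20)
})

test_that("rocAuc counts concordant pairs with midrank tie handling", {
  expect_equal(rocAuc(c(0.9, 0.7, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(c(0.9, 0.7, 0.4, 0.2), c(0, 0, 1, 1)), 0.0)
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAuc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "both classes")
})

test_that("rocAuc matches an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (rep in 1:10) {
    sc <- round(rnorm(40), 1)   # force ties
    lb <- rbinom(40, 1, 0.4)
    if (length(unique(lb)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(lb, sc,
                                                 direction = "<")))
    expect_equal(rocAuc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("ridge training separates clean fingerprints and respects the penalty", {
  g <- syntheticGenome(totalBins = 250)
  cc <- cohortConfig(seed = 3)
  tt <- simulateTrainingTable(g, defaultFingerprints(0.95), nPerClass = 15,
                              config = cc)
  fm <- discretizeFeatures(tt, g)
  mod <- trainModel(fm, seed = 2)
  pred <- predictClass(mod, fm)
  expect_gt(mean(pred$predicted == as.character(classLabels(fm))), 0.95)
  probs <- as.matrix(pred[, mod@classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)

  # larger ridge penalty never increases the coefficient norm
  norms <- vapply(c(0.01, 0.1, 1, 10), function(lam) {
    co <- glmnet::glmnet(states(fm), classLabels(fm), family = "multinomial",
                         alpha = 0, lambda = lam, standardize = FALSE)$beta
    sqrt(sum(vapply(co, function(b) sum(b^2), numeric(1))))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))

  # all-zero features -> near-uniform probabilities on balanced classes
  fm0 <- new("FeatureMatrix", states = matrix(0L, 15, ncol(states(fm))),
             labels = factor(rep(c("LUAD", "LUSC", "SCLC"), 5)),
             binIndex = fm@binIndex)
  p0 <- predictClass(trainModel(fm0, seed = 1), fm0)
  expect_true(all(p0$flat))
  expect_equal(as.numeric(as.matrix(p0[, mod@classes])),
               rep(1 / 3, 45), tolerance = 0.05)
})

test_that("flat profiles are flagged and fall to the quietest class", {
  g <- syntheticGenome(totalBins = 250)
  cc <- cohortConfig(seed = 23)
  # LUAD carries the weakest fingerprint, so an aberration-free row looks
  # most LUAD-like -- the behaviour observed for flat plasma profiles
  fps <- defaultFingerprints()
  fps$LUAD$penetrance <- 0.25
  fps$LUSC$penetrance <- 0.9
  fps$SCLC$penetrance <- 0.9
  tt <- simulateTrainingTable(g, fps, nPerClass = 12, config = cc)
  fm <- discretizeFeatures(tt, g)
  mod <- trainModel(fm, seed = 3)
  flat <- new("FeatureMatrix", states = matrix(0L, 1, ncol(states(fm))),
              labels = factor("LUSC"), binIndex = fm@binIndex)
  pr <- predictClass(mod, flat)
  expect_true(pr$flat[1])
  expect_equal(pr$predicted[1], "LUAD")
})

test_that("LOOV is deterministic and collapses to chance under permuted labels", {
  g <- syntheticGenome(totalBins = 200)
  cc <- cohortConfig(seed = 31)
  tt <- simulateTrainingTable(g, defaultFingerprints(0.9), nPerClass = 20,
                              config = cc)
  fm <- discretizeFeatures(tt, g)
  lambdaGrid <- 10^seq(2, -2, length.out = 5)
  r1 <- loovEvaluate(fm, lambdaGrid = lambdaGrid, seed = 5)
  r2 <- loovEvaluate(fm, lambdaGrid = lambdaGrid, seed = 5)
  expect_identical(r1@predictions, r2@predictions)
  expect_gt(r1@mAUC, 0.9)
  expect_equal(r1@mAUC, mean(r1@classAUC))

  perm <- fm
  perm@labels <- { set.seed(6); sample(fm@labels) }
  rp <- loovEvaluate(perm, lambdaGrid = lambdaGrid, seed = 5)
  expect_lt(rp@mAUC, r1@mAUC - 0.2)    # signal destroyed
  expect_lt(abs(rp@mAUC - 0.5), 0.2)   # near chance at n = 60
})

test_that("binary SCLC-vs-NSCLC grouping uses p(SCLC) exactly", {
  pred <- data.frame(label = c("SCLC", "LUAD", "LUSC", "SCLC"),
                     predicted = c("SCLC", "LUAD", "SCLC", "SCLC"),
                     flat = FALSE,
                     LUAD = c(0.1, 0.6, 0.2, 0.2),
                     LUSC = c(0.1, 0.3, 0.3, 0.1),
                     SCLC = c(0.8, 0.1, 0.5, 0.7))
  bg <- binaryGrouping(pred)
  expect_equal(bg$auc, rocAuc(pred$SCLC, pred$label == "SCLC"))
  expect_equal(bg$accuracy, 3 / 4)
})

test_that("coefficient report surfaces the discriminative arms", {
  g <- syntheticGenome(totalBins = 250)
  cc <- cohortConfig(seed = 41)
  fps <- list(
    LUAD = data.frame(arm = "9p", direction = "loss", penetrance = 1),
    SCLC = data.frame(arm = "1p", direction = "gain", penetrance = 1))
  tt <- simulateTrainingTable(g, fps, nPerClass = 20, config = cc)
  fm <- discretizeFeatures(tt, g)
  mod <- trainModel(fm, seed = 7)
  rep1 <- coefficientReport(mod, g, topK = 8)
  sclcTop <- rep1[rep1$class == "SCLC", ]
  expect_true("1p" %in% sclcTop$arm)
  expect_identical(rep1, coefficientReport(mod, g, topK = 8))
})
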