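# Histology classification from discrete per-bin copy-number states:
# feature discretization (loss -1 / neutral 0 / gain +1, which partly
# sidelines tumor fraction as a source of variability), class-balanced
# subsampling, ridge-penalized multinomial logistic regression with inner
# CV for the penalty strength, leave-one-out evaluation with one-vs-all
# ROC, and coefficient reporting.

#' Discretize profiles or continuous states into per-bin features
#'
#' Every usable bin of every sample is assigned the discrete state of its
#' covering segment: from called segment sets, gain -> +1, loss -> -1,
#' neutral -> 0; from array-style continuous segment states, a symmetric
#' log2 threshold (default +-0.1) is applied. Bins covered by no segment
#' (e.g. missing in that sample) become 0 with a warning.
#'
#' @param x Either a list of scored [SegmentSet]s or a continuous training
#'   table as returned by [simulateTrainingTable()] (list with `states`,
#'   `labels`, `binIndex`).
#' @param grid A [BinGrid] (defines the shared usable-bin feature space).
#' @param threshold Symmetric log2 threshold for continuous states.
#' @param labels Optional per-sample labels (for segment-set input).
#' @return A [FeatureMatrix].
#' @export
discretizeFeatures <- function(x, grid, threshold = 0.1, labels = NULL) {
  usable <- which(binMask(grid))
  if (is.list(x) && !is.null(x$states)) {
    stopifnot(identical(x$binIndex, usable))
    st <- matrix(0L, nrow(x$states), ncol(x$states))
    st[x$states > threshold] <- 1L
    st[x$states < -threshold] <- -1L
    labels <- x$labels
  } else {
    stopifnot(all(vapply(x, is, TRUE, "SegmentSet")))
    st <- matrix(0L, length(x), length(usable))
    uncovered <- FALSE
    for (s in seq_along(x)) {
      seg <- x[[s]]@segments
      row <- rep(NA_integer_, nBins(grid))
      for (k in seq_len(nrow(seg))) {
        v <- switch(seg$call[k], gain = 1L, loss = -1L, 0L)
        if (is.na(seg$call[k])) v <- 0L
        row[seg$startBin[k]:seg$endBin[k]] <- v
      }
      if (anyNA(row[usable])) uncovered <- TRUE
      row[is.na(row)] <- 0L
      st[s, ] <- row[usable]
    }
    if (uncovered) warning("bins covered by no segment set to neutral (0)")
    if (is.null(labels)) labels <- factor(rep(NA_character_, length(x)))
  }
  new("FeatureMatrix", states = st, labels = factor(labels),
      binIndex = usable)
}

#' @rdname FeatureMatrix-class
#' @export
setMethod("states", "FeatureMatrix", function(x) x@states)

#' @rdname FeatureMatrix-class
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname FeatureMatrix-class
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@states), "samples x",
      ncol(object@states), "bins;",
      if (length(object@labels)) paste(levels(object@labels), collapse = "/")
      else "unlabelled", "\n")
})

#' Subset a feature matrix by sample
#' @param fm A [FeatureMatrix].
#' @param i Row (sample) indices.
#' @export
subsetSamples <- function(fm, i) {
  new("FeatureMatrix", states = fm@states[i, , drop = FALSE],
      labels = droplevels(fm@labels[i]), binIndex = fm@binIndex)
}

#' Class-balanced subsample
#'
#' Draws, without replacement, `min(table(labels))` samples from every class
#' (e.g. 68 per class from a 424/351/68 cohort, giving n = 204).
#'
#' @param labels Factor (or character) of class labels.
#' @param seed Seed.
#' @return Integer vector of selected sample indices (sorted).
#' @export
balancedSubsample <- function(labels, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class in labels")
  k <- min(tab)
  withSeed(seed, {
    sort(unlist(lapply(levels(labels), function(cl) {
      ix <- which(labels == cl)
      sample(ix, k)
    })))
  })
}

.glmnetAlpha <- c(ridge = 0, enet = 0.5, lasso = 1)

#' Train a histology classifier
#'
#' Default family is multinomial logistic regression with ridge penalty
#' (glmnet, `alpha = 0`); `"enet"` and `"lasso"` switch the penalty,
#' `"rf"` (randomForest) and `"svm"` (e1071, probability outputs) complete
#' the comparison harness. For glmnet families the penalty strength is
#' chosen by inner 5-fold cross-validation over a log-spaced grid
#' (1e-3 to 1e3 by default).
#'
#' @param fm A labelled [FeatureMatrix].
#' @param family One of "ridge", "enet", "lasso", "rf", "svm".
#' @param lambdaGrid Candidate penalty strengths (glmnet families).
#' @param nFolds Inner CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return A [TrainedModel].
#' @export
trainModel <- function(fm, family = "ridge",
                       lambdaGrid = 10^seq(3, -3, length.out = 7),
                       nFolds = 5, seed = 1L) {
  y <- fm@labels
  if (nlevels(y) < 2) stop("need at least two classes to train")
  x <- fm@states
  if (all(x == x[1, 1])) {
    # degenerate constant features: intercept-only model, class priors
    fit <- structure(list(prior = prop.table(table(y))), class = "priorFit")
    return(new("TrainedModel", fit = fit, family = family,
               lambda = NA_real_, classes = levels(y),
               binIndex = fm@binIndex, seed = as.integer(seed)))
  }
  if (family %in% names(.glmnetAlpha)) {
    al <- .glmnetAlpha[[family]]
    foldid <- withSeed(seed, sample(rep_len(seq_len(nFolds), length(y))))
    # class-balanced observation weights: the fit is never driven by class
    # priors, so e.g. leave-one-out class depletion cannot bias held-out
    # probabilities
    wts <- 1 / as.numeric(table(y)[y])
    wts <- wts * length(y) / sum(wts)
    cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = al,
                            lambda = lambdaGrid, foldid = foldid,
                            weights = wts,
                            standardize = FALSE, keep = FALSE)
    fit <- cv$glmnet.fit
    lam <- cv$lambda.min
  } else if (family == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("family 'rf' needs the randomForest package")
    fit <- withSeed(seed, randomForest::randomForest(x, y))
    lam <- NA_real_
  } else if (family == "svm") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("family 'svm' needs the e1071 package")
    fit <- withSeed(seed, e1071::svm(x, y, probability = TRUE))
    lam <- NA_real_
  } else stop("unknown family: ", family)
  new("TrainedModel", fit = fit, family = family, lambda = lam,
      classes = levels(y), binIndex = fm@binIndex, seed = as.integer(seed))
}

#' @rdname TrainedModel-class
#' @export
setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", object@family, "over", length(object@binIndex),
      "bins; classes", paste(object@classes, collapse = "/"),
      if (is.finite(object@lambda)) sprintf("; lambda = %.3g", object@lambda)
      else "", "\n")
})

#' Predict class probabilities
#'
#' Returns per-sample class probabilities (summing to 1) and the argmax
#' class. Samples with no detectable aberrations (all-zero feature rows)
#' are still predicted -- they fall to the model's prior-dominant class --
#' but are flagged `flat` so they can be dismissed.
#'
#' @param model A [TrainedModel].
#' @param fm A [FeatureMatrix] on the same bins.
#' @return `data.frame` with `predicted`, `flat`, and one probability
#'   column per class.
#' @export
predictClass <- function(model, fm) {
  if (!identical(fm@binIndex, model@binIndex))
    stop("feature bins do not match the model's bins")
  x <- fm@states
  if (inherits(model@fit, "priorFit")) {
    pr <- matrix(rep(as.numeric(model@fit$prior), each = nrow(x)),
                 nrow = nrow(x), dimnames = list(NULL, model@classes))
  } else if (model@family %in% names(.glmnetAlpha)) {
    pr <- predict(model@fit, newx = x, s = model@lambda, type = "response")
    pr <- pr[, , 1]
  } else if (model@family == "rf") {
    pr <- predict(model@fit, x, type = "prob")
  } else {
    pv <- predict(model@fit, x, probability = TRUE)
    pr <- attr(pv, "probabilities")[, model@classes, drop = FALSE]
  }
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, model@classes))
  pr <- pr[, model@classes, drop = FALSE]
  out <- data.frame(
    predicted = model@classes[max.col(pr, ties.method = "first")],
    flat = rowSums(abs(x)) == 0)
  cbind(out, as.data.frame(pr))
}

#' One-vs-all ROC AUC
#'
#' Area under the ROC curve by the rank (Mann-Whitney) formulation, with
#' midranks for ties -- identical to trapezoidal integration of the
#' empirical ROC.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical (or 0/1) vector flagging the positive class.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated evaluation
#'
#' Fits the model n times, each holding out one sample (balancing, penalty
#' selection and fitting all see only the remaining n - 1), pools the
#' held-out class probabilities, and reports per-class one-vs-all AUCs,
#' their mean (mAUC) and argmax accuracy.
#'
#' @param fm A labelled [FeatureMatrix].
#' @param family Model family (see [trainModel()]).
#' @param lambdaGrid,nFolds,seed Passed to [trainModel()].
#' @return An [EvalReport].
#' @export
loovEvaluate <- function(fm, family = "ridge",
                         lambdaGrid = 10^seq(3, -3, length.out = 7),
                         nFolds = 5, seed = 1L) {
  n <- nrow(fm@states)
  stopifnot(n >= 10)
  y <- fm@labels
  classes <- levels(y)
  probs <- matrix(NA_real_, n, length(classes),
                  dimnames = list(NULL, classes))
  flat <- logical(n)
  for (i in seq_len(n)) {
    train <- subsetSamples(fm, setdiff(seq_len(n), i))
    mod <- trainModel(train, family = family, lambdaGrid = lambdaGrid,
                      nFolds = nFolds, seed = childSeed(seed, i))
    pred <- predictClass(mod, subsetSamples(fm, i))
    probs[i, mod@classes] <- as.numeric(pred[1, mod@classes])
    flat[i] <- pred$flat[1]
  }
  evalReport(probs, y, flat)
}

# assemble an EvalReport from pooled probabilities
evalReport <- function(probs, y, flat = rep(FALSE, nrow(probs))) {
  classes <- colnames(probs)
  aucs <- vapply(classes, function(cl) rocAuc(probs[, cl], y == cl),
                 numeric(1))
  predicted <- classes[max.col(probs, ties.method = "first")]
  new("EvalReport",
      classAUC = aucs, mAUC = mean(aucs),
      accuracy = mean(predicted == as.character(y)),
      predictions = cbind(
        data.frame(label = as.character(y), predicted = predicted,
                   flat = flat),
        as.data.frame(probs)))
}

#' @rdname EvalReport-class
#' @export
setMethod("show", "EvalReport", function(object) {
  cat("EvalReport: mAUC =", round(object@mAUC, 3),
      "accuracy =", round(object@accuracy, 3), "\n  per-class AUC:",
      paste(names(object@classAUC), round(object@classAUC, 3),
            collapse = ", "), "\n")
})

#' SCLC-vs-NSCLC binary grouping
#'
#' Pools the three-class probabilities into the clinically decisive binary
#' task: p(SCLC) against NSCLC (LUAD + LUSC), reporting the ROC AUC and the
#' accuracy of the three-class argmax rule collapsed to the binary
#' distinction.
#'
#' @param report An [EvalReport] (or its `predictions` data frame).
#' @param positive Name of the positive class (default "SCLC").
#' @return List with `auc` and `accuracy`.
#' @export
binaryGrouping <- function(report, positive = "SCLC") {
  pred <- if (is(report, "EvalReport")) report@predictions else report
  stopifnot(positive %in% names(pred))
  isPos <- pred$label == positive
  list(auc = rocAuc(pred[[positive]], isPos),
       accuracy = mean((pred$predicted == positive) == isPos))
}

#' Ranked coefficient report
#'
#' Ranks bins by absolute model coefficient per class (glmnet families) and
#' aggregates to chromosome arms, exposing which loci drive each class.
#'
#' @param model A glmnet-family [TrainedModel].
#' @param grid The [BinGrid] the features live on.
#' @param topK Rows per class (default 10).
#' @return `data.frame` with `class`, `arm`, `bin`, `beta` ranked by
#'   `abs(beta)` within class, plus an arm-level aggregate `data.frame`
#'   in attribute `"arms"`.
#' @export
coefficientReport <- function(model, grid, topK = 10) {
  stopifnot(model@family %in% names(.glmnetAlpha))
  co <- predict(model@fit, s = model@lambda, type = "coefficients")
  arms <- binArms(grid)[model@binIndex]
  rows <- list(); armAgg <- list()
  for (cl in model@classes) {
    beta <- as.numeric(co[[cl]])[-1]  # drop intercept
    ord <- order(abs(beta), decreasing = TRUE)[seq_len(min(topK, length(beta)))]
    rows[[cl]] <- data.frame(class = cl, arm = arms[ord],
                             bin = model@binIndex[ord], beta = beta[ord])
    agg <- tapply(beta, arms, mean)
    armAgg[[cl]] <- data.frame(class = cl, arm = names(agg),
                               meanBeta = as.numeric(agg))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "arms") <- do.call(rbind, armAgg)
  out
}
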