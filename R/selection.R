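# selection_classifier: univariate rank-sum filter, Random-Forest
# Gini-importance median rule, cross-validation stability intersection,
# linear SVM.

featureMatrix <- function(x) {
  if (is(x, "DeepFeatureMatrix")) x@values else as.matrix(x)
}

#' Column-wise Wilcoxon rank-sum filter
#'
#' Two-sided rank-sum p-value per feature column: exact (via the Wilcoxon
#' distribution) for tie-free columns when both groups have fewer than 50
#' observations, tie-corrected normal approximation (no continuity
#' correction) otherwise.  A constant column gets p = 1.  The filter mask
#' is strict: `p < pThreshold`.
#'
#' @param features matrix or [DeepFeatureMatrix-class] (rows = patients).
#' @param labels 0/1 vector, both classes present.
#' @param pThreshold strict threshold, default 0.005.
#' @return list with `pValues` and `mask`.
#' @export
univariateFilter <- function(features, labels, pThreshold = 0.005) {
  x <- featureMatrix(features)
  g <- as.integer(labels)
  if (length(unique(g)) < 2L) stop("both classes must be present")
  st <- cpp_ranksum_stats(x, g)
  n1 <- st$n1; n2 <- st$n2; n <- n1 + n2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - st$tieterm / (n * (n - 1)))
  p <- ifelse(sig2 > 0,
              2 * pnorm(-abs(st$u - mu) / sqrt(pmax(sig2, 0))), 1)
  exact <- !st$hasties & n1 < 50 & n2 < 50
  if (any(exact)) {
    u <- st$u[exact]
    pe <- ifelse(u > mu, 1 - pwilcox(u - 1, n1, n2), pwilcox(u, n1, n2))
    p[exact] <- pmin(1, 2 * pe)
  }
  p <- pmin(1, p)
  list(pValues = p, mask = p < pThreshold)
}

#' Random-Forest Gini-importance selection with the median rule
#'
#' Fits a Random Forest (impurity-decrease importances) on the filtered
#' features and keeps the features whose Gini importance is strictly
#' greater than the median importance of the filtered set; with all
#' importances equal nothing survives, with k distinct importances exactly
#' `floor(k/2)` survive.
#'
#' @param filtered matrix restricted to the features that passed the
#'   univariate filter (at least 2 columns).
#' @param labels 0/1 vector.
#' @param numTrees Random-Forest size, default 500.
#' @param seed integer seed (forest growing is randomized).
#' @param mtry variables per split; default `floor(sqrt(p))`.
#' @return list with `importances` (named) and `selected` (logical).
#' @export
giniSelect <- function(filtered, labels, numTrees = 500L, seed = 1L,
                       mtry = NULL) {
  x <- featureMatrix(filtered)
  if (ncol(x) < 2L) stop("empty selection: need at least 2 filtered features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- ranger::ranger(x = x, y = factor(labels, levels = c(0, 1)),
                        num.trees = numTrees, importance = "impurity",
                        mtry = mtry %||% floor(sqrt(ncol(x))),
                        seed = as.integer(seed), num.threads = 1L)
  imp <- fit$variable.importance
  list(importances = imp, selected = imp > median(imp))
}

#' One-shot filter + Gini selection
#'
#' Runs [univariateFilter()] then [giniSelect()] and assembles a
#' [SelectionResult-class] over all feature columns.
#'
#' @inheritParams univariateFilter
#' @inheritParams giniSelect
#' @param fold,round provenance identifiers when called inside CV.
#' @return a [SelectionResult-class].
#' @export
selectFeatures <- function(features, labels, pThreshold = 0.005,
                           numTrees = 500L, seed = 1L, fold = NA_integer_,
                           round = NA_integer_) {
  x <- featureMatrix(features)
  flt <- univariateFilter(x, labels, pThreshold)
  mask <- logical(ncol(x))
  imp <- numeric(0)
  if (sum(flt$mask) >= 2L) {
    keep <- which(flt$mask)
    gs <- giniSelect(x[, keep, drop = FALSE], labels, numTrees, seed)
    mask[keep[gs$selected]] <- TRUE
    imp <- gs$importances
  }
  new("SelectionResult", pValues = flt$pValues, pThreshold = pThreshold,
      importances = imp, selectedMask = mask,
      provenance = data.frame(fold = fold, round = round))
}

#' Stratified cross-validation scheme
#'
#' @param nFolds folds per round (default 10).
#' @param nRounds rounds (default 10).
#' @param seed integer seed for the fold assignments.
#' @return a list describing the scheme.
#' @export
cvScheme <- function(nFolds = 10L, nRounds = 10L, seed = 1L) {
  stopifnot(nFolds >= 1, nRounds >= 1)
  list(nFolds = as.integer(nFolds), nRounds = as.integer(nRounds),
       seed = as.integer(seed))
}

# Stratified fold assignment for one round: within each class, a random
# permutation is dealt round-robin over folds, preserving the class ratio
# per fold within rounding.
foldAssignment <- function(labels, nFolds, seed) {
  fold <- integer(length(labels))
  withSeed(seed, for (cls in unique(labels)) {
    rows <- which(labels == cls)
    fold[rows[sample.int(length(rows))]] <-
      rep_len(seq_len(nFolds), length(rows))
  })
  fold
}

#' Per-fold selection and evaluation over a CV scheme
#'
#' For every fold of every round, fits the filter + Gini selection and a
#' linear SVM on the fold-training portion, and evaluates on the held-out
#' fold.  Degenerate scheme (1 fold, 1 round) fits once on all rows with
#' no held-out evaluation.
#'
#' @param features training-set features (matrix or
#'   [DeepFeatureMatrix-class]).
#' @param labels training-set 0/1 labels.
#' @param scheme a [cvScheme()].
#' @param pThreshold,numTrees see [selectFeatures()].
#' @param cost SVM regularization.
#' @return list with `selections` (list of integer index vectors, one per
#'   fold x round) and `reports` (data.frame of per-fold metrics; empty for
#'   the degenerate scheme).
#' @export
cvSelectEvaluate <- function(features, labels, scheme = cvScheme(),
                             pThreshold = 0.005, numTrees = 500L,
                             cost = 1) {
  x <- featureMatrix(features)
  labels <- as.integer(labels)
  selections <- list()
  reports <- list()
  k <- 0L
  for (r in seq_len(scheme$nRounds)) {
    fold <- if (scheme$nFolds == 1L) rep(1L, length(labels)) else
      foldAssignment(labels, scheme$nFolds, scheme$seed + 131L * r)
    for (f in seq_len(scheme$nFolds)) {
      k <- k + 1L
      trainRows <- if (scheme$nFolds == 1L) seq_along(labels) else
        which(fold != f)
      sel <- selectFeatures(x[trainRows, , drop = FALSE],
                            labels[trainRows], pThreshold, numTrees,
                            seed = scheme$seed + 977L * k,
                            fold = f, round = r)
      selections[[k]] <- which(sel@selectedMask)
      testRows <- which(fold == f)
      if (scheme$nFolds > 1L && length(selections[[k]]) >= 1L &&
          length(unique(labels[testRows])) == 2L) {
        model <- trainSvm(x[trainRows, selections[[k]], drop = FALSE],
                          labels[trainRows], cost = cost,
                          selectedIdx = selections[[k]])
        sc <- decisionScores(model, x[testRows, , drop = FALSE])
        rep <- evaluateScores(sc, labels[testRows])
        reports[[length(reports) + 1L]] <- data.frame(
          round = r, fold = f, auc = rep@auc, accuracy = rep@accuracy,
          sensitivity = rep@sensitivity, specificity = rep@specificity,
          precision = rep@precision)
      }
    }
  }
  list(selections = selections,
       reports = if (length(reports)) do.call(rbind, reports) else
         data.frame())
}

#' Stable features: intersection across all CV selections
#'
#' Returns the features selected in every fold of every round; a feature
#' missed even once is excluded.  An empty intersection is an error that
#' reports per-fold selection sizes.
#'
#' @inheritParams cvSelectEvaluate
#' @return integer vector of stable feature indices, with the per-fold
#'   `selections` attached as an attribute.
#' @export
stableFeatures <- function(features, labels, scheme = cvScheme(),
                           pThreshold = 0.005, numTrees = 500L) {
  cv <- cvSelectEvaluate(features, labels, scheme, pThreshold, numTrees)
  stable <- Reduce(intersect, cv$selections)
  if (!length(stable))
    stop("empty stable selection: no feature survived all ",
         length(cv$selections), " folds (per-fold sizes: ",
         paste(lengths(cv$selections), collapse = ", "), ")")
  structure(sort(stable), selections = cv$selections)
}

#' Train a linear SVM on selected features
#'
#' Features are standardized with training statistics (constant features
#' get unit scale) and a linear SVM with fixed regularization `cost` is
#' fitted; decision scores are signed distances with positive values
#' pointing to class 1.
#'
#' @param x training matrix restricted to the selected features.
#' @param labels 0/1 vector containing both classes.
#' @param cost regularization parameter C, default 1.
#' @param selectedIdx original column indices of `x` (defaults to
#'   `1:ncol(x)`), kept so the model can score full feature matrices.
#' @return a [TrainedIdeModel-class].
#' @export
trainSvm <- function(x, labels, cost = 1, selectedIdx = seq_len(ncol(x))) {
  x <- featureMatrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training error: both classes required")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- e1071::svm(xs, factor(labels, levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values toward whichever class it saw first;
  # align the sign with the predicted classes so positive => class 1
  raw <- drop(xs %*% w) + b
  pred <- predict(fit, xs)
  if (mean((raw > 0) == (pred == "1")) < 0.5) { w <- -w; b <- -b }
  new("TrainedIdeModel", weights = unname(w), bias = b,
      center = unname(ctr),
      scale = unname(scl), selectedIdx = as.integer(selectedIdx),
      cost = cost)
}

#' Decision scores of a trained model
#'
#' @param model a [TrainedIdeModel-class].
#' @param features full feature matrix (or one already restricted to the
#'   model's selected columns).
#' @return numeric vector of signed distances; positive = class 1 side.
#' @export
decisionScores <- function(model, features) {
  x <- featureMatrix(features)
  if (ncol(x) != length(model@selectedIdx))
    x <- x[, model@selectedIdx, drop = FALSE]
  xs <- scale(x, model@center, model@scale)
  drop(xs %*% model@weights + model@bias)
}
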