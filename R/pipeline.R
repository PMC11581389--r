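# pipeline_cli: experiment orchestration.  One master seed deterministically
# derives all stage seeds (see stageSeed()), so any stage is independently
# re-runnable; the image layout and deep features are computed once and
# reused by the cross-validation and the permutation test.

#' Experiment configuration
#'
#' Defaults reproduce the study settings where stated: 80/20 stratified
#' hold-out, p < 0.005 univariate filter, 10-fold cross-validation over 10
#' rounds with the all-folds intersection rule, linear SVM, 100 label
#' permutations.
#'
#' @param horizon `"5y"` or `"10y"` (bookkeeping tag).
#' @param trainFraction stratified hold-out training fraction, in (0, 1).
#' @param grid image grid `c(rows, cols)`.
#' @param sigma kernel width (`NULL` = median heuristic).
#' @param pThreshold univariate filter threshold.
#' @param nFolds,nRounds cross-validation scheme.
#' @param numTrees Random-Forest size for the Gini selection.
#' @param cost SVM regularization C.
#' @param nPermutations permutation-test size (0 disables the test).
#' @param permutationMode `"refit"` or `"rescore"`.
#' @param weightsSeed extractor weight seed (`NULL`: derived from `seed`).
#' @param weightsPath optional pretrained-weight RDS (overrides
#'   `weightsSeed`).
#' @param seed master seed; all stage seeds derive from it.
#' @return a validated configuration list.
#' @export
ideConfig <- function(horizon = "5y", trainFraction = 0.8,
                      grid = c(50L, 50L), sigma = NULL, pThreshold = 0.005,
                      nFolds = 10L, nRounds = 10L, numTrees = 500L,
                      cost = 1, nPermutations = 100L,
                      permutationMode = "refit", weightsSeed = NULL,
                      weightsPath = NULL, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("validation error: trainFraction must lie in (0, 1)")
  stopifnot(pThreshold > 0, pThreshold < 1, nFolds >= 1, nRounds >= 1,
            numTrees >= 1, cost > 0, nPermutations >= 0)
  list(horizon = horizon, trainFraction = trainFraction,
       grid = as.integer(grid), sigma = sigma, pThreshold = pThreshold,
       nFolds = as.integer(nFolds), nRounds = as.integer(nRounds),
       numTrees = as.integer(numTrees), cost = cost,
       nPermutations = as.integer(nPermutations),
       permutationMode = match.arg(permutationMode,
                                   c("refit", "rescore")),
       weightsSeed = weightsSeed, weightsPath = weightsPath,
       seed = as.integer(seed))
}

resolveWeights <- function(config) {
  if (!is.null(config$weightsPath)) loadExtractorWeights(config$weightsPath)
  else randomExtractorWeights(config$weightsSeed %||%
                                stageSeed(config$seed, "weights"))
}

#' Fit the full pipeline on a training cohort
#'
#' Imputation (self-referenced), layout fitting, image rendering, deep
#' feature extraction, per-fold selection + evaluation over the CV scheme,
#' the stability intersection and the final linear SVM — all from the
#' training cohort only.
#'
#' @param trainCohort training [ClinicalCohort-class] (may contain missing
#'   values).
#' @param config an [ideConfig()].
#' @param weights optional pre-resolved [ExtractorWeights-class].
#' @return an object of class `ideFit`: list with `layout`, `weights`,
#'   `trainFeatures`, `cv` (fold selections and reports), `stable`
#'   (feature indices), `model`, `trainCohort` (imputed) and `config`.
#' @export
fitIdePipeline <- function(trainCohort, config = ideConfig(),
                           weights = NULL) {
  trainCohort <- imputeMissing(trainCohort)
  if (length(unique(trainCohort@labels)) < 2L)
    stop("training cohort must contain both classes")
  weights <- weights %||% resolveWeights(config)
  ft <- fitTransformImages(trainCohort, config$sigma, config$grid)
  feats <- extractDeepFeatures(ft$images, weights)
  scheme <- cvScheme(config$nFolds, config$nRounds,
                     stageSeed(config$seed, "cv"))
  cv <- cvSelectEvaluate(feats, trainCohort@labels, scheme,
                         config$pThreshold, config$numTrees, config$cost)
  stable <- Reduce(intersect, cv$selections)
  if (!length(stable))
    stop("empty stable selection: no feature survived all ",
         length(cv$selections), " folds (per-fold sizes: ",
         paste(lengths(cv$selections), collapse = ", "), ")")
  stable <- sort(stable)
  model <- trainSvm(feats@values[, stable, drop = FALSE],
                    trainCohort@labels, cost = config$cost,
                    selectedIdx = stable)
  structure(list(layout = ft$layout, weights = weights,
                 trainFeatures = feats, cv = cv, stable = stable,
                 model = model, trainCohort = trainCohort,
                 config = config),
            class = "ideFit")
}

#' @export
print.ideFit <- function(x, ...) {
  cat("ideFit: ", nPatients(x$trainCohort), " training patients, ",
      length(x$stable), " stable deep features\n", sep = "")
  invisible(x)
}

#' Score a cohort with a fitted pipeline
#'
#' Applies the frozen layout and extractor, restricts to the stable
#' features and returns SVM decision scores (positive = IDE side).
#' Missing values are imputed against the fit's training cohort.
#'
#' @param fit an `ideFit`.
#' @param cohort cohort to score.
#' @return numeric decision scores.
#' @export
scoreCohort <- function(fit, cohort) {
  if (any(cohort@missingMask))
    cohort <- imputeMissing(cohort, fit$trainCohort)
  imgs <- transformImages(cohort, fit$layout)
  feats <- extractDeepFeatures(imgs, fit$weights)
  decisionScores(fit$model, feats)
}

#' Run a complete hold-out experiment
#'
#' Stratified split, training-only pipeline fit, hold-out evaluation at
#' the Youden point, CV distribution summary and (optionally) the
#' label-permutation test.  Rerunning with the same configuration and
#' cohort reproduces every artifact.
#'
#' @param cohort full [ClinicalCohort-class].
#' @param config an [ideConfig()].
#' @param outDir optional artifact directory (layout JSON, evaluation
#'   JSON, fitted model JSON, per-stage log).
#' @return list with `split`, `fit`, `testReport`
#'   ([EvaluationReport-class]), `cvSummary`, `permutation`
#'   ([PermutationResult-class] or `NULL`) and `testScores`.
#' @export
runIdeExperiment <- function(cohort, config = ideConfig(), outDir = NULL) {
  t0 <- Sys.time()
  split <- stratifiedHoldout(cohort, config$trainFraction,
                             stageSeed(config$seed, "split"))
  trainC <- subsetCohort(cohort, split@trainIdx)
  fit <- fitIdePipeline(trainC, config)
  testC <- subsetCohort(cohort, split@testIdx)
  if (any(testC@missingMask)) testC <- imputeMissing(testC, fit$trainCohort)
  testImgs <- transformImages(testC, fit$layout)
  testFeats <- extractDeepFeatures(testImgs, fit$weights)
  testScores <- decisionScores(fit$model, testFeats)
  testReport <- evaluateScores(testScores, testC@labels)
  cvSummary <- if (nrow(fit$cv$reports))
    summarizeCv(fit$cv$reports, testReport) else NULL

  permutation <- NULL
  if (config$nPermutations > 0L) {
    # reassemble the cached features in original cohort row order
    xAll <- matrix(NA_real_, nPatients(cohort), 43264L)
    xAll[split@trainIdx, ] <- fit$trainFeatures@values
    xAll[split@testIdx, ] <- testFeats@values
    permutation <- permutationTest(xAll, cohort@labels, split,
                                   config$nPermutations,
                                   stageSeed(config$seed, "permutation"),
                                   config$permutationMode,
                                   config$pThreshold, config$numTrees,
                                   config$cost)
  }
  result <- list(split = split, fit = fit, testReport = testReport,
                 cvSummary = cvSummary, permutation = permutation,
                 testScores = testScores, config = config)
  if (!is.null(outDir)) writeExperimentArtifacts(result, outDir, t0)
  result
}

#' Serialize / restore a trained model as JSON
#'
#' @param model a [TrainedIdeModel-class].
#' @param path JSON path.
#' @return `modelFromJson()` returns the restored model.
#' @export
modelToJson <- function(model, path) {
  jsonlite::write_json(
    list(format = "clinimage-model", version = "1",
         weights = model@weights, bias = model@bias,
         center = model@center, scale = model@scale,
         selectedIdx = model@selectedIdx, cost = model@cost),
    path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname modelToJson
#' @export
modelFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$format[[1]], "clinimage-model"))
  new("TrainedIdeModel", weights = o$weights, bias = o$bias,
      center = o$center, scale = o$scale,
      selectedIdx = as.integer(o$selectedIdx), cost = o$cost)
}

#' Score a cohort from a saved artifact directory
#'
#' Reconstructs the frozen layout, the extractor weights (from the stage
#' seed recorded in the artifacts) and the trained model written by
#' [runIdeExperiment()], and scores a new cohort.
#'
#' @param runDir artifact directory.
#' @param cohort fully observed [ClinicalCohort-class].
#' @return numeric decision scores.
#' @export
scoreFromArtifacts <- function(runDir, cohort) {
  layout <- layoutFromJson(file.path(runDir, "layout.json"))
  model <- modelFromJson(file.path(runDir, "model.json"))
  ev <- jsonlite::read_json(file.path(runDir, "evaluation.json"),
                            simplifyVector = TRUE)
  weights <- if (!is.null(ev$config$weightsSeed))
    randomExtractorWeights(ev$config$weightsSeed)
  else randomExtractorWeights(stageSeed(ev$config$seed, "weights"))
  imgs <- transformImages(cohort, layout)
  decisionScores(model, extractDeepFeatures(imgs, weights))
}

reportToList <- function(r) {
  list(auc = r@auc, threshold = r@threshold, accuracy = r@accuracy,
       sensitivity = r@sensitivity, specificity = r@specificity,
       precision = r@precision, confusion = as.list(r@confusion),
       nPos = r@nPos, nNeg = r@nNeg)
}

writeExperimentArtifacts <- function(result, outDir, t0 = Sys.time()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  layoutToJson(result$fit$layout, file.path(outDir, "layout.json"))
  modelToJson(result$fit$model, file.path(outDir, "model.json"))
  ev <- list(testReport = reportToList(result$testReport),
             cvSummary = result$cvSummary,
             stableFeatures = result$fit$stable,
             extractor = result$fit$weights@fingerprint,
             config = result$config[setdiff(names(result$config),
                                            "weightsPath")])
  if (!is.null(result$permutation)) {
    p <- result$permutation
    ev$permutation <- list(nPermutations = p@nPermutations,
                           observedAuc = p@observedAuc,
                           pValueStandard = p@pValueStandard,
                           pValuePaper = p@pValuePaper, mode = p@mode)
  }
  jsonlite::write_json(ev, file.path(outDir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(result$fit$trainFeatures, file.path(outDir, "train_features.rds"))
  writeLines(c(
    sprintf("master seed: %d", result$config$seed),
    sprintf("stage seeds: split=%d weights=%d cv=%d permutation=%d",
            stageSeed(result$config$seed, "split"),
            stageSeed(result$config$seed, "weights"),
            stageSeed(result$config$seed, "cv"),
            stageSeed(result$config$seed, "permutation")),
    sprintf("elapsed: %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    file.path(outDir, "log.txt"))
  invisible(outDir)
}
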