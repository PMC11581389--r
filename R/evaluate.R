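# evaluation: ROC AUC, Youden operating point, CV metric summaries,
# label-permutation significance, patient-correlation diagnostics.

#' ROC AUC via the rank-sum identity
#'
#' Trapezoidal AUC with ties counted half; equals
#' `U / (n1 * n2)` where U is the Mann-Whitney statistic of the positive
#' class.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels 0/1 vector, both classes present.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index operating point and metrics
#'
#' Sweeps all midpoints between adjacent distinct scores plus the two
#' infinite thresholds, maximizing J = sensitivity + specificity - 1 under
#' the rule `score >= threshold => positive`; ties take the lowest
#' threshold.  Returns the confusion counts and the standard metrics at
#' the optimum.
#'
#' @inheritParams rocAuc
#' @return list with `threshold`, `j`, `confusion` (tp, fp, tn, fn) and
#'   `metrics` (accuracy, sensitivity, specificity, precision).
#' @export
youdenPoint <- function(scores, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (thr in cand) {
    pos <- scores >= thr
    tp <- sum(pos & labels == 1L); fp <- sum(pos & labels == 0L)
    fn <- sum(!pos & labels == 1L); tn <- sum(!pos & labels == 0L)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(threshold = thr, j = j,
                   confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  cf <- best$confusion
  best$metrics <- c(
    accuracy = unname((cf["tp"] + cf["tn"]) / sum(cf)),
    sensitivity = unname(cf["tp"] / (cf["tp"] + cf["fn"])),
    specificity = unname(cf["tn"] / (cf["tn"] + cf["fp"])),
    precision = unname(if ((cf["tp"] + cf["fp"]) > 0)
      cf["tp"] / (cf["tp"] + cf["fp"]) else NA_real_))
  best
}

#' Evaluate decision scores against labels
#'
#' Combines [rocAuc()] and [youdenPoint()] into an
#' [EvaluationReport-class].
#'
#' @inheritParams rocAuc
#' @return an [EvaluationReport-class].
#' @export
evaluateScores <- function(scores, labels) {
  labels <- as.integer(labels)
  yp <- youdenPoint(scores, labels)
  m <- yp$metrics
  new("EvaluationReport", auc = rocAuc(scores, labels),
      threshold = yp$threshold, accuracy = m[["accuracy"]],
      sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
      precision = m[["precision"]], confusion = yp$confusion,
      nPos = sum(labels == 1L), nNeg = sum(labels == 0L))
}

#' Summarize per-fold CV metric distributions
#'
#' Median and quartiles (type-7) of each metric over the fold evaluations;
#' optionally flags whether each hold-out metric falls inside
#' \[q1, q3\].
#'
#' @param reports data.frame of per-fold metrics (from
#'   [cvSelectEvaluate()]).
#' @param holdout optional [EvaluationReport-class] from the hold-out test
#'   set.
#' @return data.frame with one row per metric: `median`, `q1`, `q3` and,
#'   when `holdout` is given, `holdout` and `withinIqr`.
#' @export
summarizeCv <- function(reports, holdout = NULL) {
  metrics <- intersect(c("auc", "accuracy", "sensitivity", "specificity",
                         "precision"), colnames(reports))
  if (nrow(reports) == 0L || !length(metrics))
    stop("no fold reports to summarize")
  out <- do.call(rbind, lapply(metrics, function(m) {
    v <- reports[[m]]
    if (all(is.na(v))) stop("metric '", m, "' is empty")
    q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(metric = m, median = q[2], q1 = q[1], q3 = q[3])
  }))
  if (!is.null(holdout)) {
    hv <- c(auc = holdout@auc, accuracy = holdout@accuracy,
            sensitivity = holdout@sensitivity,
            specificity = holdout@specificity,
            precision = holdout@precision)
    out$holdout <- unname(hv[out$metric])
    out$withinIqr <- out$holdout >= out$q1 & out$holdout <= out$q3
  }
  rownames(out) <- NULL
  out
}

#' Label-permutation significance test
#'
#' Builds a null AUC distribution by permuting the patient labels
#' `nPermutations` times.  In `"refit"` mode (the honest null) the
#' univariate filter, the Gini selection and the SVM are refitted on the
#' training partition under each permutation and the AUC is recomputed on
#' the test partition; in `"rescore"` mode the observed model's test
#' scores are fixed and only the test labels are permuted.  Both add-one
#' estimators are reported: the standard convention counts permuted AUCs
#' greater than or equal to the observed AUC, the study convention counts
#' those less than or equal to it (which approaches 1 for a model far
#' above its null).
#'
#' @param features feature matrix or [DeepFeatureMatrix-class] for all
#'   patients.
#' @param labels 0/1 vector for all patients.
#' @param split a [CohortSplit-class] giving the train/test partition.
#' @param nPermutations number of permutations, default 100.
#' @param seed integer seed.
#' @param mode `"refit"` or `"rescore"`.
#' @param pThreshold,numTrees,cost selection/SVM parameters.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(features, labels, split, nPermutations = 100L,
                            seed = 1L, mode = c("refit", "rescore"),
                            pThreshold = 0.005, numTrees = 500L, cost = 1) {
  mode <- match.arg(mode)
  stopifnot(nPermutations >= 1)
  x <- featureMatrix(features)
  labels <- as.integer(labels)
  tr <- split@trainIdx; te <- split@testIdx

  fitModel <- function(y) {
    sel <- selectFeatures(x[tr, , drop = FALSE], y[tr], pThreshold,
                          numTrees, seed = seed)
    idx <- which(sel@selectedMask)
    if (length(idx) < 1L) return(NULL)
    trainSvm(x[tr, idx, drop = FALSE], y[tr], cost = cost,
             selectedIdx = idx)
  }
  fitScore <- function(y) {
    model <- fitModel(y)
    if (is.null(model)) return(NA_real_)
    rocAuc(decisionScores(model, x[te, , drop = FALSE]), y[te])
  }

  obsModel <- fitModel(labels)
  if (is.null(obsModel))
    stop("empty selection on the observed labels; nothing to test")
  obsScores <- decisionScores(obsModel, x[te, , drop = FALSE])
  observed <- rocAuc(obsScores, labels[te])
  nullAucs <- withSeed(as.integer(seed), vapply(seq_len(nPermutations),
    function(b) {
      yp <- labels[sample.int(length(labels))]
      if (length(unique(yp[tr])) < 2L || length(unique(yp[te])) < 2L)
        return(0.5)  # degenerate permutation: no class structure testable
      if (mode == "refit") {
        a <- fitScore(yp)
        # a permutation killing every feature is a no-signal draw
        if (is.na(a)) 0.5 else a
      } else {
        rocAuc(obsScores, yp[te])
      }
    }, 0))

  new("PermutationResult", nPermutations = as.integer(nPermutations),
      nullAucs = nullAucs, observedAuc = observed,
      pValueStandard = (sum(nullAucs >= observed) + 1) /
        (nPermutations + 1),
      pValuePaper = (sum(nullAucs <= observed) + 1) / (nPermutations + 1),
      seed = as.integer(seed), mode = mode)
}

#' Patient-by-patient Spearman correlation matrices
#'
#' Spearman rho between every pair of patients' feature vectors with
#' p-values from the t approximation; symmetric with unit diagonal.
#' Patients with a constant feature vector yield `NA` correlations and are
#' reported in the `flagged` element rather than raising an error.
#'
#' @param cohort a fully observed [ClinicalCohort-class] (or a numeric
#'   matrix, patients in rows).
#' @return list with `rho` (n x n), `p` (n x n) and `flagged` (integer
#'   indices of constant patients).
#' @export
patientSpearman <- function(cohort) {
  v <- if (is(cohort, "ClinicalCohort")) {
    if (any(cohort@missingMask)) stop("impute before correlating patients")
    cohort@values
  } else as.matrix(cohort)
  stopifnot(nrow(v) >= 2)
  m <- ncol(v)
  rho <- suppressWarnings(cor(t(v), method = "spearman"))
  tstat <- rho * sqrt((m - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = m - 2)
  diag(p) <- 0
  flagged <- which(apply(v, 1, function(r) length(unique(r)) == 1L))
  dimnames(rho) <- dimnames(p) <- NULL
  list(rho = rho, p = p, flagged = flagged)
}
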