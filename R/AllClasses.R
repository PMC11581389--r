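#' @import methods
#' @importFrom stats approx cor median pnorm pt pwilcox quantile rnorm runif
#'   sd setNames
#' @importFrom utils read.csv read.delim write.csv
#' @useDynLib ClinImage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Clinical feature schema
#'
#' Ordered description of the 28 clinical/histopathological features used
#' throughout the package: feature kind (continuous, ordinal, nominal or
#' binary), admissible levels, the numeric code of each level, and the
#' marginal distribution used as simulator default (5-point quantile spec for
#' continuous features, level percentages otherwise).  The stock schema is
#' shipped as a versioned YAML file and loaded with [defaultSchema()].
#'
#' @slot entries list of per-feature descriptors.
#' @slot labelColumn name of the binary outcome column in tabular files.
#' @slot idColumn name of the optional patient-identifier column.
#' @slot version schema version string.
#' @export
setClass("ClinicalSchema",
  representation(entries = "list", labelColumn = "character",
                 idColumn = "character", version = "character"))

setValidity("ClinicalSchema", function(object) {
  e <- object@entries
  if (length(e) != 28L)
    return(sprintf("schema must have exactly 28 entries, got %d", length(e)))
  for (f in e) {
    if (is.null(f$name) || is.null(f$kind))
      return("every schema entry needs a name and a kind")
    if (!f$kind %in% c("continuous", "ordinal", "nominal", "binary"))
      return(sprintf("unknown kind '%s' for feature '%s'", f$kind, f$name))
    if (f$kind == "continuous") {
      if (length(f$quantiles) != 5L || is.unsorted(f$quantiles))
        return(sprintf("feature '%s': quantiles must be 5 nondecreasing values",
                       f$name))
    } else {
      if (length(f$levels) < 2L || length(f$levels) != length(f$codes))
        return(sprintf("feature '%s': levels and codes must match", f$name))
      if (anyDuplicated(f$levels) || anyDuplicated(f$codes))
        return(sprintf("feature '%s': duplicated level or code", f$name))
      if (f$kind == "ordinal" && any(diff(f$codes) <= 0))
        return(sprintf("feature '%s': ordinal codes must be strictly increasing",
                       f$name))
      if (!is.null(f$probs)) {
        if (length(f$probs) != length(f$levels))
          return(sprintf("feature '%s': probs/levels length mismatch", f$name))
        if (abs(sum(f$probs) - 1) > 1e-9)
          return(sprintf("feature '%s': level probabilities must sum to 1",
                         f$name))
      }
    }
  }
  if (anyDuplicated(vapply(e, `[[`, "", "name")))
    return("duplicated feature names")
  TRUE
})

#' Encoded clinical cohort
#'
#' One row per patient, 28 numerically encoded features, a binary invasive
#' disease event (IDE) label and a missingness mask.  Imputed entries are
#' finite; entries flagged missing carry `NA` in `values`.
#'
#' @slot values n x 28 numeric matrix of encoded feature values.
#' @slot labels integer vector, 1 = IDE within the horizon, 0 = no IDE.
#' @slot missingMask n x 28 logical matrix, `TRUE` where the value is missing.
#' @slot patientIds character vector of patient identifiers.
#' @slot horizon follow-up horizon, `"5y"` or `"10y"`.
#' @export
setClass("ClinicalCohort",
  representation(values = "matrix", labels = "integer",
                 missingMask = "matrix", patientIds = "character",
                 horizon = "character"))

setValidity("ClinicalCohort", function(object) {
  n <- nrow(object@values)
  if (n < 2L) return("a cohort needs at least 2 patients")
  if (!all(dim(object@missingMask) == dim(object@values)))
    return("missingMask and values dimensions differ")
  if (length(object@labels) != n || length(object@patientIds) != n)
    return("labels/patientIds length must equal the number of rows")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (!object@horizon %in% c("5y", "10y"))
    return("horizon must be '5y' or '10y'")
  obs <- !object@missingMask
  if (any(!is.finite(object@values[obs])))
    return("observed values must be finite")
  TRUE
})

#' Stratified hold-out split
#'
#' @slot trainIdx,testIdx disjoint 1-based row indices covering all patients.
#' @slot n number of patients in the parent cohort.
#' @slot trainFraction requested training fraction.
#' @export
setClass("CohortSplit",
  representation(trainIdx = "integer", testIdx = "integer", n = "integer",
                 trainFraction = "numeric"))

setValidity("CohortSplit", function(object) {
  idx <- c(object@trainIdx, object@testIdx)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(object@n)))
    return("train and test indices must partition 1..n")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  TRUE
})

#' Per-feature min-max normalization parameters
#'
#' Fitted on training rows only; application clips out-of-range values to
#' \[0, 1\] and maps constant features to 0.
#'
#' @slot min,max per-feature training minimum and maximum.
#' @export
setClass("NormalizationParams",
  representation(min = "numeric", max = "numeric"))

setValidity("NormalizationParams", function(object) {
  if (length(object@min) != length(object@max))
    return("min and max lengths differ")
  if (any(object@max < object@min)) return("max must be >= min")
  TRUE
})

#' Fitted 2D feature layout
#'
#' Train-only artifact of the tabular-to-image step: per-feature min-max
#' normalization, the kernel-PCA embedding of the 28 features into the plane,
#' the convex hull and minimum-area bounding rectangle of the embedded
#' points, the rotation that puts the rectangle's longer side horizontal, and
#' the resulting pixel assignment of every feature on the raster grid.
#' Applying the layout to unseen patients reuses every field unchanged.
#'
#' @slot norm [NormalizationParams-class] fitted on training rows.
#' @slot sigma Gaussian kernel width used for the embedding.
#' @slot coords p x 2 matrix of feature coordinates (kernel-PCA scores).
#' @slot hull ordered hull vertices (counter-clockwise), one row per vertex.
#' @slot hullDegenerate `TRUE` when all features embed collinearly.
#' @slot rectCenter,rectWidth,rectHeight,rectAngle minimum-area bounding
#'   rectangle (angle in degrees, normalized to \[0, 90)).
#' @slot rotation 2 x 2 matrix sending coordinates to the horizontal frame.
#' @slot grid raster resolution `c(rows, cols)`.
#' @slot pixelOfFeature p x 2 integer matrix of 0-based (row, col) pixels,
#'   origin top-left.
#' @slot collisionGroups partition of features sharing a pixel.
#' @export
setClass("FeatureLayout",
  representation(norm = "NormalizationParams", sigma = "numeric",
                 coords = "matrix", hull = "matrix",
                 hullDegenerate = "logical", rectCenter = "numeric",
                 rectWidth = "numeric", rectHeight = "numeric",
                 rectAngle = "numeric", rotation = "matrix",
                 grid = "integer", pixelOfFeature = "matrix",
                 collisionGroups = "list"))

setValidity("FeatureLayout", function(object) {
  p <- nrow(object@coords)
  px <- object@pixelOfFeature
  if (nrow(px) != p) return("pixelOfFeature/coords row mismatch")
  if (any(px[, 1] < 0L) || any(px[, 1] >= object@grid[1]) ||
      any(px[, 2] < 0L) || any(px[, 2] >= object@grid[2]))
    return("pixel coordinates outside the grid")
  members <- sort(unlist(object@collisionGroups))
  if (!identical(members, seq_len(p)))
    return("collisionGroups must partition the feature indices")
  if (object@rectAngle < 0 || object@rectAngle >= 90)
    return("rectangle angle must lie in [0, 90)")
  TRUE
})

#' Set of rasterized patient images
#'
#' @slot pixels rows x cols x n array of intensities in \[0, 1\];
#'   background pixels are exactly 0.
#' @slot patientIds identifier per image.
#' @export
setClass("PatientImageSet",
  representation(pixels = "array", patientIds = "character"))

setValidity("PatientImageSet", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be a rows x cols x n array")
  if (d[3] != length(object@patientIds))
    return("patientIds length must match the number of images")
  if (any(!is.finite(object@pixels))) return("pixel values must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 1)
    return("pixel values must lie in [0, 1]")
  TRUE
})

#' Convolutional feature-extractor weights
#'
#' Weights of the fixed AlexNet front end (conv1 96@11x11 stride 4, max-pool
#' 3x3 stride 2, conv2 256@5x5 pad 2, max-pool 3x3 stride 2).  Weights are
#' either drawn from a seeded Gaussian (the default, fully offline) or loaded
#' from a user-supplied RDS file holding pretrained arrays of the same shape.
#'
#' @slot conv1 11 x 11 x 3 x 96 array.
#' @slot bias1 numeric length 96.
#' @slot conv2 5 x 5 x 96 x 256 array.
#' @slot bias2 numeric length 256.
#' @slot source `"seeded-random"` or `"file"`.
#' @slot seed seed used for random weights (`NA` for file weights).
#' @slot fingerprint digest-like summary identifying the weights.
#' @export
setClass("ExtractorWeights",
  representation(conv1 = "array", bias1 = "numeric", conv2 = "array",
                 bias2 = "numeric", source = "character", seed = "integer",
                 fingerprint = "character"))

setValidity("ExtractorWeights", function(object) {
  if (!identical(dim(object@conv1), c(11L, 11L, 3L, 96L)))
    return("conv1 must be 11 x 11 x 3 x 96")
  if (!identical(dim(object@conv2), c(5L, 5L, 96L, 256L)))
    return("conv2 must be 5 x 5 x 96 x 256")
  if (length(object@bias1) != 96L || length(object@bias2) != 256L)
    return("bias lengths must be 96 and 256")
  TRUE
})

#' Deep feature matrix
#'
#' Flattened pool2 activations, one row per patient, exactly
#' 43,264 = 13 x 13 x 256 columns.
#'
#' @slot values n x 43264 numeric matrix.
#' @slot fingerprint fingerprint of the extractor weights that produced it.
#' @export
setClass("DeepFeatureMatrix",
  representation(values = "matrix", fingerprint = "character"))

setValidity("DeepFeatureMatrix", function(object) {
  if (ncol(object@values) != 43264L)
    return("deep feature matrices have exactly 43264 columns")
  if (any(!is.finite(object@values))) return("entries must be finite")
  TRUE
})

#' Univariate filter + Gini-importance selection result
#'
#' @slot pValues rank-sum p-value per deep feature.
#' @slot pThreshold strict p-value threshold of the filter.
#' @slot importances named Gini importances of the filtered features.
#' @slot selectedMask logical per deep feature; selected features passed the
#'   filter and have importance strictly greater than the median importance
#'   of the filtered set.
#' @slot provenance data.frame of (fold, round) when produced inside CV.
#' @export
setClass("SelectionResult",
  representation(pValues = "numeric", pThreshold = "numeric",
                 importances = "numeric", selectedMask = "logical",
                 provenance = "data.frame"))

setValidity("SelectionResult", function(object) {
  if (length(object@selectedMask) != length(object@pValues))
    return("selectedMask/pValues length mismatch")
  if (any(object@selectedMask & !(object@pValues < object@pThreshold)))
    return("selected features must pass the p-value filter")
  TRUE
})

#' Trained linear SVM over the selected deep features
#'
#' Stores the hyperplane in the standardized feature space together with the
#' training standardization parameters, so scoring new patients needs no
#' refit.  Decision scores are signed distances: positive scores point to the
#' IDE class.
#'
#' @slot weights hyperplane weights, one per selected feature.
#' @slot bias hyperplane intercept.
#' @slot center,scale training standardization parameters.
#' @slot selectedIdx column indices of the selected deep features.
#' @slot cost SVM regularization parameter C.
#' @export
setClass("TrainedIdeModel",
  representation(weights = "numeric", bias = "numeric", center = "numeric",
                 scale = "numeric", selectedIdx = "integer",
                 cost = "numeric"))

setValidity("TrainedIdeModel", function(object) {
  k <- length(object@selectedIdx)
  if (length(object@weights) != k || length(object@center) != k ||
      length(object@scale) != k)
    return("weights/center/scale must have one entry per selected feature")
  TRUE
})

#' Classification performance report
#'
#' AUC plus the Youden-index operating point and the metrics computed there.
#' All metrics are recomputable from the stored confusion counts.
#'
#' @slot auc trapezoidal ROC AUC (ties half-credit).
#' @slot threshold Youden-optimal threshold (score >= threshold => positive).
#' @slot accuracy,sensitivity,specificity,precision operating-point metrics.
#' @slot confusion named counts (tp, fp, tn, fn) at the threshold.
#' @slot nPos,nNeg class sizes.
#' @export
setClass("EvaluationReport",
  representation(auc = "numeric", threshold = "numeric",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", precision = "numeric",
                 confusion = "numeric", nPos = "integer", nNeg = "integer"))

setValidity("EvaluationReport", function(object) {
  cf <- object@confusion
  if (!all(c("tp", "fp", "tn", "fn") %in% names(cf)))
    return("confusion must carry tp, fp, tn, fn")
  chk <- function(a, b) is.na(b) || !is.finite(a) || abs(a - b) < 1e-12
  if (!chk(object@sensitivity, cf["tp"] / (cf["tp"] + cf["fn"])))
    return("sensitivity inconsistent with confusion counts")
  if (!chk(object@specificity, cf["tn"] / (cf["tn"] + cf["fp"])))
    return("specificity inconsistent with confusion counts")
  if (!chk(object@accuracy, (cf["tp"] + cf["tn"]) / sum(cf)))
    return("accuracy inconsistent with confusion counts")
  TRUE
})

#' Label-permutation test result
#'
#' Carries the null AUC distribution and both estimator conventions: the
#' standard one counts permuted AUCs greater than or equal to the observed
#' AUC, the study convention counts permuted AUCs less than or equal to it.
#' Both use the add-one estimator (b + 1) / (N + 1).
#'
#' @slot nPermutations number of label permutations.
#' @slot nullAucs AUC under each permutation.
#' @slot observedAuc AUC with the true labels.
#' @slot pValueStandard (\#\{null >= observed\} + 1) / (N + 1).
#' @slot pValuePaper (\#\{null <= observed\} + 1) / (N + 1).
#' @slot seed RNG seed.
#' @slot mode `"refit"` (selection + SVM refitted per permutation) or
#'   `"rescore"` (fixed model, permuted labels).
#' @export
setClass("PermutationResult",
  representation(nPermutations = "integer", nullAucs = "numeric",
                 observedAuc = "numeric", pValueStandard = "numeric",
                 pValuePaper = "numeric", seed = "integer",
                 mode = "character"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullAucs) != object@nPermutations)
    return("nullAucs length must equal nPermutations")
  for (p in c(object@pValueStandard, object@pValuePaper))
    if (p <= 0 || p > 1) return("p-values must lie in (0, 1]")
  TRUE
})
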