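#' @describeIn ClinicalCohort-class number of patients.
#' @param object a ClinImage object.
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))

#' @describeIn ClinicalCohort-class encoded value matrix.
#' @export
setGeneric("cohortValues", function(object) standardGeneric("cohortValues"))

#' @describeIn ClinicalCohort-class 0/1 label vector.
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))

#' @describeIn ClinicalCohort-class logical missingness mask.
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @describeIn ClinicalCohort-class patient identifiers.
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))

#' @describeIn ClinicalCohort-class follow-up horizon.
#' @export
setGeneric("cohortHorizon", function(object) standardGeneric("cohortHorizon"))

#' @describeIn ClinicalSchema-class feature names in schema order.
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @describeIn FeatureLayout-class 0-based (row, col) pixel per feature.
#' @export
setGeneric("pixelOfFeature", function(object) standardGeneric("pixelOfFeature"))

#' @describeIn FeatureLayout-class groups of features sharing one pixel.
#' @export
setGeneric("collisionGroups",
           function(object) standardGeneric("collisionGroups"))

#' @describeIn DeepFeatureMatrix-class numeric feature matrix.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

setMethod("nPatients", "ClinicalCohort", function(object) nrow(object@values))
setMethod("cohortValues", "ClinicalCohort", function(object) object@values)
setMethod("cohortLabels", "ClinicalCohort", function(object) object@labels)
setMethod("missingMask", "ClinicalCohort", function(object) object@missingMask)
setMethod("patientIds", "ClinicalCohort", function(object) object@patientIds)
setMethod("cohortHorizon", "ClinicalCohort", function(object) object@horizon)

setMethod("featureNames", "ClinicalSchema",
          function(object) vapply(object@entries, `[[`, "", "name"))
setMethod("featureNames", "ClinicalCohort",
          function(object) colnames(object@values))

setMethod("pixelOfFeature", "FeatureLayout",
          function(object) object@pixelOfFeature)
setMethod("collisionGroups", "FeatureLayout",
          function(object) object@collisionGroups)

setMethod("featureValues", "DeepFeatureMatrix", function(object) object@values)
setMethod("nPatients", "DeepFeatureMatrix", function(object)
  nrow(object@values))
setMethod("nPatients", "PatientImageSet", function(object)
  dim(object@pixels)[3])
setMethod("patientIds", "PatientImageSet", function(object) object@patientIds)

setMethod("show", "ClinicalSchema", function(object) {
  kinds <- table(vapply(object@entries, `[[`, "", "kind"))
  cat("ClinicalSchema (version ", object@version, "): ",
      length(object@entries), " features\n  ", sep = "")
  cat(paste(names(kinds), as.integer(kinds), sep = ": "), sep = ", ")
  cat("\n  label column: ", object@labelColumn, "\n", sep = "")
})

setMethod("show", "ClinicalCohort", function(object) {
  cat("ClinicalCohort: ", nPatients(object), " patients x ",
      ncol(object@values), " features (horizon ", object@horizon, ")\n",
      "  IDE cases: ", sum(object@labels == 1L), ", controls: ",
      sum(object@labels == 0L), "\n  missing cells: ",
      sum(object@missingMask), "\n", sep = "")
})

setMethod("show", "CohortSplit", function(object) {
  cat("CohortSplit: ", length(object@trainIdx), " train / ",
      length(object@testIdx), " test (fraction ",
      object@trainFraction, ")\n", sep = "")
})

setMethod("show", "FeatureLayout", function(object) {
  cat("FeatureLayout: ", nrow(object@coords), " features on a ",
      object@grid[1], " x ", object@grid[2], " grid\n",
      "  kernel sigma: ", format(object@sigma, digits = 4),
      "; rectangle ", format(object@rectWidth, digits = 4), " x ",
      format(object@rectHeight, digits = 4), " at ",
      format(object@rectAngle, digits = 4), " deg\n",
      "  occupied pixels: ", length(object@collisionGroups),
      " (collisions: ",
      sum(lengths(object@collisionGroups) > 1L), ")\n", sep = "")
})

setMethod("show", "PatientImageSet", function(object) {
  d <- dim(object@pixels)
  cat("PatientImageSet: ", d[3], " images, ", d[1], " x ", d[2],
      " pixels in [0, 1]\n", sep = "")
})

setMethod("show", "DeepFeatureMatrix", function(object) {
  cat("DeepFeatureMatrix: ", nrow(object@values), " patients x ",
      ncol(object@values), " pool2 activations\n  extractor: ",
      object@fingerprint, "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", sum(object@pValues < object@pThreshold),
      " / ", length(object@pValues), " features pass p < ",
      object@pThreshold, "; ", sum(object@selectedMask),
      " selected above median importance\n", sep = "")
})

setMethod("show", "TrainedIdeModel", function(object) {
  cat("TrainedIdeModel: linear SVM on ", length(object@selectedIdx),
      " deep features (C = ", object@cost, ")\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(paste0("EvaluationReport (n+ = %d, n- = %d)\n",
                     "  AUC %.4f | threshold %.4g\n",
                     "  accuracy %.4f  sensitivity %.4f  specificity %.4f",
                     "  precision %.4f\n"),
              object@nPos, object@nNeg, object@auc, object@threshold,
              object@accuracy, object@sensitivity, object@specificity,
              object@precision))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(paste0("PermutationResult (%d permutations, mode %s)\n",
                     "  observed AUC %.4f\n",
                     "  p (standard, #null >= obs): %.4f\n",
                     "  p (study convention, #null <= obs): %.4f\n"),
              object@nPermutations, object@mode, object@observedAuc,
              object@pValueStandard, object@pValuePaper))
})
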