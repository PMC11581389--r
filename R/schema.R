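# cohort_io: the 28-feature schema and its YAML serialization.

.schemaCache <- new.env(parent = emptyenv())

#' Read a clinical feature schema from YAML
#'
#' The schema file enumerates the 28 features in column order with their
#' kind, admissible levels, numeric codes and marginal distributions (used
#' as simulator defaults).  Level percentages are renormalised to
#' probabilities at load time.
#'
#' @param path path to a schema YAML file.
#' @return a [ClinicalSchema-class].
#' @seealso [defaultSchema()]
#' @export
readSchema <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw$features, function(f) {
    f$name <- as.character(f$name)
    if (f$kind == "continuous") {
      f$quantiles <- as.numeric(f$quantiles)
      f$domain <- range(f$quantiles)
    } else {
      f$levels <- as.character(f$levels)
      f$codes <- as.numeric(f$codes)
      if (!is.null(f$percent)) {
        pct <- as.numeric(f$percent)
        f$probs <- pct / sum(pct)
        f$percent <- NULL
      }
    }
    f
  })
  new("ClinicalSchema", entries = entries,
      labelColumn = raw$label %||% "ide",
      idColumn = raw$id_column %||% "patient_id",
      version = as.character(raw$schema_version %||% "unversioned"))
}

#' Stock 28-feature schema
#'
#' Loads (and caches) the schema shipped with the package: 28 breast-cancer
#' clinical/histopathological features with the marginal distributions of
#' the study population as simulator defaults.
#'
#' @return a [ClinicalSchema-class].
#' @examples
#' sc <- defaultSchema()
#' featureNames(sc)[1:5]
#' @export
defaultSchema <- function() {
  if (is.null(.schemaCache$default)) {
    path <- system.file("extdata", "ide_schema.yaml", package = "ClinImage",
                        mustWork = TRUE)
    .schemaCache$default <- readSchema(path)
  }
  .schemaCache$default
}

schemaEntry <- function(schema, name) {
  i <- match(name, featureNames(schema))
  if (is.na(i)) stop("unknown feature: ", name)
  schema@entries[[i]]
}

#' Encode or decode a categorical level
#'
#' `encodeLevel()` maps a level label of a non-continuous feature to its
#' numeric code; `decodeLevel()` inverts it.  Encoding then decoding is the
#' identity for every admissible level.
#'
#' @param schema a [ClinicalSchema-class].
#' @param feature feature name.
#' @param level,code level label / numeric code.
#' @return the numeric code (resp. level label).
#' @export
encodeLevel <- function(schema, feature, level) {
  f <- schemaEntry(schema, feature)
  if (f$kind == "continuous") stop("'", feature, "' is continuous")
  i <- match(level, f$levels)
  if (anyNA(i))
    stop("value '", level[which(is.na(i))[1]], "' outside the level set of '",
         feature, "'")
  f$codes[i]
}

#' @rdname encodeLevel
#' @export
decodeLevel <- function(schema, feature, code) {
  f <- schemaEntry(schema, feature)
  if (f$kind == "continuous") stop("'", feature, "' is continuous")
  i <- match(code, f$codes)
  if (anyNA(i)) stop("code not admissible for '", feature, "'")
  f$levels[i]
}

featureKinds <- function(schema) vapply(schema@entries, `[[`, "", "kind")
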