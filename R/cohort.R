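# cohort_io: reading, encoding, imputing and splitting clinical cohorts.

#' Construct a clinical cohort from an encoded matrix
#'
#' Low-level constructor used by [readCohort()] and the simulator.  `NA`
#' entries in `values` are taken as missing and recorded in the mask.
#'
#' @param values n x p numeric matrix of encoded feature values.
#' @param labels 0/1 IDE labels.
#' @param patientIds optional identifiers (default `P0001`, ...).
#' @param horizon `"5y"` or `"10y"`.
#' @return a [ClinicalCohort-class].
#' @export
clinicalCohort <- function(values, labels, patientIds = NULL,
                           horizon = "5y") {
  values <- as.matrix(values)
  mask <- is.na(values)
  if (is.null(patientIds))
    patientIds <- sprintf("P%04d", seq_len(nrow(values)))
  new("ClinicalCohort", values = values, labels = as.integer(labels),
      missingMask = mask, patientIds = as.character(patientIds),
      horizon = horizon)
}

#' Read and encode a tabular clinical cohort
#'
#' Reads a CSV/TSV file (UTF-8, header row) with one row per patient and
#' encodes it against `schema`: categorical levels are mapped to their
#' numeric codes, blank or `NA` cells become missing, row order is
#' preserved.  Column order in the file is irrelevant; a missing feature
#' column or an inadmissible level is an error.
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file; missing cells are
#'   empty strings or `"NA"`.
#' @param schema a [ClinicalSchema-class] (default the stock schema).
#' @param horizon follow-up horizon tag for the cohort.
#' @return a [ClinicalCohort-class].
#' @export
readCohort <- function(path, schema = defaultSchema(), horizon = "5y") {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv else read.delim
  df <- reader(path, check.names = FALSE, colClasses = "character",
               na.strings = c("", "NA"), fileEncoding = "UTF-8")
  nm <- featureNames(schema)
  absent <- setdiff(nm, colnames(df))
  if (length(absent))
    stop("schema error: missing feature column(s): ",
         paste(absent, collapse = ", "))
  if (!schema@labelColumn %in% colnames(df))
    stop("schema error: missing label column '", schema@labelColumn, "'")
  unknown <- setdiff(colnames(df), c(nm, schema@labelColumn, schema@idColumn))
  if (length(unknown))
    stop("schema error: unknown column(s): ", paste(unknown, collapse = ", "))

  n <- nrow(df)
  values <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (f in schema@entries) {
    cell <- df[[f$name]]
    if (f$kind == "continuous") {
      v <- suppressWarnings(as.numeric(cell))
      v[!is.na(cell) & is.na(v)] <- NA_real_  # unparseable -> missing
      values[, f$name] <- v
    } else {
      i <- match(trimws(cell), f$levels)
      bad <- which(!is.na(cell) & is.na(i))
      if (length(bad))
        stop("validation error: row ", bad[1], ", feature '", f$name,
             "': value '", cell[bad[1]], "' outside the level set")
      values[, f$name] <- f$codes[i]
    }
  }
  labels <- as.integer(df[[schema@labelColumn]])
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("validation error: label column must be 0/1 with no missing values")
  ids <- if (schema@idColumn %in% colnames(df)) df[[schema@idColumn]] else NULL
  clinicalCohort(values, labels, ids, horizon)
}

#' Write a cohort back to CSV in schema level labels
#'
#' Inverse of [readCohort()]: categorical codes are decoded to their level
#' labels, missing cells become empty strings.
#'
#' @param cohort a [ClinicalCohort-class].
#' @param path output CSV path.
#' @param schema the schema the cohort was encoded with.
#' @export
writeCohortCsv <- function(cohort, path, schema = defaultSchema()) {
  df <- data.frame(patient_id = cohort@patientIds,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (f in schema@entries) {
    v <- cohort@values[, f$name]
    if (f$kind == "continuous") df[[f$name]] <- v
    else df[[f$name]] <- ifelse(is.na(v), NA_character_,
                                f$levels[match(v, f$codes)])
  }
  df[[schema@labelColumn]] <- cohort@labels
  write.csv(df, path, row.names = FALSE, na = "")
}

#' Nearest-neighbour donor imputation
#'
#' Replaces all missing cells of each incomplete patient with the values of
#' the complete reference patient at minimum Euclidean distance, computed
#' over the incomplete patient's observed features after per-feature
#' min-max scaling on the reference cohort.  Complete records are returned
#' unchanged; ties are broken by the lowest donor row index.  Applying the
#' imputation twice equals applying it once.
#'
#' @param cohort cohort to impute.
#' @param reference cohort providing donors (defaults to `cohort` itself);
#'   must contain at least one fully observed record.
#' @return a [ClinicalCohort-class] with an empty missingness mask.
#' @export
imputeMissing <- function(cohort, reference = cohort) {
  refComplete <- which(rowSums(reference@missingMask) == 0L)
  if (!length(refComplete))
    stop("imputation error: reference has no complete record")
  if (!any(cohort@missingMask)) return(cohort)

  refObs <- reference@values
  refObs[reference@missingMask] <- NA
  lo <- apply(refObs, 2, min, na.rm = TRUE)
  hi <- apply(refObs, 2, max, na.rm = TRUE)
  span <- ifelse(hi > lo, hi - lo, 1)
  scaleRow <- function(v) (v - lo) / span

  donors <- reference@values[refComplete, , drop = FALSE]
  donorsScaled <- t(apply(donors, 1, scaleRow))

  values <- cohort@values
  for (i in which(rowSums(cohort@missingMask) > 0L)) {
    obs <- !cohort@missingMask[i, ]
    if (!any(obs)) {
      d2 <- rep(0, nrow(donors))       # nothing observed: first donor wins
    } else {
      x <- scaleRow(cohort@values[i, ])[obs]
      diff <- sweep(donorsScaled[, obs, drop = FALSE], 2, x)
      d2 <- rowSums(diff^2)
    }
    donor <- which.min(d2)             # which.min takes the first minimum
    miss <- cohort@missingMask[i, ]
    values[i, miss] <- donors[donor, miss]
  }
  clinicalCohort(values, cohort@labels, cohort@patientIds, cohort@horizon)
}

#' Stratified hold-out split
#'
#' Samples, within each class, `round(trainFraction * class size)` patients
#' (round half up) into the training partition without replacement; the
#' remainder form the test partition.  Reproducible under `seed`.
#'
#' @param cohort a [ClinicalCohort-class] containing both classes.
#' @param trainFraction training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return a [CohortSplit-class].
#' @examples
#' ## the 10-year study sizes: 251 cases + 375 controls -> 501 train
#' co <- clinicalCohort(matrix(rnorm(626 * 2), 626),
#'                      rep(c(1, 0), c(251, 375)), horizon = "10y")
#' sp <- stratifiedHoldout(co, 0.8, seed = 1)
#' length(sp@trainIdx)
#' @export
stratifiedHoldout <- function(cohort, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  y <- cohort@labels
  if (length(unique(y)) < 2L)
    stop("split error: both classes must be present")
  roundHalfUp <- function(x) floor(x + 0.5)
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    k <- roundHalfUp(trainFraction * length(rows))
    if (k < 1L || k >= length(rows))
      stop("split error: class ", cls,
           " would get an empty train or test partition")
    train <- c(train, withSeed(seed + cls, sort(sample(rows, k))))
  }
  train <- sort(train)
  new("CohortSplit", trainIdx = train,
      testIdx = setdiff(seq_along(y), train),
      n = length(y), trainFraction = trainFraction)
}

#' Subset a cohort by row indices
#'
#' @param cohort a [ClinicalCohort-class].
#' @param idx integer row indices.
#' @return the sub-cohort, row order following `idx`.
#' @export
subsetCohort <- function(cohort, idx) {
  clinicalCohort(cohort@values[idx, , drop = FALSE], cohort@labels[idx],
                 cohort@patientIds[idx], cohort@horizon)
}

#' Serialize / restore a cohort as JSON
#'
#' The container stores the encoded value matrix (missing cells as `null`),
#' labels, identifiers and horizon; `loadCohort()` restores an identical
#' object.
#'
#' @param cohort a [ClinicalCohort-class].
#' @param path JSON path.
#' @return `loadCohort()` returns a [ClinicalCohort-class].
#' @export
saveCohort <- function(cohort, path) {
  v <- cohort@values
  v[cohort@missingMask] <- NA
  obj <- list(format = "clinimage-cohort", version = "1",
              horizon = cohort@horizon, patient_ids = cohort@patientIds,
              labels = cohort@labels, features = colnames(v),
              values = unname(apply(v, 1, as.list, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname saveCohort
#' @export
loadCohort <- function(path) {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$format, "clinimage-cohort"))
  vals <- t(vapply(obj$values, function(r)
    vapply(r, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
           0), numeric(length(obj$features))))
  colnames(vals) <- unlist(obj$features)
  clinicalCohort(vals, unlist(obj$labels), unlist(obj$patient_ids),
                 obj$horizon)
}
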