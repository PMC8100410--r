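#' PatientCohort: patients x features with MMSE scores and severity labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"features"` assay (features x patients), per-patient MMSE score and
#' severity label in `colData`, and — for synthetic cohorts — the generating
#' class-mean matrix, effect size and seed in `metadata`.
#'
#' @aliases PatientCohort-class
#' @exportClass PatientCohort
setClass("PatientCohort", contains = "SummarizedExperiment")

setValidity("PatientCohort", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("a 'features' assay is required")
  if (!all(c("mmse", "severity") %in% colnames(SummarizedExperiment::colData(object))))
    return("colData must contain 'mmse' and 'severity'")
  mm <- object$mmse
  if (any(!is.finite(mm)) || any(mm != round(mm)) || any(mm < 0 | mm > 30))
    return("mmse must be integers in [0, 30]")
  if (!identical(as.character(object$severity),
                 as.character(severityFromMmse(mm))))
    return("severity must equal severityFromMmse(mmse)")
  if (!all(is.finite(SummarizedExperiment::assay(object, "features"))))
    return("features must be finite")
  TRUE
})

setMethod("show", "PatientCohort", function(object) {
  cnt <- table(object$severity)
  cat(sprintf("PatientCohort: %d patients x %d features\n",
              ncol(object), nrow(object)))
  cat("  severity counts:",
      paste(sprintf("%s=%d", names(cnt), as.integer(cnt)), collapse = ", "), "\n")
})

#' @describeIn PatientCohort Feature matrix, patients x features.
#' @param x A `PatientCohort`.
#' @export
cohortFeatures <- function(x) {
  stopIfNot(is(x, "PatientCohort"), "'x' must be a PatientCohort")
  t(SummarizedExperiment::assay(x, "features"))
}

#' @describeIn PatientCohort Integer MMSE scores.
#' @export
mmseScores <- function(x) {
  stopIfNot(is(x, "PatientCohort"), "'x' must be a PatientCohort")
  as.integer(x$mmse)
}

#' @describeIn PatientCohort Severity labels (factor over `severityLevels()`).
#' @export
severityLabels <- function(x) {
  stopIfNot(is(x, "PatientCohort"), "'x' must be a PatientCohort")
  factor(as.character(x$severity), levels = severityLevels())
}

#' @describeIn PatientCohort Generating class-mean matrix (4 x features), or
#'   `NULL` for cohorts read from file.
#' @export
classMeans <- function(x) {
  stopIfNot(is(x, "PatientCohort"), "'x' must be a PatientCohort")
  S4Vectors::metadata(x)$classMeans
}

newPatientCohort <- function(features, mmse, severity, meta = list()) {
  nP <- nrow(features)
  ids <- sprintf("patient_%04d", seq_len(nP))
  fn <- sprintf("f%d", seq_len(ncol(features)))
  assaym <- t(features)
  dimnames(assaym) <- list(fn, ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assaym),
    colData = S4Vectors::DataFrame(mmse = as.integer(mmse),
                                   severity = severity, row.names = ids),
    metadata = meta)
  new("PatientCohort", se)
}

#' Generate a synthetic patient cohort
#'
#' Assigns each patient one of the four severity classes by
#' `classProportions`, draws its features from per-class Gaussian
#' distributions with unit within-class SD, and draws an integer MMSE score
#' uniformly from the class's band (the band convention of
#' [severityFromMmse()]). Adjacent class means differ by `effectSize`
#' within-class SDs in every feature, with an independent random sign per
#' feature, so larger `effectSize` means more separable classes.
#' Deterministic given `seed`.
#'
#' @param nPatients Cohort size (default 1000, split 800/200 downstream).
#' @param nFeatures Feature count (default 285 morphometric features).
#' @param classProportions Four nonnegative proportions (low, mild, moderate,
#'   severe) summing to 1; default `c(0.69, 0.21, 0.073, 0.027)`.
#' @param effectSize Per-feature separation of adjacent class means in
#'   within-class SD units (default 1).
#' @param seed Integer seed.
#' @return A [PatientCohort-class].
#' @examples
#' co <- makeCohort(nPatients = 50, nFeatures = 10, seed = 1)
#' table(severityLabels(co))
#' @export
makeCohort <- function(nPatients = 1000, nFeatures = 285,
                       classProportions = c(0.69, 0.21, 0.073, 0.027),
                       effectSize = 1, seed = 1) {
  stopIfNot(nPatients >= 1, "'nPatients' must be >= 1")
  stopIfNot(nFeatures >= 1, "'nFeatures' must be >= 1")
  stopIfNot(length(classProportions) == 4L && all(classProportions >= 0),
            "'classProportions' must be 4 nonnegative values")
  if (abs(sum(classProportions) - 1) > 1e-9)
    stop("'classProportions' must sum to 1 (within 1e-9)", call. = FALSE)
  stopIfNot(effectSize >= 0, "'effectSize' must be >= 0")
  lev <- severityLevels()
  withSeed(seed, {
    cls <- sample(4L, nPatients, replace = TRUE, prob = classProportions)
    signs <- sample(c(-1, 1), nFeatures, replace = TRUE)
    # class c mean in feature j: effectSize * (c - 2.5) * sign_j
    cm <- outer((1:4) - 2.5, signs) * effectSize
    dimnames(cm) <- list(lev, sprintf("f%d", seq_len(nFeatures)))
    feats <- matrix(rnorm(nPatients * nFeatures), nPatients, nFeatures) +
      cm[cls, , drop = FALSE]
    mmse <- vapply(cls, function(c) {
      band <- mmseBand(lev[c])
      band[sample.int(length(band), 1L)]
    }, 1L)
    newPatientCohort(feats, mmse, factor(lev[cls], levels = lev),
                     meta = list(classMeans = cm, effectSize = effectSize,
                                 seed = as.integer(seed),
                                 classProportions = classProportions))
  })
}

#' Write / read a cohort as CSV
#'
#' Columns: `patient_id`, `f1...fN`, `mmse`, `severity`.
#'
#' @param x A [PatientCohort-class].
#' @param file Path to a CSV file.
#' @return `writeCohortCsv` returns `file` invisibly; `readCohortCsv`
#'   returns a [PatientCohort-class].
#' @export
writeCohortCsv <- function(x, file) {
  stopIfNot(is(x, "PatientCohort"), "'x' must be a PatientCohort")
  feats <- cohortFeatures(x)
  df <- data.frame(patient_id = colnames(x), feats,
                   mmse = mmseScores(x),
                   severity = as.character(severityLabels(x)),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  fcols <- grep("^f[0-9]+$", colnames(df))
  feats <- as.matrix(df[, fcols, drop = FALSE])
  newPatientCohort(feats, df$mmse,
                   factor(df$severity, levels = severityLevels()))
}
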