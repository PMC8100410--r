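#' Run the severity-classification pipeline on a cohort
#'
#' The downstream half of the analysis in one call: stratified 80/20 split,
#' PCA fitted on the training split with the cumulative-variance (98%)
#' selection rule, projection of both splits, training of the requested
#' baseline classifiers and (optionally) the CNN, and a full
#' [evaluationReport()] per method on the held-out test split.
#'
#' @param cohort A [PatientCohort-class].
#' @param methods Baseline methods to run (default all five).
#' @param withCnn Also train the CNN (default `TRUE`).
#' @param varianceThreshold Cumulative-variance threshold for component
#'   selection (default 0.98).
#' @param trainFraction Training fraction (default 0.8).
#' @param cnnIterations CNN optimizer steps (default 420).
#' @param seed Integer seed driving the split, classifier fits and CNN.
#' @return A list: `split`, `nSelected`, `reductionPercent`, and `reports`
#'   (one [evaluationReport()] per method, plus `"cnn"`).
#' @export
runSeverityPipeline <- function(cohort,
                                methods = c("knn", "svm", "dt", "lda", "rf"),
                                withCnn = TRUE, varianceThreshold = 0.98,
                                trainFraction = 0.8, cnnIterations = 420,
                                seed = 1) {
  stopIfNot(is(cohort, "PatientCohort"), "'cohort' must be a PatientCohort")
  feats <- cohortFeatures(cohort)
  labels <- severityLabels(cohort)
  sp <- splitCohort(labels, trainFraction = trainFraction, seed = seed)
  trainX <- feats[sp$train, , drop = FALSE]
  testX <- feats[sp$test, , drop = FALSE]
  trainY <- labels[sp$train]; testY <- labels[sp$test]

  spec <- pcaFit(trainX)
  red <- selectComponents(spec, trainX, varianceThreshold)
  k <- nSelected(red)
  trainR <- reducedTable(red)
  testR <- projectFeatures(spec, testX, k)

  reports <- list()
  for (mth in methods) {
    fit <- trainClassifier(mth, trainR, trainY, seed = seed)
    pred <- predictSeverity(fit, testR)
    reports[[mth]] <- evaluationReport(testY, pred$labels, pred$scores)
  }
  if (withCnn) {
    net <- cnnBuild(nFeatures = k, seed = seed)
    net <- cnnTrain(net, trainR, trainY, iterations = cnnIterations,
                    seed = seed)
    pred <- cnnPredict(net, testR)
    reports[["cnn"]] <- evaluationReport(testY, pred$labels,
                                         pred$probabilities)
  }
  list(split = sp, nSelected = k,
       reductionPercent = reductionPercent(ncol(feats), k),
       reports = reports)
}

#' Summarize pipeline reports as a comparison table
#'
#' One row per class metric, one column per method — the layout used for
#' published per-class sensitivity/precision comparisons.
#'
#' @param reports The `reports` element of [runSeverityPipeline()].
#' @return A data frame of formatted percentages with an accuracy row.
#' @export
comparisonTable <- function(reports) {
  classes <- severityLevels()
  block <- function(metric) {
    t(vapply(reports, function(r) formatPercent(r[[metric]][classes]),
             character(4)))
  }
  sens <- block("sensitivity"); prec <- block("precision")
  acc <- vapply(reports, function(r) formatPercent(r$accuracy), "")
  out <- data.frame(method = names(reports), sens, prec,
                    accuracy = acc, check.names = FALSE,
                    row.names = names(reports))
  colnames(out) <- c("method", paste0("sens_", classes),
                     paste0("prec_", classes), "accuracy")
  out
}
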