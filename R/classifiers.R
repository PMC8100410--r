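#' Stratified train/test split
#'
#' Partitions patient indices into disjoint, exhaustive train and test sets.
#' With `stratified = TRUE` (default) the split is drawn per class, so class
#' proportions are preserved within one member. Deterministic given `seed`.
#'
#' @param labels Factor (or character) class labels.
#' @param trainFraction Fraction of patients used for training, in (0, 1);
#'   default 0.8 (the study's 80/20 convention).
#' @param stratified Preserve class proportions (default `TRUE`).
#' @param seed Integer seed.
#' @return `list(train = integer indices, test = integer indices)`.
#' @examples
#' sp <- splitCohort(factor(rep(c("a", "b"), 50)), seed = 1)
#' length(sp$train)   # 80
#' @export
splitCohort <- function(labels, trainFraction = 0.8, stratified = TRUE,
                        seed = 1) {
  stopIfNot(trainFraction > 0 && trainFraction < 1,
            "'trainFraction' must lie in (0, 1)")
  labels <- as.factor(labels)
  n <- length(labels)
  withSeed(seed, {
    if (stratified) {
      present <- levels(droplevels(labels))
      sizes <- table(labels)[present]
      if (any(sizes < 2))
        stop("stratified split needs >= 2 members per present class",
             call. = FALSE)
      train <- unlist(lapply(present, function(cl) {
        idx <- which(labels == cl)
        sample(idx, round(trainFraction * length(idx)))
      }), use.names = FALSE)
      train <- sort(train)
    } else {
      train <- sort(sample.int(n, round(trainFraction * n)))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' TrainedClassifier: one fitted baseline severity classifier
#'
#' @slot method One of `"knn"`, `"svm"`, `"dt"`, `"lda"`, `"rf"`.
#' @slot fit The underlying fitted object (opaque).
#' @slot classes Class labels in the fixed order
#'   (low, mild, moderate, severe) restricted to those present at training.
#' @slot hyperparameters Named list of the hyperparameters used.
#'
#' @aliases TrainedClassifier-class
#' @exportClass TrainedClassifier
setClass("TrainedClassifier", representation(method = "character",
                                             fit = "ANY",
                                             classes = "character",
                                             hyperparameters = "list"))

setMethod("show", "TrainedClassifier", function(object) {
  hp <- paste(names(object@hyperparameters),
              vapply(object@hyperparameters, function(v) paste(format(v), collapse = "/"), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("TrainedClassifier[%s]: classes (%s); %s\n", object@method,
              paste(object@classes, collapse = ", "), hp))
})

#' Train a baseline severity classifier
#'
#' One contract over five standard methods. Published defaults for this
#' pipeline (all overridable via `hyperparameters`): `knn` k = 5 Euclidean
#' (via \pkg{caret}'s `knn3`, which exposes per-class vote fractions);
#' `svm` RBF kernel, one-vs-one, cost 1 (\pkg{e1071}); `dt` Gini with
#' unlimited depth (\pkg{rpart}, `cp = 0`); `lda` ([MASS::lda]); `rf` 100
#' trees (\pkg{randomForest}). Refitting with the same inputs and seed gives
#' identical predictions.
#'
#' @param method `"knn"`, `"svm"`, `"dt"`, `"lda"` or `"rf"`.
#' @param features Training matrix (patients x features).
#' @param labels Factor of severity labels (>= 2 classes present).
#' @param hyperparameters Named list of overrides (see above).
#' @param seed Integer seed (used by the stochastic fitters).
#' @return A [TrainedClassifier-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' y <- factor(rep(c("low", "severe"), each = 20), levels = severityLevels())
#' fit <- trainClassifier("dt", x, y)
#' predictSeverity(fit, x)$labels
#' @export
trainClassifier <- function(method, features, labels,
                            hyperparameters = list(), seed = 1) {
  ok <- c("knn", "svm", "dt", "lda", "rf")
  if (!is.character(method) || length(method) != 1L || !(method %in% ok))
    stop("unknown method: ", paste(method, collapse = ","),
         " (expected one of ", paste(ok, collapse = ", "), ")", call. = FALSE)
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  stopIfNot(nlevels(labels) >= 2, "at least 2 classes must be present")
  stopIfNot(nrow(features) == length(labels),
            "features and labels must be aligned")
  hp <- hyperparameters
  colnames(features) <- sprintf("x%d", seq_len(ncol(features)))
  fit <- withSeed(seed, switch(method,
    knn = {
      hp$k <- hp$k %||% 5L
      list(model = caret::knn3(features, labels, k = hp$k), train = features)
    },
    svm = {
      hp$cost <- hp$cost %||% 1
      hp$kernel <- hp$kernel %||% "radial"
      e1071::svm(features, labels, kernel = hp$kernel, cost = hp$cost,
                 probability = TRUE)
    },
    dt = {
      hp$cp <- hp$cp %||% 0
      hp$minsplit <- hp$minsplit %||% 2L
      df <- data.frame(.y = labels, features, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit,
                                                  minbucket = 1L, xval = 0L))
    },
    lda = {
      hp$tol <- hp$tol %||% 1e-8
      MASS::lda(features, grouping = labels, tol = hp$tol)
    },
    rf = {
      hp$ntree <- hp$ntree %||% 100L
      randomForest::randomForest(features, labels, ntree = hp$ntree)
    }))
  new("TrainedClassifier", method = method, fit = fit,
      classes = levels(labels), hyperparameters = hp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict severity labels (and per-class scores)
#'
#' Returns one label per row plus a patients x classes score matrix (class
#' probabilities or vote fractions, higher = more confident) suitable for
#' [rocOneVsRest()]. Rows of the score matrix sum to 1 for every method.
#'
#' @param model A [TrainedClassifier-class].
#' @param features Matrix with the training dimensionality.
#' @return `list(labels = factor, scores = matrix)` (both empty for an
#'   empty input).
#' @export
predictSeverity <- function(model, features) {
  stopIfNot(is(model, "TrainedClassifier"), "'model' must be a TrainedClassifier")
  features <- as.matrix(features)
  lev <- model@classes
  if (nrow(features) == 0L)
    return(list(labels = factor(character(0), levels = lev),
                scores = matrix(0, 0, length(lev), dimnames = list(NULL, lev))))
  trainDim <- switch(model@method,
                     knn = ncol(model@fit$train),
                     svm = ncol(model@fit$SV),
                     dt = length(attr(model@fit$terms, "term.labels")),
                     lda = ncol(model@fit$means),
                     rf = length(model@fit$forest$ncat))
  if (!is.null(trainDim) && ncol(features) != trainDim)
    stop("feature dimensionality (", ncol(features),
         ") does not match training (", trainDim, ")", call. = FALSE)
  colnames(features) <- sprintf("x%d", seq_len(ncol(features)))
  scores <- switch(model@method,
    knn = as.matrix(predict(model@fit$model, features, type = "prob")),
    svm = {
      p <- predict(model@fit, features, probability = TRUE)
      attr(p, "probabilities")[, lev, drop = FALSE]
    },
    dt = predict(model@fit, data.frame(features, check.names = FALSE),
                 type = "prob"),
    lda = predict(model@fit, features)$posterior,
    rf = predict(model@fit, features, type = "prob"))
  scores <- as.matrix(scores)[, lev, drop = FALSE]
  idx <- max.col(scores, ties.method = "first")
  list(labels = factor(lev[idx], levels = severityLevels()),
       scores = scores)
}
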