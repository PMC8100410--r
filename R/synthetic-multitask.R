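#' TaskDataset: design matrices and responses for multitask regression
#'
#' Holds `m` related regression tasks. Task `i` has a design matrix
#' `X[[i]]` of shape features `d` x samples `n_i` (columns are samples) and a
#' length-`n_i` response `y[[i]]`. In the severity pipeline the tasks are the
#' MMSE follow-up time points (M06, M12, M18, M24, M36, M48).
#'
#' @slot X List of `d x n_i` numeric matrices sharing the same `d`.
#' @slot y List of numeric response vectors, `length(y[[i]]) == ncol(X[[i]])`.
#'
#' @aliases TaskDataset-class
#' @exportClass TaskDataset
setClass("TaskDataset", representation(X = "list", y = "list"))

setValidity("TaskDataset", function(object) {
  if (length(object@X) != length(object@y)) return("X and y must have equal length")
  if (length(object@X) == 0L) return("at least one task required")
  d <- nrow(object@X[[1]])
  for (i in seq_along(object@X)) {
    Xi <- object@X[[i]]
    if (!is.matrix(Xi) || nrow(Xi) != d) return("all X_i must share the same feature count")
    if (ncol(Xi) < 1L) return("every task needs at least one sample")
    if (length(object@y[[i]]) != ncol(Xi)) return("y_i length must match samples of X_i")
    if (!all(is.finite(Xi)) || !all(is.finite(object@y[[i]])))
      return("all entries must be finite")
  }
  TRUE
})

#' Construct a TaskDataset
#' @param X List of `d x n_i` design matrices (columns = samples).
#' @param y List of response vectors.
#' @return A [TaskDataset-class].
#' @export
TaskDataset <- function(X, y) new("TaskDataset", X = X, y = lapply(y, as.numeric))

#' @describeIn TaskDataset Number of tasks.
#' @param x A `TaskDataset`.
#' @export
nTasks <- function(x) { stopIfNot(is(x, "TaskDataset"), "'x' must be a TaskDataset"); length(x@X) }

#' @describeIn TaskDataset Feature count `d`.
#' @export
nFeatures <- function(x) { stopIfNot(is(x, "TaskDataset"), "'x' must be a TaskDataset"); nrow(x@X[[1]]) }

#' @describeIn TaskDataset List of design matrices.
#' @export
taskDesigns <- function(x) { stopIfNot(is(x, "TaskDataset"), "'x' must be a TaskDataset"); x@X }

#' @describeIn TaskDataset List of responses.
#' @export
taskResponses <- function(x) { stopIfNot(is(x, "TaskDataset"), "'x' must be a TaskDataset"); x@y }

setMethod("show", "TaskDataset", function(object) {
  cat(sprintf("TaskDataset: %d tasks, %d features, samples per task: %s\n",
              length(object@X), nrow(object@X[[1]]),
              paste(vapply(object@X, ncol, 1L), collapse = ", ")))
})

#' MultitaskTruth: planted ground truth of a synthetic multitask problem
#'
#' @slot P Row-sparse `d x m` shared component (nonzero rows only on
#'   `sharedSupport`).
#' @slot Q Column-sparse `d x m` outlier component (nonzero columns only on
#'   `outlierTasks`).
#' @slot sharedSupport Integer feature indices carrying shared signal.
#' @slot outlierTasks Integer task indices with task-specific signal.
#' @slot noiseSd Response noise standard deviation.
#'
#' @aliases MultitaskTruth-class
#' @exportClass MultitaskTruth
setClass("MultitaskTruth", representation(P = "matrix", Q = "matrix",
                                          sharedSupport = "integer",
                                          outlierTasks = "integer",
                                          noiseSd = "numeric"))

setValidity("MultitaskTruth", function(object) {
  off <- setdiff(seq_len(nrow(object@P)), object@sharedSupport)
  if (length(off) && any(object@P[off, , drop = FALSE] != 0))
    return("P must be zero outside sharedSupport")
  offc <- setdiff(seq_len(ncol(object@Q)), object@outlierTasks)
  if (length(offc) && any(object@Q[, offc, drop = FALSE] != 0))
    return("Q must be zero outside outlierTasks")
  TRUE
})

setMethod("show", "MultitaskTruth", function(object) {
  cat(sprintf("MultitaskTruth: %d x %d, shared support {%s}, outlier tasks {%s}, noise sd %.3g\n",
              nrow(object@P), ncol(object@P),
              paste(object@sharedSupport, collapse = ","),
              paste(object@outlierTasks, collapse = ","), object@noiseSd))
})

#' @describeIn MultitaskTruth Planted shared-feature indices.
#' @param x A `MultitaskTruth`.
#' @export
sharedSupport <- function(x) { stopIfNot(is(x, "MultitaskTruth"), "'x' must be a MultitaskTruth"); x@sharedSupport }

#' @describeIn MultitaskTruth Planted outlier-task indices.
#' @export
plantedOutliers <- function(x) { stopIfNot(is(x, "MultitaskTruth"), "'x' must be a MultitaskTruth"); x@outlierTasks }

#' Generate a multitask regression problem with planted structure
#'
#' Draws independent standard-normal designs, a row-sparse shared weight
#' matrix `P` (nonzero rows on a random `sShared`-subset of features), a
#' column-sparse outlier matrix `Q` (nonzero columns on a random
#' `kOutlier`-subset of tasks), with nonzero entries of magnitude
#' `signalScale` and random sign, and responses
#' `y_i = X_i' (p_i + q_i) + eps`, `eps ~ N(0, noiseSd^2)`. Deterministic
#' given `seed`.
#'
#' @param d Feature count.
#' @param m Task count.
#' @param nPerTask Samples per task (>= 1).
#' @param sShared Size of the shared feature support, `0 < sShared <= d`.
#' @param kOutlier Number of outlier tasks, `0 <= kOutlier < m`.
#' @param signalScale Magnitude of nonzero weight entries (default 1).
#' @param noiseSd Response noise SD (default 0.1).
#' @param seed Integer seed.
#' @return `list(data = TaskDataset, truth = MultitaskTruth)`.
#' @examples
#' pr <- makeMultitaskProblem(d = 20, m = 4, nPerTask = 30, sShared = 3,
#'                            kOutlier = 1, seed = 7)
#' sharedSupport(pr$truth)
#' @export
makeMultitaskProblem <- function(d, m, nPerTask, sShared, kOutlier,
                                 signalScale = 1, noiseSd = 0.1, seed = 1) {
  stopIfNot(sShared > 0 && sShared <= d, "'sShared' must satisfy 0 < sShared <= d")
  stopIfNot(kOutlier >= 0 && kOutlier < m, "'kOutlier' must satisfy 0 <= kOutlier < m")
  stopIfNot(nPerTask >= 1, "'nPerTask' must be >= 1")
  withSeed(seed, {
    support <- sort(sample.int(d, sShared))
    outl <- if (kOutlier > 0) sort(sample.int(m, kOutlier)) else integer(0)
    P <- matrix(0, d, m)
    P[support, ] <- signalScale * sample(c(-1, 1), sShared * m, replace = TRUE)
    Q <- matrix(0, d, m)
    if (kOutlier > 0)
      Q[, outl] <- signalScale * sample(c(-1, 1), d * kOutlier, replace = TRUE)
    X <- vector("list", m); y <- vector("list", m)
    for (i in seq_len(m)) {
      X[[i]] <- matrix(rnorm(d * nPerTask), d, nPerTask)
      eps <- if (noiseSd > 0) rnorm(nPerTask, 0, noiseSd) else numeric(nPerTask)
      y[[i]] <- as.numeric(crossprod(X[[i]], P[, i] + Q[, i])) + eps
    }
    list(data = TaskDataset(X, y),
         truth = new("MultitaskTruth", P = P, Q = Q,
                     sharedSupport = as.integer(support),
                     outlierTasks = as.integer(outl),
                     noiseSd = as.numeric(noiseSd)))
  })
}

#' Write / read a TaskDataset as per-task CSV files
#'
#' Each task is stored as `task_<i>.csv` whose rows are the `d` feature rows
#' of `X_i` and whose final row is the response `y_i`; a `manifest.csv` lists
#' the task files in order.
#'
#' @param x A [TaskDataset-class].
#' @param dir Directory to write into (created if needed).
#' @return `writeTaskDataset` returns `dir` invisibly; `readTaskDataset`
#'   returns a [TaskDataset-class].
#' @export
writeTaskDataset <- function(x, dir) {
  stopIfNot(is(x, "TaskDataset"), "'x' must be a TaskDataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("task_%d.csv", seq_along(x@X))
  for (i in seq_along(x@X)) {
    utils::write.table(rbind(x@X[[i]], x@y[[i]]),
                       file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(task = seq_along(files), file = files),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeTaskDataset
#' @export
readTaskDataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  X <- vector("list", nrow(man)); y <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    m <- as.matrix(utils::read.table(file.path(dir, man$file[i]), sep = ","))
    dimnames(m) <- NULL
    X[[i]] <- m[-nrow(m), , drop = FALSE]
    y[[i]] <- as.numeric(m[nrow(m), ])
  }
  TaskDataset(X, y)
}
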