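#' Robust multitask feature learning (rMTFL)
#'
#' rMTFL regresses `m` related tasks jointly while decomposing the weight
#' matrix as `W = P + Q`: a row-sparse `P` carries the features shared across
#' tasks, a column-sparse `Q` absorbs outlier tasks. The model minimizes
#' \deqn{\sum_{i=1}^m \frac{1}{m n_i} \|X_i^\top w_i - y_i\|^2
#'   + \lambda_1 \|P\|_{1,2} + \lambda_2 \|Q^\top\|_{1,2},}
#' where \eqn{\|M\|_{1,2}} is the sum of Euclidean norms of the ROWS of `M`
#' (so the `Q` penalty groups columns, i.e. tasks). Solved by joint proximal
#' gradient descent with backtracking; the group penalties are handled by
#' closed-form group soft-thresholding.
#'
#' @slot P,Q,W `d x m` matrices with `W = P + Q` exactly.
#' @slot lambda1,lambda2 Nonnegative penalty weights.
#' @slot objectiveTrace Objective at initialization and after each
#'   iteration; non-increasing up to 1e-9 relative.
#'
#' @aliases RmtflModel-class
#' @exportClass RmtflModel
setClass("RmtflModel", representation(P = "matrix", Q = "matrix", W = "matrix",
                                      lambda1 = "numeric", lambda2 = "numeric",
                                      objectiveTrace = "numeric"))

setValidity("RmtflModel", function(object) {
  if (!identical(dim(object@P), dim(object@Q)) ||
      !identical(dim(object@P), dim(object@W)))
    return("P, Q, W must share dimensions")
  if (!identical(object@W, object@P + object@Q))
    return("W must equal P + Q exactly")
  if (object@lambda1 < 0 || object@lambda2 < 0)
    return("lambda1 and lambda2 must be >= 0")
  TRUE
})

setMethod("show", "RmtflModel", function(object) {
  cat(sprintf(
    "RmtflModel: %d features x %d tasks, lambda1=%.3g lambda2=%.3g\n",
    nrow(object@W), ncol(object@W), object@lambda1, object@lambda2))
  cat(sprintf("  %d nonzero P rows, %d nonzero Q columns, final objective %.6g\n",
              sum(rowSums(object@P != 0) > 0), sum(colSums(object@Q != 0) > 0),
              tail(object@objectiveTrace, 1)))
})

#' @describeIn RmtflModel Shared component `P`.
#' @param x An `RmtflModel`.
#' @export
sharedComponent <- function(x) { stopIfNot(is(x, "RmtflModel"), "'x' must be an RmtflModel"); x@P }

#' @describeIn RmtflModel Outlier component `Q`.
#' @export
outlierComponent <- function(x) { stopIfNot(is(x, "RmtflModel"), "'x' must be an RmtflModel"); x@Q }

#' @describeIn RmtflModel Objective trace.
#' @export
objectiveTrace <- function(x) { stopIfNot(is(x, "RmtflModel"), "'x' must be an RmtflModel"); x@objectiveTrace }

#' Solver settings for [rmtflFit()]
#'
#' @param maxIters Iteration cap (>= 1).
#' @param tolerance Relative objective-change stopping threshold (> 0).
#' @param stepShrink Backtracking shrink factor in (0, 1).
#' @param accelerate Use momentum (FISTA) with function-value restart
#'   (default `TRUE`); the restart keeps the objective trace monotone.
#' @param init Optional warm start: `list(P =, Q =)`; default zeros.
#' @return A plain list of validated settings.
#' @export
rmtflControl <- function(maxIters = 1000L, tolerance = 1e-9,
                         stepShrink = 0.5, accelerate = TRUE, init = NULL) {
  stopIfNot(maxIters >= 1, "'maxIters' must be >= 1")
  stopIfNot(tolerance > 0, "'tolerance' must be > 0")
  stopIfNot(stepShrink > 0 && stepShrink < 1, "'stepShrink' must be in (0, 1)")
  list(maxIters = as.integer(maxIters), tolerance = tolerance,
       stepShrink = stepShrink, accelerate = isTRUE(accelerate), init = init)
}

#' Normalize task features to unit sample norm
#'
#' Scales every feature row of every task design so that the sum of its
#' squared sample values is 1. All-zero rows are left untouched and their
#' (task, feature) indices attached as the `"zeroRows"` attribute, with a
#' warning.
#'
#' @param data A [TaskDataset-class].
#' @return The normalized [TaskDataset-class].
#' @examples
#' td <- TaskDataset(list(matrix(c(3, 4), 1, 2)), list(c(0, 0)))
#' taskDesigns(normalizeFeatures(td))[[1]]   # 0.6 0.8
#' @export
normalizeFeatures <- function(data) {
  stopIfNot(is(data, "TaskDataset"), "'data' must be a TaskDataset")
  zero <- list()
  X <- lapply(seq_along(data@X), function(i) {
    Xi <- data@X[[i]]
    nrm <- sqrt(rowSums(Xi^2))
    z <- which(nrm == 0)
    if (length(z)) zero[[length(zero) + 1L]] <<- cbind(task = i, feature = z)
    nrm[nrm == 0] <- 1
    Xi / nrm
  })
  if (length(zero))
    warning("all-zero feature rows left unnormalized: ",
            paste(apply(do.call(rbind, zero), 1, paste, collapse = "/"),
                  collapse = ", "), call. = FALSE)
  out <- TaskDataset(X, data@y)
  attr(out, "zeroRows") <- if (length(zero)) do.call(rbind, zero) else NULL
  out
}

lossAndResiduals <- function(P, Q, data) {
  m <- length(data@X)
  W <- P + Q
  res <- vector("list", m)
  loss <- 0
  for (i in seq_len(m)) {
    r <- as.numeric(crossprod(data@X[[i]], W[, i])) - data@y[[i]]
    res[[i]] <- r
    loss <- loss + sum(r^2) / (m * length(r))
  }
  list(loss = loss, res = res)
}

penalty <- function(P, Q, lambda1, lambda2) {
  lambda1 * sum(sqrt(rowSums(P^2))) + lambda2 * sum(sqrt(colSums(Q^2)))
}

#' rMTFL objective value
#'
#' Evaluates the objective documented in [RmtflModel-class] for a model on a
#' dataset.
#'
#' @param model An [RmtflModel-class].
#' @param data A [TaskDataset-class] with matching dimensions.
#' @return Finite scalar.
#' @export
rmtflObjective <- function(model, data) {
  stopIfNot(is(model, "RmtflModel"), "'model' must be an RmtflModel")
  stopIfNot(is(data, "TaskDataset"), "'data' must be a TaskDataset")
  stopIfNot(nrow(model@W) == nFeatures(data) && ncol(model@W) == nTasks(data),
            "model dimensions must match data")
  lossAndResiduals(model@P, model@Q, data)$loss +
    penalty(model@P, model@Q, model@lambda1, model@lambda2)
}

#' Group soft-thresholding (proximal operator of the l2,1 norm)
#'
#' Maps each group `g` (a row or column of `M`) to
#' `g * max(0, 1 - t / ||g||_2)`; zero groups stay zero. This is the exact
#' proximal operator of `t * sum_g ||g||_2`.
#'
#' @param M Numeric matrix.
#' @param t Nonnegative threshold.
#' @param axis `"rows"` or `"columns"`: the grouping.
#' @return Matrix of the same shape.
#' @examples
#' proxGroup(matrix(c(3, 4), 1), t = 1, axis = "rows")   # 2.4 3.2
#' @export
proxGroup <- function(M, t, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopIfNot(is.numeric(t) && length(t) == 1L && t >= 0, "'t' must be >= 0")
  M <- as.matrix(M)
  if (axis == "rows") {
    nrm <- sqrt(rowSums(M^2))
    scale <- ifelse(nrm > 0, pmax(0, 1 - t / nrm), 0)
    M * scale
  } else {
    nrm <- sqrt(colSums(M^2))
    scale <- ifelse(nrm > 0, pmax(0, 1 - t / nrm), 0)
    M * rep(scale, each = nrow(M))
  }
}

#' Fit the rMTFL model by proximal gradient descent
#'
#' Joint proximal gradient on `(P, Q)`: both blocks share the smooth-loss
#' gradient `(2 / (m n_i)) X_i (X_i' (p_i + q_i) - y_i)`; after each gradient
#' step, `P` is row-group soft-thresholded with `step * lambda1` and `Q`
#' column-group soft-thresholded with `step * lambda2`. The initial step is
#' `1 / L` with `L` the spectral-norm Lipschitz constant of the joint loss
#' gradient, refined by backtracking against the standard quadratic upper
#' bound. With `accelerate = TRUE` (default) FISTA momentum is applied and
#' restarted whenever it would raise the objective, so the trace stays
#' non-increasing. Initialization is `P = Q = 0` unless a warm start is
#' supplied.
#'
#' @param data A [TaskDataset-class] (normalize with [normalizeFeatures()]
#'   first if desired; the solver takes the data as given).
#' @param lambda1,lambda2 Nonnegative penalty weights.
#' @param control A [rmtflControl()] list.
#' @return An [RmtflModel-class].
#' @examples
#' pr <- makeMultitaskProblem(d = 10, m = 3, nPerTask = 40, sShared = 2,
#'                            kOutlier = 1, seed = 1)
#' fit <- rmtflFit(pr$data, lambda1 = 0.05, lambda2 = 0.05)
#' featureScores(fit)
#' @export
rmtflFit <- function(data, lambda1, lambda2, control = rmtflControl()) {
  stopIfNot(is(data, "TaskDataset"), "'data' must be a TaskDataset")
  stopIfNot(lambda1 >= 0 && lambda2 >= 0, "lambdas must be >= 0")
  d <- nFeatures(data); m <- nTasks(data)
  ni <- vapply(data@X, ncol, 1L)
  P <- matrix(0, d, m); Q <- matrix(0, d, m)
  if (!is.null(control$init)) { P <- control$init$P; Q <- control$init$Q }

  cur <- lossAndResiduals(P, Q, data)
  obj <- cur$loss + penalty(P, Q, lambda1, lambda2)
  trace <- obj
  # joint Hessian block [[A, A], [A, A]] has spectral norm 2 sigma_max(A)
  lip <- max(vapply(seq_len(m), function(i)
    4 * norm(data@X[[i]], "2")^2 / (m * ni[i]), 0))
  step <- if (lip > 0) 1 / lip else 1

  gradAt <- function(Py, Qy) {
    ly <- lossAndResiduals(Py, Qy, data)
    G <- vapply(seq_len(m), function(i)
      (2 / (m * ni[i])) * as.numeric(data@X[[i]] %*% ly$res[[i]]),
      numeric(d))
    list(G = matrix(G, d, m), loss = ly$loss)
  }

  Py <- P; Qy <- Q      # extrapolation point
  Pprev <- P; Qprev <- Q
  tk <- 1
  stall <- 0L
  for (it in seq_len(control$maxIters)) {
    gy <- gradAt(Py, Qy)
    repeat {
      Pn <- proxGroup(Py - step * gy$G, step * lambda1, "rows")
      Qn <- proxGroup(Qy - step * gy$G, step * lambda2, "columns")
      nxt <- lossAndResiduals(Pn, Qn, data)
      dP <- Pn - Py; dQ <- Qn - Qy
      bound <- gy$loss + sum(gy$G * (dP + dQ)) +
        (sum(dP^2) + sum(dQ^2)) / (2 * step)
      if (nxt$loss <= bound + 1e-12 * max(1, abs(bound))) break
      step <- step * control$stepShrink
      if (step < 1e-15)
        stop("rMTFL solver failed: backtracking exhausted at iteration ", it,
             call. = FALSE)
    }
    objNew <- nxt$loss + penalty(Pn, Qn, lambda1, lambda2)
    if (control$accelerate && objNew > obj) {
      # momentum overshoot: restart from the last accepted iterate
      Py <- P; Qy <- Q; tk <- 1
      next
    }
    if (objNew > obj + 1e-9 * max(1, abs(obj)))
      stop("rMTFL solver failed: objective increased at iteration ", it,
           call. = FALSE)
    Pprev <- P; Qprev <- Q
    P <- Pn; Q <- Qn; cur <- nxt
    trace <- c(trace, min(objNew, obj))
    stall <- if ((obj - objNew) < control$tolerance * max(1, abs(obj)))
      stall + 1L else 0L
    obj <- min(objNew, obj)
    if (stall >= 3L) break
    if (control$accelerate) {
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Py <- P + ((tk - 1) / tn) * (P - Pprev)
      Qy <- Q + ((tk - 1) / tn) * (Q - Qprev)
      tk <- tn
    } else {
      Py <- P; Qy <- Q
    }
  }
  new("RmtflModel", P = P, Q = Q, W = P + Q,
      lambda1 = lambda1, lambda2 = lambda2, objectiveTrace = trace)
}

#' Per-feature importance scores from a fitted model
#'
#' The score of feature `j` is the Euclidean norm of row `j` of the shared
#' component `P`; features not shared across tasks score exactly 0.
#'
#' @param model An [RmtflModel-class].
#' @return Nonnegative numeric vector of length `d`.
#' @export
featureScores <- function(model) {
  stopIfNot(is(model, "RmtflModel"), "'model' must be an RmtflModel")
  sqrt(rowSums(model@P^2))
}

#' Detect outlier tasks
#'
#' Tasks whose column of `Q` has Euclidean norm above `tol`.
#'
#' @param model An [RmtflModel-class].
#' @param tol Nonnegative threshold (default 1e-6; exact zeros are produced
#'   by the group prox, so a tiny tolerance suffices).
#' @return Integer vector of task indices (possibly empty).
#' @export
outlierTasks <- function(model, tol = 1e-6) {
  stopIfNot(is(model, "RmtflModel"), "'model' must be an RmtflModel")
  stopIfNot(tol >= 0, "'tol' must be >= 0")
  which(sqrt(colSums(model@Q^2)) > tol)
}

#' Select the top-k features by score
#'
#' Indices of the `k` largest scores in descending score order; ties broken
#' by the smaller index first.
#'
#' @param scores Nonnegative score vector.
#' @param k Number of features to keep, `1 <= k <= length(scores)`.
#' @return Integer index vector of length `k`.
#' @examples
#' selectFeatures(c(0.5, 0.9, 0.1), 2)   # 2 1
#' @export
selectFeatures <- function(scores, k) {
  stopIfNot(k >= 1 && k <= length(scores), "'k' out of range")
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Choose rMTFL penalties on a small grid by hold-out error
#'
#' Splits each task's samples into a fit and a hold-out part, fits every
#' `(lambda1, lambda2)` pair of a logarithmic grid anchored at the smallest
#' penalties that zero each component entirely, and scores hold-out mean
#' squared error. Among pairs whose error is within `parsimonyFactor` of the
#' minimum, the sparsest (largest-penalty) pair is returned — the usual
#' one-standard-error-style parsimony rule.
#'
#' @param data A [TaskDataset-class].
#' @param gridFractions Fractions of the critical penalties to scan.
#' @param holdFraction Fraction of each task's samples held out.
#' @param parsimonyFactor Relative slack on the minimal hold-out MSE.
#' @param seed Seed for the hold-out split.
#' @param control Passed to [rmtflFit()].
#' @return `list(lambda1, lambda2, grid)` where `grid` logs every pair and
#'   its hold-out MSE.
#' @export
rmtflSelectLambda <- function(data, gridFractions = c(0.5, 0.2, 0.1, 0.05, 0.02),
                              holdFraction = 0.2, parsimonyFactor = 1.05,
                              seed = 1, control = rmtflControl()) {
  stopIfNot(is(data, "TaskDataset"), "'data' must be a TaskDataset")
  m <- nTasks(data); d <- nFeatures(data)
  ni <- vapply(data@X, ncol, 1L)
  withSeed(seed, {
    hold <- lapply(ni, function(n) sort(sample.int(n, max(1L, round(holdFraction * n)))))
    fitX <- lapply(seq_len(m), function(i) data@X[[i]][, -hold[[i]], drop = FALSE])
    fitY <- lapply(seq_len(m), function(i) data@y[[i]][-hold[[i]]])
    fitData <- TaskDataset(fitX, fitY)
    nif <- vapply(fitX, ncol, 1L)
    # gradient of the loss at P=Q=0 gives the critical penalties
    G0 <- vapply(seq_len(m), function(i)
      (2 / (m * nif[i])) * as.numeric(fitX[[i]] %*% fitY[[i]]), numeric(d))
    G0 <- matrix(G0, d, m)
    l1max <- max(sqrt(rowSums(G0^2)))
    l2max <- max(sqrt(colSums(G0^2)))
    grid <- expand.grid(lambda1 = gridFractions * l1max,
                        lambda2 = gridFractions * l2max)
    grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
      fit <- rmtflFit(fitData, grid$lambda1[g], grid$lambda2[g], control)
      err <- 0; ntot <- 0
      for (i in seq_len(m)) {
        Xi <- data@X[[i]][, hold[[i]], drop = FALSE]
        r <- as.numeric(crossprod(Xi, fit@W[, i])) - data@y[[i]][hold[[i]]]
        err <- err + sum(r^2); ntot <- ntot + length(r)
      }
      err / ntot
    }, 0)
    ok <- which(grid$mse <= min(grid$mse) * parsimonyFactor)
    best <- ok[which.max(grid$lambda1[ok] / l1max + grid$lambda2[ok] / l2max)]
    list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best], grid = grid)
  })
}
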