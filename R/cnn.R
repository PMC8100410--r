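#' Softmax probabilities
#'
#' Numerically safe softmax (max-subtraction) of a logit vector, or row-wise
#' for a matrix of logits. Entries are nonnegative and sum to 1 within
#' 1e-12; adding a constant to all logits leaves the output unchanged.
#'
#' @param logits Finite numeric vector, or matrix with one logit vector per
#'   row.
#' @return Probability vector / matrix of the same shape.
#' @examples
#' softmaxProb(c(0, log(3)))   # 0.25 0.75
#' @export
softmaxProb <- function(logits) {
  if (is.matrix(logits)) {
    stopIfNot(all(is.finite(logits)), "logits must be finite")
    z <- exp(logits - apply(logits, 1, max))
    z / rowSums(z)
  } else {
    stopIfNot(all(is.finite(logits)), "logits must be finite")
    z <- exp(logits - max(logits))
    z / sum(z)
  }
}

#' Mean cross-entropy loss
#'
#' Mean over the batch of `-log p(true class)`, with a probability floor of
#' 1e-12 against log(0).
#'
#' @param probabilities Matrix (batch x classes) of valid probability rows,
#'   or a single probability vector.
#' @param labels Integer true-class indices (1-based), one per row.
#' @return Nonnegative scalar.
#' @examples
#' crossentropyLoss(rep(0.25, 4), 2)   # log(4)
#' @export
crossentropyLoss <- function(probabilities, labels) {
  p <- if (is.matrix(probabilities)) probabilities else matrix(probabilities, 1)
  labels <- as.integer(labels)
  stopIfNot(length(labels) == nrow(p), "one label per probability row required")
  if (any(labels < 1L | labels > ncol(p)))
    stop("label index out of range", call. = FALSE)
  picked <- p[cbind(seq_len(nrow(p)), labels)]
  mean(-log(pmax(picked, 1e-12)))
}

#' CnnModel: a small 1-D convolutional network for feature vectors
#'
#' Architecture: length-`inputLength` feature vector -> 1-D convolution
#' (`nFilters` filters of length `filterLen`, stride 1, zero "same" padding)
#' -> rectifier -> fully connected stack (`fcSizes`, rectified) -> linear
#' output of `nClasses` -> softmax, trained with cross-entropy. A 5 x 5
#' kernel on a width-1 input collapses to this length-5 1-D convolution —
#' the only geometry consistent with a 167 x 1 x 1 input.
#'
#' @slot inputLength,filterLen,nFilters,nClasses Integer architecture sizes.
#' @slot fcSizes Hidden fully-connected widths (default 384, 384, 384; the
#'   three-layer variant `c(384, 384)` is available via [cnnBuild()]).
#' @slot params List of weights: `K` (filterLen x nFilters), `bK`, and per
#'   fully-connected layer `W`/`b`.
#' @slot center,scale Feature standardization learned by [cnnTrain()].
#' @slot classes Class labels in fixed order.
#' @slot trace Data frame of per-iteration loss and batch accuracy.
#'
#' @aliases CnnModel-class
#' @exportClass CnnModel
setClass("CnnModel", representation(inputLength = "integer",
                                    filterLen = "integer",
                                    nFilters = "integer",
                                    fcSizes = "integer",
                                    nClasses = "integer",
                                    params = "list",
                                    center = "numeric",
                                    scale = "numeric",
                                    classes = "character",
                                    trace = "data.frame"))

setMethod("show", "CnnModel", function(object) {
  np <- sum(vapply(rapply(object@params, identity, how = "list"),
                   function(p) length(unlist(p)), 1L))
  cat(sprintf("CnnModel: input %d -> conv %dx%d -> FC (%s) -> %d classes; %d parameters%s\n",
              object@inputLength, object@nFilters, object@filterLen,
              paste(object@fcSizes, collapse = ", "), object@nClasses, np,
              if (nrow(object@trace)) sprintf("; trained %d iterations", nrow(object@trace)) else " (untrained)"))
})

#' Build the CNN
#'
#' Initializes weights with small-variance symmetric (He-scaled) random
#' values; `init = "zero"` gives all-zero weights (useful to verify that the
#' untrained forward pass is uniform).
#'
#' @param nFeatures Input length (>= `filterLen`); default 167, the size of
#'   the reduced feature vector.
#' @param nClasses Output classes (default 4).
#' @param nFilters,filterLen Convolution shape (default 16 filters of
#'   length 5).
#' @param fcSizes Hidden fully-connected widths (default `c(384, 384, 384)`).
#' @param seed Integer seed for the initialization.
#' @param init `"he"` (default) or `"zero"`.
#' @return An untrained [CnnModel-class].
#' @export
cnnBuild <- function(nFeatures = 167, nClasses = 4, nFilters = 16,
                     filterLen = 5, fcSizes = c(384, 384, 384), seed = 1,
                     init = c("he", "zero")) {
  init <- match.arg(init)
  stopIfNot(nFeatures >= filterLen, "'nFeatures' must be >= 'filterLen'")
  stopIfNot(all(fcSizes >= 1) && nClasses >= 2, "widths must be positive")
  widths <- c(nFeatures * nFilters, as.integer(fcSizes), as.integer(nClasses))
  withSeed(seed, {
    draw <- function(nr, nc, fan) {
      if (init == "zero") matrix(0, nr, nc)
      else matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
    }
    params <- list(K = draw(filterLen, nFilters, filterLen),
                   bK = numeric(nFilters),
                   fc = lapply(seq_len(length(widths) - 1L), function(j)
                     list(W = draw(widths[j], widths[j + 1L], widths[j]),
                          b = numeric(widths[j + 1L]))))
    new("CnnModel", inputLength = as.integer(nFeatures),
        filterLen = as.integer(filterLen), nFilters = as.integer(nFilters),
        fcSizes = as.integer(fcSizes), nClasses = as.integer(nClasses),
        params = params, center = numeric(0), scale = numeric(0),
        classes = severityLevels()[seq_len(min(nClasses, 4L))],
        trace = data.frame())
  })
}

# forward pass; keepCache = TRUE returns intermediates for backprop
cnnForward <- function(model, x, keepCache = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, 1)
  stopIfNot(ncol(x) == model@inputLength,
            "feature length must match the model input length")
  B <- nrow(x); L <- model@inputLength
  fl <- model@filterLen; Fn <- model@nFilters
  half <- (fl - 1L) %/% 2L
  xpad <- cbind(matrix(0, B, half), x, matrix(0, B, fl - 1L - half))
  Z <- vapply(seq_len(fl), function(t) as.vector(xpad[, t:(t + L - 1L), drop = FALSE]),
              numeric(B * L))
  convPre <- sweep(Z %*% model@params$K, 2, model@params$bK, "+")
  convPost <- pmax(convPre, 0)
  h <- matrix(convPost, B, L * Fn)
  acts <- list(h); pres <- list()
  nfc <- length(model@params$fc)
  for (j in seq_len(nfc)) {
    a <- sweep(h %*% model@params$fc[[j]]$W, 2, model@params$fc[[j]]$b, "+")
    pres[[j]] <- a
    h <- if (j < nfc) pmax(a, 0) else a
    acts[[j + 1L]] <- h
  }
  probs <- softmaxProb(h)
  if (!keepCache) return(probs)
  list(probs = probs, Z = Z, convPre = convPre, acts = acts, pres = pres,
       B = B)
}

# gradients of mean cross-entropy w.r.t. all parameters
cnnGradients <- function(model, x, labels) {
  cache <- cnnForward(model, x, keepCache = TRUE)
  B <- cache$B
  K <- model@params$K; fc <- model@params$fc
  nfc <- length(fc)
  onehot <- matrix(0, B, model@nClasses)
  onehot[cbind(seq_len(B), as.integer(labels))] <- 1
  delta <- (cache$probs - onehot) / B
  gfc <- vector("list", nfc)
  for (j in rev(seq_len(nfc))) {
    hPrev <- cache$acts[[j]]
    gfc[[j]] <- list(W = crossprod(hPrev, delta), b = colSums(delta))
    if (j > 1L)
      delta <- (delta %*% t(fc[[j]]$W)) * (cache$pres[[j - 1L]] > 0)
    else
      delta <- delta %*% t(fc[[j]]$W)
  }
  # delta is now the gradient at the flattened rectified conv output
  dConvPost <- matrix(delta, nrow(cache$convPre), model@nFilters)
  dConvPre <- dConvPost * (cache$convPre > 0)
  list(K = crossprod(cache$Z, dConvPre), bK = colSums(dConvPre), fc = gfc,
       loss = crossentropyLoss(cache$probs, as.integer(labels)))
}

#' Train the CNN by stochastic gradient descent
#'
#' Features are standardized (per-feature z-score, stored in the model and
#' re-applied at prediction). Runs `iterations` plain SGD steps on
#' cross-entropy over seeded mini-batches; deterministic given `seed`.
#'
#' @param model An untrained (or warm) [CnnModel-class].
#' @param features Training matrix (patients x `inputLength`).
#' @param labels Factor of severity labels.
#' @param iterations Optimizer steps (default 420).
#' @param batchSize Mini-batch size (default 32).
#' @param learningRate Fixed SGD step (default 0.05 on standardized inputs).
#' @param seed Integer seed for batch order.
#' @return The trained [CnnModel-class] with a per-iteration `trace` of loss
#'   and batch accuracy (see [cnnTrace()]).
#' @export
cnnTrain <- function(model, features, labels, iterations = 420,
                     batchSize = 32, learningRate = 0.05,
                     standardize = c("pooled", "perFeature"), seed = 1) {
  stopIfNot(is(model, "CnnModel"), "'model' must be a CnnModel")
  stopIfNot(iterations >= 1, "'iterations' must be >= 1")
  standardize <- match.arg(standardize)
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  stopIfNot(nlevels(labels) <= model@nClasses, "too many classes for the model")
  ctr <- colMeans(features)
  scl <- if (standardize == "pooled") {
    # one pooled SD for all inputs: keeps the relative variance ordering of
    # the principal components, which carries the class signal
    rep(sqrt(mean(apply(features, 2, var))), ncol(features))
  } else apply(features, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  y <- as.integer(labels)
  n <- nrow(xs)
  model@center <- ctr; model@scale <- scl
  model@classes <- levels(labels)
  tr <- matrix(0, iterations, 2)
  withSeed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, min(batchSize, n))
      g <- cnnGradients(model, xs[idx, , drop = FALSE], y[idx])
      if (!is.finite(g$loss))
        stop("non-finite training loss at iteration ", it, call. = FALSE)
      model@params$K <- model@params$K - learningRate * g$K
      model@params$bK <- model@params$bK - learningRate * g$bK
      for (j in seq_along(model@params$fc)) {
        model@params$fc[[j]]$W <- model@params$fc[[j]]$W - learningRate * g$fc[[j]]$W
        model@params$fc[[j]]$b <- model@params$fc[[j]]$b - learningRate * g$fc[[j]]$b
      }
      p <- cnnForward(model, xs[idx, , drop = FALSE])
      tr[it, ] <- c(crossentropyLoss(p, y[idx]),
                    mean(max.col(p, ties.method = "first") == y[idx]))
    }
  })
  model@trace <- data.frame(iteration = seq_len(iterations),
                            loss = tr[, 1], accuracy = tr[, 2])
  model
}

#' @describeIn cnnTrain Per-iteration training trace accessor.
#' @export
cnnTrace <- function(model) {
  stopIfNot(is(model, "CnnModel"), "'model' must be a CnnModel")
  model@trace
}

#' Predict severity with a trained CNN
#'
#' Applies the stored standardization, runs the forward pass, and returns
#' the argmax labels together with the full softmax probability matrix
#' (rows sum to 1; usable for one-vs-rest ROC).
#'
#' @param model A trained [CnnModel-class].
#' @param features Matrix (patients x `inputLength`).
#' @return `list(labels = factor, probabilities = matrix)`.
#' @export
cnnPredict <- function(model, features) {
  stopIfNot(is(model, "CnnModel"), "'model' must be a CnnModel")
  features <- as.matrix(features)
  if (ncol(features) != model@inputLength)
    stop("feature length (", ncol(features), ") does not match input length (",
         model@inputLength, ")", call. = FALSE)
  xs <- if (length(model@center))
    sweep(sweep(features, 2, model@center), 2, model@scale, "/") else features
  p <- cnnForward(model, xs)
  lev <- model@classes
  colnames(p) <- c(lev, rep(NA, model@nClasses - length(lev)))[seq_len(model@nClasses)]
  idx <- max.col(p[, seq_along(lev), drop = FALSE], ties.method = "first")
  list(labels = factor(lev[idx], levels = severityLevels()),
       probabilities = p)
}
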