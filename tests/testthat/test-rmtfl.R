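test_that("feature normalization scales rows to unit sample norm", {
  td <- TaskDataset(list(matrix(c(3, 4), 1, 2)), list(c(0, 0)))
  out <- normalizeFeatures(td)
  expect_equal(taskDesigns(out)[[1]][1, ], c(0.6, 0.8))

  # idempotence
  out2 <- normalizeFeatures(out)
  expect_equal(taskDesigns(out2), taskDesigns(out), tolerance = 1e-12)

  # zero rows are reported, not scaled
  tdz <- TaskDataset(list(rbind(c(1, 1), c(0, 0))), list(c(0, 0)))
  expect_warning(outz <- normalizeFeatures(tdz), "all-zero")
  expect_equal(taskDesigns(outz)[[1]][2, ], c(0, 0))
  expect_equal(attr(outz, "zeroRows")[1, "feature"], c(feature = 2))
})

test_that("objective matches hand evaluation and scales linearly in lambda1", {
  # single task, d = 1: X = [1], y = 2, P = 1, Q = 0, lambdas 1 ->
  # (1/1)(1-2)^2 + 1*1 + 0 = 2
  td <- TaskDataset(list(matrix(1, 1, 1)), list(2))
  m1 <- new("RmtflModel", P = matrix(1), Q = matrix(0), W = matrix(1),
            lambda1 = 1, lambda2 = 1, objectiveTrace = numeric(0))
  expect_equal(rmtflObjective(m1, td), 2)

  # zero model on zero responses
  td0 <- TaskDataset(list(matrix(rnorm(6), 2, 3)), list(rep(0, 3)))
  m0 <- new("RmtflModel", P = matrix(0, 2, 1), Q = matrix(0, 2, 1),
            W = matrix(0, 2, 1), lambda1 = 3, lambda2 = 4,
            objectiveTrace = numeric(0))
  expect_equal(rmtflObjective(m0, td0), 0)

  # doubling lambda1 adds exactly lambda1 * ||P||_{1,2}
  P <- matrix(rnorm(6), 2, 3)
  mA <- new("RmtflModel", P = P, Q = matrix(0, 2, 3), W = P,
            lambda1 = 1, lambda2 = 0, objectiveTrace = numeric(0))
  mB <- new("RmtflModel", P = P, Q = matrix(0, 2, 3), W = P,
            lambda1 = 2, lambda2 = 0, objectiveTrace = numeric(0))
  tdm <- TaskDataset(lapply(1:3, function(i) matrix(rnorm(8), 2, 4)),
                     lapply(1:3, function(i) rnorm(4)))
  pen <- sum(sqrt(rowSums(P^2)))
  expect_equal(rmtflObjective(mB, tdm) - rmtflObjective(mA, tdm), pen,
               tolerance = 1e-12)

  expect_error(rmtflObjective(m1, td0), "dimensions")
})

test_that("group soft-thresholding matches its closed form and the numeric oracle", {
  M <- matrix(c(3, 4), 1, 2)
  expect_equal(proxGroup(M, 1, "rows"), matrix(c(2.4, 3.2), 1, 2))
  expect_equal(proxGroup(M, 0, "rows"), M)
  expect_equal(proxGroup(M, 10, "rows"), matrix(0, 1, 2))
  expect_error(proxGroup(M, -1), ">= 0")

  set.seed(17)
  for (i in 1:100) {
    g <- rnorm(sample(1:5, 1), sd = sample(c(0.1, 1, 10), 1))
    t <- runif(1, 0, 2 * sqrt(sum(g^2)))
    got <- proxGroup(matrix(g, 1), t, "rows")
    expect_equal(as.numeric(got), proxOracle(g, t), tolerance = 1e-8)
  }

  # column grouping is the row grouping of the transpose
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(proxGroup(A, 0.7, "columns"), t(proxGroup(t(A), 0.7, "rows")),
               tolerance = 1e-12)
})

test_that("huge penalties shrink the model to zero", {
  pr <- makeMultitaskProblem(d = 8, m = 3, nPerTask = 12, sShared = 2,
                             kOutlier = 1, seed = 5)
  fit <- rmtflFit(pr$data, 1e6, 1e6)
  expect_true(all(fit@P == 0))
  expect_true(all(fit@Q == 0))
})

test_that("unpenalized single-task fit matches the normal-equations oracle", {
  pr <- makeMultitaskProblem(d = 10, m = 1, nPerTask = 50, sShared = 10,
                             kOutlier = 0, noiseSd = 0, seed = 2)
  fit <- rmtflFit(pr$data, 0, 0)
  X <- taskDesigns(pr$data)[[1]]; y <- taskResponses(pr$data)[[1]]
  wls <- qr.solve(t(X), y)
  expect_lt(max(abs(fit@W[, 1] - wls)), 1e-4)
})

test_that("objective trace is non-increasing across random problems", {
  for (s in 1:5) {
    pr <- makeMultitaskProblem(d = 20, m = 4, nPerTask = 30, sShared = 4,
                               kOutlier = 1, seed = s)
    set.seed(s)
    lam <- 10^runif(2, -3, -1)
    fit <- rmtflFit(pr$data, lam[1], lam[2],
                    rmtflControl(maxIters = 300))
    tr <- objectiveTrace(fit)
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(head(tr, -1)))))
  }
})

test_that("with lambda2 large the fit matches a shared-only l2,1 solve", {
  pr <- makeMultitaskProblem(d = 15, m = 4, nPerTask = 40, sShared = 3,
                             kOutlier = 0, noiseSd = 0.05, seed = 8)
  nd <- normalizeFeatures(pr$data)
  lam1 <- 0.01
  fit <- rmtflFit(nd, lam1, 1e4)
  expect_length(outlierTasks(fit), 0)

  # independent plain row-group solver (no Q), written from the definition
  plainL21 <- function(data, lambda1, iters = 4000) {
    d <- nFeatures(data); m <- nTasks(data)
    ni <- vapply(taskDesigns(data), ncol, 1L)
    L <- max(vapply(seq_len(m), function(i)
      2 * norm(taskDesigns(data)[[i]], "2")^2 / (m * ni[i]), 0))
    P <- matrix(0, d, m)
    for (k in seq_len(iters)) {
      G <- vapply(seq_len(m), function(i) {
        r <- as.numeric(crossprod(taskDesigns(data)[[i]], P[, i])) -
          taskResponses(data)[[i]]
        (2 / (m * ni[i])) * as.numeric(taskDesigns(data)[[i]] %*% r)
      }, numeric(d))
      M <- P - (1 / L) * matrix(G, d, m)
      nrm <- sqrt(rowSums(M^2))
      P <- M * ifelse(nrm > 0, pmax(0, 1 - (lambda1 / L) / nrm), 0)
    }
    P
  }
  Pref <- plainL21(nd, lam1)
  objFit <- rmtflObjective(fit, nd)
  mref <- new("RmtflModel", P = Pref, Q = matrix(0, nrow(Pref), ncol(Pref)),
              W = Pref, lambda1 = lam1, lambda2 = 1e4,
              objectiveTrace = numeric(0))
  expect_lt(abs(objFit - rmtflObjective(mref, nd)), 1e-4)
})

test_that("feature scores are row norms of P, invariant to task permutation", {
  P <- rbind(c(1, 2, 2), c(0, 0, 0))
  m <- new("RmtflModel", P = P, Q = matrix(0, 2, 3), W = P,
           lambda1 = 0, lambda2 = 0, objectiveTrace = numeric(0))
  expect_equal(featureScores(m), c(3, 0))
  Pp <- P[, c(3, 1, 2)]
  mp <- new("RmtflModel", P = Pp, Q = matrix(0, 2, 3), W = Pp,
            lambda1 = 0, lambda2 = 0, objectiveTrace = numeric(0))
  expect_equal(featureScores(mp), featureScores(m))
})

test_that("outlier detection thresholds Q column norms", {
  Q <- cbind(c(0, 0), c(3, 4))
  m <- new("RmtflModel", P = matrix(0, 2, 2), Q = Q, W = Q,
           lambda1 = 0, lambda2 = 0, objectiveTrace = numeric(0))
  expect_identical(outlierTasks(m), 2L)
  expect_length(outlierTasks(m, tol = Inf), 0)
  m0 <- new("RmtflModel", P = matrix(0, 2, 2), Q = matrix(0, 2, 2),
            W = matrix(0, 2, 2), lambda1 = 0, lambda2 = 0,
            objectiveTrace = numeric(0))
  expect_length(outlierTasks(m0), 0)
})

test_that("selectFeatures orders by score with smallest-index tie break", {
  expect_identical(selectFeatures(c(0.5, 0.9, 0.1), 2), c(2L, 1L))
  expect_identical(selectFeatures(c(1, 1, 0), 1), 1L)
  expect_identical(selectFeatures(c(0.2, 0.8, 0.5), 3), c(2L, 3L, 1L))
  expect_error(selectFeatures(c(1, 2), 3), "out of range")
})

test_that("planted structure is recovered on a representative problem", {
  pr <- makeMultitaskProblem(d = 50, m = 5, nPerTask = 100, sShared = 5,
                             kOutlier = 1, noiseSd = 0.1, seed = 1)
  nd <- normalizeFeatures(pr$data)
  sel <- rmtflSelectLambda(nd, seed = 1)
  fit <- rmtflFit(nd, sel$lambda1, sel$lambda2)
  expect_identical(sort(selectFeatures(featureScores(fit), 5)),
                   sharedSupport(pr$truth))
  expect_identical(outlierTasks(fit), plantedOutliers(pr$truth))
})
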