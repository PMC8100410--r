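test_that("confusion counts tabulate true rows against predicted columns", {
  lev <- severityLevels()
  perfect <- confusionCounts(lev, lev)
  expect_identical(unname(diag(perfect)), rep(1L, 4))
  expect_identical(sum(perfect), 4L)

  allLow <- confusionCounts(c("low", "mild", "severe"), rep("low", 3))
  expect_identical(as.integer(colSums(allLow)), c(3L, 0L, 0L, 0L))

  expect_error(confusionCounts("low", "unknown"), "unknown label")

  # permutation equivariance under consistent relabelling
  set.seed(6)
  truth <- sample(lev, 50, replace = TRUE)
  pred <- sample(lev, 50, replace = TRUE)
  perm <- c(low = "severe", mild = "moderate", moderate = "mild",
            severe = "low")
  m1 <- confusionCounts(truth, pred)
  m2 <- confusionCounts(perm[truth], perm[pred])
  expect_identical(unname(m2[perm[lev], perm[lev]]), unname(m1))
})

test_that("the published SVM low-severity row reproduces its sensitivity", {
  m <- rbind(c(656, 30, 4, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  sens <- classSensitivity(m)
  expect_equal(asPercent(sens[1]), c(95.1), ignore_attr = TRUE)
  expect_equal(sens[[1]], 656 / 690)
})

test_that("sensitivity and precision handle perfect and degenerate classes", {
  d <- diag(c(5L, 3L, 2L, 1L))
  expect_equal(unname(classSensitivity(d)), rep(1, 4))
  expect_equal(unname(classPrecision(d)), rep(1, 4))

  m <- rbind(c(2, 1), c(0, 0))     # empty second true class
  expect_true(is.na(classSensitivity(m)[2]))
  expect_false(is.na(classPrecision(m)[2]))
  expect_identical(formatPercent(classSensitivity(m))[2], "n/a")

  toy <- rbind(c(8, 2), c(2, 8))
  expect_equal(unname(classPrecision(toy)), c(0.8, 0.8))
  expect_equal(overallAccuracy(toy), 0.8)
})

test_that("accuracy is the trace fraction with trivial bounds", {
  expect_equal(overallAccuracy(diag(1:4)), 1)
  off <- matrix(1, 2, 2) - diag(2)
  expect_equal(overallAccuracy(off), 0)
  expect_error(overallAccuracy(matrix(0, 2, 2)), "nonempty")
})

test_that("accuracy equals the frequency-weighted mean of sensitivities", {
  set.seed(11)
  for (r in 1:10) {
    truth <- sample(severityLevels(), 80, replace = TRUE,
                    prob = c(0.6, 0.2, 0.15, 0.05))
    pred <- ifelse(runif(80) < 0.7, truth,
                   sample(severityLevels(), 80, replace = TRUE))
    cm <- confusionCounts(truth, pred)
    sens <- classSensitivity(cm)
    w <- rowSums(cm) / sum(cm)
    keep <- !is.na(sens)
    expect_equal(overallAccuracy(cm), sum(w[keep] * sens[keep]),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles perfect ranking, constant scores and tied groups", {
  perfect <- rocOneVsRest(c(0.9, 0.8, 0.3, 0.1), c("a", "a", "b", "b"), "a")
  expect_equal(perfect$auc, 1)
  expect_true(all(diff(perfect$fpr) >= 0))
  expect_true(all(diff(perfect$tpr) >= 0))

  const <- rocOneVsRest(rep(0.5, 10), rep(c("a", "b"), 5), "a")
  expect_equal(const$auc, 0.5)
  expect_length(const$fpr, 2)     # single threshold step

  expect_error(rocOneVsRest(1:3, rep("b", 3), "a"), "positive class absent")
})

test_that("trapezoid AUC equals brute-force concordance", {
  set.seed(13)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))   # induce ties sometimes
    got <- rocOneVsRest(scores, ifelse(pos, "p", "n"), "p")$auc
    expect_equal(got, aucBruteForce(scores, pos), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(150)
  pos <- runif(150) < 0.5
  scores[pos] <- scores[pos] + 0.8
  got <- rocOneVsRest(scores, ifelse(pos, "p", "n"), "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the evaluation report assembles all metrics coherently", {
  set.seed(15)
  lev <- severityLevels()
  truth <- factor(sample(lev, 60, replace = TRUE), levels = lev)
  scores <- softmaxProb(matrix(rnorm(240), 60) +
                          2 * stats::model.matrix(~ 0 + truth))
  colnames(scores) <- lev
  pred <- factor(lev[max.col(scores)], levels = lev)
  rep <- evaluationReport(truth, pred, scores)
  expect_identical(sum(rep$confusion), 60L)
  expect_true(all(rep$auc > 0.5, na.rm = TRUE))
  expect_equal(rep$macroAuc, mean(rep$auc, na.rm = TRUE))
  expect_equal(rep$accuracy, overallAccuracy(rep$confusion))
})
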