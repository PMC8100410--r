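test_that("phantom generation: zero-noise identity, determinism, clean range", {
  ph0 <- makePhantom(shape = c(12, 12, 6), nBlobs = 3, noiseSigma = 0, seed = 5)
  expect_identical(volumeData(noisyVolume(ph0)), volumeData(cleanVolume(ph0)))

  a <- makePhantom(shape = c(16, 16, 8), nBlobs = 2, noiseSigma = 15, seed = 1)
  b <- makePhantom(shape = c(16, 16, 8), nBlobs = 2, noiseSigma = 15, seed = 1)
  expect_identical(volumeData(cleanVolume(a)), volumeData(cleanVolume(b)))
  expect_identical(volumeData(noisyVolume(a)), volumeData(noisyVolume(b)))

  expect_gte(min(volumeData(cleanVolume(a))), 0)
  expect_lte(max(volumeData(cleanVolume(a))), 255)
  expect_error(makePhantom(shape = c(0, 16, 8)), "positive")
})

test_that("phantom noise has the requested standard deviation", {
  ph <- makePhantom(shape = c(32, 32, 16), noiseSigma = 15, seed = 3)
  diffs <- volumeData(noisyVolume(ph)) - volumeData(cleanVolume(ph))
  empSd <- sd(diffs[2:31, 2:31, 2:15])
  expect_lt(abs(empSd - 15) / 15, 0.10)
})

test_that("rician noise option produces nonnegative intensities and differs from gaussian", {
  g <- makePhantom(shape = c(8, 8, 4), noiseSigma = 10, seed = 2)
  r <- makePhantom(shape = c(8, 8, 4), noiseSigma = 10, seed = 2,
                   noiseModel = "rician")
  expect_gte(min(volumeData(noisyVolume(r))), 0)
  expect_false(identical(volumeData(noisyVolume(r)), volumeData(noisyVolume(g))))
})

test_that("multitask problem plants the requested structure", {
  pr <- makeMultitaskProblem(d = 50, m = 5, nPerTask = 100, sShared = 5,
                             kOutlier = 1, seed = 7)
  expect_length(sharedSupport(pr$truth), 5)
  expect_length(plantedOutliers(pr$truth), 1)
  P <- pr$truth@P; Q <- pr$truth@Q
  expect_true(all(P[-sharedSupport(pr$truth), ] == 0))
  expect_true(all(Q[, -plantedOutliers(pr$truth)] == 0))

  # boundary configuration: fully shared, no outliers
  pr2 <- makeMultitaskProblem(d = 8, m = 3, nPerTask = 10, sShared = 8,
                              kOutlier = 0, seed = 1)
  expect_true(all(pr2$truth@P != 0))
  expect_true(all(pr2$truth@Q == 0))

  expect_error(makeMultitaskProblem(d = 5, m = 3, nPerTask = 10, sShared = 6,
                                    kOutlier = 0), "sShared")
  expect_error(makeMultitaskProblem(d = 5, m = 3, nPerTask = 10, sShared = 2,
                                    kOutlier = 3), "kOutlier")
})

test_that("noiseless multitask responses satisfy y = X'(p + q) exactly", {
  pr <- makeMultitaskProblem(d = 12, m = 4, nPerTask = 20, sShared = 3,
                             kOutlier = 1, noiseSd = 0, seed = 11)
  W <- pr$truth@P + pr$truth@Q
  for (i in seq_len(nTasks(pr$data))) {
    yhat <- as.numeric(crossprod(taskDesigns(pr$data)[[i]], W[, i]))
    expect_equal(taskResponses(pr$data)[[i]], yhat, tolerance = 1e-12)
  }
})

test_that("multitask generation is reproducible under the seed", {
  a <- makeMultitaskProblem(d = 10, m = 3, nPerTask = 15, sShared = 2,
                            kOutlier = 1, seed = 4)
  b <- makeMultitaskProblem(d = 10, m = 3, nPerTask = 15, sShared = 2,
                            kOutlier = 1, seed = 4)
  expect_identical(taskDesigns(a$data), taskDesigns(b$data))
  expect_identical(taskResponses(a$data), taskResponses(b$data))
  expect_identical(a$truth@P, b$truth@P)
})

test_that("cohort generation respects severity bands and proportions", {
  co <- makeCohort(nPatients = 200, nFeatures = 10,
                   classProportions = c(1, 0, 0, 0), seed = 1)
  expect_true(all(mmseScores(co) >= 25 & mmseScores(co) <= 30))
  expect_true(all(severityLabels(co) == "low"))

  # mmse always falls in the generating class's band
  co2 <- makeCohort(nPatients = 500, nFeatures = 5, seed = 9)
  expect_identical(as.character(severityFromMmse(mmseScores(co2))),
                   as.character(severityLabels(co2)))

  expect_error(makeCohort(classProportions = c(0.69, 0.21, 0.073, 0.008)),
               "sum to 1")
})

test_that("cohort effect size controls class-mean separation", {
  co0 <- makeCohort(nPatients = 50, nFeatures = 8, effectSize = 0, seed = 2)
  cm <- classMeans(co0)
  expect_true(all(cm == 0))

  co3 <- makeCohort(nPatients = 50, nFeatures = 8, effectSize = 3, seed = 2)
  cm3 <- classMeans(co3)
  expect_equal(max(abs(abs(cm3[2, ] - cm3[1, ]) - 3)), 0, tolerance = 1e-12)
})

test_that("cohort generation is reproducible and round-trips through CSV", {
  a <- makeCohort(nPatients = 40, nFeatures = 6, seed = 2)
  b <- makeCohort(nPatients = 40, nFeatures = 6, seed = 2)
  expect_identical(cohortFeatures(a), cohortFeatures(b))
  expect_identical(mmseScores(a), mmseScores(b))

  f <- tempfile(fileext = ".csv")
  writeCohortCsv(a, f)
  back <- readCohortCsv(f)
  expect_equal(unname(cohortFeatures(back)), unname(cohortFeatures(a)),
               tolerance = 1e-12)
  expect_identical(mmseScores(back), mmseScores(a))
  expect_identical(as.character(severityLabels(back)),
                   as.character(severityLabels(a)))
  unlink(f)
})

test_that("task datasets round-trip through per-task CSV plus manifest", {
  pr <- makeMultitaskProblem(d = 6, m = 3, nPerTask = 8, sShared = 2,
                             kOutlier = 1, seed = 3)
  dir <- tempfile()
  writeTaskDataset(pr$data, dir)
  back <- readTaskDataset(dir)
  expect_equal(taskDesigns(back), taskDesigns(pr$data), tolerance = 1e-12)
  expect_equal(taskResponses(back), taskResponses(pr$data), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
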