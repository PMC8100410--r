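test_that("energy of a flat candidate equal to the observation is the voxel count", {
  v <- Volume(array(7, c(4, 5, 3)))
  expect_equal(denoiseEnergy(v, v, beta = 2, lambda = 3), 60)
})

test_that("energy matches the hand-evaluated two-voxel case", {
  # I = (0, 1), I0 = (0, 0), beta = 1, lambda = 2, forward differences with
  # replicate boundary: smoothness (1+1) + (1+0), fidelity (2/2)*(0+1) -> 4
  I <- array(c(0, 1), c(2, 1, 1))
  I0 <- array(0, c(2, 1, 1))
  expect_equal(denoiseEnergy(I, I0, beta = 1, lambda = 2), 4)
})

test_that("fidelity term dominates for large lambda and shapes must agree", {
  obs <- Volume(array(rnorm(4 * 4 * 2, 100, 5), c(4, 4, 2)))
  other <- Volume(volumeData(obs) + 1)
  big <- 1e6
  expect_gt(denoiseEnergy(other, obs, 1, big), denoiseEnergy(obs, obs, 1, big))
  expect_error(denoiseEnergy(Volume(array(0, c(2, 2, 2))), obs, 1, 1), "shape")
})

test_that("analytic energy gradient matches central differences", {
  set.seed(31)
  I <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  I0 <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  g <- ADStage:::energyGradient(I, I0, beta = 1.3, lambda = 0.8)
  eps <- 1e-6
  for (idx in sample(length(I), 8)) {
    Ip <- I; Im <- I
    Ip[idx] <- Ip[idx] + eps; Im[idx] <- Im[idx] - eps
    gn <- (denoiseEnergy(Ip, I0, 1.3, 0.8) - denoiseEnergy(Im, I0, 1.3, 0.8)) /
      (2 * eps)
    expect_equal(g[idx], gn, tolerance = 1e-5)
  }
})

test_that("gradient descent keeps the energy non-increasing and fixes flat fields", {
  flat <- Volume(array(42, c(8, 8, 4)))
  fit <- denoiseVolume(flat, denoiseConfig(maxIters = 10, localSearchRate = 0))
  expect_equal(volumeData(denoisedVolume(fit)), volumeData(flat))

  ph <- makePhantom(shape = c(16, 16, 8), noiseSigma = 15, seed = 2)
  fit2 <- denoiseVolume(noisyVolume(ph), denoiseConfig(maxIters = 60))
  tr <- energyTrace(fit2)
  expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(head(tr, -1)))))
  expect_lte(tail(tr, 1),
             denoiseEnergy(noisyVolume(ph), noisyVolume(ph), 0.7, 1.5))
})

test_that("beta = 0 returns the observed volume", {
  ph <- makePhantom(shape = c(12, 12, 6), noiseSigma = 10, seed = 4)
  fit <- denoiseVolume(noisyVolume(ph),
                       denoiseConfig(beta = 0, maxIters = 50,
                                     localSearchRate = 0))
  expect_equal(volumeData(denoisedVolume(fit)),
               volumeData(noisyVolume(ph)), tolerance = 1e-10)
})

test_that("denoising improves PSNR against the clean phantom", {
  imp <- vapply(1:3, function(s) {
    ph <- makePhantom(shape = c(32, 32, 16), noiseSigma = 15, seed = s)
    fit <- denoiseVolume(noisyVolume(ph), denoiseConfig(maxIters = 100))
    psnr(cleanVolume(ph), denoisedVolume(fit)) -
      psnr(cleanVolume(ph), noisyVolume(ph))
  }, 0)
  expect_gt(mean(imp), 2)
})

test_that("candidate local search never raises the energy and is seeded", {
  ph <- makePhantom(shape = c(16, 16, 8), noiseSigma = 20, seed = 6)
  cfg <- denoiseConfig(seed = 9)
  out1 <- candidateLocalSearch(noisyVolume(ph), noisyVolume(ph), cfg)
  out2 <- candidateLocalSearch(noisyVolume(ph), noisyVolume(ph), cfg)
  expect_identical(volumeData(out1), volumeData(out2))
  expect_lte(denoiseEnergy(out1, noisyVolume(ph), cfg@beta, cfg@lambda),
             denoiseEnergy(noisyVolume(ph), noisyVolume(ph), cfg@beta, cfg@lambda))

  # a candidate that is already the energy minimizer is returned unchanged:
  # with blur-only ops on an already very smooth current iterate, blurring
  # cannot beat it against a matching observation
  flat <- Volume(array(10, c(8, 8, 4)))
  kept <- candidateLocalSearch(flat, flat, denoiseConfig(candidateOps = "gaussian_blur"))
  expect_identical(volumeData(kept), volumeData(flat))

  expect_error(candidateLocalSearch(flat, flat,
                                    denoiseConfig(candidateOps = character(0))),
               "non-empty")
})

test_that("psnr follows its closed form and sentinel conventions", {
  a <- Volume(array(100, c(4, 4, 2)))
  expect_identical(psnr(a, a), Inf)
  b <- Volume(array(100 - 255, c(4, 4, 2)))
  expect_equal(psnr(a, b), 0)
  c1 <- Volume(array(101, c(4, 4, 2)))   # MSE = 1
  expect_equal(psnr(a, c1), 10 * log10(255^2), tolerance = 1e-12)
  expect_error(psnr(a, Volume(array(0, c(2, 2, 2)))), "shape")
})

test_that("volumes round-trip through NIfTI", {
  ph <- makePhantom(shape = c(8, 8, 4), noiseSigma = 5, seed = 1)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(noisyVolume(ph), f)
  back <- readVolume(f)
  expect_equal(volumeData(back), volumeData(noisyVolume(ph)), tolerance = 1e-5)
  unlink(f)
})
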