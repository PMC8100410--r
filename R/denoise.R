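#' DenoiseConfig: settings for the variational denoiser
#'
#' The denoiser minimizes, by explicit gradient descent, the discrete energy
#' \deqn{E(I) = \sum_{\Omega} \left[ 1 + \beta^2 |\nabla I|^2 +
#'   \frac{\lambda}{2} (I - I_0)^2 \right],}
#' where \eqn{I_0} is the observed (noisy) volume, \eqn{\nabla I} the
#' forward-difference gradient with replicate (zero-flux) boundaries, and
#' \eqn{\Omega} the voxel set. `beta` weighs smoothness, `lambda` fidelity to
#' the observation; the constant term contributes the voxel count so the
#' energy of a flat field equals its size. A candidate-filter local search
#' (Gaussian blur, mean filter, global intensity scaling) can be interleaved
#' with the descent at rate `localSearchRate`; a candidate is only ever
#' accepted when it lowers the energy.
#'
#' @slot beta Smoothness weight, >= 0.
#' @slot lambda Fidelity weight, >= 0.
#' @slot stepSize Gradient-descent step; `NA` picks `1.5 / (24 beta^2 + lambda)`,
#'   inside the stability bound of the explicit scheme.
#' @slot maxIters Iteration cap, >= 1.
#' @slot tolerance Relative energy-decrease stopping threshold.
#' @slot localSearchRate Probability in \[0, 1\] of running the candidate
#'   search at an iteration.
#' @slot candidateOps Subset of `"gaussian_blur"`, `"mean_filter"`,
#'   `"intensity_scale"`.
#' @slot seed Integer seed for the candidate search randomness.
#'
#' @aliases DenoiseConfig-class
#' @exportClass DenoiseConfig
setClass("DenoiseConfig", representation(
  beta = "numeric", lambda = "numeric", stepSize = "numeric",
  maxIters = "integer", tolerance = "numeric", localSearchRate = "numeric",
  candidateOps = "character", seed = "integer"))

setValidity("DenoiseConfig", function(object) {
  if (object@beta < 0 || object@lambda < 0) return("beta and lambda must be >= 0")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@localSearchRate < 0 || object@localSearchRate > 1)
    return("localSearchRate must lie in [0, 1]")
  ok <- c("gaussian_blur", "mean_filter", "intensity_scale")
  if (!all(object@candidateOps %in% ok))
    return("unknown candidate op")
  TRUE
})

#' @describeIn DenoiseConfig Constructor with the package defaults.
#' @param beta,lambda,stepSize,maxIters,tolerance,localSearchRate,candidateOps,seed
#'   See slots.
#' @export
denoiseConfig <- function(beta = 0.7, lambda = 1.5, stepSize = NA_real_,
                          maxIters = 200L, tolerance = 1e-6,
                          localSearchRate = 0.1,
                          candidateOps = c("gaussian_blur", "mean_filter",
                                           "intensity_scale"),
                          seed = 1L) {
  if (is.na(stepSize)) stepSize <- 1.5 / (24 * beta^2 + lambda)
  stopIfNot(stepSize > 0, "'stepSize' must be positive")
  new("DenoiseConfig", beta = beta, lambda = lambda, stepSize = stepSize,
      maxIters = as.integer(maxIters), tolerance = tolerance,
      localSearchRate = localSearchRate, candidateOps = candidateOps,
      seed = as.integer(seed))
}

# forward difference along one axis, replicate boundary (last slice -> 0)
forwardDiff <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  idx <- c(seq_len(n - 1L) + 1L, n)
  out <- switch(axis,
                a[idx, , , drop = FALSE],
                a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE]) - a
  out
}

# adjoint of forwardDiff: (D^T v)_k = v_{k-1} - v_k, with the replicate
# boundary folded in (v at the last slice is zero by construction)
forwardDiffAdjoint <- function(v, axis) {
  d <- dim(v); n <- d[axis]
  shifted <- array(0, d)
  src <- seq_len(n - 1L)
  if (axis == 1L) shifted[src + 1L, , ] <- v[src, , , drop = FALSE]
  if (axis == 2L) shifted[, src + 1L, ] <- v[, src, , drop = FALSE]
  if (axis == 3L) shifted[, , src + 1L] <- v[, , src, drop = FALSE]
  shifted - v
}

#' Variational denoising energy of a candidate volume
#'
#' Evaluates the energy described in [DenoiseConfig-class] for a candidate
#' image against the observed one. The constant term (one per voxel) is
#' included, so a flat candidate equal to the observation scores exactly the
#' voxel count.
#'
#' @param candidate,observed [Volume-class] objects (or 3-D arrays) of
#'   identical shape.
#' @param beta Smoothness weight.
#' @param lambda Fidelity weight.
#' @return Finite scalar energy.
#' @examples
#' v <- Volume(array(5, c(4, 4, 4)))
#' denoiseEnergy(v, v, beta = 1, lambda = 1)   # = 64 voxels
#' @export
denoiseEnergy <- function(candidate, observed, beta, lambda) {
  I <- if (is(candidate, "Volume")) candidate@data else as.array(candidate)
  I0 <- if (is(observed, "Volume")) observed@data else as.array(observed)
  stopIfNot(identical(dim(I), dim(I0)), "volumes must have identical shapes")
  gradsq <- 0
  for (ax in 1:3) gradsq <- gradsq + sum(forwardDiff(I, ax)^2)
  prod(dim(I)) + beta^2 * gradsq + (lambda / 2) * sum((I - I0)^2)
}

# gradient of denoiseEnergy w.r.t. the candidate image
energyGradient <- function(I, I0, beta, lambda) {
  g <- lambda * (I - I0)
  for (ax in 1:3) g <- g + 2 * beta^2 * forwardDiffAdjoint(forwardDiff(I, ax), ax)
  g
}

# separable convolution along all axes with replicate padding
smoothSeparable <- function(a, kernel) {
  half <- (length(kernel) - 1L) / 2L
  for (ax in 1:3) {
    n <- dim(a)[ax]
    out <- array(0, dim(a))
    for (t in seq_along(kernel)) {
      idx <- pmin(pmax(seq_len(n) + (t - 1L - half), 1L), n)
      out <- out + kernel[t] * switch(ax,
                                      a[idx, , , drop = FALSE],
                                      a[, idx, , drop = FALSE],
                                      a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

gaussianKernel1d <- function(size) {
  sigma <- size / 4
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Candidate-filter local search
#'
#' Generates one candidate per configured operation — Gaussian blur with a
#' random kernel size in \{3, 5\}, mean (box) filter with a random size in
#' \{3, 5\}, and a global intensity scaling by a random factor in
#' \[0.7, 1.3\] — and returns whichever of the candidates and the current
#' volume has the lowest energy. The energy therefore never increases.
#' Deterministic given `config@seed`.
#'
#' @param current Current iterate ([Volume-class]).
#' @param observed Observed noisy volume.
#' @param config A [DenoiseConfig-class].
#' @return A [Volume-class] with energy `<=` that of `current`.
#' @export
candidateLocalSearch <- function(current, observed, config = denoiseConfig()) {
  stopIfNot(is(current, "Volume") && is(observed, "Volume"),
            "'current' and 'observed' must be Volumes")
  stopIfNot(length(config@candidateOps) > 0, "'candidateOps' must be non-empty")
  I <- current@data; I0 <- observed@data
  withSeed(config@seed, {
    cands <- lapply(config@candidateOps, function(op) {
      switch(op,
             gaussian_blur = smoothSeparable(I, gaussianKernel1d(sample(c(3L, 5L), 1L))),
             mean_filter = {
               sz <- sample(c(3L, 5L), 1L)
               smoothSeparable(I, rep(1 / sz, sz))
             },
             intensity_scale = I * runif(1, 0.7, 1.3))
    })
    energies <- vapply(cands, denoiseEnergy, 0, observed = I0,
                       beta = config@beta, lambda = config@lambda)
    e0 <- denoiseEnergy(I, I0, config@beta, config@lambda)
    if (min(energies) < e0) Volume(cands[[which.min(energies)]], current@spacing)
    else current
  })
}

#' Denoise a volume by gradient descent on the variational energy
#'
#' Explicit gradient descent on the energy of [denoiseEnergy()], starting
#' from the observed volume, with step halving whenever a step would raise
#' the energy, optional interleaved [candidateLocalSearch()] sweeps, and a
#' relative-decrease stopping rule. The returned energy trace is
#' non-increasing.
#'
#' @param observed Observed noisy [Volume-class].
#' @param config A [DenoiseConfig-class].
#' @return A `DenoiseFit` object; see [DenoiseFit-class].
#' @examples
#' ph <- makePhantom(shape = c(16, 16, 8), noiseSigma = 15, seed = 1)
#' fit <- denoiseVolume(noisyVolume(ph), denoiseConfig(maxIters = 50))
#' psnr(cleanVolume(ph), denoisedVolume(fit)) >
#'   psnr(cleanVolume(ph), noisyVolume(ph))
#' @export
denoiseVolume <- function(observed, config = denoiseConfig()) {
  stopIfNot(is(observed, "Volume"), "'observed' must be a Volume")
  I0 <- observed@data
  I <- I0
  beta <- config@beta; lam <- config@lambda
  step <- config@stepSize
  doSearch <- config@localSearchRate > 0 && length(config@candidateOps) > 0
  searchDraw <- if (doSearch)
    withSeed(config@seed, runif(config@maxIters)) else numeric(0)
  e <- denoiseEnergy(I, I0, beta, lam)
  trace <- e
  for (it in seq_len(config@maxIters)) {
    g <- energyGradient(I, I0, beta, lam)
    s <- step
    repeat {
      Inew <- I - s * g
      enew <- denoiseEnergy(Inew, I0, beta, lam)
      if (!is.finite(enew))
        stop("non-finite energy at iteration ", it, call. = FALSE)
      if (enew <= e || s < 1e-12 * step) break
      s <- s / 2
    }
    if (enew <= e) { I <- Inew } else enew <- e
    if (doSearch && searchDraw[it] < config@localSearchRate) {
      cfgIt <- config
      cfgIt@seed <- config@seed + it   # fresh but reproducible draws per sweep
      cand <- candidateLocalSearch(Volume(I, observed@spacing), observed,
                                   cfgIt)
      ecand <- denoiseEnergy(cand@data, I0, beta, lam)
      if (ecand < enew) { I <- cand@data; enew <- ecand }
    }
    trace <- c(trace, enew)
    if (e - enew < config@tolerance * abs(e)) { e <- enew; break }
    e <- enew
  }
  new("DenoiseFit", volume = Volume(I, observed@spacing),
      energyTrace = trace, config = config)
}

#' DenoiseFit: result of [denoiseVolume()]
#'
#' @slot volume The denoised [Volume-class].
#' @slot energyTrace Energy at the start and after each iteration;
#'   non-increasing.
#' @slot config The [DenoiseConfig-class] used.
#'
#' @aliases DenoiseFit-class
#' @exportClass DenoiseFit
setClass("DenoiseFit", representation(volume = "Volume",
                                      energyTrace = "numeric",
                                      config = "DenoiseConfig"))

setMethod("show", "DenoiseFit", function(object) {
  cat(sprintf("DenoiseFit: %d iterations, energy %.4g -> %.4g\n",
              length(object@energyTrace) - 1L,
              object@energyTrace[1], tail(object@energyTrace, 1)))
})

#' @describeIn DenoiseFit Denoised volume accessor.
#' @param x A `DenoiseFit`.
#' @export
denoisedVolume <- function(x) { stopIfNot(is(x, "DenoiseFit"), "'x' must be a DenoiseFit"); x@volume }

#' @describeIn DenoiseFit Energy trace accessor.
#' @export
energyTrace <- function(x) { stopIfNot(is(x, "DenoiseFit"), "'x' must be a DenoiseFit"); x@energyTrace }
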