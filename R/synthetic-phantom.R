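#' Phantom: paired clean / noisy synthetic volumes
#'
#' A seeded synthetic stand-in for resting-state fMRI volumes: a smooth
#' "clean" reference built from ellipsoidal blobs on a dark background, and a
#' "noisy" observation of it. Having the clean truth makes PSNR of any
#' denoiser directly measurable.
#'
#' @slot clean,noisy [Volume-class] objects of identical shape; clean
#'   intensities lie in \[0, 255\].
#' @slot noiseSigma Standard deviation of the added noise (intensity units).
#' @slot seed Integer seed that reproduces both volumes bit-identically.
#'
#' @aliases Phantom-class
#' @exportClass Phantom
setClass("Phantom", representation(clean = "Volume", noisy = "Volume",
                                   noiseSigma = "numeric", seed = "integer"))

setValidity("Phantom", function(object) {
  if (!identical(dim(object@clean@data), dim(object@noisy@data)))
    return("clean and noisy must have identical shapes")
  if (min(object@clean@data) < 0 || max(object@clean@data) > 255)
    return("clean intensities must lie in [0, 255]")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@clean@data)
  cat(sprintf("Phantom %d x %d x %d, noise sd %.2f, seed %d\n",
              d[1], d[2], d[3], object@noiseSigma, object@seed))
})

#' @describeIn Phantom Clean reference volume.
#' @param x A `Phantom`.
#' @export
cleanVolume <- function(x) { stopIfNot(is(x, "Phantom"), "'x' must be a Phantom"); x@clean }

#' @describeIn Phantom Noisy observation.
#' @export
noisyVolume <- function(x) { stopIfNot(is(x, "Phantom"), "'x' must be a Phantom"); x@noisy }

#' Generate a phantom volume with known clean reference
#'
#' The clean image is a dark background plus `nBlobs` smooth Gaussian
#' ellipsoidal blobs with random centres, semi-axes and amplitudes, clipped to
#' \[0, 255\]. Noise is additive zero-mean Gaussian of standard deviation
#' `noiseSigma` by default (`noiseModel = "rician"` applies Rician noise of
#' the same scale instead); the noisy image is clipped to \[0, 255\] as well.
#' Output is deterministic given `seed`.
#'
#' @param shape Integer length-3 vector of positive volume dimensions
#'   (default `c(64, 64, 48)`, the study's volume shape).
#' @param nBlobs Number of blobs (>= 1).
#' @param noiseSigma Noise standard deviation, >= 0 (default 15).
#' @param seed Integer seed.
#' @param noiseModel `"gaussian"` (default) or `"rician"`.
#' @param background Background intensity of the clean image (default 30).
#' @return A [Phantom-class] object.
#' @examples
#' ph <- makePhantom(shape = c(16, 16, 8), nBlobs = 2, noiseSigma = 10, seed = 1)
#' psnr(cleanVolume(ph), noisyVolume(ph))
#' @export
makePhantom <- function(shape = c(64, 64, 48), nBlobs = 5, noiseSigma = 15,
                        seed = 1, noiseModel = c("gaussian", "rician"),
                        background = 30) {
  noiseModel <- match.arg(noiseModel)
  shape <- as.integer(shape)
  stopIfNot(length(shape) == 3L && all(shape >= 1L),
            "'shape' must have 3 positive dimensions")
  stopIfNot(nBlobs >= 1, "'nBlobs' must be >= 1")
  stopIfNot(noiseSigma >= 0, "'noiseSigma' must be >= 0")

  withSeed(seed, {
    gx <- seq_len(shape[1]); gy <- seq_len(shape[2]); gz <- seq_len(shape[3])
    clean <- array(background, dim = shape)
    for (b in seq_len(nBlobs)) {
      ctr <- runif(3, 0.25, 0.75) * shape
      ax <- runif(3, 0.10, 0.25) * shape
      amp <- runif(1, 80, 170)
      # separable Gaussian profile => outer products, no voxel loop
      fx <- exp(-((gx - ctr[1]) / ax[1])^2)
      fy <- exp(-((gy - ctr[2]) / ax[2])^2)
      fz <- exp(-((gz - ctr[3]) / ax[3])^2)
      clean <- clean + amp * (fx %o% fy %o% fz)
    }
    clean <- pmin(pmax(clean, 0), 255)
    noisy <- if (noiseSigma == 0) {
      clean
    } else if (noiseModel == "gaussian") {
      clean + array(rnorm(prod(shape), 0, noiseSigma), dim = shape)
    } else {
      n1 <- array(rnorm(prod(shape), 0, noiseSigma), dim = shape)
      n2 <- array(rnorm(prod(shape), 0, noiseSigma), dim = shape)
      sqrt((clean + n1)^2 + n2^2)
    }
    noisy <- pmin(pmax(noisy, 0), 255)
    new("Phantom", clean = Volume(clean), noisy = Volume(noisy),
        noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
  })
}
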