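#' Volume: a 3-D intensity grid
#'
#' Container for a single 3-D image volume with per-axis voxel spacing.
#' Intensities are real-valued on a nominal \[0, 255\] scale; shape is fixed
#' through denoising.
#'
#' @slot data 3-D numeric array of finite intensities.
#' @slot spacing Numeric length-3 vector of positive voxel sizes
#'   (arbitrary units, default 1).
#'
#' @aliases Volume-class
#' @exportClass Volume
setClass("Volume", representation(data = "array", spacing = "numeric"))

setValidity("Volume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("'data' must be a 3-D array")
  if (!all(is.finite(object@data)))
    return("all intensities must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be 3 positive finite values")
  TRUE
})

#' Construct a Volume
#'
#' @param data 3-D numeric array.
#' @param spacing Positive per-axis voxel size, recycled to length 3.
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(array(0, c(4, 4, 2)))
#' dim(volumeData(v))
#' @export
Volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = rep(as.numeric(spacing), length.out = 3L))
}

#' @describeIn Volume Intensity array accessor.
#' @param x A `Volume`.
#' @export
volumeData <- function(x) {
  stopIfNot(is(x, "Volume"), "'x' must be a Volume")
  x@data
}

#' @describeIn Volume Voxel spacing accessor.
#' @export
voxelSpacing <- function(x) {
  stopIfNot(is(x, "Volume"), "'x' must be a Volume")
  x@spacing
}

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d (spacing %s), intensity range [%.2f, %.2f]\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x "),
              min(object@data), max(object@data)))
})

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} for `.nii` / `.nii.gz` files. Voxel
#' spacing is taken from (written to) the NIfTI header.
#'
#' @param file Path to a NIfTI file.
#' @return `readVolume` returns a [Volume-class]; `writeVolume` returns
#'   `file` invisibly.
#' @export
readVolume <- function(file) {
  img <- RNifti::readNifti(file)
  sp <- attr(RNifti::niftiHeader(img), "pixdim")
  sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  Volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname readVolume
#' @param x A [Volume-class] to write.
#' @export
writeVolume <- function(x, file) {
  stopIfNot(is(x, "Volume"), "'x' must be a Volume")
  img <- RNifti::asNifti(x@data)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Peak signal-to-noise ratio between two volumes
#'
#' PSNR = 10 log10(max_val^2 / MSE) in decibels, with MSE the mean squared
#' voxel difference. Identical volumes (MSE = 0) return `Inf`.
#'
#' @param reference,test [Volume-class] objects (or 3-D arrays) of identical
#'   shape.
#' @param maxVal Peak intensity of the scale (default 255).
#' @return PSNR in decibels.
#' @examples
#' a <- Volume(array(0, c(4, 4, 4)))
#' b <- Volume(array(1, c(4, 4, 4)))
#' psnr(a, b)            # 10*log10(255^2) ~ 48.13 dB
#' @export
psnr <- function(reference, test, maxVal = 255) {
  r <- if (is(reference, "Volume")) reference@data else as.array(reference)
  t <- if (is(test, "Volume")) test@data else as.array(test)
  stopIfNot(identical(dim(r), dim(t)), "volumes must have identical shapes")
  stopIfNot(is.numeric(maxVal) && maxVal > 0, "'maxVal' must be positive")
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(maxVal^2 / mse)
}
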