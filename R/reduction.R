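#' EigenSpectrum: principal-component decomposition of a feature table
#'
#' Mean-centred covariance PCA of a patients x features matrix. Eigenvalues
#' are sorted descending and clipped at zero (values below 1e-10 are treated
#' as numerical noise near rank deficiency); components are the matching
#' orthonormal loading vectors.
#'
#' @slot eigenvalues Descending nonnegative reals, length `N_f`.
#' @slot components `d x N_f` orthonormal loading matrix.
#' @slot meanVector Feature means removed before decomposition.
#'
#' @aliases EigenSpectrum-class
#' @exportClass EigenSpectrum
setClass("EigenSpectrum", representation(eigenvalues = "numeric",
                                         components = "matrix",
                                         meanVector = "numeric"))

setValidity("EigenSpectrum", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev))) return("eigenvalues must be sorted descending")
  if (any(ev < 0)) return("eigenvalues must be nonnegative")
  if (ncol(object@components) != length(ev))
    return("one component per eigenvalue required")
  G <- crossprod(object@components)
  if (max(abs(G - diag(nrow(G)))) > 1e-8)
    return("components must be orthonormal within 1e-8")
  TRUE
})

setMethod("show", "EigenSpectrum", function(object) {
  cat(sprintf("EigenSpectrum: %d components, total variance %.4g\n",
              length(object@eigenvalues), sum(object@eigenvalues)))
})

#' @describeIn EigenSpectrum Eigenvalue accessor.
#' @param x An `EigenSpectrum`.
#' @export
eigenvalues <- function(x) { stopIfNot(is(x, "EigenSpectrum"), "'x' must be an EigenSpectrum"); x@eigenvalues }

#' Fit PCA to a feature table
#'
#' Covariance (not correlation) PCA via [stats::prcomp]; features are
#' expected to be normalized upstream, so no second scaling is applied.
#'
#' @param features Patients x features numeric matrix with at least 2 rows.
#' @return An [EigenSpectrum-class].
#' @examples
#' sp <- pcaFit(matrix(rnorm(200), 20, 10))
#' sum(eigenvalues(sp))
#' @export
pcaFit <- function(features) {
  features <- as.matrix(features)
  stopIfNot(nrow(features) >= 2, "at least 2 patients required")
  stopIfNot(all(is.finite(features)), "features must be finite")
  pr <- prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  ev[ev < 1e-10] <- 0
  comp <- pr$rotation
  dimnames(comp) <- NULL
  new("EigenSpectrum", eigenvalues = ev, components = comp,
      meanVector = as.numeric(pr$center))
}

#' Normalized cumulative sum of eigenvalues (NCSE)
#'
#' `NCSE(i)` is the fraction of total variance captured by the first `i`
#' principal components:
#' \deqn{\mathrm{NCSE}(i) = \sum_{n=1}^{i} \mathrm{ev}(n) \Big/
#'   \sum_{n=1}^{N_f} \mathrm{ev}(n).}
#' Non-decreasing in `i` with `NCSE(N_f) = 1`.
#'
#' @param spectrum An [EigenSpectrum-class].
#' @param i Component count, `1 <= i <= N_f`. Vectorized.
#' @return Fraction(s) in \[0, 1\].
#' @export
ncse <- function(spectrum, i) {
  stopIfNot(is(spectrum, "EigenSpectrum"), "'spectrum' must be an EigenSpectrum")
  ev <- spectrum@eigenvalues
  tot <- sum(ev)
  stopIfNot(tot > 0, "total variance must be > 0")
  stopIfNot(all(i >= 1 & i <= length(ev)), "'i' out of range")
  cumsum(ev)[i] / tot
}

#' ReductionResult: selected components and the projected table
#'
#' @slot nSelected Number of retained components.
#' @slot ncseAtSelection NCSE at the selection point (>= the threshold used).
#' @slot reducedTable Patients x `nSelected` projected (centred) data.
#'
#' @aliases ReductionResult-class
#' @exportClass ReductionResult
setClass("ReductionResult", representation(nSelected = "integer",
                                           ncseAtSelection = "numeric",
                                           reducedTable = "matrix"))

setMethod("show", "ReductionResult", function(object) {
  cat(sprintf("ReductionResult: %d components retained (NCSE %.4f), %d patients\n",
              object@nSelected, object@ncseAtSelection, nrow(object@reducedTable)))
})

#' @describeIn ReductionResult Retained component count.
#' @param x A `ReductionResult`.
#' @export
nSelected <- function(x) { stopIfNot(is(x, "ReductionResult"), "'x' must be a ReductionResult"); x@nSelected }

#' @describeIn ReductionResult Projected table accessor.
#' @export
reducedTable <- function(x) { stopIfNot(is(x, "ReductionResult"), "'x' must be a ReductionResult"); x@reducedTable }

#' Select components by the cumulative-variance rule and project
#'
#' Retains the smallest `i` with `NCSE(i) >= varianceThreshold` (default
#' 0.98, i.e. 98% of variance) and projects the centred data onto those
#' components.
#'
#' @param spectrum An [EigenSpectrum-class].
#' @param features The patients x features matrix to project (typically the
#'   matrix the spectrum was fitted on, or a held-out table).
#' @param varianceThreshold Fraction in (0, 1\].
#' @return A [ReductionResult-class].
#' @export
selectComponents <- function(spectrum, features, varianceThreshold = 0.98) {
  stopIfNot(is(spectrum, "EigenSpectrum"), "'spectrum' must be an EigenSpectrum")
  stopIfNot(varianceThreshold > 0 && varianceThreshold <= 1,
            "'varianceThreshold' must lie in (0, 1]")
  frac <- ncse(spectrum, seq_along(spectrum@eigenvalues))
  nSel <- which(frac >= varianceThreshold - 1e-12)[1]
  if (is.na(nSel)) nSel <- length(spectrum@eigenvalues)
  new("ReductionResult", nSelected = as.integer(nSel),
      ncseAtSelection = frac[nSel],
      reducedTable = projectFeatures(spectrum, features, nSel))
}

#' @describeIn selectComponents Project a (new) feature table onto the first
#'   `n` components of a fitted spectrum.
#' @param n Number of leading components.
#' @export
projectFeatures <- function(spectrum, features, n) {
  stopIfNot(is(spectrum, "EigenSpectrum"), "'spectrum' must be an EigenSpectrum")
  features <- as.matrix(features)
  stopIfNot(ncol(features) == nrow(spectrum@components),
            "feature dimensionality must match the spectrum")
  ctr <- sweep(features, 2, spectrum@meanVector)
  ctr %*% spectrum@components[, seq_len(n), drop = FALSE]
}

#' Percentage reduction in feature count
#'
#' `100 * (total - retained) / total`, reported to one decimal — e.g. going
#' from 285 to 167 features is a 41.4% reduction.
#'
#' @param total,retained Positive counts with `retained <= total`.
#' @return Percentage to one decimal.
#' @examples
#' reductionPercent(285, 167)   # 41.4
#' @export
reductionPercent <- function(total, retained) {
  stopIfNot(retained >= 1 && total >= retained,
            "'retained' must satisfy 1 <= retained <= total")
  round(100 * (total - retained) / total, 1)
}
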