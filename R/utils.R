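#' @import methods
#' @importFrom stats rnorm runif prcomp predict sd var quantile setNames
#' @importFrom utils head tail read.csv write.csv read.table write.table
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps all generators reproducible without clobbering the session stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Severity classes in the fixed reporting order used throughout the package.
#' Severity class levels
#'
#' The four ordinal severity stages, ordered from least to most impaired.
#' All labelling, classification and evaluation code uses this fixed order.
#'
#' @return Character vector `c("low", "mild", "moderate", "severe")`.
#' @export
severityLevels <- function() c("low", "mild", "moderate", "severe")
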