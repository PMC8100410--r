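# Independent oracles used across the suite.

# Numeric minimizer of (1/2)||v - g||^2 + t ||v||_2. By rotational symmetry
# the minimizer lies on the ray through g, so the problem reduces to a 1-D
# convex minimization over the ray coordinate, solved by stats::optimize.
# (Scale invariance lets the search run on the unit-norm direction, and two
# Newton polish steps on numeric central differences push the ray coordinate
# to ~1e-11 — Brent alone only reaches ~1e-8.)
proxOracle <- function(g, t) {
  gn <- sqrt(sum(g^2))
  if (gn == 0) return(g * 0)
  tt <- t / gn
  f <- function(a) 0.5 * (a - 1)^2 + tt * abs(a)
  a <- stats::optimize(f, c(-0.5, 1.5), tol = 1e-10)$minimum
  h <- 1e-5
  for (k in 1:3) {
    if (a - h <= 0) break             # too close to the kink at 0
    d1 <- (f(a + h) - f(a - h)) / (2 * h)
    d2 <- (f(a + h) - 2 * f(a) + f(a - h)) / h^2
    if (!is.finite(d2) || d2 <= 1e-8) break
    a <- a - d1 / d2
  }
  if (a < 0 || f(0) <= f(max(a, 0))) a <- 0
  a * g
}

# Mann-Whitney concordance: P(score_pos > score_neg) + 0.5 P(tie), by brute
# force over all positive/negative pairs.
aucBruteForce <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Build an EigenSpectrum directly from eigenvalues (identity loadings).
spectrumFromEigenvalues <- function(ev) {
  new("EigenSpectrum", eigenvalues = as.numeric(ev),
      components = diag(length(ev)), meanVector = rep(0, length(ev)))
}

# Smallest i whose cumulative eigenvalue fraction reaches the threshold,
# by exhaustive scan.
minComponentsBruteForce <- function(ev, threshold) {
  for (i in seq_along(ev)) {
    if (sum(ev[seq_len(i)]) / sum(ev) >= threshold - 1e-12) return(i)
  }
  length(ev)
}

# A small, well-separated two-cluster dataset for classifier sanity checks.
twoClusterData <- function(n = 30, d = 5, gap = 8, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, gap), n))
    y <- factor(rep(c("low", "severe"), each = n), levels = severityLevels())
    list(x = x, y = y)
  })
}
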