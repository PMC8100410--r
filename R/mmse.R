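#' Map MMSE scores to severity classes
#'
#' The Mini-Mental State Examination (MMSE) is an integer 0-30 cognitive
#' screen; lower scores mean worse impairment. Scores are banded into four
#' ordinal severity stages: low 25-30, mild 20-25, moderate 10-20, severe
#' 0-10. The published bands share their boundary scores; the convention
#' here assigns each shared boundary to the LESS impaired class (25 -> low,
#' 20 -> mild, 10 -> moderate), matching the clinical reading that 25 is
#' still within the normal/low band. The cutpoints are configurable.
#'
#' @param score Integer MMSE score(s) in \[0, 30\]. Vectorized.
#' @param cutpoints Ascending lower bounds of the moderate, mild and low
#'   bands; default `c(10, 20, 25)`. A score `s` maps to severe if
#'   `s < cutpoints[1]`, moderate if `cutpoints[1] <= s < cutpoints[2]`,
#'   mild if `cutpoints[2] <= s < cutpoints[3]`, low otherwise.
#' @return Factor with levels `severityLevels()`.
#' @examples
#' severityFromMmse(c(30, 28, 22, 15, 5, 0))
#' @export
severityFromMmse <- function(score, cutpoints = c(10, 20, 25)) {
  stopIfNot(length(score) >= 1L && is.numeric(score), "'score' must be numeric")
  stopIfNot(all(is.finite(score)) && all(score == round(score)),
            "MMSE scores must be integers")
  stopIfNot(all(score >= 0 & score <= 30), "MMSE scores must lie in [0, 30]")
  stopIfNot(length(cutpoints) == 3L && !is.unsorted(cutpoints),
            "'cutpoints' must be 3 ascending values")
  lev <- severityLevels()
  idx <- 4L - findInterval(score, cutpoints)  # 4=severe .. 1=low
  factor(lev[idx], levels = lev)
}

#' Label a cohort of MMSE scores
#'
#' Element-wise [severityFromMmse()] plus a four-way class count summary.
#' Invalid scores are reported with their offending positions.
#'
#' @param scores Integer MMSE scores.
#' @param cutpoints Passed to [severityFromMmse()].
#' @return `list(labels = factor, counts = named integer vector)`.
#' @examples
#' labelCohort(c(30, 22, 12, 3))$counts
#' @export
labelCohort <- function(scores, cutpoints = c(10, 20, 25)) {
  if (length(scores) == 0L)
    return(list(labels = factor(character(0), levels = severityLevels()),
                counts = setNames(integer(4), severityLevels())))
  bad <- which(!is.finite(scores) | scores != round(scores) |
                 scores < 0 | scores > 30)
  if (length(bad))
    stop("invalid MMSE score at position(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  labels <- severityFromMmse(scores, cutpoints)
  list(labels = labels, counts = table(labels)[severityLevels()])
}

# Integer MMSE values belonging to each severity band under the default
# boundary convention; used by the cohort generator.
mmseBand <- function(class, cutpoints = c(10, 20, 25)) {
  switch(class,
         low      = seq.int(cutpoints[3], 30),
         mild     = seq.int(cutpoints[2], cutpoints[3] - 1L),
         moderate = seq.int(cutpoints[1], cutpoints[2] - 1L),
         severe   = seq.int(0L, cutpoints[1] - 1L),
         stop("unknown severity class: ", class, call. = FALSE))
}
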