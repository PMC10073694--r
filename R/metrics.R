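## Per-limb functional proportions and the paretic/less-affected use ratio,
## from any label source (video truth, ML predictions, count baseline).

#' Paretic / less-affected use ratio
#'
#' The percent functional use of the paretic limb normalized to the
#' less-affected limb. Deliberately not clipped: ratios above 1 (paretic
#' limb used more than the less-affected one) are legal and observed.
#'
#' @param x paretic-limb functional proportion (numeric method of the
#'   [useRatio][accessors] generic).
#' @param pLessaffected less-affected-limb functional proportion.
#' @param ... unused.
#' @return the quotient, or `NA` (with a warning) when the denominator is 0.
#' @export
setMethod("useRatio", "numeric", function(x, pLessaffected, ...) {
  if (pLessaffected <= 0) {
    warning("use ratio undefined: less-affected proportion is zero")
    return(NA_real_)
  }
  x / pLessaffected
})

#' Label count-proxy epochs by the conventional >2-count threshold
#'
#' @param counts numeric vector (or matrix) of per-epoch count-proxy values
#'   from [activityCount()].
#' @param threshold movement threshold; epochs strictly above it are labeled
#'   functional (default 2, the conventional rule).
#' @return character labels over `functional/nonfunctional`, one per epoch.
#' @export
countThresholdLabels <- function(counts, threshold = 2) {
  ifelse(as.vector(counts) > threshold, .LBL_FUN, .LBL_NON)
}

#' Per-subject use-ratio result from two per-limb label vectors
#'
#' @param labelsParetic,labelsLessaffected label vectors (samples, blocks or
#'   epochs) for the two limbs; `unknown`/`ambiguous` entries are excluded
#'   by [functionalProportion()].
#' @param subjectId subject identifier.
#' @param provenance `"video"`, `"ml"` or `"counts"`.
#' @return a [UseRatioResult-class].
#' @export
useRatioFromLabels <- function(labelsParetic, labelsLessaffected,
                               subjectId = "unknown", provenance = "video") {
  pp <- functionalProportion(labelsParetic)
  pl <- functionalProportion(labelsLessaffected)
  new("UseRatioResult", subjectId = subjectId, provenance = provenance,
      propParetic = pp, propLessaffected = pl,
      useRatio = if (pl > 0) pp / pl else NA_real_)
}
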