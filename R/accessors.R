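#' Accessor generics for package classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("limb", function(x) standardGeneric("limb"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("accelMatrix", function(x) standardGeneric("accelMatrix"))
#' @rdname accessors
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))
#' @rdname accessors
#' @export
setGeneric("blockFeatures", function(x) standardGeneric("blockFeatures"))
#' @rdname accessors
#' @export
setGeneric("blockLabels", function(x) standardGeneric("blockLabels"))
#' @rdname accessors
#' @export
setGeneric("blockCounts", function(x) standardGeneric("blockCounts"))
#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @rdname accessors
#' @export
setGeneric("useRatio", function(x, ...) standardGeneric("useRatio"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname accessors
setMethod("limb", "AccelRecording", function(x) x@limb)
#' @rdname accessors
setMethod("limb", "ConsensusTrack", function(x) x@limb)
#' @rdname accessors
setMethod("limb", "LabeledBlockSet", function(x) x@limb)
#' @rdname accessors
setMethod("sampleRate", "AccelRecording", function(x) x@sampleRate)
#' @rdname accessors
setMethod("nSamples", "AccelRecording", function(x) length(x@t))
#' @rdname accessors
setMethod("accelMatrix", "AccelRecording", function(x)
  cbind(ax = x@ax, ay = x@ay, az = x@az))
#' @rdname accessors
setMethod("trackLabels", "ConsensusTrack", function(x) x@labels)
#' @rdname accessors
setMethod("blockFeatures", "LabeledBlockSet", function(x) x@features)
#' @rdname accessors
setMethod("blockLabels", "LabeledBlockSet", function(x) x@blockLabels)
#' @rdname accessors
setMethod("blockCounts", "LabeledBlockSet", function(x) x@counts)
#' @rdname accessors
setMethod("nBlocks", "LabeledBlockSet", function(x) nrow(x@features))
#' @rdname accessors
setMethod("useRatio", "UseRatioResult", function(x, ...) x@useRatio)
#' @rdname accessors
setMethod("accuracy", "SubjectModelResult", function(x) x@accuracy)
#' @rdname accessors
setMethod("sensitivity", "SubjectModelResult", function(x) x@sensitivity)
#' @rdname accessors
setMethod("specificity", "SubjectModelResult", function(x) x@specificity)

setMethod("show", "AccelRecording", function(object) {
  cat(sprintf("AccelRecording: subject %s, %s limb\n  %d samples at %g Hz (%.1f s)\n",
              object@subjectId, object@limb, length(object@t),
              object@sampleRate, length(object@t) / object@sampleRate))
})

setMethod("show", "ConsensusTrack", function(object) {
  tb <- table(factor(object@labels, collapsedLevels()))
  cat(sprintf("ConsensusTrack: %s limb, %g fps, %d frames (F %d / N %d / U %d)\n",
              object@limb, object@fps, length(object@labels),
              tb[[.LBL_FUN]], tb[[.LBL_NON]], tb[[.LBL_UNK]]))
})

setMethod("show", "LabeledBlockSet", function(object) {
  tb <- table(factor(object@blockLabels, c(.LBL_FUN, .LBL_NON, .LBL_AMB)))
  cat(sprintf(
    "LabeledBlockSet: subject %s, %s limb\n  %d blocks x %d features (functional %d, nonfunctional %d, ambiguous %d)\n",
    object@subjectId, object@limb, nrow(object@features), ncol(object@features),
    tb[[.LBL_FUN]], tb[[.LBL_NON]], tb[[.LBL_AMB]]))
})

setMethod("show", "SubjectModelResult", function(object) {
  cat(sprintf(
    "SubjectModelResult (%s limb): accuracy %.3f, sensitivity %.3f, specificity %.3f\n  confusion TP=%d FP=%d TN=%d FN=%d\n",
    object@limb, object@accuracy, object@sensitivity, object@specificity,
    object@confusion[["TP"]], object@confusion[["FP"]],
    object@confusion[["TN"]], object@confusion[["FN"]]))
})

setMethod("show", "UseRatioResult", function(object) {
  cat(sprintf(
    "UseRatioResult [%s] subject %s: paretic %.3f / less-affected %.3f -> ratio %.3f\n",
    object@provenance, object@subjectId, object@propParetic,
    object@propLessaffected, object@useRatio))
})

setMethod("show", "TimeMap", function(object) {
  cat(sprintf(
    "TimeMap: sample = %.4f + %.6f * frame (residual RMS %.3g samples)\n",
    object@intercept, object@slope, object@residualRms))
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n  correlations:\n")
  print(object@correlations, row.names = FALSE)
  ba <- object@blandAltman
  cat(sprintf("  Bland-Altman: bias %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              ba$bias, ba$sdDiff, ba$loaLow, ba$loaHigh))
  cat(sprintf("  factor analysis: %d component(s) retained, %.1f%% variance\n",
              object@factors$auto$nFactors,
              100 * object@factors$auto$totalVariance))
})

#' Turn a list of UseRatioResult objects into a data.frame
#'
#' @param results list of [UseRatioResult-class] objects.
#' @return data.frame with columns `subject_id, provenance, prop_paretic,
#'   prop_lessaffected, use_ratio`.
#' @export
useRatioTable <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    subject_id = r@subjectId, provenance = r@provenance,
    prop_paretic = r@propParetic, prop_lessaffected = r@propLessaffected,
    use_ratio = r@useRatio, stringsAsFactors = FALSE)))
}
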