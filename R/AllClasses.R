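#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' AccelRecording: one limb's tri-axial acceleration stream
#'
#' Holds a uniformly sampled tri-axial wrist acceleration stream in gravity
#' units for one limb of one subject. Timestamps are seconds since stream
#' start and must be uniformly spaced at `1/sampleRate`.
#'
#' @slot subjectId subject identifier.
#' @slot limb `"paretic"` or `"less_affected"`.
#' @slot sampleRate sampling rate in Hz (50 for the supported sensors).
#' @slot t numeric vector of timestamps (s).
#' @slot ax,ay,az numeric acceleration per axis (g).
#' @export
setClass("AccelRecording",
  representation(subjectId = "character", limb = "character",
                 sampleRate = "numeric", t = "numeric",
                 ax = "numeric", ay = "numeric", az = "numeric"))

setValidity("AccelRecording", function(object) {
  n <- length(object@t)
  if (!object@limb %in% c("paretic", "less_affected"))
    return("limb must be 'paretic' or 'less_affected'")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    return("sampleRate must be a single positive number")
  if (n < 2L) return("recording needs at least 2 samples")
  if (length(object@ax) != n || length(object@ay) != n || length(object@az) != n)
    return("axis arrays must match timestamp length")
  if (anyNA(c(object@ax, object@ay, object@az)))
    return("NaN/NA acceleration values")
  dt <- diff(object@t)
  if (any(dt <= 0)) return("non-monotone time")
  if (any(abs(dt - 1 / object@sampleRate) > 0.5 / object@sampleRate))
    return("timestamps not uniformly spaced at 1/sampleRate (gap detected)")
  TRUE
})

#' Construct an AccelRecording
#'
#' @param t timestamps (s), uniformly spaced.
#' @param ax,ay,az per-axis acceleration (g).
#' @param sampleRate Hz; inferred from the median timestamp spacing if `NULL`.
#' @param subjectId,limb identifiers.
#' @return an [AccelRecording-class] object.
#' @export
AccelRecording <- function(t, ax, ay, az, sampleRate = NULL,
                           subjectId = "unknown", limb = "paretic") {
  if (is.null(sampleRate)) {
    if (length(t) < 2L) stopf("cannot infer sample rate from %d samples", length(t))
    sampleRate <- round(1 / stats::median(diff(t)))
  }
  new("AccelRecording", subjectId = subjectId, limb = limb,
      sampleRate = as.numeric(sampleRate), t = as.numeric(t),
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az))
}

#' SyncMark: the 5+5 shake-pulse landmarks of one recording
#'
#' Each recording is book-ended by a train of five rapid z-axis shakes; the
#' oscillation reversal peaks are the synchronization landmarks. A SyncMark
#' stores the five start-train and five end-train landmark positions either
#' in sensor time (seconds, `unit = "seconds"`) or as video frame positions
#' (`unit = "frames"`, possibly fractional).
#'
#' @slot startPulses five strictly increasing landmark positions (start train).
#' @slot endPulses five strictly increasing landmark positions (end train).
#' @slot unit `"seconds"` or `"frames"`.
#' @slot rate sampling rate of the carrying stream (Hz or fps).
#' @export
setClass("SyncMark",
  representation(startPulses = "numeric", endPulses = "numeric",
                 unit = "character", rate = "numeric"))

setValidity("SyncMark", function(object) {
  if (length(object@startPulses) != 5L || length(object@endPulses) != 5L)
    return("exactly 5 start and 5 end pulse landmarks required")
  if (any(diff(object@startPulses) <= 0) || any(diff(object@endPulses) <= 0))
    return("pulse landmarks must be strictly increasing")
  if (!object@unit %in% c("seconds", "frames"))
    return("unit must be 'seconds' or 'frames'")
  if (object@rate <= 0) return("rate must be positive")
  TRUE
})

#' @rdname SyncMark-class
#' @param startPulses,endPulses,unit,rate see slots.
#' @export
SyncMark <- function(startPulses, endPulses, unit = "seconds", rate = 50) {
  new("SyncMark", startPulses = as.numeric(startPulses),
      endPulses = as.numeric(endPulses), unit = unit, rate = as.numeric(rate))
}

#' TimeMap: affine video-frame to sensor-sample mapping
#'
#' `sample = intercept + slope * frame` (1-based sample index, 0-based frame
#' position). Fitted by least squares on the ten paired pulse landmarks.
#'
#' @slot intercept,slope affine coefficients.
#' @slot residualRms RMS of fit residuals, in sensor samples.
#' @slot sampleRate,videoFps the two clock rates (Hz).
#' @export
setClass("TimeMap",
  representation(intercept = "numeric", slope = "numeric",
                 residualRms = "numeric", sampleRate = "numeric",
                 videoFps = "numeric"))

setValidity("TimeMap", function(object) {
  if (object@slope == 0) return("degenerate (non-invertible) mapping")
  TRUE
})

#' ConsensusTrack: per-frame collapsed labels for one limb
#'
#' @slot limb `"paretic"` or `"less_affected"`.
#' @slot fps video frame rate (Hz).
#' @slot labels character vector over
#'   `c("functional", "nonfunctional", "unknown")`, one entry per frame.
#' @export
setClass("ConsensusTrack",
  representation(limb = "character", fps = "numeric", labels = "character"))

setValidity("ConsensusTrack", function(object) {
  if (!object@limb %in% c("paretic", "less_affected"))
    return("limb must be 'paretic' or 'less_affected'")
  if (!all(object@labels %in% collapsedLevels()))
    return("labels outside {functional, nonfunctional, unknown}")
  if (object@fps <= 0) return("fps must be positive")
  TRUE
})

#' @rdname ConsensusTrack-class
#' @param labels,limb,fps see slots.
#' @export
ConsensusTrack <- function(labels, limb = "paretic", fps = 30) {
  new("ConsensusTrack", limb = limb, fps = as.numeric(fps),
      labels = as.character(labels))
}

#' LabeledBlockSet: featurized 2-second blocks for one limb
#'
#' The unit of classification: non-overlapping 2-s windows of the usable
#' (between-pulse-train) stream, each carrying its 17-feature vector, its
#' purity-rule block label, and its count-proxy epochs.
#'
#' @slot features numeric matrix, blocks x 17, columns in the fixed
#'   documented order (see [featureNames()]).
#' @slot blockLabels character over
#'   `c("functional", "nonfunctional", "ambiguous")`.
#' @slot startTimes block start times (s, sensor clock).
#' @slot counts numeric matrix, blocks x epochs-per-block, count-proxy values.
#' @slot limb,subjectId identifiers.
#' @export
setClass("LabeledBlockSet",
  representation(features = "matrix", blockLabels = "character",
                 startTimes = "numeric", counts = "matrix",
                 limb = "character", subjectId = "character"))

setValidity("LabeledBlockSet", function(object) {
  n <- nrow(object@features)
  if (ncol(object@features) != 17L) return("feature matrix must have 17 columns")
  if (length(object@blockLabels) != n || length(object@startTimes) != n ||
      nrow(object@counts) != n)
    return("per-block slots must agree in length")
  if (!all(object@blockLabels %in% c(.LBL_FUN, .LBL_NON, .LBL_AMB)))
    return("block labels outside {functional, nonfunctional, ambiguous}")
  TRUE
})

#' ModelConfig: random-forest and cross-validation settings
#'
#' @slot nTrees trees per forest (default 100).
#' @slot mtry candidate features per split; `NA` means `floor(sqrt(p))`.
#' @slot minLeaf minimum terminal-node size (default 1).
#' @slot cvFolds stratified cross-validation folds (default 5).
#' @slot shuffleSeed seed for fold assignment and forest fitting.
#' @export
setClass("ModelConfig",
  representation(nTrees = "numeric", mtry = "numeric", minLeaf = "numeric",
                 cvFolds = "numeric", shuffleSeed = "numeric"),
  prototype(nTrees = 100, mtry = NA_real_, minLeaf = 1, cvFolds = 5,
            shuffleSeed = 1))

setValidity("ModelConfig", function(object) {
  if (object@cvFolds < 2) return("cvFolds must be >= 2")
  if (object@nTrees < 1) return("nTrees must be >= 1")
  TRUE
})

#' @rdname ModelConfig-class
#' @param nTrees,mtry,minLeaf,cvFolds,shuffleSeed see slots.
#' @export
ModelConfig <- function(nTrees = 100, mtry = NA, minLeaf = 1, cvFolds = 5,
                        shuffleSeed = 1) {
  new("ModelConfig", nTrees = nTrees, mtry = as.numeric(mtry),
      minLeaf = minLeaf, cvFolds = cvFolds, shuffleSeed = shuffleSeed)
}

#' SubjectModelResult: held-out predictions and metrics for one limb
#'
#' @slot limb limb the model was fit for.
#' @slot predictions per-block predicted label (held-out for unambiguous
#'   blocks; cross-fold majority for ambiguous blocks).
#' @slot folds fold index per block (`NA` for ambiguous blocks).
#' @slot confusion named numeric `c(TP, FP, TN, FN)` over unambiguous blocks,
#'   functional = positive class.
#' @slot accuracy,sensitivity,specificity performance fractions.
#' @export
setClass("SubjectModelResult",
  representation(limb = "character", predictions = "character",
                 folds = "numeric", confusion = "numeric",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric"))

setValidity("SubjectModelResult", function(object) {
  if (!setequal(names(object@confusion), c("TP", "FP", "TN", "FN")))
    return("confusion must have names TP, FP, TN, FN")
  TRUE
})

#' UseRatioResult: per-subject functional proportions and their ratio
#'
#' @slot subjectId subject identifier.
#' @slot provenance `"video"`, `"ml"`, or `"counts"`.
#' @slot propParetic,propLessaffected per-limb functional proportions in
#'   `[0, 1]`.
#' @slot useRatio paretic proportion / less-affected proportion; `NA` when
#'   the denominator is zero; deliberately not clipped at 1.
#' @export
setClass("UseRatioResult",
  representation(subjectId = "character", provenance = "character",
                 propParetic = "numeric", propLessaffected = "numeric",
                 useRatio = "numeric"))

setValidity("UseRatioResult", function(object) {
  if (!object@provenance %in% c("video", "ml", "counts"))
    return("provenance must be video, ml or counts")
  p <- c(object@propParetic, object@propLessaffected)
  if (any(p < 0 | p > 1)) return("proportions must lie in [0, 1]")
  TRUE
})

#' ValidationReport: cohort-level concurrent-validity statistics
#'
#' @slot correlations data.frame: pair, n, r, ciLow, ciHigh.
#' @slot regressions data.frame: pair, slope, intercept, r2.
#' @slot blandAltman list: bias, sdDiff, loaLow, loaHigh, biasCiLow,
#'   biasCiHigh, means, diffs.
#' @slot factors list with `auto` and `forced2` factor solutions.
#' @slot useRatios data.frame of per-subject use ratios by provenance.
#' @export
setClass("ValidationReport",
  representation(correlations = "data.frame", regressions = "data.frame",
                 blandAltman = "list", factors = "list",
                 useRatios = "data.frame"))

#' SimSubjectSpec: parameters of one synthetic subject session
#'
#' @slot subjectId identifier.
#' @slot impairment latent severity in `[0, 1]`; scales paretic burst
#'   amplitude by `1 - impairment` and drives the clinical-score couplings.
#' @slot propFunctionalParetic,propFunctionalLessaffected target fraction of
#'   schedulable session time spent in functional epochs, per limb.
#' @slot gaitFraction fraction of session time in whole-body (gait) epochs,
#'   shared by both limbs.
#' @slot sessionLength schedulable seconds (sync trains are added on top).
#' @slot seed integer seed; identical spec + seed reproduces the session
#'   bit-identically.
#' @export
setClass("SimSubjectSpec",
  representation(subjectId = "character", impairment = "numeric",
                 propFunctionalParetic = "numeric",
                 propFunctionalLessaffected = "numeric",
                 gaitFraction = "numeric", sessionLength = "numeric",
                 seed = "numeric"))

setValidity("SimSubjectSpec", function(object) {
  fr <- c(object@impairment, object@propFunctionalParetic,
          object@propFunctionalLessaffected, object@gaitFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@propFunctionalParetic + object@gaitFraction > 1 ||
      object@propFunctionalLessaffected + object@gaitFraction > 1)
    return("gait + functional fraction exceeds schedulable time on a limb")
  if (object@sessionLength < 60) return("sessionLength must be >= 60 s")
  TRUE
})

#' @rdname SimSubjectSpec-class
#'
#' @param subjectId identifier.
#' @param impairment latent severity in `[0, 1]`.
#' @param propFunctionalParetic,propFunctionalLessaffected target functional
#'   fractions; by default coupled to impairment as
#'   `0.05 + 0.40 * (1 - impairment)` (paretic) and `0.45` (less-affected),
#'   so the true use ratio falls with severity.
#' @param gaitFraction fraction of time in whole-body movement (default 0.2).
#' @param sessionLength schedulable seconds (default 300).
#' @param seed session seed.
#' @export
SimSubjectSpec <- function(subjectId = "S1", impairment = 0.5,
                           propFunctionalParetic = NULL,
                           propFunctionalLessaffected = NULL,
                           gaitFraction = 0.2, sessionLength = 300, seed = 1) {
  if (is.null(propFunctionalParetic))
    propFunctionalParetic <- 0.05 + 0.40 * (1 - impairment)
  if (is.null(propFunctionalLessaffected))
    propFunctionalLessaffected <- 0.45
  new("SimSubjectSpec", subjectId = subjectId, impairment = impairment,
      propFunctionalParetic = propFunctionalParetic,
      propFunctionalLessaffected = propFunctionalLessaffected,
      gaitFraction = gaitFraction, sessionLength = sessionLength, seed = seed)
}

#' SimCohortSpec: parameters of a synthetic cohort
#'
#' Clinical-score couplings are linear in the latent impairment with Gaussian
#' noise, clipped to instrument range: ARAT `57*(1-imp) + N(0,4^2)` in
#' `[0,57]`; UEFM `66*0.8*(1-imp) + 10 + N(0,4^2)` in `[0,66]`; MAL
#' `5*(1-imp) + N(0,0.5^2)` in `[0,5]`; nine-hole peg time
#' `30 + 250*imp + N(0,15^2)` seconds, floored at 1.
#'
#' @slot nSubjects cohort size (>= 3).
#' @slot impairmentRange interval in `[0, 1]` spanned evenly by the cohort.
#' @slot couplings named list of `c(slope, intercept, noiseSd)` per scale.
#' @slot annotatorErrorRate per-frame mislabel probability in `[0, 0.5)`.
#' @slot nAnnotators number of independent annotators (default 3).
#' @slot sessionLength,gaitFraction forwarded to each subject spec.
#' @slot nMissingSecondary number of subjects with UEFM/MAL/peg masked
#'   (ARAT-only batteries); one additional subject loses only the peg time.
#' @slot masterSeed master seed for the whole cohort.
#' @export
setClass("SimCohortSpec",
  representation(nSubjects = "numeric", impairmentRange = "numeric",
                 couplings = "list", annotatorErrorRate = "numeric",
                 nAnnotators = "numeric", sessionLength = "numeric",
                 gaitFraction = "numeric", nMissingSecondary = "numeric",
                 masterSeed = "numeric"))

setValidity("SimCohortSpec", function(object) {
  if (object@nSubjects < 3) return("nSubjects must be >= 3")
  if (length(object@impairmentRange) != 2L ||
      any(object@impairmentRange < 0 | object@impairmentRange > 1) ||
      diff(object@impairmentRange) < 0)
    return("impairmentRange must be an increasing interval inside [0, 1]")
  if (object@annotatorErrorRate < 0 || object@annotatorErrorRate >= 0.5)
    return("annotatorErrorRate must lie in [0, 0.5)")
  sds <- vapply(object@couplings, function(cc) cc[["noiseSd"]], 0)
  if (any(sds < 0)) return("negative noise SD in couplings")
  TRUE
})

defaultCouplings <- function() list(
  ARAT = c(slope = -57, intercept = 57, noiseSd = 4),
  UEFM = c(slope = -66 * 0.8, intercept = 66 * 0.8 + 10, noiseSd = 4),
  MAL  = c(slope = -5, intercept = 5, noiseSd = 0.5),
  peg  = c(slope = 250, intercept = 30, noiseSd = 15))

#' @rdname SimCohortSpec-class
#' @param nSubjects,impairmentRange,couplings,annotatorErrorRate,nAnnotators
#'   see slots.
#' @param sessionLength,gaitFraction,nMissingSecondary,masterSeed see slots.
#' @export
SimCohortSpec <- function(nSubjects = 12, impairmentRange = c(0.1, 0.8),
                          couplings = defaultCouplings(),
                          annotatorErrorRate = 0.05, nAnnotators = 3,
                          sessionLength = 300, gaitFraction = 0.2,
                          nMissingSecondary = 0, masterSeed = 1) {
  new("SimCohortSpec", nSubjects = nSubjects,
      impairmentRange = as.numeric(impairmentRange), couplings = couplings,
      annotatorErrorRate = annotatorErrorRate, nAnnotators = nAnnotators,
      sessionLength = sessionLength, gaitFraction = gaitFraction,
      nMissingSecondary = nMissingSecondary, masterSeed = masterSeed)
}
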