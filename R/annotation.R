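## FAABOS collapse, majority-vote annotator merging, label transfer onto the
## sensor timeline, and video-ground-truth functional proportions.

#' Default FAABOS collapse mapping
#'
#' The five raw frame codes collapse to three categories: the two lowest
#' codes (no movement, and arm motion secondary to gait/whole-body movement)
#' to `nonfunctional`, the two task-engaged codes to `functional`, and the
#' remaining/unscorable code to `unknown`. The mapping is configurable and
#' should be echoed into the run manifest.
#'
#' @return named character vector, names `"0"`-`"4"`.
#' @export
faabosDefaultMapping <- function() {
  c("0" = .LBL_NON, "1" = .LBL_NON, "2" = .LBL_FUN, "3" = .LBL_FUN,
    "4" = .LBL_UNK)
}

#' Collapse raw FAABOS codes to the three-category alphabet
#'
#' @param codes integer vector of raw codes; `NA` is the unscored sentinel
#'   and collapses to `unknown`.
#' @param mapping named character vector from code (as character) to
#'   collapsed label; must cover every non-NA code present.
#' @return character vector over `functional/nonfunctional/unknown`.
#' @export
collapseFaabos <- function(codes, mapping = faabosDefaultMapping()) {
  if (!all(mapping %in% collapsedLevels()))
    stopf("mapping values outside the collapsed alphabet")
  out <- rep(.LBL_UNK, length(codes))
  scored <- !is.na(codes)
  key <- as.character(codes[scored])
  bad <- setdiff(unique(key), names(mapping))
  if (length(bad)) stopf("code(s) outside alphabet: %s", paste(bad, collapse = ", "))
  out[scored] <- unname(mapping[key])
  out
}

#' Merge collapsed annotator tracks by strict per-frame majority vote
#'
#' A frame's consensus label is the category chosen by a strict majority of
#' annotators; frames with no strict majority (e.g. a functional /
#' nonfunctional / unknown three-way split) become `unknown`, preserving
#' timeline alignment. With a single annotator the merge is the identity.
#'
#' @param tracks list of equal-length character vectors over the collapsed
#'   alphabet, or a list of [ConsensusTrack-class] objects (same limb/fps).
#' @param limb,fps used when `tracks` are bare vectors.
#' @return a [ConsensusTrack-class].
#' @export
mergeAnnotators <- function(tracks, limb = "paretic", fps = 30) {
  if (!length(tracks)) stopf("at least one annotator track required")
  if (is(tracks[[1]], "ConsensusTrack")) {
    limbs <- vapply(tracks, function(x) x@limb, "")
    if (length(unique(limbs)) != 1L) stopf("limb mismatch between tracks")
    limb <- limbs[1]
    fps <- tracks[[1]]@fps
    tracks <- lapply(tracks, function(x) x@labels)
  }
  n <- unique(lengths(tracks))
  if (length(n) != 1L) stopf("length mismatch between annotator tracks")
  k <- length(tracks)
  counts <- vapply(collapsedLevels(), function(lv)
    Reduce(`+`, lapply(tracks, function(tr) tr == lv)) + 0, numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1,
                                dimnames = list(NULL, collapsedLevels()))
  top <- max.col(counts, ties.method = "first")
  out <- ifelse(counts[cbind(seq_len(n), top)] > k / 2,
                collapsedLevels()[top], .LBL_UNK)
  ConsensusTrack(out, limb = limb, fps = fps)
}

#' Transfer consensus frame labels onto the sensor timeline
#'
#' Each sensor sample takes the label of the nearest video frame under the
#' time map; samples mapping outside the video's frame range become
#' `unknown`.
#'
#' @param consensus a [ConsensusTrack-class].
#' @param map a [TimeMap-class] fitted by [buildTimeMap()].
#' @param rec the [AccelRecording-class] receiving the labels.
#' @return character vector, one collapsed label per sensor sample.
#' @export
transferLabels <- function(consensus, map, rec) {
  nF <- length(consensus@labels)
  frame <- round(sampleToFrame(map, seq_len(length(rec@t))))
  out <- rep(.LBL_UNK, length(frame))
  covered <- frame >= 0 & frame <= nF - 1
  out[covered] <- consensus@labels[frame[covered] + 1L]
  out
}

#' Functional proportion of a label sequence
#'
#' `functional / (functional + nonfunctional)`; `unknown` (and any other
#' value, e.g. `ambiguous` or `sync`) is excluded from both numerator and
#' denominator. Works for per-sample and per-block label vectors alike.
#'
#' @param labels character label vector.
#' @return fraction in `[0, 1]`.
#' @export
functionalProportion <- function(labels) {
  nf <- sum(labels == .LBL_FUN)
  nn <- sum(labels == .LBL_NON)
  if (nf + nn == 0L) stopf("no classifiable (functional/nonfunctional) labels")
  nf / (nf + nn)
}

#' @rdname functionalProportion
#' @inheritParams functionalProportion
#' @details `groundTruthProportion` is an alias used for video-derived
#'   sample labels.
#' @export
groundTruthProportion <- functionalProportion

#' Read/write annotator label CSV files
#'
#' Schema: `frame,annotator,limb,faabos_code`, frame indices 0-based; one
#' row per frame per annotator. Consensus output schema: `frame,limb,label`.
#'
#' @param path CSV path.
#' @return `readLabelsCsv`: list of raw annotator tracks (as in
#'   [simulateAnnotators()]).
#' @export
readLabelsCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "annotator", "limb", "faabos_code")
  if (!all(need %in% names(df)))
    stopf("malformed header: expected %s", paste(need, collapse = ","))
  lapply(split(df, df$annotator), function(d) {
    d <- d[order(d$frame), ]
    list(annotatorId = as.character(d$annotator[1]),
         limb = as.character(d$limb[1]), fps = 30, codes = d$faabos_code)
  })
}

#' @rdname readLabelsCsv
#' @param tracks list of raw annotator tracks.
#' @export
writeLabelsCsv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) data.frame(
    frame = seq_along(tr$codes) - 1L, annotator = tr$annotatorId,
    limb = tr$limb, faabos_code = tr$codes, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
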