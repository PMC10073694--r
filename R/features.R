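## Block partitioning, the >90% purity labeling rule, the 17-feature vector,
## and the band-pass/rectify/integrate activity-count proxy.

#' Names of the 17 block features, in the fixed export order
#'
#' Per-axis mean, variance (population), maximum, minimum (12 values), then
#' the same four summaries of the per-sample vector magnitude
#' `sqrt(ax^2 + ay^2 + az^2)` (4 values), then the Shannon entropy of the
#' magnitude sequence (1 value). This order is part of the model contract
#' and is embedded in exported feature matrices.
#'
#' @return character vector of length 17.
#' @export
featureNames <- function() {
  c(as.vector(outer(c("mean", "var", "max", "min"), c("ax", "ay", "az"),
                    function(s, a) paste(a, s, sep = "_"))),
    "mag_mean", "mag_var", "mag_max", "mag_min", "mag_entropy")
}

#' Partition the usable stream into non-overlapping 2-second blocks
#'
#' Blocks are contiguous, non-overlapping windows of
#' `blockLengthS * sampleRate` samples anchored at the first sample after
#' the leading shake-pulse train; samples inside either pulse train (plus a
#' small guard) never enter blocks, and a trailing partial block is dropped.
#'
#' @param rec an [AccelRecording-class].
#' @param sampleLabels optional per-sample collapsed labels (from
#'   [transferLabels()]); recycled into the blocks for the purity rule.
#' @param blockLengthS block length in seconds (default 2).
#' @param syncMarks optional sensor-side [SyncMark-class]; when given, the
#'   usable span is (last start-train peak + guard, first end-train peak -
#'   guard), otherwise the whole recording is used.
#' @param guardS guard after/before the pulse trains (default 0.5 s).
#' @return list of blocks; each block is a list with `index`, `startTime`,
#'   `samples` (n x 3 matrix), and `sampleLabels` (or `NULL`).
#' @export
partitionBlocks <- function(rec, sampleLabels = NULL, blockLengthS = 2,
                            syncMarks = NULL, guardS = 0.5) {
  fs <- rec@sampleRate
  n <- length(rec@t)
  from <- 1L
  to <- n
  if (!is.null(syncMarks)) {
    from <- which(rec@t >= max(syncMarks@startPulses) + guardS)[1]
    to <- max(which(rec@t < min(syncMarks@endPulses) - guardS))
    if (is.na(from) || from >= to) stopf("empty usable span")
  }
  bl <- round(blockLengthS * fs)
  nb <- (to - from + 1L) %/% bl
  if (nb < 1L) stopf("empty usable span: fewer than one block")
  acc <- accelMatrix(rec)
  lapply(seq_len(nb), function(b) {
    idx <- from + (b - 1L) * bl + seq_len(bl) - 1L
    list(index = b, startTime = rec@t[idx[1]],
         samples = acc[idx, , drop = FALSE],
         sampleLabels = if (!is.null(sampleLabels)) sampleLabels[idx])
  })
}

#' Label a block by the >90% purity rule
#'
#' A block is labeled `functional` or `nonfunctional` when the count of that
#' class strictly exceeds `purityThreshold` of ALL samples in the block
#' (unknown-labeled samples count in the denominator but can never satisfy
#' the rule); otherwise the block is `ambiguous` and is excluded from
#' training, though still predicted at test time.
#'
#' @param block a block from [partitionBlocks()] with `sampleLabels`.
#' @param purityThreshold purity fraction (default 0.90).
#' @return one of `"functional"`, `"nonfunctional"`, `"ambiguous"`.
#' @export
labelBlock <- function(block, purityThreshold = 0.90) {
  lab <- block$sampleLabels
  if (is.null(lab)) stopf("block carries no sample labels")
  n <- length(lab)
  for (cls in c(.LBL_FUN, .LBL_NON))
    if (sum(lab == cls) > purityThreshold * n) return(cls)
  .LBL_AMB
}

#' Shannon entropy of a sample sequence (bits)
#'
#' Histogram entropy over `nBins` equal-width bins spanning `[min, max]` of
#' the sequence: `-sum(p * log2(p))` over non-empty bins. A constant
#' sequence (zero range) has entropy 0; the maximum is `log2(nBins)`.
#'
#' @param x numeric vector (here: a block's vector-magnitude sequence).
#' @param nBins number of bins (default 16).
#' @return entropy in bits.
#' @export
shannonEntropy <- function(x, nBins = 16) {
  if (!length(x)) stopf("empty sequence")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  breaks <- seq(lo, hi, length.out = nBins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  p <- tabulate(bin, nBins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the 17-feature vector from a block
#'
#' @param block a block from [partitionBlocks()] (only `samples` is used).
#' @param nBins entropy bins, forwarded to [shannonEntropy()].
#' @return named numeric vector of length 17, in [featureNames()] order.
#' @export
extractFeatures <- function(block, nBins = 16) {
  s <- block$samples
  mag <- sqrt(rowSums(s^2))
  axisFeats <- unlist(lapply(1:3, function(a) {
    x <- s[, a]
    c(mean(x), popVar(x), max(x), min(x))
  }))
  out <- c(axisFeats, mean(mag), popVar(mag), max(mag), min(mag),
           shannonEntropy(mag, nBins))
  stats::setNames(out, featureNames())
}

#' Activity-count proxy per epoch
#'
#' A documented stand-in for legacy actigraphy counts: the gravity-removed
#' vector magnitude is band-pass filtered (Butterworth order 2,
#' `band` Hz, zero-phase), rectified, and integrated over consecutive
#' `epochS`-second epochs, scaled by a fixed gain. The gain (1 count per
#' g-sample) was calibrated once so that rest-level noise falls below the
#' conventional >2-count movement threshold while whole-body (gait)
#' oscillation and functional movement fall above it; it is an approximate
#' baseline, not an emulation of any proprietary count algorithm.
#'
#' @param block a block from [partitionBlocks()].
#' @param band band-pass corner frequencies in Hz (default 0.25-2.5).
#' @param epochS epoch length in seconds (default 1).
#' @param sampleRate sampling rate (default 50).
#' @param gain fixed scale to count-like units (default 1).
#' @return numeric vector of counts, one per epoch in the block.
#' @export
activityCount <- function(block, band = c(0.25, 2.5), epochS = 1,
                          sampleRate = 50, gain = 1) {
  s <- block$samples
  mag <- sqrt(rowSums(s^2)) - 1
  bf <- signal::butter(2, band / (sampleRate / 2), type = "pass")
  y <- signal::filtfilt(bf, mag)
  perEpoch <- round(epochS * sampleRate)
  nE <- length(y) %/% perEpoch
  vapply(seq_len(nE), function(e)
    gain * sum(abs(y[(e - 1) * perEpoch + seq_len(perEpoch)])), 0)
}

#' Build a LabeledBlockSet for one limb
#'
#' Convenience assembly: partitions the usable stream, applies the purity
#' rule, extracts features and count epochs per block.
#'
#' @inheritParams partitionBlocks
#' @param purityThreshold forwarded to [labelBlock()].
#' @return a [LabeledBlockSet-class].
#' @export
buildBlockSet <- function(rec, sampleLabels, syncMarks = NULL,
                          blockLengthS = 2, purityThreshold = 0.90,
                          guardS = 0.5) {
  blocks <- partitionBlocks(rec, sampleLabels, blockLengthS = blockLengthS,
                            syncMarks = syncMarks, guardS = guardS)
  feats <- t(vapply(blocks, extractFeatures, numeric(17)))
  labs <- vapply(blocks, labelBlock, "", purityThreshold = purityThreshold)
  counts <- t(vapply(blocks, activityCount, numeric(round(blockLengthS)),
                     sampleRate = rec@sampleRate))
  new("LabeledBlockSet", features = feats, blockLabels = labs,
      startTimes = vapply(blocks, `[[`, 0, "startTime"), counts = counts,
      limb = rec@limb, subjectId = rec@subjectId)
}
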