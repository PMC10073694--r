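## Sensor stream I/O, shake-pulse detection, and the video<->sensor time map.

#' Read an acceleration stream from CSV
#'
#' Canonical dialect: header `time_s,ax_g,ay_g,az_g`, comma-separated, UTF-8.
#' Units are part of the header contract; files with other column names are
#' accepted only through an explicit `columns` map.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping canonical names
#'   (`time_s, ax_g, ay_g, az_g`) to the file's column names.
#' @param subjectId,limb identifiers attached to the recording.
#' @param sampleRate Hz; inferred from timestamps when `NULL`.
#' @return an [AccelRecording-class].
#' @export
readAccelCsv <- function(path, columns = NULL, subjectId = "unknown",
                         limb = "paretic", sampleRate = NULL) {
  canon <- c("time_s", "ax_g", "ay_g", "az_g")
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(columns)) columns <- stats::setNames(canon, canon)
  if (!all(canon %in% names(columns)))
    stopf("columns map must cover %s", paste(canon, collapse = ", "))
  missing <- setdiff(unname(columns[canon]), names(df))
  if (length(missing))
    stopf("malformed header: missing column(s) %s", paste(missing, collapse = ", "))
  t <- df[[columns[["time_s"]]]]
  if (anyNA(t) || any(diff(t) <= 0)) stopf("non-monotone time")
  if (is.null(sampleRate)) sampleRate <- round(1 / stats::median(diff(t)))
  if (any(diff(t) > 1.5 / sampleRate)) stopf("gap in timestamps (> 1.5 sample intervals)")
  acc <- lapply(c("ax_g", "ay_g", "az_g"), function(a) df[[columns[[a]]]])
  if (anyNA(unlist(acc))) stopf("NaN acceleration values")
  AccelRecording(t, acc[[1]], acc[[2]], acc[[3]], sampleRate = sampleRate,
                 subjectId = subjectId, limb = limb)
}

#' Write an acceleration stream to CSV (canonical dialect)
#'
#' @param rec an [AccelRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAccelCsv <- function(rec, path) {
  df <- data.frame(time_s = rec@t, ax_g = rec@ax, ay_g = rec@ay, az_g = rec@az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read video-side sync marks from CSV
#'
#' Schema: header `train,frame_index` with `train` in `{start, end}`; frame
#' positions may be fractional.
#'
#' @param path CSV path.
#' @param fps video frame rate.
#' @return a [SyncMark-class] with `unit = "frames"`.
#' @export
readSyncMarksCsv <- function(path, fps = 30) {
  df <- utils::read.csv(path)
  if (!all(c("train", "frame_index") %in% names(df)))
    stopf("malformed header: expected train,frame_index")
  SyncMark(sort(df$frame_index[df$train == "start"]),
           sort(df$frame_index[df$train == "end"]),
           unit = "frames", rate = fps)
}

#' @rdname readSyncMarksCsv
#' @param marks a [SyncMark-class] with `unit = "frames"`.
#' @export
writeSyncMarksCsv <- function(marks, path) {
  df <- data.frame(train = rep(c("start", "end"), each = 5),
                   frame_index = c(marks@startPulses, marks@endPulses))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## strict local maxima of x above `thr` separated by >= refractory samples
localMaxima <- function(x, thr, refractorySamples) {
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] > x[cand - 1] & x[cand] > x[cand + 1]]
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractorySamples) {
      keep <- c(keep, i)
      last <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i   # same burst, higher peak wins
      last <- i
    }
  }
  keep
}

#' Detect the shake-pulse trains in a recording
#'
#' The synchronization protocol shakes both sensors rapidly in z five times
#' before donning and after removal, leaving five large z-axis peaks per
#' train. Peaks are strict local maxima of the z signal above
#' `minAmplitudeG`, with a 100 ms refractory separation, searched in the
#' leading and trailing `searchWindowS` seconds.
#'
#' @param rec an [AccelRecording-class].
#' @param minAmplitudeG detection threshold (g); default 2, well above the
#'   <= 1.5 g activity content and below the 4 g pulse amplitude.
#' @param searchWindowS seconds searched at each end of the stream.
#' @return a [SyncMark-class] with `unit = "seconds"` (sensor side).
#' @export
detectSyncPulses <- function(rec, minAmplitudeG = 2, searchWindowS = 10) {
  fs <- rec@sampleRate
  refr <- ceiling(0.1 * fs)
  n <- length(rec@t)
  pickTrain <- function(idx, name) {
    pk <- localMaxima(rec@az[idx], minAmplitudeG, refr)
    if (length(pk) < 5L)
      stopf("sync not found (%d peaks) in %s window", length(pk), name)
    if (length(pk) > 5L)   # keep the five largest, restore time order
      pk <- sort(pk[order(rec@az[idx][pk], decreasing = TRUE)[1:5]])
    rec@t[idx[pk]]
  }
  lead <- seq_len(min(n, round(searchWindowS * fs)))
  trail <- seq.int(max(1L, n - round(searchWindowS * fs) + 1L), n)
  SyncMark(pickTrain(lead, "leading"), pickTrain(trail, "trailing"),
           unit = "seconds", rate = fs)
}

#' Fit the affine video-frame to sensor-sample time map
#'
#' Least-squares affine fit (offset + clock drift) through the ten paired
#' pulse landmarks: `sample_index = intercept + slope * frame`. An
#' offset-only fit (slope fixed at the nominal rate ratio) is available for
#' short sessions where drift is negligible.
#'
#' @param sensorMarks [SyncMark-class] in seconds (from
#'   [detectSyncPulses()] or generator truth).
#' @param videoMarks [SyncMark-class] in frames.
#' @param sampleRate sensor rate (Hz).
#' @param maxResidualSamples reject the pairing when the residual RMS
#'   exceeds this many sensor samples (default 2).
#' @param driftFree if `TRUE`, fix the slope at `sampleRate / videoFps` and
#'   fit only the offset.
#' @return a [TimeMap-class].
#' @export
buildTimeMap <- function(sensorMarks, videoMarks, sampleRate = 50,
                         maxResidualSamples = 2, driftFree = FALSE) {
  stopifnot(is(sensorMarks, "SyncMark"), is(videoMarks, "SyncMark"))
  if (sensorMarks@unit != "seconds" || videoMarks@unit != "frames")
    stopf("sensorMarks must be in seconds and videoMarks in frames")
  frames <- c(videoMarks@startPulses, videoMarks@endPulses)
  samples <- 1 + c(sensorMarks@startPulses, sensorMarks@endPulses) * sampleRate
  if (driftFree) {
    slope <- sampleRate / videoMarks@rate
    intercept <- mean(samples - slope * frames)
  } else {
    fit <- stats::lm.fit(cbind(1, frames), samples)
    intercept <- fit$coefficients[[1]]
    slope <- fit$coefficients[[2]]
  }
  resid <- samples - (intercept + slope * frames)
  rms <- sqrt(mean(resid^2))
  if (rms > maxResidualSamples)
    stopf("sync inconsistent: residual RMS %.2f samples exceeds %g", rms,
          maxResidualSamples)
  new("TimeMap", intercept = intercept, slope = slope, residualRms = rms,
      sampleRate = sampleRate, videoFps = videoMarks@rate)
}

#' Map video frames to sensor sample indices and back
#'
#' @param map a [TimeMap-class].
#' @param frame 0-based video frame positions.
#' @return `frameToSample`: fractional 1-based sample indices;
#'   `sampleToFrame`: fractional 0-based frame positions.
#' @export
frameToSample <- function(map, frame) map@intercept + map@slope * frame

#' @rdname frameToSample
#' @param sample 1-based sensor sample indices.
#' @export
sampleToFrame <- function(map, sample) (sample - map@intercept) / map@slope
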