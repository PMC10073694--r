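## Synthetic session generator: seeded epoch schedules (rest / functional /
## gait) rendered as 50 Hz tri-axial signals on two limbs, with 30 Hz
## frame-level truth tracks and z-axis shake-pulse trains at both ends.

.SYNC_DUR <- 2.5    # 5 cycles at 2 Hz
.SYNC_FREQ <- 2     # Hz
.SYNC_AMP <- 4      # g, z axis
.REST_SD <- 0.02    # g, sensor noise floor on every axis
.SAMPLE_RATE <- 50
.VIDEO_FPS <- 30

#' Sensor-time landmark truth for a simulated pulse train
#'
#' Positive z-peak (oscillation reversal) times of a 5-cycle sinusoidal shake
#' train starting at `t0`.
#' @param t0 train start time (s).
#' @return five peak times (s).
#' @keywords internal
syncPeakTimes <- function(t0) t0 + 1 / (4 * .SYNC_FREQ) + (0:4) / .SYNC_FREQ

## split a time budget into epoch-sized chunks (uniform 2-6 s, seeded caller RNG)
chunkBudget <- function(total, minD = 2, maxD = 6) {
  out <- numeric(0)
  left <- total
  while (left > 1e-9) {
    d <- stats::runif(1, minD, maxD)
    if (left - d < minD) d <- left
    out <- c(out, d)
    left <- left - d
  }
  out
}

## Epoch schedule. Gait epochs occupy shared positions on the global
## timeline (whole-body movement moves both wrists at once); each limb's
## functional epochs are then placed independently inside the non-gait gaps,
## so the two limbs' functional time may overlap (bimanual activity) and the
## per-limb constraint is functional + gait <= 1.
## Returns list(gait = data.frame(start, end),
##              func = list(paretic = ..., lessAffected = ...)).
buildSchedule <- function(spec) {
  T <- spec@sessionLength
  gaitChunks <- if (spec@gaitFraction > 0) chunkBudget(spec@gaitFraction * T)
                else numeric(0)
  gapChunks <- chunkBudget(T - sum(gaitChunks))
  segs <- data.frame(
    type = c(rep("gait", length(gaitChunks)), rep("gap", length(gapChunks))),
    dur = c(gaitChunks, gapChunks), stringsAsFactors = FALSE)
  segs <- segs[sample.int(nrow(segs)), , drop = FALSE]
  segs$end <- cumsum(segs$dur)
  segs$start <- segs$end - segs$dur
  gaps <- segs[segs$type == "gap", , drop = FALSE]

  placeFunctional <- function(budget) {
    remaining <- budget * T
    out <- data.frame(start = numeric(0), end = numeric(0))
    for (i in sample.int(nrow(gaps))) {
      if (remaining <= 1e-9) break
      take <- min(remaining, gaps$dur[i])
      out <- rbind(out, data.frame(start = gaps$start[i],
                                   end = gaps$start[i] + take))
      remaining <- remaining - take
    }
    if (remaining > 1e-6) stopf("fractions cannot be scheduled within the session")
    out[order(out$start), , drop = FALSE]
  }
  list(gait = segs[segs$type == "gait", c("start", "end"), drop = FALSE],
       func = list(paretic = placeFunctional(spec@propFunctionalParetic),
                   lessAffected = placeFunctional(spec@propFunctionalLessaffected)))
}

## membership of times (relative to schedule origin) in a set of intervals
inIntervals <- function(tt, iv) {
  out <- rep(FALSE, length(tt))
  for (k in seq_len(nrow(iv))) out <- out | (tt >= iv$start[k] & tt < iv$end[k])
  out
}

## per-limb functional epoch: a train of Gaussian-windowed 0.5-3 Hz
## reach-like bursts whose centers tile the epoch (~1 burst per 0.8 s, so
## every 2-s block inside the epoch sees burst energy), amplitude scaled by
## (1 - impairment) on the paretic limb
addFunctionalBursts <- function(sig, idx, t, ampScale) {
  t0 <- t[idx[1]]; t1 <- t[idx[length(idx)]]
  dur <- max(t1 - t0, 0.5)
  nb <- max(2L, round(dur / 0.8))
  ctrs <- t0 + (seq_len(nb) - 0.5) / nb * dur +
    stats::runif(nb, -0.15, 0.15) * dur / nb
  for (b in seq_len(nb)) {
    sigma <- stats::runif(1, 0.25, 0.6)
    freq <- stats::runif(1, 0.5, 3)
    phase <- stats::runif(1, 0, 2 * pi)
    env <- exp(-(t[idx] - ctrs[b])^2 / (2 * sigma^2))
    for (ax in 1:3) {
      amp <- stats::runif(1, 0.4, 1.0) * stats::runif(1, 0.4, 1) * ampScale
      sig[idx, ax] <- sig[idx, ax] +
        amp * env * sin(2 * pi * freq * t[idx] + phase + (ax - 1))
    }
  }
  sig
}

## whole-body (gait) oscillation: common fundamental + harmonic on both limbs
## with limb-specific phase; the count-baseline confuser
addGait <- function(sig, idx, t, gaitPar, phase) {
  axw <- c(1, 0.5, 0.3)
  f <- gaitPar$freq; A <- gaitPar$amp
  for (ax in 1:3) {
    sig[idx, ax] <- sig[idx, ax] + axw[ax] *
      (A * sin(2 * pi * f * t[idx] + phase + (ax - 1) * 0.7) +
       0.3 * A * sin(4 * pi * f * t[idx] + 2 * phase + ax))
  }
  sig
}

#' Simulate one two-limb session
#'
#' Renders a seeded epoch schedule (rest, functional bursts per limb, shared
#' whole-body gait) as 50 Hz tri-axial acceleration on both wrists, adds the
#' sensor noise floor and gravity on z, prepends/appends the 5-cycle z-axis
#' shake-pulse trains, and emits 30 Hz frame-level truth tracks per limb.
#'
#' @param spec a [SimSubjectSpec-class].
#' @return list with elements `paretic`, `lessAffected`
#'   ([AccelRecording-class]), `truth` (list: per-limb frame labels over
#'   `functional/nonfunctional/sync`, `fps`), `videoMarks` / `sensorMarks`
#'   ([SyncMark-class] truth), `realized` (per-limb realized functional
#'   fraction over non-sync frames), `schedule`, and `spec`.
#' @export
simulateSession <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    sched <- buildSchedule(spec)
    total <- .SYNC_DUR + spec@sessionLength + .SYNC_DUR
    nS <- round(total * .SAMPLE_RATE)
    t <- (seq_len(nS) - 1) / .SAMPLE_RATE

    sigP <- matrix(stats::rnorm(3 * nS, 0, .REST_SD), ncol = 3)
    sigL <- matrix(stats::rnorm(3 * nS, 0, .REST_SD), ncol = 3)

    gaitPar <- list(freq = stats::runif(1, 1.5, 2),
                    amp = stats::runif(1, 0.25, 0.45))
    phiP <- stats::runif(1, 0, 2 * pi)
    phiL <- phiP + stats::runif(1, 2, 4)

    for (k in seq_len(nrow(sched$gait))) {
      idx <- which(t >= .SYNC_DUR + sched$gait$start[k] &
                   t < .SYNC_DUR + sched$gait$end[k])
      if (!length(idx)) next
      sigP <- addGait(sigP, idx, t, gaitPar, phiP)
      sigL <- addGait(sigL, idx, t, gaitPar, phiL)
    }
    for (k in seq_len(nrow(sched$func$paretic))) {
      idx <- which(t >= .SYNC_DUR + sched$func$paretic$start[k] &
                   t < .SYNC_DUR + sched$func$paretic$end[k])
      if (length(idx))
        sigP <- addFunctionalBursts(sigP, idx, t, 1 - spec@impairment)
    }
    for (k in seq_len(nrow(sched$func$lessAffected))) {
      idx <- which(t >= .SYNC_DUR + sched$func$lessAffected$start[k] &
                   t < .SYNC_DUR + sched$func$lessAffected$end[k])
      if (length(idx))
        sigL <- addFunctionalBursts(sigL, idx, t, 1)
    }

    ## gravity on z, then the shake-pulse trains on z of both sensors
    sigP[, 3] <- sigP[, 3] + 1
    sigL[, 3] <- sigL[, 3] + 1
    endT0 <- .SYNC_DUR + spec@sessionLength
    for (t0 in c(0, endT0)) {
      idx <- which(t >= t0 & t < t0 + .SYNC_DUR)
      pulse <- .SYNC_AMP * sin(2 * pi * .SYNC_FREQ * (t[idx] - t0))
      sigP[idx, 3] <- sigP[idx, 3] + pulse
      sigL[idx, 3] <- sigL[idx, 3] + pulse
    }

    ## 30 Hz truth tracks (frame f covers time f/fps)
    nF <- floor(total * .VIDEO_FPS)
    ft <- (seq_len(nF) - 1) / .VIDEO_FPS
    labP <- rep(.LBL_NON, nF)
    labL <- rep(.LBL_NON, nF)
    rel <- ft - .SYNC_DUR
    labP[inIntervals(rel, sched$func$paretic)] <- .LBL_FUN
    labL[inIntervals(rel, sched$func$lessAffected)] <- .LBL_FUN
    isSync <- ft < .SYNC_DUR | ft >= endT0
    labP[isSync] <- .LBL_SYNC
    labL[isSync] <- .LBL_SYNC

    recP <- AccelRecording(t, sigP[, 1], sigP[, 2], sigP[, 3],
                           sampleRate = .SAMPLE_RATE,
                           subjectId = spec@subjectId, limb = "paretic")
    recL <- AccelRecording(t, sigL[, 1], sigL[, 2], sigL[, 3],
                           sampleRate = .SAMPLE_RATE,
                           subjectId = spec@subjectId, limb = "less_affected")

    startPk <- syncPeakTimes(0)
    endPk <- syncPeakTimes(endT0)
    list(
      paretic = recP, lessAffected = recL,
      truth = list(paretic = labP, lessAffected = labL, fps = .VIDEO_FPS),
      sensorMarks = SyncMark(startPk, endPk, unit = "seconds",
                             rate = .SAMPLE_RATE),
      videoMarks = SyncMark(startPk * .VIDEO_FPS, endPk * .VIDEO_FPS,
                            unit = "frames", rate = .VIDEO_FPS),
      realized = c(
        paretic = mean(labP[!isSync] == .LBL_FUN),
        lessAffected = mean(labL[!isSync] == .LBL_FUN)),
      schedule = sched, spec = spec)
  })
}

#' Simulate independent annotator tracks from a truth track
#'
#' Each annotator reproduces the collapsed truth with i.i.d. per-frame
#' corruption: with probability `errorRate` the frame's collapsed label is
#' replaced by one of the other two categories (uniformly, including
#' unknown). Collapsed labels are then re-expressed as raw FAABOS codes by
#' drawing uniformly from the code preimage of the default mapping, so the
#' full collapse + merge path is exercised downstream.
#'
#' @param truth character frame labels (`sync` frames are treated as
#'   nonfunctional: the shake happens before donning).
#' @param errorRate per-frame mislabel probability in `[0, 0.5)`.
#' @param nAnnotators number of annotators.
#' @param seed integer seed.
#' @param limb limb tag carried on each track.
#' @param fps video frame rate.
#' @return list of raw annotator tracks, each a list with `annotatorId`,
#'   `limb`, `fps`, and integer `codes` (FAABOS 0-4).
#' @export
simulateAnnotators <- function(truth, errorRate, nAnnotators = 3, seed = 1,
                               limb = "paretic", fps = 30) {
  if (errorRate < 0 || errorRate >= 0.5)
    stopf("errorRate must lie in [0, 0.5)")
  truth <- ifelse(truth == .LBL_SYNC, .LBL_NON, truth)
  lv <- collapsedLevels()
  preimage <- list(functional = c(2L, 3L), nonfunctional = c(0L, 1L),
                   unknown = 4L)
  withSeed(seed, {
    lapply(seq_len(nAnnotators), function(a) {
      lab <- truth
      err <- stats::runif(length(lab)) < errorRate
      if (any(err)) {
        lab[err] <- vapply(lab[err], function(l) sample(setdiff(lv, l), 1), "")
      }
      codes <- vapply(lab, function(l) {
        p <- preimage[[l]]
        if (length(p) == 1L) p else sample(p, 1)
      }, 0L, USE.NAMES = FALSE)
      list(annotatorId = sprintf("A%d", a), limb = limb, fps = fps,
           codes = codes)
    })
  })
}

#' Mirror the paretic limb onto the less-affected slot of a session
#'
#' Produces a perfectly symmetric subject — identical streams and truth
#' tracks on both limbs — for symmetry checks: the video-truth use ratio of
#' such a session is exactly 1.
#'
#' @param session a session from [simulateSession()].
#' @return the session with the less-affected limb replaced by a copy of
#'   the paretic stream (relabeled) and matching truth.
#' @export
makeSymmetricSession <- function(session) {
  rec <- session$paretic
  session$lessAffected <- AccelRecording(
    rec@t, rec@ax, rec@ay, rec@az, sampleRate = rec@sampleRate,
    subjectId = rec@subjectId, limb = "less_affected")
  session$truth$lessAffected <- session$truth$paretic
  session$realized["lessAffected"] <- session$realized["paretic"]
  session
}

#' Simulate a cohort of subjects with coupled clinical scores
#'
#' Subjects span `impairmentRange` evenly; each gets a seeded session via
#' [simulateSession()] and clinical scores drawn from the linear couplings in
#' the cohort spec, clipped to instrument range (ARAT 0-57, UEFM 0-66, MAL
#' 0-5, peg time >= 1 s). Optionally masks the secondary battery
#' (UEFM/MAL/peg) for `nMissingSecondary` subjects, plus one further subject
#' missing only the peg time, mimicking partially complete batteries.
#'
#' @param spec a [SimCohortSpec-class].
#' @return list with `subjects` (list of per-subject lists: `spec`,
#'   `session`), `scores` (data.frame: subject_id, ARAT, UEFM, peg_time_s,
#'   MAL), `truth` (data.frame of realized per-limb functional fractions and
#'   the true use ratio), and `spec`.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nSubjects
  imp <- seq(spec@impairmentRange[1], spec@impairmentRange[2], length.out = n)
  ids <- sprintf("S%02d", seq_len(n))

  subjects <- lapply(seq_len(n), function(i) {
    ss <- SimSubjectSpec(subjectId = ids[i], impairment = imp[i],
                         gaitFraction = spec@gaitFraction,
                         sessionLength = spec@sessionLength,
                         seed = deriveSeed(spec@masterSeed, "subject", i))
    list(spec = ss, session = simulateSession(ss))
  })

  scores <- withSeed(deriveSeed(spec@masterSeed, "scores"), {
    draw <- function(name, lo, hi) {
      cc <- spec@couplings[[name]]
      pmin(hi, pmax(lo, cc[["intercept"]] + cc[["slope"]] * imp +
                          stats::rnorm(n, 0, cc[["noiseSd"]])))
    }
    data.frame(
      subject_id = ids,
      ARAT = draw("ARAT", 0, 57),
      UEFM = draw("UEFM", 0, 66),
      peg_time_s = draw("peg", 1, Inf),
      MAL = draw("MAL", 0, 5),
      stringsAsFactors = FALSE)
  })

  if (spec@nMissingSecondary > 0) {
    masked <- withSeed(deriveSeed(spec@masterSeed, "mask"),
                       sample.int(n, min(spec@nMissingSecondary, n)))
    scores[masked, c("UEFM", "peg_time_s", "MAL")] <- NA
    extra <- setdiff(seq_len(n), masked)
    if (length(extra))
      scores[withSeed(deriveSeed(spec@masterSeed, "maskpeg"),
                      sample(extra, 1)), "peg_time_s"] <- NA
  }

  truth <- do.call(rbind, lapply(subjects, function(s) data.frame(
    subject_id = s$spec@subjectId,
    impairment = s$spec@impairment,
    true_prop_paretic = unname(s$session$realized["paretic"]),
    true_prop_lessaffected = unname(s$session$realized["lessAffected"]),
    stringsAsFactors = FALSE)))
  truth$true_use_ratio <- truth$true_prop_paretic /
    truth$true_prop_lessaffected

  list(subjects = subjects, scores = scores, truth = truth, spec = spec)
}
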