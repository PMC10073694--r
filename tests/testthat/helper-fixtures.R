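## Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## moderately impaired, gait-heavy subject used across module tests
fixtureSession <- function() memo("session", {
  simulateSession(SimSubjectSpec(subjectId = "FIX", impairment = 0.4,
                                 gaitFraction = 0.3, sessionLength = 120,
                                 seed = 7))
})

fixtureSubjectRun <- function() memo("subjectRun", {
  runSubject(fixtureSession())
})

## the 12-subject cohort at a fixed master seed (parameter-recovery checks)
fixtureCohort <- function() memo("cohort", {
  simulateCohort(SimCohortSpec(nSubjects = 12, masterSeed = 11))
})

fixtureCohortReport <- function() memo("cohortReport", {
  runCohort(fixtureCohort())
})

## random 2-s blocks in a realistic amplitude range
randomBlock <- function(n = 100) {
  list(index = 1L, startTime = 0,
       samples = matrix(stats::rnorm(3 * n, 0, 0.5), ncol = 3),
       sampleLabels = NULL)
}

## build a LabeledBlockSet directly from a feature matrix (classifier tests)
featureBlockSet <- function(features, labels, limb = "paretic") {
  n <- nrow(features)
  colnames(features) <- featureNames()
  methods::new("LabeledBlockSet", features = features, blockLabels = labels,
               startTimes = as.numeric(seq_len(n)),
               counts = matrix(0, n, 2), limb = limb, subjectId = "synth")
}

## independent element-wise oracle for the 17 features (loops, no vector
## shortcuts shared with the implementation)
oracleFeatures <- function(samples, nBins = 16) {
  n <- nrow(samples)
  out <- numeric(0)
  for (a in 1:3) {
    x <- samples[, a]
    m <- 0; for (i in seq_len(n)) m <- m + x[i]; m <- m / n
    v <- 0; for (i in seq_len(n)) v <- v + (x[i] - m)^2; v <- v / n
    mx <- x[1]; mn <- x[1]
    for (i in seq_len(n)) { if (x[i] > mx) mx <- x[i]; if (x[i] < mn) mn <- x[i] }
    out <- c(out, m, v, mx, mn)
  }
  mag <- numeric(n)
  for (i in seq_len(n))
    mag[i] <- sqrt(samples[i, 1]^2 + samples[i, 2]^2 + samples[i, 3]^2)
  m <- sum(mag) / n
  v <- 0; for (i in seq_len(n)) v <- v + (mag[i] - m)^2; v <- v / n
  out <- c(out, m, v, max(mag), min(mag), oracleEntropy(mag, nBins))
  out
}

oracleEntropy <- function(x, nBins = 16) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- integer(nBins)
  w <- (hi - lo) / nBins
  for (v in x) {
    b <- floor((v - lo) / w) + 1
    if (b > nBins) b <- nBins
    counts[b] <- counts[b] + 1L
  }
  h <- 0
  for (c in counts) if (c > 0) { p <- c / length(x); h <- h - p * log2(p) }
  h
}
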