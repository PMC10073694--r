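test_that("sessions are reproducible and conserve the frame schedule", {
  spec <- SimSubjectSpec(subjectId = "D", impairment = 0.3, sessionLength = 90,
                         seed = 42)
  s1 <- simulateSession(spec)
  s2 <- simulateSession(spec)
  expect_identical(accelMatrix(s1$paretic), accelMatrix(s2$paretic))
  expect_identical(accelMatrix(s1$lessAffected), accelMatrix(s2$lessAffected))
  expect_identical(s1$truth, s2$truth)

  for (lab in list(s1$truth$paretic, s1$truth$lessAffected)) {
    counts <- table(factor(lab, c("functional", "nonfunctional", "sync")))
    expect_identical(sum(counts), length(lab))
    expect_identical(sum(lab == "sync"),
                     sum(s1$truth$paretic == "sync"))  # shared sync span
  }
})

test_that("degenerate functional fraction yields no functional paretic frames", {
  spec <- SimSubjectSpec(subjectId = "Z", propFunctionalParetic = 0,
                         propFunctionalLessaffected = 0.4, sessionLength = 60,
                         seed = 3)
  ses <- simulateSession(spec)
  nonSync <- ses$truth$paretic != "sync"
  expect_identical(sum(ses$truth$paretic[nonSync] == "functional"), 0L)
})

test_that("identical target fractions realize nearly identical limb fractions", {
  spec <- SimSubjectSpec(subjectId = "E", propFunctionalParetic = 0.3,
                         propFunctionalLessaffected = 0.3, gaitFraction = 0.2,
                         sessionLength = 120, seed = 5)
  ses <- simulateSession(spec)
  expect_lt(abs(ses$realized["paretic"] - ses$realized["lessAffected"]), 0.02)
})

test_that("gait epochs are a nonfunctional confuser with supra-rest motion", {
  ses <- fixtureSession()   # gaitFraction 0.3
  for (limbName in c("paretic", "lessAffected")) {
    lab <- ses$truth[[limbName]]
    nonSync <- lab != "sync"
    expect_gte(mean(lab[nonSync] == "nonfunctional"), 0.25)
  }
  ## acceleration variance inside gait frames exceeds the rest noise floor
  rec <- ses$paretic
  gait <- ses$schedule$gait
  gaitIdx <- rep(FALSE, nSamples(rec))
  for (k in seq_len(nrow(gait)))
    gaitIdx <- gaitIdx | (rec@t >= 2.5 + gait$start[k] &
                          rec@t < 2.5 + gait$end[k])
  expect_gt(var(rec@ax[gaitIdx]), 10 * 0.02^2)
})

test_that("unschedulable fractions and short sessions are rejected", {
  expect_error(SimSubjectSpec(propFunctionalParetic = 0.9, gaitFraction = 0.3),
               "exceeds schedulable")
  expect_error(SimSubjectSpec(sessionLength = 30), "60")
})

test_that("annotator corruption is seeded, bounded, and majority-recoverable", {
  truth <- fixtureSession()$truth$paretic
  clean <- simulateAnnotators(truth, errorRate = 0, nAnnotators = 3, seed = 2)
  collapsedTruth <- ifelse(truth == "sync", "nonfunctional", truth)
  for (tr in clean)
    expect_identical(collapseFaabos(tr$codes), collapsedTruth)

  ## binomial oracle: with eps = 0.1 and 3 annotators a frame is lost when
  ## >= 2 annotators err, P = 3*eps^2*(1-eps) + eps^3 = 0.028, so strict
  ## majority recovers ~97.2% of a 10,000-frame track (Monte-Carlo band)
  longTruth <- rep(c("functional", "nonfunctional"), 5000)
  tracks <- simulateAnnotators(longTruth, errorRate = 0.1, nAnnotators = 3,
                               seed = 9)
  consensus <- mergeAnnotators(lapply(tracks, function(tr)
    collapseFaabos(tr$codes)))
  recovery <- mean(trackLabels(consensus) == longTruth)
  expect_lt(abs(recovery - 0.972), 0.01)   # ~6 Monte-Carlo SDs

  ## single annotator: merge reduces to identity
  one <- simulateAnnotators(longTruth, errorRate = 0.2, nAnnotators = 1,
                            seed = 4)
  lab1 <- collapseFaabos(one[[1]]$codes)
  expect_identical(trackLabels(mergeAnnotators(list(lab1))), lab1)

  expect_error(simulateAnnotators(longTruth, errorRate = 0.6), "0.5")
})

test_that("cohort couplings drive scores and masking is bookkept", {
  ## zero noise, pure linear map: sample correlation is exactly -1
  noiseless <- SimCohortSpec(nSubjects = 6, sessionLength = 60,
                             couplings = list(
                               ARAT = c(slope = -57, intercept = 57, noiseSd = 0),
                               UEFM = c(slope = -52.8, intercept = 62.8, noiseSd = 0),
                               MAL = c(slope = -5, intercept = 5, noiseSd = 0),
                               peg = c(slope = 250, intercept = 30, noiseSd = 0)),
                             masterSeed = 2)
  coh <- simulateCohort(noiseless)
  expect_equal(cor(coh$truth$impairment, coh$scores$ARAT), -1)

  ## default couplings: the true use ratio tracks ARAT strongly
  coh12 <- fixtureCohort()
  expect_gte(cor(coh12$truth$true_use_ratio, coh12$scores$ARAT), 0.8)

  masked <- simulateCohort(SimCohortSpec(nSubjects = 12, sessionLength = 60,
                                         nMissingSecondary = 4, masterSeed = 3))
  expect_identical(sum(is.na(masked$scores$UEFM)), 4L)
  expect_identical(sum(is.na(masked$scores$MAL)), 4L)
  expect_identical(sum(is.na(masked$scores$peg_time_s)), 5L)
  expect_identical(sum(is.na(masked$scores$ARAT)), 0L)

  expect_error(simulateCohort(SimCohortSpec(nSubjects = 2)), "3")
  expect_error(simulateCohort(SimCohortSpec(
    couplings = list(ARAT = c(slope = -1, intercept = 57, noiseSd = -2)))),
    "noise")
})
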