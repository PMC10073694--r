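test_that("FAABOS codes collapse per the default mapping", {
  expect_identical(collapseFaabos(0L), "nonfunctional")  # no movement
  expect_identical(collapseFaabos(1L), "nonfunctional")  # gait/whole-body
  expect_identical(collapseFaabos(c(2L, 3L)), c("functional", "functional"))
  expect_identical(collapseFaabos(NA_integer_), "unknown")  # unscored sentinel
  expect_identical(collapseFaabos(4L), "unknown")
  expect_error(collapseFaabos(7L), "outside alphabet")
  expect_error(collapseFaabos(0L, mapping = c("0" = "banana")), "alphabet")
})

test_that("strict-majority merge matches full enumeration of annotator triples", {
  lv <- c("functional", "nonfunctional", "unknown")
  triples <- expand.grid(a = lv, b = lv, c = lv, stringsAsFactors = FALSE)
  ## independent oracle: count occurrences, demand a strict > 3/2 majority
  oracle <- apply(triples, 1, function(tr) {
    tab <- table(tr)
    if (max(tab) > 1.5) names(tab)[which.max(tab)] else "unknown"
  })
  merged <- trackLabels(mergeAnnotators(list(triples$a, triples$b, triples$c)))
  expect_identical(merged, unname(oracle))
  ## 6 of the 27 ordered triples are three-way splits with no strict majority
  expect_identical(sum(apply(triples, 1, function(tr) length(unique(tr)) == 3L)),
                   6L)
  expect_identical(merged[triples$a == "functional" &
                          triples$b == "functional" &
                          triples$c == "nonfunctional"], "functional")
})

test_that("merge is permutation-invariant and validates its inputs", {
  lv <- c("functional", "nonfunctional", "unknown")
  withr::with_seed(31, {
    for (rep in 1:5) {
      tracks <- lapply(1:3, function(i) sample(lv, 200, replace = TRUE))
      m1 <- mergeAnnotators(tracks)
      m2 <- mergeAnnotators(tracks[c(3, 1, 2)])
      expect_identical(trackLabels(m1), trackLabels(m2))
    }
  })
  expect_error(mergeAnnotators(list(rep("functional", 5),
                                    rep("functional", 6))),
               "length mismatch")
  expect_error(mergeAnnotators(list(
    ConsensusTrack(rep("functional", 3), limb = "paretic"),
    ConsensusTrack(rep("functional", 3), limb = "less_affected"))),
    "limb mismatch")
})

test_that("consensus frame-error rate follows the binomial prediction", {
  eps <- 0.1
  truth <- rep(c("functional", "nonfunctional"), 5000)
  tracks <- simulateAnnotators(truth, errorRate = eps, nAnnotators = 3,
                               seed = 77)
  consensus <- mergeAnnotators(lapply(tracks, function(tr)
    collapseFaabos(tr$codes)))
  observed <- mean(trackLabels(consensus) != truth)
  predicted <- 3 * eps^2 * (1 - eps) + eps^3
  expect_lt(abs(observed - predicted), 0.01)   # ~6 Monte-Carlo SDs
})

test_that("labels transfer to the sensor timeline by nearest frame", {
  ## exact 50/30 map with no offset: sample 1 <-> frame 0
  map <- buildTimeMap(SyncMark((c(0:4) + 0.125), (c(0:4) + 20.125)),
                      SyncMark((c(0:4) + 0.125) * 30, (c(0:4) + 20.125) * 30,
                               unit = "frames", rate = 30))
  rec <- AccelRecording(seq(0, 21, by = 0.02), rep(0, 1051), rep(0, 1051),
                        rep(1, 1051), sampleRate = 50)

  constant <- ConsensusTrack(rep("functional", 640))
  expect_true(all(transferLabels(constant, map, rec)[1:600] == "functional"))

  ## alternating 1-s-period track transfers with <= 1 frame timing error
  alt <- ConsensusTrack(rep(rep(c("functional", "nonfunctional"), each = 30),
                            length.out = 640))
  lab <- transferLabels(alt, map, rec)
  expected <- rep(rep(c("functional", "nonfunctional"), each = 50),
                  length.out = length(lab))
  covered <- which(lab != "unknown")
  mismatches <- sum(lab[covered] != expected[covered])
  ## transitions every 50 samples; a 1-frame (1.67-sample) error bound allows
  ## at most 2 mismatched samples per transition
  nTransitions <- floor(length(covered) / 50)
  expect_lte(mismatches, 2 * nTransitions)

  ## samples mapping past the video's last frame are unknown
  short <- ConsensusTrack(rep("functional", 100))
  lab2 <- transferLabels(short, map, rec)
  expect_true(all(lab2[170:1051] == "unknown"))
  expect_true(all(lab2[1:160] == "functional"))
})

test_that("functional proportion excludes unknowns and needs a denominator", {
  lab <- c(rep("functional", 300), rep("nonfunctional", 700))
  expect_equal(functionalProportion(lab), 0.3)
  expect_equal(functionalProportion(c(lab, rep("unknown", 500))), 0.3)
  expect_equal(groundTruthProportion(lab), 0.3)
  expect_error(functionalProportion(rep("unknown", 10)), "no classifiable")
})

test_that("annotator label CSVs round-trip", {
  truth <- rep(c("functional", "nonfunctional"), 50)
  tracks <- simulateAnnotators(truth, 0.1, nAnnotators = 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLabelsCsv(tracks, f)
  back <- readLabelsCsv(f)
  expect_identical(length(back), 2L)
  expect_identical(back[["A1"]]$codes, tracks[[1]]$codes)
  expect_identical(back[["A2"]]$codes, tracks[[2]]$codes)
})
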