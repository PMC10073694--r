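mkRec <- function(nSec, fs = 50) {
  n <- nSec * fs
  AccelRecording((seq_len(n) - 1) / fs, rep(0.1, n), rep(0.2, n), rep(1, n),
                 sampleRate = fs)
}

test_that("block partitioning floors to whole blocks and round-trips", {
  rec <- mkRec(10.5)
  blocks <- partitionBlocks(rec)
  expect_length(blocks, 5L)
  expect_true(all(vapply(blocks, function(b) nrow(b$samples), 0L) == 100L))

  expect_length(partitionBlocks(mkRec(2)), 1L)

  ## concatenated blocks reconstruct the stream minus the dropped tail
  recon <- do.call(rbind, lapply(blocks, `[[`, "samples"))
  expect_identical(recon, accelMatrix(rec)[1:500, ])

  expect_error(partitionBlocks(mkRec(1.5)), "empty usable span")
})

test_that("sync regions are masked out of blocks", {
  ses <- fixtureSession()
  marks <- detectSyncPulses(ses$paretic)
  blocks <- partitionBlocks(ses$paretic, syncMarks = marks)
  firstStart <- blocks[[1]]$startTime
  lastEnd <- blocks[[length(blocks)]]$startTime + 2
  expect_gte(firstStart, max(marks@startPulses))
  expect_lte(lastEnd, min(marks@endPulses))
})

test_that("the >90% purity rule is exact at its boundary", {
  mk <- function(labels) list(samples = matrix(0, length(labels), 3),
                              sampleLabels = labels)
  expect_identical(labelBlock(mk(c(rep("functional", 91),
                                   rep("nonfunctional", 9)))), "functional")
  expect_identical(labelBlock(mk(c(rep("functional", 90),
                                   rep("nonfunctional", 10)))), "ambiguous")
  ## unknown counts in the denominator but can never win
  expect_identical(labelBlock(mk(c(rep("nonfunctional", 95),
                                   rep("unknown", 5)))), "nonfunctional")
  expect_identical(labelBlock(mk(c(rep("unknown", 95),
                                   rep("functional", 5)))), "ambiguous")
})

test_that("replacing nonfunctional with functional samples never demotes a block", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      nf <- sample(0:100, 1)
      lab <- c(rep("functional", nf), rep("nonfunctional", 100 - nf))
      blk <- list(samples = matrix(0, 100, 3), sampleLabels = lab)
      before <- labelBlock(blk)
      k <- sample.int(100 - nf + 1, 1) - 1
      lab2 <- c(rep("functional", nf + k), rep("nonfunctional", 100 - nf - k))
      after <- labelBlock(list(samples = blk$samples, sampleLabels = lab2))
      if (before == "functional") expect_identical(after, "functional")
      if (after == "nonfunctional") expect_identical(before, "nonfunctional")
    }
  })
})

test_that("features of a constant block are degenerate and ordered", {
  blk <- list(samples = cbind(rep(0.3, 100), rep(0.4, 100), rep(0, 100)))
  f <- extractFeatures(blk)
  expect_length(f, 17L)
  expect_identical(names(f), featureNames())
  expect_equal(unname(f[c("ax_var", "ay_var", "az_var", "mag_var")]),
               rep(0, 4))
  expect_equal(unname(f["mag_mean"]), 0.5)   # 3-4-5 triple
  expect_equal(unname(f["mag_entropy"]), 0)
})

test_that("features satisfy order statistics and match the loop oracle", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      blk <- randomBlock()
      f <- extractFeatures(blk)
      for (a in c("ax", "ay", "az", "mag")) {
        expect_gte(f[paste0(a, "_max")], f[paste0(a, "_mean")])
        expect_gte(f[paste0(a, "_mean")], f[paste0(a, "_min")])
        expect_gte(f[paste0(a, "_var")], 0)
      }
      expect_equal(unname(f), oracleFeatures(blk$samples), tolerance = 1e-9)
    }
  })
})

test_that("entropy is histogram entropy in bits with the documented binning", {
  expect_equal(shannonEntropy(rep(3.7, 50)), 0)
  ## 96 samples spread evenly across all 16 equal-width bins: log2(16) bits
  x <- rep(seq(0.5, 16, by = 1), each = 6) / 16
  expect_equal(shannonEntropy(x), 4)
  withr::with_seed(5, {
    for (rep in 1:20) {
      y <- runif(100)
      h <- shannonEntropy(y)
      expect_lte(h, log2(16))
      expect_equal(h, oracleEntropy(y), tolerance = 1e-12)
      expect_gt(h, 0)
    }
  })
  expect_error(shannonEntropy(numeric(0)), "empty")
})

test_that("the count proxy separates rest from gait at the >2 threshold", {
  zero <- list(samples = cbind(rep(0, 100), rep(0, 100), rep(1, 100)))
  expect_equal(activityCount(zero), c(0, 0))

  withr::with_seed(21, {
    rest <- list(samples = matrix(c(rnorm(200, 0, 0.02),
                                    rnorm(100, 1, 0.02)), ncol = 3))
    expect_true(all(activityCount(rest) < 2))
  })

  ## gait-epoch block straight from the simulator
  ses <- fixtureSession()
  gait <- ses$schedule$gait[which.max(ses$schedule$gait$end -
                                      ses$schedule$gait$start), ]
  idx <- which(ses$paretic@t >= 2.5 + gait$start)[1] + 0:99
  blk <- list(samples = accelMatrix(ses$paretic)[idx, ])
  expect_true(all(activityCount(blk) > 2))
})

test_that("buildBlockSet assembles a coherent container", {
  ses <- fixtureSession()
  marks <- detectSyncPulses(ses$paretic)
  map <- buildTimeMap(marks, ses$videoMarks)
  lab <- transferLabels(mergeAnnotators(list(ifelse(
    ses$truth$paretic == "sync", "nonfunctional", ses$truth$paretic))),
    map, ses$paretic)
  bs <- buildBlockSet(ses$paretic, lab, syncMarks = marks)
  expect_s4_class(bs, "LabeledBlockSet")
  expect_identical(colnames(blockFeatures(bs)), featureNames())
  expect_identical(nrow(blockCounts(bs)), nBlocks(bs))
  expect_true(all(blockLabels(bs) %in%
                  c("functional", "nonfunctional", "ambiguous")))
})
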