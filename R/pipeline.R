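## End-to-end orchestration: simulate -> sync -> annotate -> featurize ->
## classify -> use ratios -> cohort validity, with a YAML config surface and
## a reproducibility manifest.

#' Default pipeline configuration
#'
#' One nested list holding every tunable that affects outputs; all defaults
#' equal the module-level defaults. A YAML file with any subset of these
#' keys can be merged over it with [readRunConfig()], and the effective
#' configuration is echoed into the run manifest.
#'
#' @return nested list of settings.
#' @export
defaultConfig <- function() {
  list(
    sim = list(nSubjects = 12, impairmentRange = c(0.1, 0.8),
               sessionLength = 300, gaitFraction = 0.2,
               annotatorErrorRate = 0.05, nAnnotators = 3,
               nMissingSecondary = 0),
    sync = list(minAmplitudeG = 2, searchWindowS = 10, maxResidualSamples = 2,
                guardS = 0.5),
    features = list(blockLengthS = 2, purityThreshold = 0.90, entropyBins = 16,
                    countBand = c(0.25, 2.5), countEpochS = 1, countGain = 1),
    model = list(nTrees = 100, mtry = NA, minLeaf = 1, cvFolds = 5),
    metrics = list(countThreshold = 2),
    seed = 1)
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file path (may cover any subset of keys).
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeLists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeLists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  mergeLists(defaultConfig(), user)
}

## one limb: consensus -> transfer -> blocks -> CV -> labels for all sources
processLimb <- function(rec, truthTrack, videoMarks, cfg, annotSeed) {
  tracks <- simulateAnnotators(truthTrack, cfg$sim$annotatorErrorRate,
                               cfg$sim$nAnnotators, seed = annotSeed,
                               limb = rec@limb)
  collapsed <- lapply(tracks, function(tr)
    ConsensusTrack(collapseFaabos(tr$codes), limb = tr$limb, fps = tr$fps))
  consensus <- mergeAnnotators(collapsed)
  sensorMarks <- detectSyncPulses(rec, cfg$sync$minAmplitudeG,
                                  cfg$sync$searchWindowS)
  map <- buildTimeMap(sensorMarks, videoMarks, sampleRate = rec@sampleRate,
                      maxResidualSamples = cfg$sync$maxResidualSamples)
  sampleLabels <- transferLabels(consensus, map, rec)
  bs <- buildBlockSet(rec, sampleLabels, syncMarks = sensorMarks,
                      blockLengthS = cfg$features$blockLengthS,
                      purityThreshold = cfg$features$purityThreshold,
                      guardS = cfg$sync$guardS)
  mc <- ModelConfig(nTrees = cfg$model$nTrees, mtry = cfg$model$mtry,
                    minLeaf = cfg$model$minLeaf, cvFolds = cfg$model$cvFolds,
                    shuffleSeed = deriveSeed(cfg$seed, "model", rec@subjectId,
                                             rec@limb))
  model <- crossvalSubject(bs, mc)
  ## video-truth labels at sample resolution, restricted to the block span
  usable <- seq.int(which(rec@t >= bs@startTimes[1])[1],
                    length.out = nBlocks(bs) * round(cfg$features$blockLengthS *
                                                       rec@sampleRate))
  list(blockSet = bs, model = model,
       videoSampleLabels = sampleLabels[usable],
       countLabels = countThresholdLabels(blockCounts(bs),
                                          cfg$metrics$countThreshold))
}

#' Run the full pipeline for one simulated subject
#'
#' Annotator simulation, FAABOS collapse, majority merge, sync detection,
#' time-map fit, label transfer, block featurization, cross-validated
#' classification, and the three use-ratio provenances (video truth, ML
#' estimate, count-threshold baseline).
#'
#' @param session a session from [simulateSession()].
#' @param config nested configuration list (see [defaultConfig()]).
#' @return list with `models` (per-limb [SubjectModelResult-class]),
#'   `useRatios` (list of three [UseRatioResult-class] objects named
#'   `video`, `ml`, `counts`), `blockSets`, and `blockCounts` (total /
#'   unambiguous / ambiguous per limb).
#' @export
runSubject <- function(session, config = defaultConfig()) {
  sid <- session$spec@subjectId
  limbs <- list(
    paretic = processLimb(session$paretic, session$truth$paretic,
                          session$videoMarks, config,
                          deriveSeed(config$seed, "annot", sid, "P")),
    lessAffected = processLimb(session$lessAffected,
                               session$truth$lessAffected,
                               session$videoMarks, config,
                               deriveSeed(config$seed, "annot", sid, "L")))

  ratio <- function(provenance, labP, labL)
    useRatioFromLabels(labP, labL, subjectId = sid, provenance = provenance)
  useRatios <- list(
    video = ratio("video", limbs$paretic$videoSampleLabels,
                  limbs$lessAffected$videoSampleLabels),
    ml = ratio("ml", limbs$paretic$model@predictions,
               limbs$lessAffected$model@predictions),
    counts = ratio("counts", limbs$paretic$countLabels,
                   limbs$lessAffected$countLabels))

  blockCounts <- lapply(limbs, function(l) {
    labs <- blockLabels(l$blockSet)
    c(total = length(labs), unambiguous = sum(labs != .LBL_AMB),
      ambiguous = sum(labs == .LBL_AMB))
  })
  list(models = lapply(limbs, `[[`, "model"), useRatios = useRatios,
       blockSets = lapply(limbs, `[[`, "blockSet"), blockCounts = blockCounts)
}

#' Run the pipeline over a simulated cohort and assemble the validity report
#'
#' Per-subject runs, then the concurrent-validity suite: correlation rows
#' (ML use ratio against video use ratio, ARAT, UEFM, nine-hole peg time,
#' MAL) with Fisher-z intervals and pairwise-complete n, OLS fits for ARAT
#' and MAL, Bland-Altman agreement of ML vs video ratios, and 1-/2-factor
#' varimax solutions over the six-measure battery (listwise-complete).
#'
#' @param cohort a cohort from [simulateCohort()].
#' @param config nested configuration list.
#' @param outDir optional directory; when given, per-subject use-ratio and
#'   metrics tables plus a JSON run manifest are written there.
#' @return a [ValidationReport-class] plus per-subject results in
#'   `attr(, "subjectResults")`.
#' @export
runCohort <- function(cohort, config = defaultConfig(), outDir = NULL) {
  results <- lapply(cohort$subjects, function(s) runSubject(s$session, config))
  names(results) <- vapply(cohort$subjects, function(s) s$spec@subjectId, "")

  urt <- useRatioTable(unlist(lapply(results, function(r) r$useRatios),
                              recursive = FALSE))
  wide <- data.frame(subject_id = names(results),
                     video = vapply(results, function(r) r$useRatios$video@useRatio, 0),
                     ml = vapply(results, function(r) r$useRatios$ml@useRatio, 0),
                     counts = vapply(results, function(r) r$useRatios$counts@useRatio, 0),
                     stringsAsFactors = FALSE)
  tab <- merge(wide, cohort$scores, by = "subject_id", sort = TRUE)

  corRow <- function(pair, x) {
    pc <- pearsonWithCi(x, tab$ml)
    data.frame(pair = pair, n = pc$n, r = pc$r, ciLow = pc$ciLow,
               ciHigh = pc$ciHigh, stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    corRow("video_use_ratio", tab$video),
    corRow("ARAT", tab$ARAT),
    corRow("UEFM", tab$UEFM),
    corRow("peg_time_s", tab$peg_time_s),
    corRow("MAL", tab$MAL))

  regRow <- function(pair, x) {
    f <- linearFitR2(x, tab$ml)
    data.frame(pair = pair, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
  }
  regressions <- rbind(regRow("ARAT", tab$ARAT), regRow("MAL", tab$MAL))

  ba <- blandAltman(tab$ml, tab$video)

  battery <- tab[, c("ARAT", "UEFM", "MAL", "peg_time_s", "video", "ml")]
  factors <- list(auto = factorAnalysis(battery, "auto"),
                  forced2 = factorAnalysis(battery, 2))

  report <- new("ValidationReport", correlations = correlations,
                regressions = regressions, blandAltman = ba,
                factors = factors, useRatios = urt)
  attr(report, "subjectResults") <- results

  if (!is.null(outDir)) writeRunOutputs(report, results, cohort, config, outDir)
  report
}

## run directory: use-ratio table, per-subject metrics, manifest
writeRunOutputs <- function(report, results, cohort, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@useRatios, file.path(outDir, "use_ratios.csv"),
                   row.names = FALSE, quote = FALSE)
  metrics <- lapply(results, function(r) lapply(r$models, function(m) list(
    accuracy = m@accuracy, sensitivity = m@sensitivity,
    specificity = m@specificity, confusion = as.list(m@confusion))))
  jsonlite::write_json(metrics, file.path(outDir, "subject_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "armuse",
    version = as.character(utils::packageVersion("armuse")),
    config = config,
    faabosMapping = as.list(faabosDefaultMapping()),
    featureOrder = featureNames(),
    nSubjects = length(results),
    blockCounts = lapply(results, `[[`, "blockCounts"))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Read/write the clinical-scores table
#'
#' Schema: `subject_id,ARAT,UEFM,peg_time_s,MAL`, empty cells for missing
#' values. Ranges are enforced on ingest (ARAT 0-57, UEFM 0-66, MAL 0-5,
#' peg time > 0); missingness is recorded, never imputed.
#'
#' @param path CSV path.
#' @return data.frame of scores.
#' @export
readScoresCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "ARAT", "UEFM", "peg_time_s", "MAL")
  if (!all(need %in% names(df)))
    stopf("malformed header: expected %s", paste(need, collapse = ","))
  chk <- function(x, lo, hi, nm) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) stopf("%s out of range [%g, %g]", nm, lo, hi)
  }
  chk(df$ARAT, 0, 57, "ARAT"); chk(df$UEFM, 0, 66, "UEFM")
  chk(df$MAL, 0, 5, "MAL")
  if (any(!is.na(df$peg_time_s) & df$peg_time_s <= 0))
    stopf("peg_time_s must be positive")
  df
}

#' @rdname readScoresCsv
#' @param scores data.frame of scores.
#' @export
writeScoresCsv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
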