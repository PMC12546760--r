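# Shared misspecification experiment: one reference campaign, three trained
# posteriors (standard; noise-robust against shifted and against unshifted
# observations) and their posterior-predictive evaluations. Built once and
# memoised; the acceptance checks and the heavier property tests all read
# from it. Sizes are desk scale: a 20k campaign, 50 observations, MAP from
# 2,500 posterior samples.

misspecExperiment <- function() {
  if (!is.null(.fixtures$misspec)) return(.fixtures$misspec)
  lib <- referenceLibrary()
  cells <- makeCells(nFamilies = 5, cellsPerFamily = 10, spread = 0.05,
                     seed = 42)
  obsShift <- makeObservations(cells$theta, standardizer(lib), delta = 0.5,
                               measSd = 0, seed = 43)
  obsClean <- makeObservations(cells$theta, standardizer(lib), delta = 0,
                               measSd = 0, seed = 43)
  ok <- stats::complete.cases(obsShift) & stats::complete.cases(obsClean)
  obsShift <- obsShift[ok, , drop = FALSE]
  obsClean <- obsClean[ok, , drop = FALSE]

  schStd <- trainingSchedule("standard")
  pairsStd <- selectTrainingSet(lib, schedule = schStd)
  mStd <- trainNPE(pairsStd$theta, pairsStd$x,
                   featureStandardizer = standardizer(lib),
                   schedule = schStd, seed = 7)
  schN <- trainingSchedule("noise_features", noiseSdFeatures = 0.1, seed = 5)
  pairsN <- selectTrainingSet(lib, obsShift, schN)
  mNpe <- trainNPE(pairsN$theta, pairsN$x,
                   featureStandardizer = standardizer(lib), schedule = schN,
                   seed = 7)
  pairsN0 <- selectTrainingSet(lib, obsClean, schN)
  mNpe0 <- trainNPE(pairsN0$theta, pairsN0$x,
                    featureStandardizer = standardizer(lib), schedule = schN,
                    seed = 7)

  mapSamples <- 2000
  repStdShift <- evaluateFit(mStd, obsShift, nPosterior = 10,
                             mapSamples = mapSamples, seed = 9)
  repNpeShift <- evaluateFit(mNpe, obsShift, nPosterior = 10,
                             mapSamples = mapSamples, seed = 9)
  repStdClean <- evaluateFit(mStd, obsClean, nPosterior = 1,
                             mapSamples = mapSamples, seed = 9)
  repNpeClean <- evaluateFit(mNpe0, obsClean, nPosterior = 1,
                             mapSamples = mapSamples, seed = 9)

  .fixtures$misspec <- list(
    lib = lib, cells = cells, obsShift = obsShift, obsClean = obsClean,
    mStd = mStd, mNpe = mNpe, mNpe0 = mNpe0,
    repStdShift = repStdShift, repNpeShift = repNpeShift,
    repStdClean = repStdClean, repNpeClean = repNpeClean)
  .fixtures$misspec
}
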