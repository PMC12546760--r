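# Training-set selection, posterior sampling contracts, MAP refinement,
# entropy, and the posterior-predictive evaluation protocol.

test_that("training-set selection follows the schedule semantics", {
  lib <- referenceLibrary()
  nValid <- sum(validMask(lib))
  std <- selectTrainingSet(lib, schedule = trainingSchedule("standard"))
  expect_equal(nrow(std$theta), nValid)
  expect_equal(nrow(std$x), nValid)

  z <- featureMatrix(lib, "z")
  vIdx <- which(validMask(lib))
  obs <- z[vIdx[7], ]
  one <- selectTrainingSet(lib, obs,
                           trainingSchedule("best_euclidean", k = 1))
  expect_equal(nrow(one$theta), 1)
  expect_equal(unname(one$theta[1, ]), unname(parameterMatrix(lib)[vIdx[7], ]))

  # zero noise makes the noise schedule identical to best-euclidean
  be <- selectTrainingSet(lib, obs, trainingSchedule("best_euclidean", k = 50))
  nz <- selectTrainingSet(lib, obs,
                          trainingSchedule("noise_features",
                                           noiseSdFeatures = 0, k = 50))
  expect_equal(be$x, nz$x, tolerance = 1e-12)
  expect_equal(be$theta, nz$theta)

  # data augmentation doubles the selected set
  da <- selectTrainingSet(lib, obs,
                          trainingSchedule("data_augmentation",
                                           noiseSdFeatures = 0.1, k = 50))
  expect_equal(nrow(da$theta), 2 * nrow(be$theta))
  expect_equal(da$x[seq_len(nrow(be$x)), ], be$x, tolerance = 1e-12)

  expect_error(selectTrainingSet(lib, obs,
                                 trainingSchedule("best_euclidean",
                                                  k = nValid + 1)),
               "fewer valid")
})

test_that("noise perturbations have the scheduled magnitude", {
  lib <- referenceLibrary()
  z <- featureMatrix(lib, "z")
  obs <- z[which(validMask(lib))[1], ]
  k <- 500
  be <- selectTrainingSet(lib, obs, trainingSchedule("best_euclidean", k = k))
  nz <- selectTrainingSet(lib, obs,
                          trainingSchedule("noise_features",
                                           noiseSdFeatures = 0.1, k = k,
                                           seed = 4))
  dev <- nz$x - be$x
  expect_equal(sd(as.numeric(dev)), 0.1, tolerance = 0.01)
  expect_equal(mean(as.numeric(dev)), 0, tolerance = 0.005)
})

test_that("posterior samples stay inside the prior box and reproduce under seeds", {
  m <- toyModel()
  s1 <- samplePosterior(m, 0.9, 500, seed = 5)
  expect_true(all(s1 >= -1 & s1 <= 1))
  s2 <- samplePosterior(m, 0.9, 500, seed = 5)
  expect_identical(s1, s2)
})

test_that("MAP refinement never decreases the posterior density", {
  m <- toyModel()
  set.seed(6)
  smp <- samplePosterior(m, 0.2, 2000, seed = 7)
  bestSample <- max(logPosterior(m, smp, 0.2))
  mp <- mapEstimate(m, 0.2, nSamples = 2000, seed = 7)
  expect_gte(attr(mp, "logDensity"), bestSample - 1e-9)
  # analytic oracle: the truncated-Gaussian mode at x0 = 0 is 0
  mp0 <- mapEstimate(m, 0, nSamples = 2000, seed = 8)
  expect_lt(abs(mp0), 3 * 0.1 / sqrt(2000) + 0.02)
})

test_that("posterior entropy orders tight and wide posteriors correctly", {
  # noise levels chosen so both posteriors are wide enough for positive
  # Monte-Carlo entropies (a sharp one-dimensional density exceeds 1)
  pairsTight <- toyPairs(n = 8000, seed = 41, noiseSd = 0.3)
  pairsWide <- toyPairs(n = 8000, seed = 41, noiseSd = 0.6)
  cfg <- list(nBlocks = 2, hidden = 16, maxEpochs = 30, patience = 8)
  box <- matrix(c(-1, 1), 1, 2)
  mTight <- suppressWarnings(trainNPE(pairsTight$theta, pairsTight$x,
                                      priorBox = box, flowConfig = cfg,
                                      seed = 42))
  mWide <- suppressWarnings(trainNPE(pairsWide$theta, pairsWide$x,
                                     priorBox = box, flowConfig = cfg,
                                     seed = 42))
  eT <- posteriorEntropy(mTight, 0, n = 400, seed = 43)
  eW <- posteriorEntropy(mWide, 0, n = 400, seed = 43)
  expect_lt(eT, eW)
  expect_equal(posteriorEntropy(mTight, 0, n = 400, seed = 43), eT)
  # normalization sets the least-entropy cell to 1
  expect_equal(min(normalizeEntropy(c(eT, eW, eT + 5))), 1)
})

test_that("evaluateFit with an identity simulator stub reports perfect fits", {
  m <- toyModel()
  obs <- matrix(c(-0.3, 0, 0.4), ncol = 1)
  stub <- function(theta) matrix(rep(NA_real_, nrow(theta)), ncol = 1)
  # stub returning the observation itself -> fail 0%, distance 0
  makeStub <- function(xo) function(theta) matrix(xo, nrow(theta), 1)
  for (i in seq_len(nrow(obs))) {
    rep <- evaluateFit(m, obs[i, , drop = FALSE],
                       simFeatures = makeStub(obs[i, ]), nPosterior = 3,
                       mapSamples = 500, seed = 1)
    expect_equal(rep@mapFailPct, 0)
    expect_equal(rep@postFailPct, 0)
    expect_equal(rep@mapDistMean, 0)
    expect_equal(rep@postDistMean, 0)
  }
})

test_that("random prior draws fail at the campaign's invalid rate", {
  lib <- referenceLibrary()
  # simulate fresh prior draws and featurize them exactly as the evaluation
  # protocol would for posterior samples
  set.seed(51)
  th <- samplePrior(400, seed = 51)
  fails <- logical(nrow(th))
  pr <- stimProtocol()
  for (i in seq_len(nrow(th))) {
    pr$seed <- childSeed(52, i)
    fv <- transformFeatures(extractFeatures(simulateHH(th[i, ], pr)))
    fails[i] <- anyNA(fv)
  }
  expected <- 1 - validFraction(lib)
  se <- sqrt(expected * (1 - expected) / length(fails))
  expect_lt(abs(mean(fails) - expected), 4 * se)
})
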