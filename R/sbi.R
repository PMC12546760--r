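#' Construct an NPE training schedule
#'
#' `"standard"` trains on all valid prior simulations. `"best_euclidean"`
#' trains only on the union, over observations, of the `k` nearest valid
#' simulations in standardized feature space. `"noise_features"` additionally
#' perturbs the selected features with isotropic Gaussian noise of
#' `noiseSdFeatures` (in units of the campaign feature SDs) -- this is the
#' noise-robust schedule; `"noise_features_params"` also perturbs the
#' parameters (in parameter z-units); `"data_augmentation"` concatenates the
#' clean and the noise-perturbed copies of the selected set.
#'
#' @param mode schedule mode (see above).
#' @param noiseSdFeatures,noiseSdParams Gaussian noise SDs in z-units.
#' @param k nearest simulations per observation; `NA` picks
#'   `min(10000, floor(nValid / 10))`.
#' @param seed seed for the noise draws.
#' @return A [TrainingSchedule-class].
#' @export
trainingSchedule <- function(mode = c("standard", "best_euclidean",
                                      "noise_features",
                                      "noise_features_params",
                                      "data_augmentation"),
                             noiseSdFeatures = 0.1, noiseSdParams = 0,
                             k = NA_real_, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "standard") noiseSdFeatures <- noiseSdParams <- 0
  new("TrainingSchedule", mode = mode, noiseSdFeatures = noiseSdFeatures,
      noiseSdParams = noiseSdParams, k = as.numeric(k), seed = seed)
}

#' Select and perturb the training pairs for NPE
#'
#' @param lib a [SimulationLibrary-class].
#' @param observations z-scored observation matrix (rows = cells); required
#'   for every mode except `"standard"`.
#' @param schedule a [TrainingSchedule-class].
#' @return List with `theta` (raw parameter matrix) and `x` (z-scored,
#'   possibly noise-perturbed feature matrix).
#' @export
selectTrainingSet <- function(lib, observations = NULL,
                              schedule = trainingSchedule("standard")) {
  vIdx <- which(lib@valid)
  if (!length(vIdx)) stop("library has no valid rows")
  z <- standardizeFeatures(lib@features[vIdx, , drop = FALSE],
                           lib@standardizer)
  th <- lib@params[vIdx, , drop = FALSE]
  if (schedule@mode == "standard") {
    return(list(theta = th, x = z))
  }
  if (is.null(observations)) stop("subset schedules need observations")
  observations <- rbind(observations)
  k <- schedule@k
  if (is.na(k)) k <- min(10000, max(1, floor(length(vIdx) / 10)))
  if (k > length(vIdx)) stop("fewer valid simulations (", length(vIdx),
                             ") than neighborhood size k = ", k)
  sel <- integer(0)
  for (i in seq_len(nrow(observations))) {
    d2 <- rowSums(sweep(z, 2, observations[i, ], "-")^2)
    sel <- c(sel, order(d2)[seq_len(k)])
  }
  sel <- sort(unique(sel))
  thS <- th[sel, , drop = FALSE]
  xS <- z[sel, , drop = FALSE]
  if (schedule@mode == "best_euclidean") {
    return(list(theta = thS, x = xS))
  }
  set.seed(schedule@seed)
  xN <- xS + matrix(stats::rnorm(length(xS), sd = schedule@noiseSdFeatures),
                    nrow(xS))
  if (schedule@mode == "noise_features") {
    return(list(theta = thS, x = xN))
  }
  if (schedule@mode == "noise_features_params") {
    mu <- colMeans(th)
    sd <- apply(th, 2, stats::sd)
    thZ <- sweep(sweep(thS, 2, mu, "-"), 2, sd, "/")
    thZ <- thZ + matrix(stats::rnorm(length(thZ), sd = schedule@noiseSdParams),
                        nrow(thZ))
    thN <- sweep(sweep(thZ, 2, sd, "*"), 2, mu, "+")
    return(list(theta = thN, x = xN))
  }
  # data augmentation: clean plus perturbed copies
  list(theta = rbind(thS, thS), x = rbind(xS, xN))
}

.identityStandardizer <- function(d, names = NULL) {
  nm <- names %||% paste0("x", seq_len(d))
  new("FeatureStandardizer", mean = stats::setNames(rep(0, d), nm),
      sd = stats::setNames(rep(1, d), nm))
}

#' Train a neural posterior estimator
#'
#' Fits a conditional masked autoregressive flow for the parameter posterior
#' given features, by maximum likelihood on (parameter, feature) pairs with a
#' held-out validation split and early stopping. Parameters are z-scored
#' internally; features are expected already z-scored (pass the library
#' standardizer so the model can place new simulations on the same scale).
#'
#' @param theta training parameter matrix (natural units).
#' @param x training feature matrix (z-scored), same number of rows.
#' @param priorBox box used to reject samples outside the prior support.
#' @param featureStandardizer the [FeatureStandardizer-class] that produced
#'   `x` (identity if `NULL`).
#' @param schedule the [TrainingSchedule-class] that produced the pairs
#'   (metadata; defaults to standard).
#' @param flowConfig list overriding flow defaults: `nBlocks` (5), `hidden`
#'   (50), `batch` (256), `lr` (1e-3), `valFraction` (0.1), `patience` (20),
#'   `maxEpochs` (300).
#' @param seed integer seed controlling initialization, the split and
#'   minibatch order.
#' @return A [PosteriorModel-class].
#' @export
trainNPE <- function(theta, x, priorBox = defaultPriorBox(),
                     featureStandardizer = NULL,
                     schedule = trainingSchedule("standard"),
                     flowConfig = list(), seed = 1) {
  theta <- rbind(theta)
  x <- rbind(x)
  stopifnot(nrow(theta) == nrow(x))
  if (nrow(theta) < 1000) {
    warning("training on fewer than 1,000 pairs; the posterior may be poor")
  }
  cfg <- utils::modifyList(list(nBlocks = 5, hidden = 50, batch = 256,
                                lr = 1e-3, valFraction = 0.1, patience = 20,
                                maxEpochs = 300, verbose = FALSE), flowConfig)
  mu <- colMeans(theta)
  sd <- apply(theta, 2, stats::sd)
  sd[sd == 0] <- 1e-12 # degenerate targets collapse to a point
  thZ <- sweep(sweep(theta, 2, mu, "-"), 2, sd, "/")
  set.seed(seed)
  fit <- .trainFlow(thZ, x, nBlocks = cfg$nBlocks, hidden = cfg$hidden,
                    batch = cfg$batch, lr = cfg$lr,
                    valFraction = cfg$valFraction, patience = cfg$patience,
                    maxEpochs = cfg$maxEpochs, verbose = cfg$verbose)
  std <- featureStandardizer %||%
    .identityStandardizer(ncol(x), colnames(x))
  if (is.null(dim(priorBox))) priorBox <- rbind(priorBox)
  new("PosteriorModel", flow = fit$flow, thetaMean = mu, thetaSd = sd,
      standardizer = std, priorBox = priorBox, schedule = schedule,
      history = list(valCurve = fit$valCurve, bestEpoch = fit$bestEpoch,
                     bestVal = fit$bestVal, nPairs = nrow(theta),
                     seed = seed))
}

#' Posterior log-density
#'
#' @param model a [PosteriorModel-class].
#' @param theta parameter vector or matrix (natural units).
#' @param xo z-scored observation vector.
#' @return Log-density values (natural-unit scale) for each row of `theta`.
#' @export
logPosterior <- function(model, theta, xo) {
  theta <- rbind(theta)
  thZ <- sweep(sweep(theta, 2, model@thetaMean, "-"), 2, model@thetaSd, "/")
  ctx <- matrix(rep(as.numeric(xo), each = nrow(thZ)), nrow = nrow(thZ))
  .flowLogDensity(model@flow, thZ, ctx) - sum(log(model@thetaSd))
}

#' Sample from the posterior, rejecting outside the prior box
#'
#' @param model a [PosteriorModel-class].
#' @param xo z-scored observation vector (fully defined).
#' @param n number of accepted samples.
#' @param seed optional seed.
#' @param maxRounds cap on rejection rounds.
#' @param partial return the accepted draws (at least 50) instead of
#'   erroring when the cap is hit before `n` samples are in the box.
#' @return Up to n x D matrix of parameter samples (natural units).
#' @export
samplePosterior <- function(model, xo, n, seed = NULL, maxRounds = 1000,
                            partial = FALSE) {
  if (anyNA(xo)) stop("observation has undefined features")
  if (!is.null(seed)) set.seed(seed)
  box <- model@priorBox
  out <- matrix(NA_real_, 0, length(model@thetaMean))
  drawn <- 0
  for (round in seq_len(maxRounds)) {
    m <- max(4096, n - nrow(out))
    z <- .flowSample(model@flow, xo, m)
    th <- sweep(sweep(z, 2, model@thetaSd, "*"), 2, model@thetaMean, "+")
    inBox <- rep(TRUE, m)
    for (j in seq_len(ncol(th))) {
      inBox <- inBox & th[, j] >= box[j, 1] & th[, j] <= box[j, 2]
    }
    out <- rbind(out, th[inBox, , drop = FALSE])
    drawn <- drawn + m
    if (nrow(out) >= n) break
    if (drawn >= 8400 && nrow(out) / drawn < 0.001) {
      perDim <- sapply(seq_len(ncol(th)), function(j) {
        mean(th[, j] < box[j, 1] | th[, j] > box[j, 2])
      })
      bad <- rownames(box)[order(perDim, decreasing = TRUE)][1:3]
      stop("posterior mass leaks out of the prior box (acceptance < 0.1%), ",
           "worst dimensions: ", paste(bad, collapse = ", "))
    }
  }
  if (nrow(out) < n) {
    if (!partial || nrow(out) < 50) {
      stop("could not draw enough in-box samples")
    }
  } else {
    out <- out[seq_len(n), , drop = FALSE]
  }
  colnames(out) <- rownames(box)
  out
}

#' Maximum a posteriori estimate
#'
#' Draws `nSamples` posterior samples, takes the sample with the highest
#' posterior density, and (optionally) refines it by box-constrained local
#' ascent on the flow log-density.
#'
#' @param model a [PosteriorModel-class].
#' @param xo z-scored observation vector.
#' @param nSamples samples scanned for the argmax (default 10,000).
#' @param refine logical; run L-BFGS-B refinement.
#' @param seed optional seed.
#' @return Named parameter vector with attribute `logDensity`.
#' @export
mapEstimate <- function(model, xo, nSamples = 10000, refine = TRUE,
                        seed = NULL) {
  # the argmax scan works with whatever in-box draws a bounded number of
  # rejection rounds yields; the gradient refinement absorbs the difference
  smp <- samplePosterior(model, xo, nSamples, seed = seed, maxRounds = 3,
                         partial = TRUE)
  ld <- logPosterior(model, smp, xo)
  best <- smp[which.min(-ld), ]
  bestLd <- max(ld)
  if (refine) {
    box <- model@priorBox
    zlo <- (box[, 1] - model@thetaMean) / model@thetaSd
    zhi <- (box[, 2] - model@thetaMean) / model@thetaSd
    z0 <- (best - model@thetaMean) / model@thetaSd
    ctx1 <- matrix(as.numeric(xo), nrow = 1)
    D <- length(z0)
    f <- function(z) {
      -.flowLogDensity(model@flow, matrix(z, nrow = 1), ctx1)
    }
    # central-difference gradient, all perturbations in one batched pass
    gr <- function(z) {
      eps <- 1e-5
      pts <- matrix(rep(z, each = 2 * D), 2 * D, D)
      idx <- rep(seq_len(D), each = 2)
      pts[cbind(seq_len(2 * D), idx)] <-
        pts[cbind(seq_len(2 * D), idx)] + rep(c(eps, -eps), D)
      ctxB <- matrix(as.numeric(xo), 2 * D, length(xo), byrow = TRUE)
      ld <- .flowLogDensity(model@flow, pts, ctxB)
      -(ld[seq(1, 2 * D, 2)] - ld[seq(2, 2 * D, 2)]) / (2 * eps)
    }
    opt <- try(stats::optim(z0, f, gr, method = "L-BFGS-B", lower = zlo,
                            upper = zhi, control = list(maxit = 50)),
               silent = TRUE)
    if (!inherits(opt, "try-error")) {
      cand <- opt$par * model@thetaSd + model@thetaMean
      candLd <- -opt$value - sum(log(model@thetaSd))
      if (candLd >= bestLd) {
        best <- cand
        bestLd <- candLd
      }
    }
  }
  names(best) <- rownames(model@priorBox)
  attr(best, "logDensity") <- bestLd
  best
}

#' Posterior entropy score of an observation
#'
#' Monte-Carlo uncertainty score: the negative sum of posterior log-densities
#' of `n` posterior draws. Larger values indicate a wider (less constrained)
#' posterior.
#'
#' @param model a [PosteriorModel-class].
#' @param xo z-scored observation vector.
#' @param n number of draws (default 1000).
#' @param seed optional seed.
#' @return Numeric scalar.
#' @export
posteriorEntropy <- function(model, xo, n = 1000, seed = NULL) {
  smp <- samplePosterior(model, xo, n, seed = seed)
  -sum(logPosterior(model, smp, xo))
}

#' Normalize entropy scores across cells
#'
#' Divides by the cell with the least entropy so the best-constrained cell
#' scores 1.
#'
#' @param x numeric vector of positive entropy scores.
#' @return Rescaled vector with minimum 1.
#' @export
normalizeEntropy <- function(x) {
  if (min(x) <= 0) stop("entropy scores must be positive to normalize")
  x / min(x)
}

# default simulator->z-features map used by evaluateFit: simulate every row,
# featurize, transform, standardize with the model's feature standardizer
.makeSimFeatures <- function(model, protocol, constants, seed) {
  force(model); force(protocol); force(constants); force(seed)
  counter <- new.env()
  counter$i <- 0
  function(theta) {
    theta <- rbind(theta)
    out <- matrix(NA_real_, nrow(theta), 23,
                  dimnames = list(NULL, ephysFeatureNames()))
    for (i in seq_len(nrow(theta))) {
      counter$i <- counter$i + 1
      pr <- protocol
      pr$seed <- childSeed(seed, counter$i)
      tr <- simulateHH(theta[i, ], pr, constants)
      out[i, ] <- extractFeatures(tr)
    }
    standardizeFeatures(transformFeatures(out), model@standardizer)
  }
}

#' Posterior-predictive evaluation
#'
#' For each observation, simulates the MAP parameter set and `nPosterior`
#' random posterior parameter sets, and reports the percentage of simulation
#' fails (at least one undefined feature) together with the mean +/- SD
#' Euclidean distance to the observation in standardized feature space over
#' the non-failed simulations, separately for the MAP and the
#' posterior-sample columns.
#'
#' @param model a [PosteriorModel-class].
#' @param observations z-scored observation matrix (rows = cells).
#' @param simFeatures function mapping a parameter matrix to a z-scored
#'   feature matrix; defaults to simulating with `protocol`/`constants` and
#'   the model's feature standardizer. Tests may pass a stub.
#' @param nPosterior posterior samples per observation (default 10).
#' @param protocol,constants simulation settings for the default simulator.
#' @param mapSamples,refineMap forwarded to [mapEstimate()].
#' @param seed master seed.
#' @return A [FitReport-class].
#' @export
evaluateFit <- function(model, observations, simFeatures = NULL,
                        nPosterior = 10, protocol = stimProtocol(),
                        constants = physConstants(), mapSamples = 10000,
                        refineMap = TRUE, seed = 1) {
  observations <- rbind(observations)
  if (anyNA(observations)) stop("observations must be fully defined")
  if (is.null(simFeatures)) {
    simFeatures <- .makeSimFeatures(model, protocol, constants, seed)
  }
  m <- nrow(observations)
  mapDist <- rep(NA_real_, m)
  mapFail <- logical(m)
  postDist <- list()
  postFail <- 0L
  postTot <- 0L
  perObs <- vector("list", m)
  for (i in seq_len(m)) {
    xo <- observations[i, ]
    # a posterior that cannot be sampled inside the prior box (mass leaked
    # out under misspecification) counts as failing all its simulations
    thMap <- tryCatch(
      mapEstimate(model, xo, nSamples = mapSamples, refine = refineMap,
                  seed = childSeed(seed, 2L * i)),
      error = function(e) NULL)
    if (is.null(thMap)) {
      mapFail[i] <- TRUE
    } else {
      zMap <- simFeatures(rbind(thMap))
      mapFail[i] <- anyNA(zMap)
      if (!mapFail[i]) mapDist[i] <- featureDistance(zMap[1, ], xo)
    }
    thPost <- tryCatch(
      samplePosterior(model, xo, nPosterior,
                      seed = childSeed(seed, 2L * i + 1L)),
      error = function(e) NULL)
    dists <- rep(NA_real_, nPosterior)
    if (is.null(thPost)) {
      fails <- rep(TRUE, nPosterior)
    } else {
      zPost <- simFeatures(thPost)
      fails <- apply(zPost, 1, anyNA)
      ok <- which(!fails)
      for (j in ok) dists[j] <- featureDistance(zPost[j, ], xo)
    }
    postFail <- postFail + sum(fails)
    postTot <- postTot + nPosterior
    postDist[[i]] <- dists
    perObs[[i]] <- data.frame(observation = i, map_fail = mapFail[i],
                              map_distance = mapDist[i],
                              posterior_fails = sum(fails),
                              posterior_distance_mean = mean(dists, na.rm = TRUE))
  }
  allPost <- unlist(postDist)
  new("FitReport",
      mapFailPct = 100 * mean(mapFail),
      mapDistMean = mean(mapDist, na.rm = TRUE),
      mapDistSd = stats::sd(mapDist[!is.na(mapDist)]),
      postFailPct = 100 * postFail / postTot,
      postDistMean = mean(allPost, na.rm = TRUE),
      postDistSd = stats::sd(allPost[!is.na(allPost)]),
      perObservation = do.call(rbind, perObs))
}

#' Save / load a posterior model checkpoint
#'
#' Single-file archive holding the flow weights, both standardizers, the
#' prior box, the schedule and the training history.
#'
#' @param model a [PosteriorModel-class].
#' @param path file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "PosteriorModel")) stop("file does not contain a PosteriorModel")
  m
}
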