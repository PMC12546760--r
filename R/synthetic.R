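# Generators for ground-truth cohorts: parameter sets arranged in families,
# feature-space observations with an optional systematic shift emulating
# model-data mismatch, and linked overdispersed count matrices whose
# informative genes carry a sparse linear map to the parameters.

#' Generate ground-truth cells grouped into families
#'
#' Family centers are drawn uniformly in the central 60% of the prior box;
#' cells jitter around their center with Gaussian noise of SD
#' `spread * range`, truncated to the box. Only parameter sets whose
#' simulation has all 23 features defined are kept (centers that rarely
#' produce valid cells are redrawn), so every retained cell is feature-valid
#' by construction.
#'
#' @param nFamilies number of families.
#' @param cellsPerFamily cells per family.
#' @param spread within-family jitter as a fraction of each parameter range.
#' @param seed master seed.
#' @param box prior box.
#' @param protocol,constants simulation settings used for the validity check.
#' @return List with `theta` (cells x 13) and `labels` (factor).
#' @export
makeCells <- function(nFamilies = 6, cellsPerFamily = 150, spread = 0.05,
                      seed = 1, box = defaultPriorBox(),
                      protocol = stimProtocol(),
                      constants = physConstants()) {
  box <- .checkBox(box)
  rng <- box[, 2] - box[, 1]
  lo60 <- box[, 1] + 0.2 * rng
  hi60 <- box[, 2] - 0.2 * rng
  set.seed(childSeed(seed, 0))
  counter <- 0L
  validTheta <- function(th, idx) {
    pr <- protocol
    pr$seed <- childSeed(seed, idx)
    fv <- extractFeatures(simulateHH(th, pr, constants))
    all(is.finite(transformFeatures(fv)))
  }
  theta <- matrix(NA_real_, nFamilies * cellsPerFamily, 13,
                  dimnames = list(NULL, rownames(box)))
  labels <- rep(seq_len(nFamilies), each = cellsPerFamily)
  row <- 0L
  for (f in seq_len(nFamilies)) {
    repeat {
      center <- lo60 + stats::runif(13) * (hi60 - lo60)
      counter <- counter + 1L
      if (validTheta(center, counter)) break
    }
    got <- 0L
    tries <- 0L
    while (got < cellsPerFamily) {
      th <- center + stats::rnorm(13, sd = spread * rng)
      th <- pmin(pmax(th, box[, 1]), box[, 2])
      # keep hard positivity invariants after truncation
      counter <- counter + 1L
      tries <- tries + 1L
      if (spread == 0 || validTheta(th, counter)) {
        row <- row + 1L
        got <- got + 1L
        theta[row, ] <- if (spread == 0) center else th
      }
      if (tries > 50 * cellsPerFamily) {
        stop("family ", f, " cannot be filled with valid cells; ",
             "reduce spread or redraw")
      }
    }
  }
  list(theta = theta, labels = factor(paste0("family_", labels)))
}

#' Simulate feature-space observations for known cells
#'
#' Simulates each parameter set, extracts and transforms the features,
#' z-scores them with the supplied standardizer, and adds a constant shift
#' `delta` (z-units; scalar, recycled, or length-23) plus independent
#' Gaussian measurement noise. A nonzero shift emulates the systematic
#' mismatch between the manifold of simulator outputs and real recordings.
#'
#' @param theta cells x 13 parameter matrix.
#' @param standardizer the [FeatureStandardizer-class] of the reference
#'   campaign.
#' @param delta systematic shift in z-units.
#' @param measSd independent measurement noise SD in z-units.
#' @param protocol,constants simulation settings.
#' @param retries re-simulation attempts (fresh noise seed) when a draw has
#'   undefined features.
#' @param seed master seed.
#' @return cells x 23 matrix of z-scored observations (rows that stayed
#'   undefined after `retries` attempts are `NA`).
#' @export
makeObservations <- function(theta, standardizer, delta = 0, measSd = 0,
                             protocol = stimProtocol(),
                             constants = physConstants(), retries = 5,
                             seed = 1) {
  theta <- rbind(theta)
  if (length(delta) == 1) delta <- rep(delta, 23)
  stopifnot(length(delta) == 23)
  m <- nrow(theta)
  out <- matrix(NA_real_, m, 23, dimnames = list(NULL, ephysFeatureNames()))
  for (i in seq_len(m)) {
    for (r in seq_len(retries)) {
      pr <- protocol
      pr$seed <- childSeed(seed, (i - 1L) * retries + r)
      fv <- transformFeatures(extractFeatures(simulateHH(theta[i, ], pr,
                                                         constants)))
      if (all(is.finite(fv))) {
        out[i, ] <- standardizeFeatures(fv, standardizer)
        break
      }
    }
  }
  set.seed(childSeed(seed, m * retries + 1L))
  noise <- matrix(stats::rnorm(m * 23, sd = measSd), m, 23)
  sweep(out, 2, delta, "+") + noise
}

#' Generate an expression matrix linked to biophysical parameters
#'
#' Informative genes have log-rates `baseline + loading . z(theta)`; marker
#' genes carry family-specific offsets; all counts are negative-binomial with
#' the given dispersion and lognormal per-cell depth variation, emulating
#' Smart-seq style overdispersed counts.
#'
#' @param theta cells x 13 parameter matrix.
#' @param labels family labels (one marker gene per family when
#'   `nMarkers > 0`).
#' @param nGenes total genes.
#' @param nInformative genes carrying parameter loadings.
#' @param nMarkers family marker genes.
#' @param loadingScale SD of the nonzero loadings.
#' @param dispersion negative-binomial dispersion (`1/size`).
#' @param depthMean,depthCV lognormal per-cell depth factor.
#' @param seed seed.
#' @return List with `counts` (cells x genes integer matrix) and `loadings`
#'   (genes x 13; nonzero rows are the planted informative genes).
#' @export
makeExpression <- function(theta, labels = NULL, nGenes = 400,
                           nInformative = 20, nMarkers = 0,
                           loadingScale = 0.5, dispersion = 0.5,
                           depthMean = 1, depthCV = 0.3, seed = 1) {
  theta <- rbind(theta)
  n <- nrow(theta)
  set.seed(childSeed(seed, 0))
  thZ <- scale(theta)
  thZ[is.nan(thZ)] <- 0
  genes <- sprintf("gene_%03d", seq_len(nGenes))
  loadings <- matrix(0, nGenes, 13, dimnames = list(genes, colnames(theta)))
  info <- sample.int(nGenes, nInformative)
  for (g in info) {
    k <- sample(1:3, 1)
    loadings[g, sample.int(13, k)] <- stats::rnorm(k, sd = loadingScale)
  }
  baseline <- stats::rnorm(nGenes, mean = log(5), sd = 1)
  logRate <- matrix(baseline, n, nGenes, byrow = TRUE) +
    thZ %*% t(loadings)
  if (!is.null(labels) && nMarkers > 0) {
    labels <- droplevels(as.factor(labels))
    nonInfo <- setdiff(seq_len(nGenes), info)
    markers <- sample(nonInfo, min(nMarkers * nlevels(labels),
                                   length(nonInfo)))
    for (j in seq_along(markers)) {
      fam <- levels(labels)[(j - 1) %% nlevels(labels) + 1]
      logRate[labels == fam, markers[j]] <-
        logRate[labels == fam, markers[j]] + 2
    }
  }
  sdlog <- sqrt(log(1 + depthCV^2))
  depth <- stats::rlnorm(n, meanlog = log(depthMean) - sdlog^2 / 2,
                         sdlog = sdlog)
  mu <- exp(logRate) * depth
  counts <- matrix(stats::rnbinom(n * nGenes, mu = mu, size = 1 / dispersion),
                   n, nGenes, dimnames = list(NULL, genes))
  list(counts = counts, loadings = loadings)
}

#' Planted sparse reduced-rank regression problem
#'
#' A Gaussian design with a known low-rank coefficient matrix supported on
#' `k` of `p` genes, with noise scaled to the requested signal-to-noise
#' ratio. Used to benchmark support recovery and predictive accuracy against
#' the oracle least-squares refit on the true support.
#'
#' @param n cells, `p` genes, `k` informative genes.
#' @param q number of targets.
#' @param rank planted rank.
#' @param snr signal variance divided by noise variance.
#' @param seed seed.
#' @return List with `X`, `Y`, `support` (integer indices), `B` (true p x q
#'   coefficients), `noiseSd`.
#' @export
makePlantedSRRR <- function(n = 500, p = 400, k = 20, q = 13, rank = 2,
                            snr = 1, seed = 1) {
  set.seed(childSeed(seed, 0))
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("gene_%03d", seq_len(p))))
  support <- sort(sample.int(p, k))
  Wk <- matrix(stats::rnorm(k * rank), k, rank)
  V <- qr.Q(qr(matrix(stats::rnorm(q * rank), q, rank)))
  B <- matrix(0, p, q)
  B[support, ] <- Wk %*% t(V)
  S <- X %*% B
  noiseSd <- sqrt(mean(apply(S, 2, stats::var)) / snr)
  Y <- S + matrix(stats::rnorm(n * q, sd = noiseSd), n, q)
  colnames(Y) <- hhParameterNames()
  list(X = X, Y = Y, support = support, B = B, noiseSd = noiseSd)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [makeCells()], [makeObservations()] and
#' [makeExpression()] into a [SyntheticCohort-class]. The default shape (6
#' families of 150 cells, a 400-gene panel with 20 informative genes)
#' mirrors a desk-scale Patch-seq study.
#'
#' @param standardizer feature standardizer of the reference campaign.
#' @param box prior box the cells are drawn from.
#' @param nFamilies,cellsPerFamily,spread cohort shape.
#' @param delta,measSd observation shift and measurement noise (z-units).
#' @param nGenes,nInformative,loadingScale,dispersion expression settings.
#' @param protocol,constants simulation settings.
#' @param seed master seed.
#' @return A [SyntheticCohort-class].
#' @export
makeCohort <- function(standardizer, nFamilies = 6, cellsPerFamily = 150,
                       spread = 0.05, delta = 0, measSd = 0, nGenes = 400,
                       nInformative = 20, loadingScale = 0.5,
                       dispersion = 0.5, box = defaultPriorBox(),
                       protocol = stimProtocol(),
                       constants = physConstants(), seed = 1) {
  cells <- makeCells(nFamilies, cellsPerFamily, spread, seed = childSeed(seed, 1),
                     box = box, protocol = protocol, constants = constants)
  obs <- makeObservations(cells$theta, standardizer, delta = delta,
                          measSd = measSd, protocol = protocol,
                          constants = constants, seed = childSeed(seed, 2))
  expr <- makeExpression(cells$theta, cells$labels, nGenes = nGenes,
                         nInformative = nInformative,
                         loadingScale = loadingScale, dispersion = dispersion,
                         seed = childSeed(seed, 3))
  delta23 <- if (length(delta) == 1) rep(delta, 23) else delta
  new("SyntheticCohort", theta = cells$theta, labels = cells$labels,
      observations = obs, shift = delta23, counts = expr$counts,
      loadings = expr$loadings,
      meta = list(seed = seed, spread = spread, measSd = measSd,
                  dispersion = dispersion))
}
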