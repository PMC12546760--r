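# End-to-end orchestration: campaign -> cohort -> NPE training -> inference
# (MAP + entropy) -> posterior-predictive evaluation -> gene-expression
# linkage, with per-stage resumability and provenance in every artifact.

#' Default pipeline configuration
#'
#' Returns the complete run configuration as a nested list; any entry can be
#' overridden. Round-trips losslessly through YAML via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param ... named overrides merged into the defaults (nested lists merge
#'   recursively). An optional `prior` entry (`list(lower = ..., upper = ...)`
#'   with named per-parameter bounds) overrides the default prior box.
#' @return Named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1,
    campaign = list(n = 20000, batchSize = 2000),
    protocol = stimProtocol(),
    constants = physConstants(),
    cohort = list(nFamilies = 6, cellsPerFamily = 25, spread = 0.05,
                  delta = 0, measSd = 0, nGenes = 400, nInformative = 20,
                  loadingScale = 0.5, dispersion = 0.5),
    schedule = list(mode = "noise_features", noiseSdFeatures = 0.1,
                    noiseSdParams = 0, k = NA),
    flow = list(nBlocks = 5, hidden = 50, batch = 256, lr = 1e-3,
                valFraction = 0.1, patience = 20, maxEpochs = 300),
    evaluate = list(nPosterior = 10, mapSamples = 10000),
    srrr = list(rank = 2, alpha = 0.5, folds = 5))
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param cfg configuration list from [runConfig()].
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig` the
#'   configuration merged over the defaults.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg)
}

#' Digest of a configuration (for provenance logging)
#'
#' FNV-1a hash of the canonical JSON serialization; every pipeline artifact
#' records it so runs can be matched to their configuration.
#'
#' @param cfg configuration list.
#' @return 8-character hexadecimal string.
#' @export
configDigest <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte, keeping h a double below 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stageMsg <- function(quiet, ...) if (!quiet) message("[neurosbi] ", ...)

#' Run the complete pipeline
#'
#' Executes, in order: prior campaign, synthetic cohort generation, NPE
#' training (per the configured schedule), per-cell inference (MAP estimates
#' and posterior entropies), posterior-predictive evaluation, and sRRR gene
#' linkage. Each stage writes one artifact into `outDir` and is skipped on
#' rerun when its artifact already exists, so a deleted artifact resumes the
#' pipeline at that stage. Artifacts: `library/` (CSV directory),
#' `cohort.rds`, `model.rds`, `map_params.csv`, `entropy.csv`,
#' `evaluation.json`, `srrr_report.json`.
#'
#' @param config configuration from [runConfig()].
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config = runConfig(), outDir, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  digest <- configDigest(config)
  .stageMsg(quiet, "config digest ", digest)
  protocol <- do.call(stimProtocol, config$protocol[setdiff(names(config$protocol), "seed")])
  constants <- do.call(physConstants, config$constants)
  box <- defaultPriorBox()
  if (!is.null(config$prior)) { # per-parameter bound overrides
    for (p in names(config$prior$lower)) box[p, 1] <- config$prior$lower[[p]]
    for (p in names(config$prior$upper)) box[p, 2] <- config$prior$upper[[p]]
  }
  paths <- list(library = file.path(outDir, "library"),
                cohort = file.path(outDir, "cohort.rds"),
                model = file.path(outDir, "model.rds"),
                map = file.path(outDir, "map_params.csv"),
                entropy = file.path(outDir, "entropy.csv"),
                evaluation = file.path(outDir, "evaluation.json"),
                srrr = file.path(outDir, "srrr_report.json"))

  # 1. prior campaign
  if (!file.exists(file.path(paths$library, "params.csv"))) {
    .stageMsg(quiet, "stage campaign: ", config$campaign$n, " simulations")
    lib <- tryCatch(
      runCampaign(config$campaign$n, box = box, protocol = protocol,
                  constants = constants, seed = childSeed(config$seed, 11),
                  batchSize = config$campaign$batchSize,
                  checkpoint = file.path(outDir, "campaign_checkpoint.rds")),
      error = function(e) stop("stage 'campaign' failed (resumable from ",
                               outDir, "): ", conditionMessage(e)))
    writeLibrary(lib, paths$library)
  } else {
    .stageMsg(quiet, "stage campaign: artifact exists, skipping")
    lib <- readLibrary(paths$library)
  }

  # 2. synthetic cohort
  if (!file.exists(paths$cohort)) {
    .stageMsg(quiet, "stage cohort")
    co <- config$cohort
    cohort <- makeCohort(standardizer(lib), nFamilies = co$nFamilies,
                         cellsPerFamily = co$cellsPerFamily,
                         spread = co$spread, delta = co$delta,
                         measSd = co$measSd, nGenes = co$nGenes,
                         nInformative = co$nInformative,
                         loadingScale = co$loadingScale,
                         dispersion = co$dispersion, box = box,
                         protocol = protocol,
                         constants = constants,
                         seed = childSeed(config$seed, 12))
    saveRDS(cohort, paths$cohort)
  } else {
    .stageMsg(quiet, "stage cohort: artifact exists, skipping")
    cohort <- readRDS(paths$cohort)
  }
  obs <- cohort@observations
  ok <- stats::complete.cases(obs)
  obs <- obs[ok, , drop = FALSE]

  # 3. NPE training
  if (!file.exists(paths$model)) {
    sc <- config$schedule
    .stageMsg(quiet, "stage train: schedule ", sc$mode)
    schedule <- trainingSchedule(sc$mode, noiseSdFeatures = sc$noiseSdFeatures,
                                 noiseSdParams = sc$noiseSdParams,
                                 k = if (is.null(sc$k) || is.na(sc$k)) NA else sc$k,
                                 seed = childSeed(config$seed, 13))
    pairs <- selectTrainingSet(lib, obs, schedule)
    model <- trainNPE(pairs$theta, pairs$x, priorBox = box,
                      featureStandardizer = standardizer(lib),
                      schedule = schedule, flowConfig = config$flow,
                      seed = childSeed(config$seed, 14))
    model@history$configDigest <- digest
    saveModel(model, paths$model)
  } else {
    .stageMsg(quiet, "stage train: artifact exists, skipping")
    model <- loadModel(paths$model)
  }

  # 4. inference: MAP + entropy per cell
  if (!file.exists(paths$map) || !file.exists(paths$entropy)) {
    .stageMsg(quiet, "stage infer: ", nrow(obs), " cells")
    mapMat <- matrix(NA_real_, nrow(obs), 13,
                     dimnames = list(NULL, hhParameterNames()))
    ent <- rep(NA_real_, nrow(obs))
    for (i in seq_len(nrow(obs))) {
      mapMat[i, ] <- mapEstimate(model, obs[i, ],
                                 nSamples = config$evaluate$mapSamples,
                                 seed = childSeed(config$seed, 100 + i))
      ent[i] <- posteriorEntropy(model, obs[i, ], n = 1000,
                                 seed = childSeed(config$seed, 5000 + i))
    }
    ids <- sprintf("cell_%04d", which(ok))
    writeParamsCSV(mapMat, paths$map, ids = ids)
    utils::write.csv(data.frame(cell_id = ids, entropy = ent,
                                entropy_normalized = normalizeEntropy(ent)),
                     paths$entropy, row.names = FALSE)
  } else {
    .stageMsg(quiet, "stage infer: artifacts exist, skipping")
    mapMat <- readParamsCSV(paths$map)
  }

  # 5. posterior-predictive evaluation
  if (!file.exists(paths$evaluation)) {
    .stageMsg(quiet, "stage evaluate")
    rep <- evaluateFit(model, obs, nPosterior = config$evaluate$nPosterior,
                       protocol = protocol, constants = constants,
                       mapSamples = config$evaluate$mapSamples,
                       seed = childSeed(config$seed, 15))
    jsonlite::write_json(list(config_digest = digest,
                              map_fail_pct = rep@mapFailPct,
                              map_dist_mean = rep@mapDistMean,
                              map_dist_sd = rep@mapDistSd,
                              posterior_fail_pct = rep@postFailPct,
                              posterior_dist_mean = rep@postDistMean,
                              posterior_dist_sd = rep@postDistSd),
                         paths$evaluation, auto_unbox = TRUE, digits = NA)
  } else .stageMsg(quiet, "stage evaluate: artifact exists, skipping")

  # 6. gene linkage
  if (!file.exists(paths$srrr)) {
    .stageMsg(quiet, "stage srrr")
    X <- preprocessExpression(cohort@counts[ok, , drop = FALSE])
    Y <- scale(mapMat)
    sg <- config$srrr
    lambdaGrid <- sg$lambdaGrid
    if (is.null(lambdaGrid)) {
      lambdaGrid <- srrrLambdaGrid(X, Y, rank = sg$rank, alpha = sg$alpha)
    }
    cv <- crossValidateSRRR(X, Y, lambdaGrid = lambdaGrid,
                            alpha = sg$alpha, rank = sg$rank,
                            folds = sg$folds,
                            seed = childSeed(config$seed, 16))
    bestL <- cv$lambda[which.max(cv$r2_mean)]
    fit <- fitSRRR(X, Y, rank = sg$rank, lambda = bestL, alpha = sg$alpha)
    jsonlite::write_json(list(config_digest = digest,
                              cv = cv, lambda = bestL,
                              selected_genes = as.list(selectedGenes(fit)),
                              per_target_r2 = as.list(perTargetR2(Y, predict(fit, X)))),
                         paths$srrr, auto_unbox = TRUE, digits = NA)
  } else .stageMsg(quiet, "stage srrr: artifact exists, skipping")

  invisible(paths)
}
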