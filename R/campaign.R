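#' Run a prior simulation campaign
#'
#' Draws `n` parameter sets from the prior box, simulates each with the step
#' protocol, extracts and transforms the 23 features, flags validity (all 23
#' transformed features defined) and fits the feature standardizer on the
#' valid rows. Each simulation uses a child seed derived from the master seed
#' and its index, so results are invariant to batching and the campaign is
#' resumable from a checkpoint.
#'
#' @param n number of simulations (>= 100 for a meaningful standardizer; the
#'   floor is relaxed for the passive-box edge case used in tests).
#' @param box prior box (13 x 2).
#' @param protocol stimulation protocol from [stimProtocol()].
#' @param constants constants from [physConstants()].
#' @param seed master seed.
#' @param batchSize simulations per checkpoint batch.
#' @param checkpoint optional path to an `.rds` checkpoint file; if it exists
#'   the campaign resumes after the last completed batch.
#' @param verbose print progress.
#' @return A [SimulationLibrary-class]. When no row is valid the standardizer
#'   is degenerate (unit scale) and flagged in the provenance.
#' @export
runCampaign <- function(n, box = defaultPriorBox(), protocol = stimProtocol(),
                        constants = physConstants(), seed = 1,
                        batchSize = 1000, checkpoint = NULL, verbose = FALSE) {
  if (n < 1) stop("n must be positive")
  box <- .checkBox(box)
  params <- samplePrior(n, box, seed = childSeed(seed, 0))
  raw <- matrix(NA_real_, n, 23, dimnames = list(NULL, ephysFeatureNames()))
  done <- 0L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- readRDS(checkpoint)
    if (identical(st$n, n) && identical(st$seed, seed)) {
      raw <- st$raw
      done <- st$done
      if (verbose) message("resuming campaign at simulation ", done + 1)
    }
  }
  while (done < n) {
    hi <- min(n, done + batchSize)
    for (i in (done + 1L):hi) {
      pr <- protocol
      pr$seed <- childSeed(seed, i)
      tr <- simulateHH(params[i, ], pr, constants)
      raw[i, ] <- extractFeatures(tr)
    }
    done <- hi
    if (!is.null(checkpoint)) {
      saveRDS(list(n = n, seed = seed, raw = raw, done = done), checkpoint)
    }
    if (verbose) message("simulated ", done, "/", n)
  }
  trans <- transformFeatures(raw)
  valid <- apply(trans, 1, function(z) all(is.finite(z)))
  degenerate <- sum(valid) < 2
  std <- if (degenerate) {
    new("FeatureStandardizer",
        mean = stats::setNames(rep(0, 23), ephysFeatureNames()),
        sd = stats::setNames(rep(1, 23), ephysFeatureNames()))
  } else fitStandardizer(trans, valid)
  new("SimulationLibrary", params = params, rawFeatures = raw,
      features = trans, valid = unname(valid), standardizer = std,
      provenance = list(seed = seed, n = n, dt = protocol$dt,
                        protocol = protocol, constants = constants,
                        degenerateStandardizer = degenerate))
}

#' Best prior match for an observation
#'
#' Scans the valid rows of a library and returns the parameter set whose
#' simulation lies closest to the observation in standardized feature space
#' (Euclidean distance); ties break to the lowest row index.
#'
#' @param observation fully defined z-scored feature vector (library
#'   standardizer scale).
#' @param lib a [SimulationLibrary-class].
#' @return List with `params` (named vector), `distance`, and `index` (row in
#'   the library).
#' @export
bestPriorMatch <- function(observation, lib) {
  if (anyNA(observation)) stop("observation has undefined features")
  vIdx <- which(lib@valid)
  if (!length(vIdx)) stop("library has no valid rows")
  z <- standardizeFeatures(lib@features[vIdx, , drop = FALSE], lib@standardizer)
  d2 <- rowSums(sweep(z, 2, as.numeric(observation), "-")^2)
  j <- which.min(d2)
  list(params = lib@params[vIdx[j], ], distance = sqrt(d2[j]),
       index = vIdx[j])
}

#' Write / read a simulation library as plain-text files
#'
#' A library directory contains `params.csv`, `features_raw.csv`,
#' `features_transformed.csv`, `valid.csv`, `standardizer.json` and
#' `provenance.json`.
#'
#' @param lib a [SimulationLibrary-class].
#' @param dir directory path.
#' @return `writeLibrary` returns `dir` invisibly; `readLibrary` returns the
#'   reconstructed [SimulationLibrary-class].
#' @export
writeLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(lib@params), file.path(dir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(lib@rawFeatures),
                   file.path(dir, "features_raw.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(lib@features),
                   file.path(dir, "features_transformed.csv"), row.names = FALSE)
  utils::write.csv(data.frame(valid = lib@valid), file.path(dir, "valid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(mean = as.list(lib@standardizer@mean),
                            sd = as.list(lib@standardizer@sd)),
                       file.path(dir, "standardizer.json"), auto_unbox = TRUE,
                       digits = NA)
  prov <- lib@provenance
  prov$protocol <- NULL # nested lists stored flat
  prov$constants <- NULL
  jsonlite::write_json(c(prov, lib@provenance$protocol,
                         lib@provenance$constants),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(dir) {
  need <- c("params.csv", "features_raw.csv", "features_transformed.csv",
            "valid.csv", "standardizer.json")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("library directory is missing: ",
                         paste(miss, collapse = ", "))
  params <- as.matrix(utils::read.csv(file.path(dir, "params.csv")))
  raw <- as.matrix(utils::read.csv(file.path(dir, "features_raw.csv")))
  trans <- as.matrix(utils::read.csv(file.path(dir, "features_transformed.csv")))
  valid <- utils::read.csv(file.path(dir, "valid.csv"))$valid
  sj <- jsonlite::read_json(file.path(dir, "standardizer.json"),
                            simplifyVector = TRUE)
  prov <- if (file.exists(file.path(dir, "provenance.json"))) {
    jsonlite::read_json(file.path(dir, "provenance.json"),
                        simplifyVector = TRUE)
  } else list()
  new("SimulationLibrary", params = params, rawFeatures = raw,
      features = trans, valid = as.logical(valid),
      standardizer = new("FeatureStandardizer", mean = unlist(sj$mean),
                         sd = unlist(sj$sd)),
      provenance = as.list(prov))
}
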