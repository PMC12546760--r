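#' @import methods
NULL

#' Names of the 13 inferable biophysical parameters
#'
#' Canonical order used everywhere a parameter vector or matrix appears:
#' membrane capacitance density `C` (uF/cm^2), input resistance `R_input`
#' (MOhm), effective charging time constant `tau` (ms), six maximal
#' conductance densities (mS/cm^2) for the fast inactivating Na+ current
#' (`gbar_Nat`), the minimal-model Na+ current (`gbar_Na`), the delayed
#' rectifier K+ current (`gbar_Kd`), the muscarinic K+ current (`gbar_M`),
#' the fast non-inactivating K+ current (`gbar_Kv31`) and the high-threshold
#' Ca2+ current (`gbar_L`), the leak reversal `E_leak` (mV), the muscarinic
#' time-constant scale `tau_max` (ms), the spike-threshold adjustment `V_T`
#' (mV) and the dimensionless steady-state rate scale `r_SS`.
#'
#' @return Character vector of length 13.
#' @export
hhParameterNames <- function() {
  c("C", "R_input", "tau", "gbar_Nat", "gbar_Na", "gbar_Kd", "gbar_M",
    "gbar_Kv31", "gbar_L", "E_leak", "tau_max", "V_T", "r_SS")
}

#' Names of the 23 electrophysiological summary features
#'
#' Canonical order of the feature vector extracted from a voltage trace:
#' first-spike threshold/amplitude/width/afterhyperpolarization, the same
#' four quantities for the third spike, five spike counts (whole stimulus
#' window and four sub-windows), two amplitude-adaptation ratios, the
#' amplitude coefficient of variation, interspike-interval adaptation and
#' coefficient of variation, latency to the first spike, and four membrane
#' potential moments (resting mean, stimulus-window mean, SD and skewness).
#'
#' @return Character vector of length 23.
#' @export
ephysFeatureNames <- function() {
  c("ap_threshold", "ap_amplitude", "ap_width", "ahp",
    "ap3_threshold", "ap3_amplitude", "ap3_width", "ahp3",
    "ap_count", "ap_count_1st_8th", "ap_count_1st_quarter",
    "ap_count_1st_half", "ap_count_2nd_half",
    "ap_amp_adapt", "ap_avg_amp_adapt", "ap_cv",
    "isi_adapt", "isi_cv", "latency",
    "rest_vm_mean", "vm_mean", "vm_sd", "vm_skewness")
}

# features whose transformed value is the natural log of the raw value;
# ap_avg_amp_adapt instead receives the logistic sigmoid
.logFeatures <- function() {
  c("ap_count", "ap_count_1st_8th", "ap_count_1st_quarter",
    "ap_count_1st_half", "ap_count_2nd_half", "ap_amp_adapt", "ap_cv",
    "isi_adapt", "isi_cv", "latency")
}

#' Membrane voltage trace from one current-clamp sweep
#'
#' Holds the membrane potential sampled on a uniform time grid together with
#' the stimulus protocol and, when simulated, the generating parameters.
#'
#' @slot vm numeric vector of membrane potential samples (mV), length
#'   `t_total/dt + 1`.
#' @slot dt sampling interval (ms).
#' @slot tOn,tOff stimulus onset/offset (ms).
#' @slot iInj injected current amplitude (pA).
#' @slot params named numeric vector of generating parameters (may be empty
#'   for experimental traces).
#' @slot diverged logical flag set when the integration produced non-finite
#'   values; the remaining samples are `NA`.
#' @export
setClass("VoltageTrace",
  representation(vm = "numeric", dt = "numeric", tOn = "numeric",
                 tOff = "numeric", iInj = "numeric", params = "numeric",
                 diverged = "logical"),
  prototype(params = numeric(0), diverged = FALSE))

setValidity("VoltageTrace", function(object) {
  if (length(object@dt) != 1 || object@dt <= 0) return("dt must be a single positive number")
  if (object@tOn < 0 || object@tOff < object@tOn) return("need 0 <= tOn <= tOff")
  TRUE
})

#' Per-feature location/scale used for z-scoring
#'
#' Means and standard deviations of the transformed features, fitted on the
#' valid rows of a simulation campaign and reused to place simulations and
#' observations in the same standardized space.
#'
#' @slot mean,sd named numeric vectors, one entry per feature.
#' @export
setClass("FeatureStandardizer",
  representation(mean = "numeric", sd = "numeric"))

setValidity("FeatureStandardizer", function(object) {
  if (length(object@mean) != length(object@sd)) return("mean/sd length mismatch")
  if (any(!is.finite(object@sd)) || any(object@sd <= 0)) return("all SDs must be positive and finite")
  TRUE
})

#' Library of prior simulations
#'
#' The product of a simulation campaign: sampled parameters, raw and
#' transformed feature matrices, the validity mask (a row is valid iff all 23
#' transformed features are defined), and the standardizer fitted on the
#' valid rows.
#'
#' @slot params n x 13 parameter matrix.
#' @slot rawFeatures,features n x 23 raw and transformed feature matrices.
#' @slot valid logical vector of length n.
#' @slot standardizer a [FeatureStandardizer-class].
#' @slot provenance list recording seed, dt, constants and protocol.
#' @export
setClass("SimulationLibrary",
  representation(params = "matrix", rawFeatures = "matrix",
                 features = "matrix", valid = "logical",
                 standardizer = "FeatureStandardizer", provenance = "list"))

setValidity("SimulationLibrary", function(object) {
  n <- nrow(object@params)
  if (ncol(object@params) != 13) return("params must have 13 columns")
  if (nrow(object@features) != n || nrow(object@rawFeatures) != n ||
      length(object@valid) != n) return("row counts disagree")
  if (ncol(object@features) != 23) return("features must have 23 columns")
  ok <- stats::complete.cases(object@features) &
    apply(object@features, 1, function(z) all(is.finite(z)))
  if (!identical(unname(ok), unname(object@valid)))
    return("valid mask must flag exactly the rows with 23 finite transformed features")
  TRUE
})

#' Training schedule for neural posterior estimation
#'
#' @slot mode one of `"standard"`, `"best_euclidean"`, `"noise_features"`
#'   (the noise-robust schedule), `"noise_features_params"`,
#'   `"data_augmentation"`.
#' @slot noiseSdFeatures,noiseSdParams isotropic Gaussian noise SDs in
#'   z-score units applied to features / parameters of the selected
#'   simulations.
#' @slot k number of nearest valid simulations selected per observation in
#'   the subset modes (`NA` = automatic).
#' @slot seed integer seed for the noise draws.
#' @export
setClass("TrainingSchedule",
  representation(mode = "character", noiseSdFeatures = "numeric",
                 noiseSdParams = "numeric", k = "numeric", seed = "numeric"))

setValidity("TrainingSchedule", function(object) {
  modes <- c("standard", "best_euclidean", "noise_features",
             "noise_features_params", "data_augmentation")
  if (!(object@mode %in% modes)) return("unknown schedule mode")
  if (object@noiseSdFeatures < 0 || object@noiseSdParams < 0)
    return("noise SDs must be >= 0")
  if (!is.na(object@k) && object@k < 1) return("k must be >= 1")
  TRUE
})

#' Trained conditional posterior density estimator
#'
#' A masked autoregressive normalizing flow over the 13 z-scored model
#' parameters conditioned on the 23 z-scored electrophysiological features,
#' together with the standardizers needed to map to and from natural units
#' and the prior box used for rejection at sampling time.
#'
#' @slot flow list holding the flow architecture and weights.
#' @slot thetaMean,thetaSd parameter standardizer (natural units).
#' @slot standardizer the feature [FeatureStandardizer-class].
#' @slot priorBox 13 x 2 matrix of prior bounds.
#' @slot schedule the [TrainingSchedule-class] used for training.
#' @slot history list with training diagnostics (loss curves, epochs).
#' @export
setClass("PosteriorModel",
  representation(flow = "list", thetaMean = "numeric", thetaSd = "numeric",
                 standardizer = "FeatureStandardizer", priorBox = "matrix",
                 schedule = "TrainingSchedule", history = "list"))

#' Posterior-predictive evaluation report
#'
#' Percentage of simulation fails (at least one undefined feature) and the
#' mean +/- SD Euclidean feature distance to the observations, separately for
#' simulations of the MAP parameters and of random posterior samples.
#'
#' @slot mapFailPct,postFailPct fail percentages in `[0, 100]`.
#' @slot mapDistMean,mapDistSd,postDistMean,postDistSd distance statistics
#'   over the non-failed simulations.
#' @slot perObservation data.frame with one row per observation.
#' @export
setClass("FitReport",
  representation(mapFailPct = "numeric", mapDistMean = "numeric",
                 mapDistSd = "numeric", postFailPct = "numeric",
                 postDistMean = "numeric", postDistSd = "numeric",
                 perObservation = "data.frame"))

#' Sparse reduced-rank regression model
#'
#' Encoder `W` (genes x rank) and decoder `V` (targets x rank, orthonormal
#' columns) so that predictions are `intercept + (X - xCenter) W V'`. Genes
#' with a nonzero encoder row norm form the selected gene set.
#'
#' @slot W,V encoder and decoder matrices.
#' @slot intercept per-target intercepts.
#' @slot xCenter per-gene centers used at fit time.
#' @slot rank,lambda,alpha hyperparameters.
#' @slot meta list with convergence diagnostics and options.
#' @export
setClass("SRRRModel",
  representation(W = "matrix", V = "matrix", intercept = "numeric",
                 xCenter = "numeric", rank = "numeric", lambda = "numeric",
                 alpha = "numeric", meta = "list"))

setValidity("SRRRModel", function(object) {
  if (object@rank < 1) return("rank must be >= 1")
  if (ncol(object@W) != object@rank || ncol(object@V) != object@rank)
    return("W/V column count must equal rank")
  TRUE
})

#' Synthetic Patch-seq style cohort
#'
#' Ground-truth cells with known biophysical parameters, feature-space
#' observations (optionally carrying a systematic shift emulating model-data
#' mismatch), and a linked overdispersed expression matrix whose informative
#' genes carry a sparse linear map to the parameters.
#'
#' @slot theta cells x 13 true parameter matrix.
#' @slot labels factor of family labels.
#' @slot observations cells x 23 z-scored feature observations.
#' @slot shift the systematic feature-space shift (z-units) applied.
#' @slot counts cells x genes count matrix.
#' @slot loadings genes x 13 sparse loading matrix (the planted gene map).
#' @slot meta list of generator settings.
#' @export
setClass("SyntheticCohort",
  representation(theta = "matrix", labels = "factor",
                 observations = "matrix", shift = "numeric",
                 counts = "matrix", loadings = "matrix", meta = "list"))

setMethod("show", "VoltageTrace", function(object) {
  cat(sprintf("VoltageTrace: %d samples, dt = %g ms (%.0f ms total), %g pA on [%g, %g) ms%s\n",
              length(object@vm), object@dt, (length(object@vm) - 1) * object@dt,
              object@iInj, object@tOn, object@tOff,
              if (object@diverged) " [diverged]" else ""))
})

setMethod("show", "SimulationLibrary", function(object) {
  cat(sprintf("SimulationLibrary: %d simulations, %.1f%% valid (seed %s)\n",
              nrow(object@params), 100 * mean(object@valid),
              as.character(object@provenance$seed %||% NA)))
})

setMethod("show", "PosteriorModel", function(object) {
  cat(sprintf("PosteriorModel: %d-block flow, schedule '%s', trained on %d pairs\n",
              length(object@flow$blocks), object@schedule@mode,
              object@history$nPairs %||% NA_integer_))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport (n = %d observations)\n", nrow(object@perObservation)))
  cat(sprintf("  MAP:       fails %5.2f%%, distance %.2f +/- %.2f\n",
              object@mapFailPct, object@mapDistMean, object@mapDistSd))
  cat(sprintf("  posterior: fails %5.2f%%, distance %.2f +/- %.2f\n",
              object@postFailPct, object@postDistMean, object@postDistSd))
})

setMethod("show", "SRRRModel", function(object) {
  cat(sprintf("SRRRModel: rank %d, lambda = %g, alpha = %g, %d genes selected of %d\n",
              object@rank, object@lambda, object@alpha,
              length(selectedGenes(object)), nrow(object@W)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d cells, %d families, %d genes, |shift| = %.3g\n",
              nrow(object@theta), nlevels(object@labels), ncol(object@counts),
              sqrt(sum(object@shift^2))))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
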