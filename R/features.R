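#' Detect action potentials in a voltage trace
#'
#' A spike threshold is the sample where the first time-derivative of the
#' voltage first reaches `dvdtThreshold` (upward crossing); the spike peak is
#' the first local voltage maximum after the crossing. The
#' afterhyperpolarization depth is measured from the threshold voltage down
#' to the voltage minimum between the peak and the next spike's threshold
#' (or the stimulus end for the last spike).
#'
#' @param trace a [VoltageTrace-class].
#' @param dvdtThreshold derivative criterion (mV/ms), default 20.
#' @return data.frame with one row per spike: `threshold_time`,
#'   `threshold_vm`, `peak_time`, `peak_vm`, `amplitude`,
#'   `width_half_height`, `ahp_depth` (AHP may be `NA`). Events that never
#'   repolarize through their half height are not counted as spikes. Zero
#'   rows when no spike is detected.
#' @export
detectSpikes <- function(trace, dvdtThreshold = 20) {
  vm <- trace@vm
  dt <- trace@dt
  empty <- data.frame(threshold_time = numeric(0), threshold_vm = numeric(0),
                      peak_time = numeric(0), peak_vm = numeric(0),
                      amplitude = numeric(0), width_half_height = numeric(0),
                      ahp_depth = numeric(0))
  n <- length(vm)
  if (n < 3 || anyNA(vm)) return(empty)
  dvdt <- diff(vm) / dt
  above <- dvdt >= dvdtThreshold
  cross <- which(above[-1] & !above[-length(above)]) + 1L
  if (!length(cross)) return(empty)

  thrIdx <- integer(0)
  peakIdx <- integer(0)
  for (i in cross) {
    j <- i
    while (j < n - 1 && vm[j + 1] > vm[j]) j <- j + 1L
    if (j >= n - 1) next
    if (vm[j] <= vm[i]) next
    if (length(peakIdx) && j == peakIdx[length(peakIdx)]) {
      # several criterion crossings on one upstroke (e.g. the passive
      # charging transient at stimulus onset followed by the true spike
      # upstroke): the threshold is the last crossing before the peak
      thrIdx[length(thrIdx)] <- i
    } else if (!length(peakIdx) || j > peakIdx[length(peakIdx)]) {
      thrIdx <- c(thrIdx, i)
      peakIdx <- c(peakIdx, j)
    }
  }
  if (!length(thrIdx)) return(empty)

  # adaptive threshold refinement: when the upstroke's peak dV/dt is much
  # larger than the fixed criterion (e.g. an AP riding the fast charging
  # transient at stimulus onset), the threshold is taken at the last upward
  # crossing of 5% of the segment's maximal dV/dt instead, so it stays on
  # the spike foot rather than at the stimulus step
  for (s in seq_along(thrIdx)) {
    segStart <- if (s > 1) peakIdx[s - 1] + 1L else 1L
    seg <- segStart:(peakIdx[s] - 1L)
    cut <- max(dvdtThreshold, 0.05 * max(dvdt[seg]))
    if (cut > dvdtThreshold) {
      # walk back from the steepest point of the upstroke to the crossing
      k2 <- seg[which.max(dvdt[seg])]
      while (k2 > segStart && dvdt[k2 - 1L] >= cut) k2 <- k2 - 1L
      if (k2 > thrIdx[s] && k2 < peakIdx[s]) thrIdx[s] <- k2
    }
  }

  offIdx <- min(n, as.integer(round(trace@tOff / dt)) + 1L)
  .spikeGeometry(vm, dt, thrIdx, peakIdx, offIdx)
}

# width/AHP geometry for an event set; an event that never repolarizes
# through its half height (a rebound to a plateau, or a clipped ride on a
# depolarized envelope) is not a spike and is dropped, widening the windows
# of its neighbours, until the set is stable
.spikeGeometry <- function(vm, dt, thrIdx, peakIdx, offIdx) {
  n <- length(vm)
  k <- length(thrIdx)
  thr_vm <- vm[thrIdx]
  pk_vm <- vm[peakIdx]
  amp <- pk_vm - thr_vm
  width <- ahp <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    half <- thr_vm[s] + amp[s] / 2
    iu <- peakIdx[s]
    while (iu > thrIdx[s] && vm[iu - 1] >= half) iu <- iu - 1L
    tUp <- if (vm[iu - 1] < half && vm[iu] >= half) {
      ((iu - 2) + (half - vm[iu - 1]) / (vm[iu] - vm[iu - 1])) * dt
    } else NA_real_
    lim <- if (s < k) thrIdx[s + 1] else n
    idn <- peakIdx[s]
    while (idn < lim && vm[idn + 1] > half) idn <- idn + 1L
    tDown <- if (idn < lim && vm[idn] > half && vm[idn + 1] <= half) {
      ((idn - 1) + (vm[idn] - half) / (vm[idn] - vm[idn + 1])) * dt
    } else NA_real_
    width[s] <- tDown - tUp
    searchEnd <- if (s < k) thrIdx[s + 1] else offIdx
    if (searchEnd > peakIdx[s]) {
      ahp[s] <- thr_vm[s] - min(vm[peakIdx[s]:searchEnd])
    }
  }
  out <- data.frame(threshold_time = (thrIdx - 1) * dt, threshold_vm = thr_vm,
                    peak_time = (peakIdx - 1) * dt, peak_vm = pk_vm,
                    amplitude = amp, width_half_height = width,
                    ahp_depth = ahp)
  if (anyNA(out$width_half_height)) {
    keep <- !is.na(out$width_half_height)
    if (!any(keep)) {
      return(out[0, , drop = FALSE])
    }
    return(.spikeGeometry(vm, dt, thrIdx[keep], peakIdx[keep], offIdx))
  }
  out
}

.skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NaN)
  mean((x - m)^3) / s2^1.5
}

#' Extract the 23 raw electrophysiological features
#'
#' Computes the canonical feature vector (see [ephysFeatureNames()]) from a
#' trace recorded with the 800 ms step protocol. Spike-dependent features are
#' undefined (`NA`) when their prerequisite spikes are absent: first-spike
#' shape features need at least one spike inside the stimulus window,
#' amplitude adaptation and the amplitude CV need two, and all third-spike
#' features plus the interspike-interval statistics need three. Window
#' membership and latency use spike threshold times; latency is measured from
#' stimulus onset to the first threshold.
#'
#' @param trace a [VoltageTrace-class].
#' @param dvdtThreshold spike-detection criterion (mV/ms).
#' @return Named numeric vector of length 23 with `NA` for undefined entries.
#' @export
extractFeatures <- function(trace, dvdtThreshold = 20) {
  fn <- ephysFeatureNames()
  out <- stats::setNames(rep(NA_real_, 23), fn)
  vm <- trace@vm
  dt <- trace@dt
  tOn <- trace@tOn
  tOff <- trace@tOff
  if (trace@diverged || anyNA(vm)) return(out)
  tt <- (seq_along(vm) - 1) * dt

  rest <- vm[tt < tOn]
  stim <- vm[tt >= tOn & tt < tOff]
  if (length(rest) < 2 || length(stim) < 2) stop("trace grid does not cover the protocol windows")
  out["rest_vm_mean"] <- mean(rest)
  out["vm_mean"] <- mean(stim)
  out["vm_sd"] <- stats::sd(stim)
  out["vm_skewness"] <- .skewness(stim)

  sp <- detectSpikes(trace, dvdtThreshold)
  sp <- sp[sp$threshold_time >= tOn & sp$threshold_time < tOff, , drop = FALSE]
  nSp <- nrow(sp)
  tth <- sp$threshold_time
  dur <- tOff - tOn
  out["ap_count"] <- nSp
  out["ap_count_1st_8th"] <- sum(tth < tOn + dur / 8)
  out["ap_count_1st_quarter"] <- sum(tth < tOn + dur / 4)
  out["ap_count_1st_half"] <- sum(tth < tOn + dur / 2)
  out["ap_count_2nd_half"] <- sum(tth >= tOn + dur / 2)

  if (nSp >= 1) {
    out["ap_threshold"] <- sp$threshold_vm[1]
    out["ap_amplitude"] <- sp$amplitude[1]
    out["ap_width"] <- sp$width_half_height[1]
    out["ahp"] <- sp$ahp_depth[1]
    out["latency"] <- tth[1] - tOn
  }
  if (nSp >= 2) {
    out["ap_amp_adapt"] <- sp$amplitude[1] / sp$amplitude[2]
    ratios <- sp$amplitude[-nSp] / sp$amplitude[-1]
    out["ap_avg_amp_adapt"] <- mean(ratios)
    out["ap_cv"] <- stats::sd(sp$amplitude) / mean(sp$amplitude)
  }
  if (nSp >= 3) {
    out["ap3_threshold"] <- sp$threshold_vm[3]
    out["ap3_amplitude"] <- sp$amplitude[3]
    out["ap3_width"] <- sp$width_half_height[3]
    out["ahp3"] <- sp$ahp_depth[3]
    isi <- diff(tth)
    out["isi_adapt"] <- isi[2] / isi[1]
    out["isi_cv"] <- stats::sd(isi) / mean(isi)
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Transform raw features toward Gaussianity
#'
#' Applies the natural log to the five spike counts, both
#' adaptation-ratio features except the average amplitude adaptation, the
#' amplitude and interspike-interval CVs and the latency; the average
#' amplitude adaptation receives the logistic sigmoid `1/(1 + exp(-x))`.
#' Non-positive arguments to the log are undefined (`NA`) -- in particular a
#' zero spike count in any window invalidates the vector.
#'
#' @param fv raw feature vector or matrix (rows = traces) with canonical
#'   names.
#' @return Transformed vector/matrix of the same shape.
#' @export
transformFeatures <- function(fv) {
  one <- function(x) {
    x <- x[ephysFeatureNames()]
    lg <- .logFeatures()
    x[lg] <- ifelse(!is.na(x[lg]) & x[lg] > 0, log(x[lg]), NA_real_)
    x["ap_avg_amp_adapt"] <- 1 / (1 + exp(-x["ap_avg_amp_adapt"]))
    x
  }
  if (is.matrix(fv)) t(apply(fv, 1, one)) else one(fv)
}

#' Fit a feature standardizer on the valid rows
#'
#' @param x matrix of transformed features (rows = simulations).
#' @param valid logical mask of rows to use; defaults to rows with all
#'   entries defined and finite.
#' @return A [FeatureStandardizer-class].
#' @export
fitStandardizer <- function(x, valid = NULL) {
  if (is.null(valid)) valid <- apply(x, 1, function(z) all(is.finite(z)))
  if (sum(valid) < 2) stop("need at least 2 valid rows to fit a standardizer")
  xv <- x[valid, , drop = FALSE]
  m <- colMeans(xv)
  s <- apply(xv, 2, stats::sd)
  if (any(s == 0)) stop("constant feature column(s): ",
                        paste(colnames(x)[s == 0], collapse = ", "))
  new("FeatureStandardizer", mean = m, sd = s)
}

#' Standardize / invert feature matrices
#'
#' @param x feature vector or matrix (transformed scale).
#' @param std a [FeatureStandardizer-class].
#' @return z-scored object of the same shape.
#' @export
standardizeFeatures <- function(x, std) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, std@mean, "-"), 2, std@sd, "/")
  } else (x - std@mean) / std@sd
}

#' @rdname standardizeFeatures
#' @export
unstandardizeFeatures <- function(x, std) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, std@sd, "*"), 2, std@mean, "+")
  } else x * std@sd + std@mean
}

#' Euclidean distance in standardized feature space
#'
#' @param z1,z2 fully defined z-scored feature vectors on the same
#'   standardizer.
#' @return Nonnegative scalar.
#' @export
featureDistance <- function(z1, z2) {
  if (anyNA(z1) || anyNA(z2)) stop("feature vectors contain undefined entries")
  sqrt(sum((z1 - z2)^2))
}
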