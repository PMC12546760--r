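# Shared fixtures, built in code. Heavy artifacts (the reference campaign
# and the trained toy flow) are memoised in this environment so the test
# files that need them share one computation.

.fixtures <- new.env(parent = emptyenv())

# passive parameter template; individual tests override fields
passiveParams <- function(C = 1, R_input = 100, tau = 20, E_leak = -70,
                          V_T = -60, tau_max = 1000, r_SS = 1) {
  c(C = C, R_input = R_input, tau = tau, gbar_Nat = 0, gbar_Na = 0,
    gbar_Kd = 0, gbar_M = 0, gbar_Kv31 = 0, gbar_L = 0, E_leak = E_leak,
    tau_max = tau_max, V_T = V_T, r_SS = r_SS)
}

# a robustly spiking reference cell used by several tests
spikingParams <- function() {
  p <- passiveParams(tau = 10)
  p["gbar_Nat"] <- 150
  p["gbar_Kd"] <- 20
  p
}

# piecewise-linear trace with template spikes whose threshold, peak,
# amplitude and width are hand-computable: for each requested peak time the
# voltage ramps -70 -> -60 over 1 ms (10 mV/ms, below the 20 mV/ms
# criterion), -60 -> +20 over 2 ms (40 mV/ms), then +20 -> -70 over 5 ms
# (18 mV/ms, so the time-reversed trace never reaches the criterion).
# Threshold lands at peak - 2 ms with value -60 mV, amplitude 80 mV, and the
# half-height width is 1 + 40/18 ms.
templateTrace <- function(peaks = c(150, 250, 350), dt = 0.1, tTotal = 800,
                          baseline = -70, invert = FALSE) {
  tt <- seq(0, tTotal, by = dt)
  vm <- rep(baseline, length(tt))
  for (pk in peaks) {
    ramp <- tt >= pk - 3 & tt < pk - 2
    vm[ramp] <- -70 + 10 * (tt[ramp] - (pk - 3))
    up <- tt >= pk - 2 & tt <= pk
    vm[up] <- -60 + 40 * (tt[up] - (pk - 2))
    down <- tt > pk & tt <= pk + 5
    vm[down] <- 20 - 18 * (tt[down] - pk)
  }
  if (invert) vm <- baseline - (vm - baseline)
  new("VoltageTrace", vm = vm, dt = dt, tOn = 100, tOff = 700, iInj = 300,
      diverged = FALSE)
}

templateSpikeWidth <- function() 1 + 40 / 18

constantTrace <- function(level = -70, dt = 0.1, tTotal = 800) {
  new("VoltageTrace", vm = rep(level, tTotal / dt + 1), dt = dt, tOn = 100,
      tOff = 700, iInj = 300, diverged = FALSE)
}

# reference campaign shared across test files (acceptance criteria 1/2/6 and
# the heavier property tests); built once per test run
referenceLibrary <- function(n = 20000, seed = 101) {
  key <- sprintf("lib_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- runCampaign(n, seed = seed, batchSize = 5000)
  }
  .fixtures[[key]]
}

# linear-Gaussian conjugate toy: x = theta + eps, eps ~ N(0, 0.1^2),
# theta ~ U(-1, 1); the analytic posterior at x0 is N(x0, 0.1^2) truncated
# to [-1, 1]
toyPairs <- function(n = 50000, seed = 11, noiseSd = 0.1) {
  set.seed(seed)
  theta <- matrix(runif(n, -1, 1), ncol = 1)
  x <- theta + matrix(rnorm(n, sd = noiseSd), ncol = 1)
  list(theta = theta, x = x, noiseSd = noiseSd)
}

toyModel <- function(n = 50000, seed = 11) {
  key <- sprintf("toy_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    pairs <- toyPairs(n, seed)
    .fixtures[[key]] <- suppressWarnings(trainNPE(
      pairs$theta, pairs$x, priorBox = matrix(c(-1, 1), 1, 2,
                                              dimnames = list("theta", c("lower", "upper"))),
      flowConfig = list(nBlocks = 3, hidden = 32, maxEpochs = 60,
                        patience = 10),
      seed = seed))
  }
  .fixtures[[key]]
}

# truncated-normal moments for the toy oracle
truncNormMoments <- function(mu, sd, lo = -1, hi = 1) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}
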