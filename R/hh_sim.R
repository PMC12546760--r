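#' @useDynLib neurosbi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default uniform prior box over the 13 model parameters
#'
#' Biologically plausible ranges for the inferable parameters: capacitance
#' density 0.1-15 uF/cm^2, input resistance 20-1000 MOhm, charging time
#' constant 0.1-70 ms, conductance densities 0-250 (fast Na+), 0-100 (Na+),
#' 0-30 (delayed rectifier K+), 0-3 (muscarinic K+), 0-250 (Kv3.1), 0-3
#' (high-threshold Ca2+) mS/cm^2, leak reversal -130 to -50 mV, muscarinic
#' time-constant scale 50-4000 ms, threshold adjustment -90 to -35 mV, and
#' steady-state rate scale 0.1-3.
#'
#' @return 13 x 2 matrix with rownames [hhParameterNames()] and columns
#'   `lower`, `upper`.
#' @export
#' @examples
#' defaultPriorBox()["gbar_Kd", ]
defaultPriorBox <- function() {
  box <- rbind(
    C         = c(0.1, 15),
    R_input   = c(20, 1000),
    tau       = c(0.1, 70),
    gbar_Nat  = c(0, 250),
    gbar_Na   = c(0, 100),
    gbar_Kd   = c(0, 30),
    gbar_M    = c(0, 3),
    gbar_Kv31 = c(0, 250),
    gbar_L    = c(0, 3),
    E_leak    = c(-130, -50),
    tau_max   = c(50, 4000),
    V_T       = c(-90, -35),
    r_SS      = c(0.1, 3))
  colnames(box) <- c("lower", "upper")
  box
}

.checkBox <- function(box) {
  stopifnot(is.matrix(box), nrow(box) == 13, ncol(box) == 2)
  if (any(box[, 1] >= box[, 2])) stop("prior box must have lower < upper for every parameter")
  if (is.null(rownames(box))) rownames(box) <- hhParameterNames()
  box
}

#' Physical and experimental constants of the model
#'
#' @param e_na,e_k,e_ca reversal potentials (mV). Sodium defaults to +69 mV
#'   (motor cortex recordings); potassium and calcium to -90 and +120 mV.
#' @param q10 temperature coefficient for gating kinetics.
#' @param t_exp experiment temperature (deg C).
#' @param t_ref_minimal,t_ref_peri reference temperatures at which the
#'   minimal-model and perisomatic channel kinetics were characterized.
#' @param i_inj injected current amplitude (pA).
#' @param noise_mean,noise_sd per-step Gaussian current noise (pA).
#' @return Named list of constants.
#' @export
physConstants <- function(e_na = 69, e_k = -90, e_ca = 120, q10 = 2.3,
                          t_exp = 25, t_ref_minimal = 36, t_ref_peri = 21,
                          i_inj = 300, noise_mean = 10, noise_sd = 1) {
  stopifnot(q10 > 0, noise_sd >= 0)
  list(e_na = e_na, e_k = e_k, e_ca = e_ca, q10 = q10, t_exp = t_exp,
       t_ref_minimal = t_ref_minimal, t_ref_peri = t_ref_peri, i_inj = i_inj,
       noise_mean = noise_mean, noise_sd = noise_sd)
}

#' Step-current stimulation protocol
#'
#' @param t_total sweep duration (ms).
#' @param t_on,t_off current onset/offset (ms).
#' @param dt integration and sampling step (ms). The default 0.05 ms is part
#'   of the model definition because the per-step current noise statistics
#'   are tied to the step size.
#' @param noise logical; draw per-step Gaussian current noise.
#' @param seed integer seed used when this protocol's noise is drawn inside
#'   [simulateHH()] (ignored when `noise = FALSE`; `NA` leaves the RNG state
#'   untouched so the caller controls it).
#' @return Named list describing the protocol.
#' @export
stimProtocol <- function(t_total = 800, t_on = 100, t_off = 700, dt = 0.05,
                         noise = TRUE, seed = NA_integer_) {
  stopifnot(dt > 0, t_on >= 0, t_on < t_off, t_off <= t_total)
  list(t_total = t_total, t_on = t_on, t_off = t_off, dt = dt, noise = noise,
       seed = seed)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based derivation so that campaigns are invariant to
#' batching and resumable: the i-th simulation always receives the same seed.
#'
#' @param master integer master seed.
#' @param i nonnegative integer counter.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(master, i) {
  m <- 2147483647
  x <- (as.double(master) %% m) * 48271 %% m
  x <- (x + as.double(i) * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}

.asParamVector <- function(params) {
  pn <- hhParameterNames()
  if (is.matrix(params)) params <- params[1, ]
  if (!is.null(names(params))) {
    miss <- setdiff(pn, names(params))
    if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
    params <- params[pn]
  } else if (length(params) == 13) {
    names(params) <- pn
  } else stop("params must be a named vector or have length 13")
  if (any(!is.finite(params))) stop("parameters must be finite")
  if (params["C"] <= 0 || params["R_input"] <= 0 || params["tau"] <= 0 ||
      params["r_SS"] <= 0) stop("C, R_input, tau, r_SS must be positive")
  if (any(params[c("gbar_Nat", "gbar_Na", "gbar_Kd", "gbar_M", "gbar_Kv31",
                   "gbar_L")] < 0)) stop("conductance densities must be >= 0")
  params
}

#' Sample parameter sets from the uniform prior
#'
#' Each of the 13 parameters is drawn independently and uniformly from its
#' prior range.
#'
#' @param n number of draws (>= 1).
#' @param box prior box as from [defaultPriorBox()].
#' @param seed optional integer seed for reproducibility.
#' @return n x 13 matrix with column names [hhParameterNames()].
#' @export
#' @examples
#' th <- samplePrior(5, seed = 1)
samplePrior <- function(n, box = defaultPriorBox(), seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive count")
  box <- .checkBox(box)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(n * 13), nrow = n)
  out <- sweep(sweep(u, 2, box[, 2] - box[, 1], "*"), 2, box[, 1], "+")
  colnames(out) <- rownames(box)
  out
}

#' Voltage-dependent gate rate constants
#'
#' Opening and closing rates (1/ms) of the nine gating variables at a given
#' membrane voltage, at the kinetics source temperatures and before any
#' Q10 or `r_SS` scaling. Gates `p` and `v` are defined through
#' steady-state/time-constant pairs and are reported as the equivalent
#' `alpha = inf/tau`, `beta = (1 - inf)/tau`.
#'
#' @param v membrane voltage (mV).
#' @param v_t spike-threshold adjustment (mV) entering the minimal-model
#'   Na+/K+ kinetics.
#' @param tau_max muscarinic time-constant scale (ms).
#' @return 9 x 2 matrix (`alpha`, `beta`) with gate rownames.
#' @export
gateRates <- function(v, v_t = -60, tau_max = 1000) {
  .hh_rates_cpp(v, v_t, tau_max)
}

#' Resting-state initialization
#'
#' Returns the initial condition used by the integrator: the membrane at the
#' leak reversal and every gate at its voltage-dependent steady state
#' `alpha/(alpha + beta)` evaluated there.
#'
#' @param params parameter vector (see [hhParameterNames()]).
#' @param constants constants from [physConstants()] (unused by the steady
#'   state itself; kept for interface symmetry).
#' @return List with `v0` (mV) and `gates` (named vector of 9 open fractions).
#' @export
steadyStateInit <- function(params, constants = physConstants()) {
  params <- .asParamVector(params)
  v0 <- unname(params["E_leak"])
  gates <- .hh_steady_gates_cpp(v0, params["V_T"], params["tau_max"])
  list(v0 = v0, gates = gates)
}

#' Simulate the conductance-based model
#'
#' Integrates the membrane equation `C dV/dt = sum_i g_i (E_i - V) + I_inj +
#' I_noise` together with nine gating ODEs `dx/dt = alpha (1 - x) - beta x`
#' using a simultaneous exponential-Euler scheme. Gate rates are scaled by
#' `Q10^((T_exp - T_ref)/10)` with channel-family specific reference
#' temperatures, and additionally by `r_SS` for the gates of the
#' minimal-model Na+ and delayed-rectifier K+ currents. Per-step Gaussian
#' current noise is drawn when the protocol enables it.
#'
#' Numerical blow-up does not raise an error: the trace is flagged as
#' diverged and the remaining samples are `NA`.
#'
#' @param params parameter vector or 1-row matrix (see [hhParameterNames()]).
#' @param protocol stimulation protocol from [stimProtocol()].
#' @param constants constants from [physConstants()].
#' @return A [VoltageTrace-class].
#' @export
#' @examples
#' th <- samplePrior(1, seed = 42)
#' tr <- simulateHH(th, stimProtocol(noise = FALSE))
simulateHH <- function(params, protocol = stimProtocol(),
                       constants = physConstants()) {
  params <- .asParamVector(params)
  if (isTRUE(protocol$noise) && !is.na(protocol$seed)) set.seed(protocol$seed)
  res <- .hh_integrate_cpp(params, protocol$dt, protocol$t_total,
                           protocol$t_on, protocol$t_off, constants$i_inj,
                           isTRUE(protocol$noise), constants$noise_mean,
                           constants$noise_sd, constants$e_na, constants$e_k,
                           constants$e_ca, constants$q10, constants$t_exp,
                           constants$t_ref_minimal, constants$t_ref_peri)
  new("VoltageTrace", vm = res$vm, dt = protocol$dt, tOn = protocol$t_on,
      tOff = protocol$t_off, iInj = constants$i_inj, params = params,
      diverged = res$diverged)
}

# simulate returning also the gate range bookkeeping (used by property tests)
.simulateHHFull <- function(params, protocol = stimProtocol(),
                            constants = physConstants()) {
  params <- .asParamVector(params)
  if (isTRUE(protocol$noise) && !is.na(protocol$seed)) set.seed(protocol$seed)
  .hh_integrate_cpp(params, protocol$dt, protocol$t_total, protocol$t_on,
                    protocol$t_off, constants$i_inj, isTRUE(protocol$noise),
                    constants$noise_mean, constants$noise_sd, constants$e_na,
                    constants$e_k, constants$e_ca, constants$q10,
                    constants$t_exp, constants$t_ref_minimal,
                    constants$t_ref_peri)
}

#' Closed-form passive membrane response
#'
#' Analytic RC response used as an integration oracle when all active
#' conductances are zero and noise is off: a piecewise exponential with time
#' constant `tau` and steady-state deflection `R_input * I_inj`, by the
#' definition of `tau` as the time for the potential to rise by a fraction
#' `1 - 1/e` of the step amplitude.
#'
#' @param params parameter vector; only `R_input`, `tau`, `E_leak` are used.
#' @param protocol protocol from [stimProtocol()] (noise must be off).
#' @param constants constants from [physConstants()]; supplies `i_inj` (pA).
#' @return A [VoltageTrace-class] with the analytic solution on the grid.
#' @export
passiveClosedForm <- function(params, protocol = stimProtocol(noise = FALSE),
                              constants = physConstants()) {
  if (isTRUE(protocol$noise)) stop("passive closed form requires noise off")
  params <- .asParamVector(params)
  tt <- seq(0, protocol$t_total, by = protocol$dt)
  # MOhm * pA = 1e6 V/A * 1e-12 A = 1e-6 V = 1e-3 mV
  amp <- unname(params["R_input"] * constants$i_inj * 1e-3)
  tau <- unname(params["tau"])
  v <- rep(unname(params["E_leak"]), length(tt))
  on <- tt >= protocol$t_on & tt <= protocol$t_off
  v[on] <- v[on] + amp * (1 - exp(-(tt[on] - protocol$t_on) / tau))
  after <- tt > protocol$t_off
  vOff <- amp * (1 - exp(-(protocol$t_off - protocol$t_on) / tau))
  v[after] <- v[after] + vOff * exp(-(tt[after] - protocol$t_off) / tau)
  new("VoltageTrace", vm = v, dt = protocol$dt, tOn = protocol$t_on,
      tOff = protocol$t_off, iInj = constants$i_inj, params = params,
      diverged = FALSE)
}
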