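# Simulator: prior sampling, gate kinetics, passive oracle, integration
# properties.

test_that("prior sampling is uniform on the box, independent and reproducible", {
  box <- defaultPriorBox()
  th <- samplePrior(1e5, box, seed = 3)
  rng <- box[, 2] - box[, 1]
  # support: column extremes within 0.1% of the bounds
  expect_true(all(apply(th, 2, min) <= box[, 1] + 0.001 * rng))
  expect_true(all(apply(th, 2, max) >= box[, 2] - 0.001 * rng))
  expect_true(all(th >= matrix(box[, 1], nrow(th), 13, byrow = TRUE)))
  # means within 3 SE of the midpoints
  se <- rng / sqrt(12) / sqrt(nrow(th))
  expect_true(all(abs(colMeans(th) - (box[, 1] + rng / 2)) < 3 * se))
  expect_identical(samplePrior(3, box, seed = 7), samplePrior(3, box, seed = 7))
  expect_error(samplePrior(0), "positive")
})

test_that("gate rate formulas are pinned at reference voltages", {
  # hand-evaluated from the published kinetics at V_T = -60, tau_max = 1000
  vt <- -60
  for (v in c(-60, -40, 0)) {
    r <- gateRates(v, v_t = vt, tau_max = 1000)
    vs <- v - vt
    ef <- function(x, y) if (abs(x / y) < 1e-9) y else x / (exp(x / y) - 1)
    tp <- function(x, y) if (abs(x / y) < 1e-9) y else x / (1 - exp(-x / y))
    expect_equal(r["m", "alpha"], 0.32 * ef(13 - vs, 4), tolerance = 1e-12)
    expect_equal(r["m", "beta"], 0.28 * ef(vs - 40, 5), tolerance = 1e-12)
    expect_equal(r["h", "alpha"], 0.128 * exp(-(vs - 17) / 18), tolerance = 1e-12)
    expect_equal(r["h", "beta"], 4 / (1 + exp(-(vs - 40) / 5)), tolerance = 1e-12)
    expect_equal(r["n", "alpha"], 0.032 * ef(15 - vs, 5), tolerance = 1e-12)
    expect_equal(r["n", "beta"], 0.5 * exp(-(vs - 10) / 40), tolerance = 1e-12)
    expect_equal(r["mt", "alpha"], 0.182 * tp(v + 38, 6), tolerance = 1e-12)
    expect_equal(r["mt", "beta"], 0.124 * tp(-(v + 38), 6), tolerance = 1e-12)
    expect_equal(r["ht", "alpha"], 0.015 * tp(-(v + 66), 6), tolerance = 1e-12)
    expect_equal(r["ht", "beta"], 0.015 * tp(v + 66, 6), tolerance = 1e-12)
    pinf <- 1 / (1 + exp(-(v + 35) / 10))
    ptau <- 1000 / (3.3 * exp((v + 35) / 20) + exp(-(v + 35) / 20))
    expect_equal(r["p", "alpha"] + r["p", "beta"], 1 / ptau, tolerance = 1e-12)
    expect_equal(r["p", "alpha"] / (r["p", "alpha"] + r["p", "beta"]), pinf,
                 tolerance = 1e-12)
    vinf <- 1 / (1 + exp(-(v - 18.7) / 9.7))
    vtau <- 4 / (1 + exp(-(v + 46.56) / 44.14))
    expect_equal(r["v", "alpha"] + r["v", "beta"], 1 / vtau, tolerance = 1e-12)
    expect_equal(r["v", "alpha"] / (r["v", "alpha"] + r["v", "beta"]), vinf,
                 tolerance = 1e-12)
    expect_equal(r["q", "alpha"], 0.055 * ef(-27 - v, 3.8), tolerance = 1e-12)
    expect_equal(r["q", "beta"], 0.94 * exp((-75 - v) / 17), tolerance = 1e-12)
    expect_equal(r["r", "alpha"], 0.000457 * exp((-13 - v) / 50), tolerance = 1e-12)
    expect_equal(r["r", "beta"], 0.0065 / (exp((-15 - v) / 28) + 1), tolerance = 1e-12)
    expect_true(all(r >= 0))
  }
})

test_that("rates stay nonnegative across the plausible voltage range", {
  for (v in seq(-130, 60, by = 5)) {
    expect_true(all(gateRates(v, -60, 1000) >= 0))
    expect_true(all(gateRates(v, -90, 50) >= 0))
    expect_true(all(gateRates(v, -35, 4000) >= 0))
  }
})

test_that("a fully passive membrane rests at the leak reversal", {
  p <- passiveParams()
  tr <- simulateHH(p, stimProtocol(noise = FALSE),
                   physConstants(i_inj = 0))
  expect_lt(max(abs(voltage(tr) - p["E_leak"])), 1e-9)
})

test_that("passive closed form encodes the tau definition and Ohmic scaling", {
  p <- passiveParams(R_input = 100, tau = 20)
  pr <- stimProtocol(noise = FALSE, dt = 0.05)
  cf <- passiveClosedForm(p, pr)
  tt <- traceTime(cf)
  # at t = t_on + tau the deflection is (1 - 1/e) of the step amplitude
  i <- which.min(abs(tt - (100 + 20)))
  expect_equal(voltage(cf)[i] - p["E_leak"],
               unname((1 - exp(-1)) * 100 * 300 * 1e-3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # late-time deflection equals R * I = 30 mV
  j <- which.min(abs(tt - 699))
  expect_equal(voltage(cf)[j] - p["E_leak"], 30, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("passive simulation matches the RC closed form", {
  set.seed(42)
  for (rep in 1:20) {
    p <- passiveParams(C = runif(1, 0.5, 5), R_input = runif(1, 20, 1000),
                       tau = runif(1, 1, 70), E_leak = runif(1, -130, -50))
    pr <- stimProtocol(noise = FALSE)
    tr <- simulateHH(p, pr)
    cf <- passiveClosedForm(p, pr)
    amp <- p["R_input"] * 300 * 1e-3
    expect_lt(max(abs(voltage(tr) - voltage(cf))) / amp, 0.01)
  }
})

test_that("spiking reference crosses 0 mV and matches a 10x finer integration", {
  p <- spikingParams()
  tr <- simulateHH(p, stimProtocol(noise = FALSE, dt = 0.05))
  expect_gt(max(voltage(tr)), 0)
  fine <- simulateHH(p, stimProtocol(noise = FALSE, dt = 0.005))
  expect_gt(max(voltage(fine)), 0)
  # spike count agrees with the fine reference to within one spike
  expect_lte(abs(nrow(detectSpikes(tr)) - nrow(detectSpikes(fine))), 1)
})

test_that("steady-state initialization is a fixed point of the dynamics", {
  set.seed(5)
  th <- samplePrior(20, seed = 5)
  for (i in 1:20) {
    st <- steadyStateInit(th[i, ])
    expect_true(all(st$gates >= 0 & st$gates <= 1))
    expect_identical(st, steadyStateInit(th[i, ]))
  }
  # gates sit exactly at alpha/(alpha+beta) evaluated at the leak reversal
  for (i in 1:10) {
    st <- steadyStateInit(th[i, ])
    r <- gateRates(st$v0, th[i, "V_T"], th[i, "tau_max"])
    expect_equal(unname(st$gates), unname(r[, "alpha"] / rowSums(r)),
                 tolerance = 1e-12)
  }
  # for passive membranes the initialization is an exact equilibrium: 100 ms
  # without input stays at the leak reversal (active cells may genuinely be
  # unstable at rest, e.g. spontaneous spiking, so equilibrium is only
  # guaranteed in the passive limit)
  for (i in 1:10) {
    p <- th[i, ]
    p[c("gbar_Nat", "gbar_Na", "gbar_Kd", "gbar_M", "gbar_Kv31", "gbar_L")] <- 0
    tr <- simulateHH(p, stimProtocol(t_total = 100, t_on = 50,
                                     t_off = 50.01, noise = FALSE),
                     physConstants(i_inj = 0))
    expect_lt(max(abs(voltage(tr) - p["E_leak"])), 2)
  }
})

test_that("gates remain in [0,1] along random prior trajectories", {
  th <- samplePrior(1000, seed = 9)
  pr <- stimProtocol(noise = TRUE)
  for (i in seq_len(nrow(th))) {
    pr$seed <- childSeed(9, i)
    res <- neurosbi:::.simulateHHFull(th[i, ], pr)
    expect_gte(res$gate_min, 0)
    expect_lte(res$gate_max, 1)
  }
})

test_that("simulation is reproducible: bit-exact without noise, seeded with", {
  p <- spikingParams()
  a <- simulateHH(p, stimProtocol(noise = FALSE))
  b <- simulateHH(p, stimProtocol(noise = FALSE))
  expect_identical(voltage(a), voltage(b))
  n1 <- simulateHH(p, stimProtocol(noise = TRUE, seed = 33))
  n2 <- simulateHH(p, stimProtocol(noise = TRUE, seed = 33))
  n3 <- simulateHH(p, stimProtocol(noise = TRUE, seed = 34))
  expect_identical(voltage(n1), voltage(n2))
  expect_false(identical(voltage(n1), voltage(n3)))
})

test_that("halving the step converges: counts, spike shape, voltage moments", {
  # interval statistics of long spike trains are sensitive to accumulated
  # phase drift at any step size, so convergence is asserted on the
  # well-posed observables: spike counts (within one spike), first-spike
  # shape, and voltage moments
  th <- samplePrior(100, seed = 13)
  countsClose <- 0L
  shapeRel <- widthRel <- numeric(0)
  for (i in seq_len(nrow(th))) {
    f1 <- extractFeatures(simulateHH(th[i, ], stimProtocol(noise = FALSE, dt = 0.05)))
    f2 <- extractFeatures(simulateHH(th[i, ], stimProtocol(noise = FALSE, dt = 0.025)))
    relCount <- abs(f1["ap_count"] - f2["ap_count"]) /
      max(f1["ap_count"], f2["ap_count"], 1)
    if (relCount <= 0.1) countsClose <- countsClose + 1L
    if (isTRUE(f1["ap_count"] == f2["ap_count"])) {
      for (nm in c("ap_threshold", "ap_amplitude", "vm_mean", "rest_vm_mean")) {
        if (is.finite(f1[nm]) && is.finite(f2[nm])) {
          shapeRel <- c(shapeRel, abs(f1[nm] - f2[nm]) / max(abs(f1[nm]), 1))
        }
      }
      for (nm in c("ap_width", "vm_sd")) {
        if (is.finite(f1[nm]) && is.finite(f2[nm])) {
          widthRel <- c(widthRel, abs(f1[nm] - f2[nm]) / max(abs(f1[nm]), 0.1))
        }
      }
    }
  }
  expect_gte(countsClose, 85)
  # bulk of the distribution converges; isolated bifurcation-boundary draws
  # may sit in the tail
  expect_lt(quantile(shapeRel, 0.95), 0.05)
  expect_lt(quantile(widthRel, 0.95), 0.10)
  expect_lt(median(shapeRel), 0.005)
})

test_that("raising the delayed-rectifier conductance does not widen spikes", {
  base <- spikingParams()
  widths <- sapply(c(10, 15, 20, 25, 30), function(g) {
    p <- base
    p["gbar_Kd"] <- g
    extractFeatures(simulateHH(p, stimProtocol(noise = FALSE)))["ap_width"]
  })
  expect_true(all(is.finite(widths)))
  expect_true(all(diff(widths) <= 1e-9))
})

test_that("parameter validation rejects invalid inputs", {
  p <- passiveParams()
  p2 <- p; p2["C"] <- -1
  expect_error(simulateHH(p2), "positive")
  p3 <- p; p3["gbar_Kd"] <- -5
  expect_error(simulateHH(p3), "conductance")
  p4 <- p[-1]
  expect_error(simulateHH(p4), "missing")
})
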