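# Feature extraction: spike detection, the 23 summaries, transforms,
# standardization and distances.

test_that("constant and downward-deflection traces carry no spikes", {
  expect_equal(nrow(detectSpikes(constantTrace())), 0)
  expect_equal(nrow(detectSpikes(templateTrace(invert = TRUE))), 0)
  fv <- extractFeatures(constantTrace(-70))
  expect_equal(unname(fv["rest_vm_mean"]), -70)
  expect_equal(unname(fv["vm_mean"]), -70)
  expect_equal(unname(fv["vm_sd"]), 0)
  expect_equal(unname(fv["ap_count"]), 0)
  expect_true(is.na(fv["latency"]))
  expect_true(is.na(fv["ap_threshold"]))
})

test_that("template spikes are detected with hand-computable geometry", {
  tr <- templateTrace(peaks = c(150, 250, 350))
  sp <- detectSpikes(tr)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$peak_time, c(150, 250, 350), tolerance = 1e-8)
  expect_equal(sp$peak_vm, rep(20, 3), tolerance = 1e-8)
  expect_equal(sp$threshold_time, c(148, 248, 348), tolerance = 0.11)
  expect_equal(sp$threshold_vm, rep(-60, 3), tolerance = 0.5)
  expect_equal(sp$amplitude, rep(80, 3), tolerance = 0.5)
  expect_equal(sp$width_half_height, rep(templateSpikeWidth(), 3),
               tolerance = 0.02)
  # descent reaches the -70 baseline; depth measured from threshold
  expect_equal(sp$ahp_depth, rep(10, 3), tolerance = 0.5)
})

test_that("template-trace features match hand counts", {
  fv <- extractFeatures(templateTrace(peaks = c(150, 250, 350)))
  expect_equal(unname(fv["ap_count"]), 3)
  expect_equal(unname(fv["ap_count_1st_8th"]), 1)
  expect_equal(unname(fv["ap_count_1st_quarter"]), 2)
  expect_equal(unname(fv["ap_count_1st_half"]), 3)
  expect_equal(unname(fv["ap_count_2nd_half"]), 0)
  expect_equal(unname(fv["isi_adapt"]), 1, tolerance = 1e-8)
  expect_equal(unname(fv["ap_cv"]), 0, tolerance = 1e-8)
  expect_equal(unname(fv["isi_cv"]), 0, tolerance = 1e-8)
  expect_equal(unname(fv["ap_amp_adapt"]), 1, tolerance = 1e-8)
  expect_equal(unname(fv["latency"]), 48, tolerance = 0.11)
  expect_equal(unname(fv["ap3_amplitude"]), unname(fv["ap_amplitude"]),
               tolerance = 1e-8)
})

test_that("spike-count prerequisites gate the dependent features", {
  two <- extractFeatures(templateTrace(peaks = c(150, 250)))
  expect_false(is.na(two["ap_amp_adapt"]))
  expect_false(is.na(two["ap_cv"]))
  expect_true(is.na(two["isi_adapt"]))
  expect_true(is.na(two["isi_cv"]))
  expect_true(is.na(two["ap3_threshold"]))
  expect_true(is.na(two["ap3_width"]))
  one <- extractFeatures(templateTrace(peaks = 150))
  expect_false(is.na(one["ap_threshold"]))
  expect_false(is.na(one["latency"]))
  expect_true(is.na(one["ap_amp_adapt"]))
})

test_that("transforms follow the log/sigmoid footnote rules", {
  fv <- setNames(rep(NA_real_, 23), ephysFeatureNames())
  fv["ap_count"] <- 1
  fv["ap_count_1st_8th"] <- 0
  fv["ap_avg_amp_adapt"] <- 0
  fv["latency"] <- exp(2)
  fv["isi_adapt"] <- 2
  fv["rest_vm_mean"] <- -70
  tf <- transformFeatures(fv)
  expect_equal(unname(tf["ap_count"]), 0)             # ln 1
  expect_true(is.na(tf["ap_count_1st_8th"]))          # ln 0 undefined
  expect_equal(unname(tf["ap_avg_amp_adapt"]), 0.5)   # sigmoid at 0
  expect_equal(unname(tf["latency"]), 2)
  expect_equal(unname(tf["isi_adapt"]), log(2))
  expect_equal(unname(tf["rest_vm_mean"]), -70)       # moments untouched
})

test_that("standardizer round-trips and z-scores its fitting set", {
  set.seed(1)
  x <- matrix(rnorm(200 * 23, mean = 3, sd = 2), 200, 23,
              dimnames = list(NULL, ephysFeatureNames()))
  std <- fitStandardizer(x)
  z <- standardizeFeatures(x, std)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 23), tolerance = 1e-12)
  expect_lt(max(abs(unstandardizeFeatures(z, std) - x)), 1e-12)
  one <- standardizeFeatures(x[1, ], std)
  expect_equal(one, (x[1, ] - std@mean) / std@sd, tolerance = 1e-12)
  xc <- x; xc[, 2] <- 5
  expect_error(fitStandardizer(xc), "constant")
})

test_that("feature distance is a Euclidean metric on z-vectors", {
  set.seed(2)
  a <- rnorm(23); b <- rnorm(23)
  expect_equal(featureDistance(a, a), 0)
  d1 <- a; d1[5] <- d1[5] + 1
  expect_equal(featureDistance(a, d1), 1)
  expect_equal(featureDistance(a, b), featureDistance(b, a))
  b[1] <- NA
  expect_error(featureDistance(a, b), "undefined")
})

test_that("features shift consistently under a constant voltage offset", {
  tr <- templateTrace(peaks = c(150, 250, 350))
  f0 <- extractFeatures(tr)
  trC <- tr
  trC@vm <- tr@vm + 7
  f7 <- extractFeatures(trC)
  shifted <- c("ap_threshold", "ap3_threshold", "rest_vm_mean", "vm_mean")
  invariant <- c("ap_amplitude", "ap_width", "ahp", "ap_count", "ap_cv",
                 "isi_adapt", "latency", "vm_sd", "vm_skewness")
  expect_equal(f7[shifted], f0[shifted] + 7, tolerance = 1e-8)
  expect_equal(f7[invariant], f0[invariant], tolerance = 1e-8)
})

test_that("pre-stimulus samples only affect the resting features", {
  tr <- templateTrace(peaks = c(150, 250, 350))
  set.seed(3)
  restIdx <- which((seq_along(tr@vm) - 1) * tr@dt < 100)
  tr2 <- tr
  tr2@vm[restIdx] <- tr@vm[sample(restIdx)]
  f1 <- extractFeatures(tr)
  f2 <- extractFeatures(tr2)
  stimFeatures <- setdiff(ephysFeatureNames(), "rest_vm_mean")
  expect_equal(f1[stimFeatures], f2[stimFeatures], tolerance = 1e-10)
  expect_equal(unname(f1["rest_vm_mean"]), unname(f2["rest_vm_mean"]),
               tolerance = 1e-10) # permutation preserves the mean too
})

test_that("validity equals all-23-transformed-features-defined on prior draws", {
  lib <- referenceLibrary()
  idx <- seq_len(500)
  trans <- featureMatrix(lib)[idx, ]
  raw <- featureMatrix(lib, type = "raw")[idx, ]
  mask <- validMask(lib)[idx]
  allDef <- apply(trans, 1, function(z) all(is.finite(z)))
  expect_identical(unname(allDef), unname(mask))
  # every valid row carries >= 3 spikes and finite moments; the converse
  # needs every count window populated, so >= 3 spikes alone is not enough
  expect_true(all(raw[mask, "ap_count"] >= 3))
  expect_true(all(is.finite(raw[mask, c("vm_mean", "vm_sd", "vm_skewness")])))
  windows <- c("ap_count_1st_8th", "ap_count_1st_quarter",
               "ap_count_1st_half", "ap_count_2nd_half")
  expect_true(all(raw[mask, windows] >= 1))
})
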