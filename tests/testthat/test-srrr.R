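# Sparse reduced-rank regression: preprocessing, identifiable recovery,
# shrinkage behavior, cross-validation and the group-level summaries.

test_that("expression preprocessing normalizes depth and rejects degenerate genes", {
  set.seed(1)
  counts <- matrix(rpois(30 * 10, lambda = 20), 30, 10,
                   dimnames = list(NULL, paste0("g", 1:10)))
  # proportional cells map to identical normalized rows
  counts[2, ] <- counts[1, ] * 3
  X <- preprocessExpression(counts)
  expect_lt(max(abs(X[1, ] - X[2, ])), 1e-12)
  expect_lt(max(abs(colMeans(X))), 1e-12)
  # z-scoring round-trips
  back <- sweep(sweep(X, 2, attr(X, "geneSd"), "*"), 2, attr(X, "geneMean"), "+")
  expect_equal(unname(back), unname(log1p(sweep(counts, 1, rowSums(counts), "/") * 1e6)),
               tolerance = 1e-12, ignore_attr = TRUE)
  countsZ <- counts
  countsZ[, 4] <- 0
  expect_error(preprocessExpression(countsZ), "g4")
  countsN <- counts
  countsN[1, 1] <- -1
  expect_error(preprocessExpression(countsN), "nonnegative")
})

test_that("a noiseless single-gene signal is recovered exactly", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("g", 1:30)))
  v <- rnorm(13)
  Y <- X[, 7] %*% t(v)
  colnames(Y) <- hhParameterNames()
  fit <- fitSRRR(X, Y, rank = 2, lambda = 0.01)
  expect_identical(selectedGenes(fit), "g7")
  r2 <- perTargetR2(Y, predict(fit, X))
  expect_true(all(r2 > 0.99))
})

test_that("a large penalty shrinks every gene out of the model", {
  set.seed(3)
  n <- 80
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("g", 1:20)))
  Y <- matrix(rnorm(n * 13), n, 13)
  fit <- fitSRRR(X, Y, rank = 2, lambda = 100)
  expect_length(selectedGenes(fit), 0)
  pred <- predict(fit, X)
  expect_lt(max(abs(sweep(pred, 2, colMeans(Y), "-"))), 1e-10)
})

test_that("gene count is nonincreasing in the penalty", {
  pl <- makePlantedSRRR(n = 200, p = 80, k = 10, seed = 4)
  grid <- c(0.005, 0.02, 0.05, 0.1, 0.3, 1)
  nGenes <- sapply(grid, function(l) {
    length(selectedGenes(fitSRRR(pl$X, pl$Y, lambda = l, relaxed = FALSE)))
  })
  expect_true(all(diff(nGenes) <= 0))
})

test_that("predictions are invariant to gene-column permutation", {
  pl <- makePlantedSRRR(n = 150, p = 40, k = 5, seed = 5)
  fit <- fitSRRR(pl$X, pl$Y, lambda = 0.05)
  set.seed(6)
  perm <- sample(ncol(pl$X))
  fitP <- fitSRRR(pl$X[, perm], pl$Y, lambda = 0.05)
  expect_equal(predict(fitP, pl$X[, perm]), predict(fit, pl$X),
               tolerance = 1e-6)
  expect_setequal(selectedGenes(fitP), selectedGenes(fit))
})

test_that("in-sample fit respects the nested-rank ordering", {
  pl <- makePlantedSRRR(n = 300, p = 100, k = 10, seed = 7)
  r2 <- sapply(c(1, 2, 13), function(r) {
    fit <- fitSRRR(pl$X, pl$Y, rank = r, lambda = 0.05)
    mean(perTargetR2(pl$Y, predict(fit, pl$X)))
  })
  expect_lte(r2[1], r2[2] + 1e-8)
  expect_lte(r2[2], r2[3] + 1e-8)
})

test_that("planted support is recovered and matches the oracle refit", {
  pl <- makePlantedSRRR(n = 500, p = 400, k = 20, snr = 1, seed = 8)
  grid <- srrrLambdaGrid(pl$X, pl$Y, rank = 2, nLambda = 12, ratio = 0.05)
  cv <- crossValidateSRRR(pl$X, pl$Y, grid, rank = 2, folds = 5, seed = 9)
  # one-SE rule: sparsest model within one SE of the best mean R^2
  best <- which.max(cv$r2_mean)
  thr <- cv$r2_mean[best] - cv$r2_sd[best] / sqrt(5)
  ok1se <- which(cv$r2_mean >= thr)
  pick <- ok1se[which.max(cv$lambda[ok1se])]
  fit <- fitSRRR(pl$X, pl$Y, rank = 2, lambda = cv$lambda[pick])
  sel <- match(selectedGenes(fit), colnames(pl$X))
  tp <- length(intersect(sel, pl$support))
  f1 <- 2 * tp / (length(sel) + length(pl$support))
  expect_gte(f1, 0.8)
  # oracle: least squares on the true support, same CV protocol
  oracleR2 <- local({
    set.seed(9)
    foldId <- sample(rep(1:5, length.out = nrow(pl$X)))
    r2 <- numeric(5)
    for (f in 1:5) {
      tr <- foldId != f
      Xs <- pl$X[tr, pl$support]
      B <- solve(crossprod(Xs) + diag(1e-8, length(pl$support)),
                 crossprod(Xs, pl$Y[tr, ]))
      pred <- pl$X[!tr, pl$support] %*% B
      mu <- colMeans(pl$Y[tr, ])
      r2[f] <- 1 - sum((pl$Y[!tr, ] - pred)^2) /
        sum(sweep(pl$Y[!tr, ], 2, mu, "-")^2)
    }
    mean(r2)
  })
  expect_lt(abs(cv$r2_mean[pick] - oracleR2), 0.05)
})

test_that("pure-noise responses have no cross-validated signal", {
  set.seed(10)
  X <- matrix(rnorm(200 * 50), 200, 50, dimnames = list(NULL, paste0("g", 1:50)))
  Y <- matrix(rnorm(200 * 13), 200, 13)
  cv <- crossValidateSRRR(X, Y, c(0.02, 0.1, 0.5), folds = 5, seed = 11)
  expect_true(all(cv$r2_mean <= 0.05))
  cv2 <- crossValidateSRRR(X, Y, c(0.02, 0.1, 0.5), folds = 5, seed = 11)
  expect_identical(cv, cv2)
})

test_that("per-target R2 has its closed-form limits and pooled consistency", {
  set.seed(12)
  Y <- matrix(rnorm(100 * 13), 100, 13)
  expect_true(all(perTargetR2(Y, Y) == 1))
  mu <- matrix(colMeans(Y), 100, 13, byrow = TRUE)
  expect_equal(unname(perTargetR2(Y, mu)), rep(0, 13))
  # equal-variance targets: pooled R2 equals the mean per-target R2
  Yz <- scale(Y)
  Yhat <- Yz * 0.5
  pooled <- 1 - sum((Yz - Yhat)^2) / sum(scale(Yz, scale = FALSE)^2)
  expect_equal(mean(perTargetR2(Yz, Yhat)), pooled, tolerance = 1e-10)
})

test_that("group-average distance behaves on constructed hierarchies", {
  set.seed(13)
  n <- 120
  Y <- matrix(rnorm(n * 13), n, 13)
  expect_equal(groupAverageDistance(Y, Y, rep(c("a", "b"), n / 2)), 0)
  # single group: distance between the overall mean vectors in z-space
  Yp <- Y + 0.3
  d1 <- groupAverageDistance(Y, Yp, rep("all", n))
  mu <- colMeans(Y); sd <- apply(Y, 2, sd)
  expect_equal(d1, sqrt(sum(((colMeans(Y) - colMeans(Yp)) / sd)^2)),
               tolerance = 1e-10)
  # predictions capturing only coarse structure: finer labels score worse
  coarse <- rep(c("A", "B"), each = n / 2)
  fine <- rep(c("A1", "A2", "B1", "B2"), each = n / 4)
  muFine <- c(A1 = 0, A2 = 2, B1 = 5, B2 = 7)
  muCoarse <- c(A = 1, B = 6)
  Ytrue <- Y
  Ytrue[, 1] <- Ytrue[, 1] + muFine[fine]
  Ypred <- Y
  Ypred[, 1] <- Ypred[, 1] + muCoarse[coarse]
  dCoarse <- groupAverageDistance(Ytrue, Ypred, coarse)
  dFine <- groupAverageDistance(Ytrue, Ypred, fine)
  expect_gt(dFine, dCoarse)
})

test_that("parameter-based classification separates what is separable", {
  set.seed(14)
  n <- 150
  labels <- rep(c("a", "b", "c"), each = n / 3)
  Y <- matrix(rnorm(n * 5, sd = 0.2), n, 5)
  Y[labels == "b", 1] <- Y[labels == "b", 1] + 5
  Y[labels == "c", 2] <- Y[labels == "c", 2] + 5
  res <- classifyFromParams(Y, labels, seed = 15)
  expect_gte(res$accuracy, 0.95)
  resPerm <- classifyFromParams(Y, sample(labels), seed = 15)
  expect_lt(resPerm$accuracy, 0.67)
  res2 <- classifyFromParams(Y, labels, seed = 15)
  expect_equal(res$accuracy, res2$accuracy)
})
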