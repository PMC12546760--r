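#' Normalize a count matrix for regression
#'
#' Depth-normalizes each cell to counts per million, applies `log(1 + x)` and
#' z-scores every gene. Deterministic; the per-gene centers and scales are
#' attached as attributes so new cells can be placed on the same scale.
#'
#' @param counts cells x genes nonnegative count matrix with unique gene
#'   identifiers as column names.
#' @return Normalized numeric matrix with attributes `geneMean`, `geneSd`.
#' @export
preprocessExpression <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("gene identifiers must be unique")
  zero <- colSums(counts) == 0
  if (any(zero)) stop("gene(s) with all-zero counts: ",
                      paste(utils::head(colnames(counts)[zero], 5),
                            collapse = ", "))
  depth <- rowSums(counts)
  if (any(depth == 0)) stop("cell(s) with zero total counts")
  cpm <- sweep(counts, 1, depth, "/") * 1e6
  lx <- log1p(cpm)
  m <- colMeans(lx)
  s <- apply(lx, 2, stats::sd)
  if (any(s == 0)) stop("gene(s) constant after normalization: ",
                        paste(utils::head(colnames(lx)[s == 0], 5),
                              collapse = ", "))
  out <- sweep(sweep(lx, 2, m, "-"), 2, s, "/")
  attr(out, "geneMean") <- m
  attr(out, "geneSd") <- s
  out
}

#' Data-driven penalty grid for sRRR
#'
#' Log-spaced grid from the smallest penalty that zeroes every gene
#' (`lambda_max`, computed from the gene-wise gradient norms at the
#' rank-truncated response, as in coordinate-descent solvers) down to
#' `ratio * lambda_max`.
#'
#' @param X,Y design and response matrices (see [fitSRRR()]).
#' @param rank latent rank used to form the initial decoder.
#' @param alpha elastic-net mixing.
#' @param nLambda grid length.
#' @param ratio smallest/largest penalty ratio.
#' @return Decreasing numeric vector of penalties.
#' @export
srrrLambdaGrid <- function(X, Y, rank = 2, alpha = 0.5, nLambda = 12,
                           ratio = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2, colMeans(X), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  V <- svd(crossprod(Xc, Yc), nu = 0, nv = min(rank, ncol(Y)))$v
  Z <- Yc %*% V
  gradNorm <- sqrt(rowSums(crossprod(Xc, Z)^2)) / nrow(X)
  lmax <- max(gradNorm) / max(alpha, 0.001)
  exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda))
}

# rank-r reduced-rank least squares refit on the selected genes
.rrrRefit <- function(Xs, Yc, rank) {
  p <- ncol(Xs)
  G <- crossprod(Xs) + diag(1e-8, p)
  Bols <- solve(G, crossprod(Xs, Yc))
  Fhat <- Xs %*% Bols
  sv <- svd(Fhat, nu = 0, nv = min(rank, ncol(Yc)))
  Vr <- sv$v[, seq_len(min(rank, ncol(sv$v))), drop = FALSE]
  list(B = Bols %*% Vr %*% t(Vr), V = Vr)
}

#' Fit sparse reduced-rank regression
#'
#' Minimizes `||Y - X W V'||_F^2` with a group-sparse elastic-net penalty on
#' the rows of the encoder `W` (so genes are selected in or out of the model
#' as a whole) by alternating a multi-response elastic-net update of `W`
#' given `V` and an orthogonal Procrustes update of `V` given `W`. After the
#' selected support stabilizes, an unpenalized reduced-rank refit on the
#' selected genes removes the shrinkage bias (relaxed fit).
#'
#' @param X cells x genes normalized design matrix (see
#'   [preprocessExpression()]).
#' @param Y cells x targets response matrix (z-scored parameters).
#' @param rank latent dimensionality (default 2; use `ncol(Y)` for the
#'   full-rank model).
#' @param lambda elastic-net strength.
#' @param alpha elastic-net mixing (1 = group lasso, 0 = ridge); default 0.5.
#' @param relaxed run the unpenalized refit on the selected support.
#' @param maxIter,tol alternation controls (relative loss change).
#' @return A [SRRRModel-class].
#' @export
fitSRRR <- function(X, Y, rank = 2, lambda = 0.1, alpha = 0.5,
                    relaxed = TRUE, maxIter = 500, tol = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (anyNA(X) || anyNA(Y)) stop("X and Y must have no undefined entries")
  if (nrow(X) < 20) stop("need at least 20 cells")
  n <- nrow(X); q <- ncol(Y)
  rank <- min(rank, q)
  muY <- colMeans(Y)
  muX <- colMeans(X)
  Yc <- sweep(Y, 2, muY, "-")
  Xc <- sweep(X, 2, muX, "-")

  sv0 <- svd(crossprod(Xc, Yc), nu = 0, nv = rank)
  V <- sv0$v
  W <- matrix(0, ncol(X), rank)
  lossOld <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Z <- Yc %*% V
    if (rank == 1) {
      fit <- glmnet::glmnet(Xc, as.numeric(Z), family = "gaussian",
                            lambda = lambda, alpha = alpha, intercept = FALSE,
                            standardize = FALSE)
      W <- matrix(as.numeric(stats::coef(fit, s = lambda))[-1], ncol = 1)
    } else {
      fit <- glmnet::glmnet(Xc, Z, family = "mgaussian", lambda = lambda,
                            alpha = alpha, intercept = FALSE,
                            standardize = FALSE, standardize.response = FALSE)
      co <- stats::coef(fit, s = lambda)
      W <- do.call(cbind, lapply(co, function(cc) as.numeric(cc)[-1]))
    }
    XW <- Xc %*% W
    sv <- svd(crossprod(Yc, XW), nu = rank, nv = rank)
    V <- sv$u %*% t(sv$v)
    loss <- sum((Yc - XW %*% t(V))^2) / (2 * n) +
      lambda * (alpha * sum(sqrt(rowSums(W^2))) +
                  (1 - alpha) / 2 * sum(W^2))
    if (is.finite(lossOld) && abs(lossOld - loss) <= tol * max(1, lossOld)) {
      converged <- TRUE
      break
    }
    lossOld <- loss
  }
  if (!converged && maxIter > 1) {
    warning("sRRR alternation did not converge in ", maxIter,
            " iterations; returning best iterate")
  }
  sel <- which(rowSums(W^2) > 0)
  if (relaxed && length(sel) >= 1) {
    rf <- .rrrRefit(Xc[, sel, drop = FALSE], Yc, rank)
    # express the refit through the same encoder/decoder factorization
    svB <- svd(rf$B, nu = min(rank, length(sel)), nv = rank)
    r2 <- min(rank, length(sel), sum(svB$d > 1e-12))
    Wnew <- matrix(0, ncol(X), rank)
    if (r2 >= 1) {
      Wnew[sel, seq_len(r2)] <- svB$u[, seq_len(r2), drop = FALSE] %*%
        diag(svB$d[seq_len(r2)], r2)
      Vnew <- matrix(0, q, rank)
      Vnew[, seq_len(r2)] <- svB$v[, seq_len(r2), drop = FALSE]
      # complete the decoder to orthonormal columns
      if (r2 < rank) {
        extra <- qr.Q(qr(cbind(Vnew[, seq_len(r2)], diag(q))))[, (r2 + 1):rank,
                                                               drop = FALSE]
        Vnew[, (r2 + 1):rank] <- extra
      }
      W <- Wnew
      V <- Vnew
    }
  }
  rownames(W) <- colnames(X)
  rownames(V) <- colnames(Y)
  new("SRRRModel", W = W, V = V, intercept = muY, xCenter = muX,
      rank = rank, lambda = lambda, alpha = alpha,
      meta = list(iterations = it, converged = converged,
                  relaxed = relaxed, nSelected = length(sel)))
}

#' Predict targets from expression with a fitted sRRR model
#'
#' @param object a [SRRRModel-class].
#' @param newdata cells x genes matrix on the training normalization scale.
#' @return cells x targets matrix of predictions.
#' @export
setMethod("predict", "SRRRModel", function(object, newdata) {
  Xc <- sweep(as.matrix(newdata), 2, object@xCenter, "-")
  out <- Xc %*% object@W %*% t(object@V)
  sweep(out, 2, object@intercept, "+")
})

#' Cross-validate sRRR over a penalty grid
#'
#' K-fold cross-validation; for each penalty the held-out `R^2` is pooled
#' over all targets (`1 - SS_res / SS_tot`, with `SS_tot` taken around the
#' training-fold means) and the number of selected genes is averaged over
#' folds.
#'
#' @param X,Y design and response matrices as in [fitSRRR()].
#' @param lambdaGrid numeric vector of penalties.
#' @param alpha elastic-net mixing.
#' @param rank latent rank (use `ncol(Y)` for full rank).
#' @param folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param relaxed forwarded to [fitSRRR()].
#' @return data.frame with columns `lambda`, `r2_mean`, `r2_sd`,
#'   `genes_mean`.
#' @export
crossValidateSRRR <- function(X, Y, lambdaGrid, alpha = 0.5, rank = 2,
                              folds = 10, seed = 1, relaxed = TRUE) {
  stopifnot(folds >= 2)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  set.seed(seed)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  r2 <- genes <- matrix(NA_real_, length(lambdaGrid), folds)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    for (li in seq_along(lambdaGrid)) {
      fit <- fitSRRR(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     rank = rank, lambda = lambdaGrid[li], alpha = alpha,
                     relaxed = relaxed)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      Yho <- Y[!tr, , drop = FALSE]
      mu <- colMeans(Y[tr, , drop = FALSE])
      ssRes <- sum((Yho - pred)^2)
      ssTot <- sum(sweep(Yho, 2, mu, "-")^2)
      r2[li, f] <- 1 - ssRes / ssTot
      genes[li, f] <- length(selectedGenes(fit))
    }
  }
  data.frame(lambda = lambdaGrid, r2_mean = rowMeans(r2),
             r2_sd = apply(r2, 1, stats::sd), genes_mean = rowMeans(genes))
}

#' Per-target coefficient of determination
#'
#' @param Y observed targets (matrix).
#' @param Yhat predictions of the same shape.
#' @return Named numeric vector, one `R^2` per target column.
#' @export
perTargetR2 <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  mu <- colMeans(Y)
  ssRes <- colSums((Y - Yhat)^2)
  ssTot <- colSums(sweep(Y, 2, mu, "-")^2)
  stats::setNames(1 - ssRes / ssTot, colnames(Y))
}

#' Group-averaged parameter-matrix distance
#'
#' Z-scores both matrices columnwise by the mean and SD of the full fitted
#' (MAP) set, averages rows within each label, and returns the Frobenius
#' (Euclidean) distance between the two group-averaged matrices.
#'
#' @param yMap fitted MAP parameter matrix (cells x parameters).
#' @param yPred predicted parameter matrix of the same shape.
#' @param labels group labels (factor or character), every group nonempty.
#' @return Nonnegative scalar.
#' @export
groupAverageDistance <- function(yMap, yPred, labels) {
  yMap <- as.matrix(yMap); yPred <- as.matrix(yPred)
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(yMap) == nrow(yPred), length(labels) == nrow(yMap))
  mu <- colMeans(yMap)
  sd <- apply(yMap, 2, stats::sd)
  if (any(sd == 0)) stop("constant parameter column in the MAP matrix")
  zs <- function(m) sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  gm <- function(m) {
    do.call(rbind, lapply(levels(labels), function(l) {
      colMeans(m[labels == l, , drop = FALSE])
    }))
  }
  sqrt(sum((gm(zs(yMap)) - gm(zs(yPred)))^2))
}

#' Classify cell labels from parameter values
#'
#' Multinomial logistic regression trained on a stratified random split and
#' scored on the held-out cells.
#'
#' @param Y cells x parameters matrix of predictors.
#' @param labels class labels.
#' @param trainFraction fraction of cells used for training (default 0.8,
#'   stratified by class).
#' @param seed seed for the split.
#' @return List with `accuracy`, `nTest`, and the held-out `predicted` /
#'   `truth` factors.
#' @export
classifyFromParams <- function(Y, labels, trainFraction = 0.8, seed = 1) {
  Y <- as.matrix(Y)
  labels <- droplevels(as.factor(labels))
  set.seed(seed)
  testIdx <- unlist(lapply(levels(labels), function(l) {
    idx <- which(labels == l)
    nTest <- max(1, round(length(idx) * (1 - trainFraction)))
    sample(idx, nTest)
  }))
  tr <- setdiff(seq_len(nrow(Y)), testIdx)
  df <- data.frame(Y)
  df$.label <- labels
  fit <- nnet::multinom(.label ~ ., data = df[tr, , drop = FALSE],
                        trace = FALSE, MaxNWts = 5000, maxit = 300)
  pred <- stats::predict(fit, newdata = df[testIdx, , drop = FALSE])
  list(accuracy = mean(pred == labels[testIdx]), nTest = length(testIdx),
       predicted = pred, truth = labels[testIdx])
}
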