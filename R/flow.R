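# Conditional masked autoregressive flow (MAF), implemented directly with
# dense linear algebra and manual backpropagation.
#
# Each block is a MADE-style masked two-layer network mapping the current
# representation u (dimension D) and the conditioning context c (dimension
# Dc) to per-dimension shift mu_i and log-scale s_i that depend only on
# u_{<i}; the block transform is z_i = (u_i - mu_i) * exp(-s_i), an
# invertible autoregressive map with log|det| = -sum_i s_i. Blocks are
# stacked with order-reversing permutations; the base density is standard
# normal. Density evaluation is a single pass; sampling inverts the blocks
# dimension by dimension. Log-scales are soft-clamped with a scaled tanh for
# numerical stability.
#
# Training maximizes the conditional log-likelihood with Adam, minibatches, a
# held-out validation split and early stopping on the validation loss.

.madeMasks <- function(D, H) {
  degIn <- seq_len(D)
  degH <- rep(0:(max(D - 1, 0)), length.out = H)
  M1 <- outer(degIn, degH, "<=") * 1            # D x H
  M2 <- outer(degH, degIn, "<") * 1             # H x D
  list(M1 = M1, M2 = M2)
}

.flowInit <- function(D, Dc, H = 50, nBlocks = 5, smax = 7) {
  masks <- .madeMasks(D, H)
  blocks <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    perm <- if (b %% 2 == 1) seq_len(D) else rev(seq_len(D))
    blocks[[b]] <- list(
      perm = perm,
      W1 = matrix(stats::rnorm(D * H, sd = 1 / sqrt(max(D, 1))), D, H) * masks$M1,
      U1 = matrix(stats::rnorm(Dc * H, sd = 1 / sqrt(max(Dc, 1))), Dc, H),
      b1 = rep(0, H),
      Wm = matrix(0, H, D), bm = rep(0, D),
      Ws = matrix(0, H, D), bs = rep(0, D))
  }
  list(D = D, Dc = Dc, H = H, smax = smax, blocks = blocks,
       M1 = masks$M1, M2 = masks$M2)
}

# forward pass; returns per-sample negative log-likelihood and (optionally)
# the per-block cache needed for backpropagation
.flowForward <- function(flow, u, ctx, cache = FALSE) {
  B <- nrow(u)
  smax <- flow$smax
  nll <- rep(0.5 * flow$D * log(2 * pi), B)
  caches <- if (cache) vector("list", length(flow$blocks)) else NULL
  for (b in seq_along(flow$blocks)) {
    bl <- flow$blocks[[b]]
    up <- u[, bl$perm, drop = FALSE]
    a <- up %*% (bl$W1 * flow$M1) + ctx %*% bl$U1
    a <- sweep(a, 2, bl$b1, "+")
    h <- tanh(a)
    mu <- sweep(h %*% (bl$Wm * flow$M2), 2, bl$bm, "+")
    sraw <- sweep(h %*% (bl$Ws * flow$M2), 2, bl$bs, "+")
    s <- smax * tanh(sraw / smax)
    es <- exp(-s)
    z <- (up - mu) * es
    nll <- nll + rowSums(s)
    if (cache) caches[[b]] <- list(up = up, h = h, s = s, es = es, z = z)
    u <- z
  }
  nll <- nll + 0.5 * rowSums(u^2)
  list(nll = nll, z = u, caches = caches)
}

.flowLogDensity <- function(flow, u, ctx) {
  -.flowForward(flow, u, ctx)$nll
}

# gradients of mean NLL w.r.t. all block parameters
.flowBackward <- function(flow, caches, ctx) {
  B <- nrow(ctx)
  smax <- flow$smax
  grads <- vector("list", length(flow$blocks))
  G <- caches[[length(caches)]]$z / B # d(mean nll)/dz_final
  for (b in rev(seq_along(flow$blocks))) {
    cc <- caches[[b]]
    bl <- flow$blocks[[b]]
    dLds <- -G * cc$z + 1 / B              # includes the log-det term
    dLdmu <- -G * cc$es
    dLdsraw <- dLds * (1 - (cc$s / smax)^2)
    dh <- dLdmu %*% t(bl$Wm * flow$M2) + dLdsraw %*% t(bl$Ws * flow$M2)
    da <- dh * (1 - cc$h^2)
    grads[[b]] <- list(
      W1 = crossprod(cc$up, da) * flow$M1,
      U1 = crossprod(ctx, da),
      b1 = colSums(da),
      Wm = crossprod(cc$h, dLdmu) * flow$M2, bm = colSums(dLdmu),
      Ws = crossprod(cc$h, dLdsraw) * flow$M2, bs = colSums(dLdsraw))
    dup <- G * cc$es + da %*% t(bl$W1 * flow$M1)
    Gn <- matrix(0, B, flow$D)
    Gn[, bl$perm] <- dup
    G <- Gn
  }
  grads
}

# draw n samples given one context row
.flowSample <- function(flow, ctxRow, n) {
  D <- flow$D
  smax <- flow$smax
  ctx <- matrix(rep(as.numeric(ctxRow), each = n), nrow = n)
  z <- matrix(stats::rnorm(n * D), n, D)
  for (b in rev(seq_along(flow$blocks))) {
    bl <- flow$blocks[[b]]
    up <- matrix(0, n, D)
    ctxPart <- ctx %*% bl$U1
    for (i in seq_len(D)) {
      a <- sweep(up %*% (bl$W1 * flow$M1) + ctxPart, 2, bl$b1, "+")
      h <- tanh(a)
      mu_i <- h %*% (bl$Wm[, i] * flow$M2[, i]) + bl$bm[i]
      sraw_i <- h %*% (bl$Ws[, i] * flow$M2[, i]) + bl$bs[i]
      s_i <- smax * tanh(sraw_i / smax)
      up[, i] <- z[, i] * exp(s_i) + mu_i
    }
    u <- matrix(0, n, D)
    u[, bl$perm] <- up
    z <- u
  }
  z
}

.adamInit <- function(blocks) {
  lapply(blocks, function(bl) {
    keep <- c("W1", "U1", "b1", "Wm", "bm", "Ws", "bs")
    list(m = lapply(bl[keep], function(p) p * 0),
         v = lapply(bl[keep], function(p) p * 0))
  })
}

.adamStep <- function(blocks, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  keep <- c("W1", "U1", "b1", "Wm", "bm", "Ws", "bs")
  for (b in seq_along(blocks)) {
    for (p in keep) {
      g <- grads[[b]][[p]]
      state[[b]]$m[[p]] <- beta1 * state[[b]]$m[[p]] + (1 - beta1) * g
      state[[b]]$v[[p]] <- beta2 * state[[b]]$v[[p]] + (1 - beta2) * g^2
      mhat <- state[[b]]$m[[p]] / (1 - beta1^t)
      vhat <- state[[b]]$v[[p]] / (1 - beta2^t)
      blocks[[b]][[p]] <- blocks[[b]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(blocks = blocks, state = state)
}

# maximum-likelihood training loop
.trainFlow <- function(theta, x, nBlocks = 5, hidden = 50, batch = 256,
                       lr = 1e-3, valFraction = 0.1, patience = 20,
                       maxEpochs = 300, smax = 7, verbose = FALSE) {
  n <- nrow(theta)
  D <- ncol(theta)
  Dc <- ncol(x)
  flow <- .flowInit(D, Dc, hidden, nBlocks, smax)
  nVal <- max(1L, floor(n * valFraction))
  idx <- sample.int(n)
  valIdx <- idx[seq_len(nVal)]
  trIdx <- idx[-seq_len(nVal)]
  thTr <- theta[trIdx, , drop = FALSE]; xTr <- x[trIdx, , drop = FALSE]
  thVal <- theta[valIdx, , drop = FALSE]; xVal <- x[valIdx, , drop = FALSE]
  nTr <- nrow(thTr)

  state <- .adamInit(flow$blocks)
  t <- 0
  best <- list(val = Inf, blocks = flow$blocks, epoch = 0)
  valCurve <- numeric(0)
  for (epoch in seq_len(maxEpochs)) {
    ord <- sample.int(nTr)
    for (start in seq(1, nTr, by = batch)) {
      bi <- ord[start:min(start + batch - 1, nTr)]
      fw <- .flowForward(flow, thTr[bi, , drop = FALSE],
                         xTr[bi, , drop = FALSE], cache = TRUE)
      if (!all(is.finite(fw$nll))) stop("non-finite training loss at epoch ",
                                        epoch)
      grads <- .flowBackward(flow, fw$caches, xTr[bi, , drop = FALSE])
      t <- t + 1
      upd <- .adamStep(flow$blocks, grads, state, lr, t)
      flow$blocks <- upd$blocks
      state <- upd$state
    }
    val <- mean(.flowForward(flow, thVal, xVal)$nll)
    valCurve <- c(valCurve, val)
    if (verbose) message(sprintf("epoch %d: val nll %.4f", epoch, val))
    if (is.finite(val) && val < best$val - 1e-6) {
      best <- list(val = val, blocks = flow$blocks, epoch = epoch)
    } else if (epoch - best$epoch >= patience) break
  }
  flow$blocks <- best$blocks
  list(flow = flow, valCurve = valCurve, bestEpoch = best$epoch,
       bestVal = best$val)
}
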