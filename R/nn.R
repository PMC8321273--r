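## Internal neural-network machinery for the motion classifier: a linear
## feature projection, a single-layer LSTM aggregator, a one-hidden-layer
## MLP head with sigmoid output, exact backpropagation through all three,
## and an Adam optimizer. Written in vectorized base R (BLAS matrix ops);
## batches are matrices with one row per sequence.

sigmoid <- function(x) 1 / (1 + exp(-x))

## Glorot-uniform init, seeded by the caller.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## Parameter set. D = descriptor dim, Fd = feature dim (psi), H = LSTM
## hidden, M = head hidden. Gate column blocks in Wx/Wh/b order: i, f, g, o.
## The forget-gate bias starts at 1 (standard LSTM practice) so early
## training does not wash out the cell state.
nnInitParams <- function(D, Fd, H, M, recurrent, projInit = NULL) {
  p <- list()
  p$Wp <- if (is.null(projInit)) glorot(D, Fd) else projInit$W
  p$bp <- if (is.null(projInit)) numeric(Fd) else projInit$b
  if (recurrent) {
    p$Wx <- glorot(Fd, 4L * H)
    p$Wh <- glorot(H, 4L * H)
    p$b <- numeric(4L * H)
    p$b[(H + 1L):(2L * H)] <- 1
    headIn <- H
  } else headIn <- Fd
  p$W1 <- glorot(headIn, M)
  p$b1 <- numeric(M)
  p$W2 <- glorot(M, 1L)
  p$b2 <- 0
  p
}

## LSTM forward over a batch. psiSeq: list of T matrices [B x Fd].
## Returns h: list of T [B x H], plus caches for backprop.
lstmForward <- function(psiSeq, params) {
  Tn <- length(psiSeq)
  B <- nrow(psiSeq[[1]])
  H <- ncol(params$Wh)
  H <- H / 4L
  h <- vector("list", Tn); cache <- vector("list", Tn)
  hPrev <- matrix(0, B, H); cPrev <- matrix(0, B, H)
  bRep <- matrix(params$b, B, 4L * H, byrow = TRUE)
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  for (t in seq_len(Tn)) {
    Z <- psiSeq[[t]] %*% params$Wx + hPrev %*% params$Wh + bRep
    i <- sigmoid(Z[, idx(1L), drop = FALSE])
    f <- sigmoid(Z[, idx(2L), drop = FALSE])
    g <- tanh(Z[, idx(3L), drop = FALSE])
    o <- sigmoid(Z[, idx(4L), drop = FALSE])
    c <- f * cPrev + i * g
    tc <- tanh(c)
    ht <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = c, tc = tc,
                       hPrev = hPrev, cPrev = cPrev)
    h[[t]] <- ht
    hPrev <- ht; cPrev <- c
  }
  list(h = h, cache = cache)
}

## Backprop through time. dh: list of T [B x H] gradients w.r.t. h_t from
## the head. Returns gradients for Wx, Wh, b and dPsi (list of T [B x Fd]).
lstmBackward <- function(psiSeq, params, fwd, dh) {
  Tn <- length(psiSeq)
  B <- nrow(psiSeq[[1]])
  H <- ncol(params$Wh) / 4L
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dPsi <- vector("list", Tn)
  dhNext <- matrix(0, B, H); dcNext <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dht <- dh[[t]] + dhNext
    do <- dht * cc$tc
    dc <- dht * cc$o * (1 - cc$tc^2) + dcNext
    di <- dc * cc$g
    df <- dc * cc$cPrev
    dg <- dc * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(psiSeq[[t]], dZ)
    dWh <- dWh + crossprod(cc$hPrev, dZ)
    db <- db + colSums(dZ)
    dPsi[[t]] <- dZ %*% t(params$Wx)
    dhNext <- dZ %*% t(params$Wh)
    dcNext <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dPsi = dPsi)
}

## Head forward: X [n x headIn] -> p [n]. Caches pre-activations.
headForward <- function(X, params) {
  A1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  R <- pmax(A1, 0)
  logit <- drop(R %*% params$W2) + params$b2
  list(p = sigmoid(logit), A1 = A1, R = R, X = X)
}

## Head backward from dLogit [n] -> grads + dX.
headBackward <- function(params, fwd, dLogit) {
  dW2 <- crossprod(fwd$R, dLogit)
  db2 <- sum(dLogit)
  dR <- matrix(dLogit, ncol = 1L) %*% t(params$W2)
  dA1 <- dR * (fwd$A1 > 0)
  dW1 <- crossprod(fwd$X, dA1)
  db1 <- colSums(dA1)
  dX <- dA1 %*% t(params$W1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dX = dX)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## Full forward pass for a batch of sequences.
## descr: array [B, T, D] of raw descriptors (already standardized).
## dropMask: NULL or [B*T x Fd] inverted-dropout mask applied to psi.
## Returns per-timestep probabilities as a [B x T] matrix plus caches.
nnForwardSeq <- function(descr, params, dropMask = NULL) {
  B <- dim(descr)[1]; Tn <- dim(descr)[2]; D <- dim(descr)[3]
  Xf <- matrix(aperm(descr, c(1, 2, 3)), B * Tn, D)
  psiFlat <- sweep(Xf %*% params$Wp, 2L, params$bp, "+")
  if (!is.null(dropMask)) psiFlat <- psiFlat * dropMask
  psiSeq <- lapply(seq_len(Tn), function(t)
    psiFlat[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  lf <- lstmForward(psiSeq, params)
  Hmat <- do.call(rbind, lf$h)          # [T*B x H], t-major like psiFlat
  hf <- headForward(Hmat, params)
  P <- matrix(hf$p, B, Tn)              # column t = timestep t
  list(P = P, Xf = Xf, psiSeq = psiSeq, lstm = lf, head = hf)
}

## Backward pass. dLogitMat: [B x T] gradient w.r.t. the head logits.
nnBackwardSeq <- function(fwd, params, dLogitMat, dropMask = NULL) {
  B <- nrow(dLogitMat); Tn <- ncol(dLogitMat)
  hb <- headBackward(params, fwd$head, as.vector(dLogitMat))
  H <- ncol(hb$dX)
  dh <- lapply(seq_len(Tn), function(t)
    hb$dX[((t - 1L) * B + 1L):(t * B), , drop = FALSE])
  lb <- lstmBackward(fwd$psiSeq, params, fwd$lstm, dh)
  dPsiFlat <- do.call(rbind, lb$dPsi)
  if (!is.null(dropMask)) dPsiFlat <- dPsiFlat * dropMask
  dWp <- crossprod(fwd$Xf, dPsiFlat)
  dbp <- colSums(dPsiFlat)
  list(Wp = dWp, bp = dbp, Wx = lb$dWx, Wh = lb$dWh, b = lb$db,
       W1 = hb$dW1, b1 = hb$db1, W2 = hb$dW2, b2 = hb$db2)
}

## Per-frame (non-recurrent) forward/backward: descriptors [n x D] -> p [n].
nnForwardFrame <- function(X, params, dropMask = NULL) {
  psi <- sweep(X %*% params$Wp, 2L, params$bp, "+")
  if (!is.null(dropMask)) psi <- psi * dropMask
  hf <- headForward(psi, params)
  list(p = hf$p, X = X, head = hf)
}

nnBackwardFrame <- function(fwd, params, dLogit, dropMask = NULL) {
  hb <- headBackward(params, fwd$head, dLogit)
  dPsi <- hb$dX
  if (!is.null(dropMask)) dPsi <- dPsi * dropMask
  list(Wp = crossprod(fwd$X, dPsi), bp = colSums(dPsi),
       W1 = hb$dW1, b1 = hb$db1, W2 = hb$dW2, b2 = hb$db2)
}
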