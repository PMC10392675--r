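#' @include utils.R
NULL

# Standard LSTM cell (gate order i, f, g, o; sigmoid gates, tanh
# activation, forget-gate bias initialized to 1). Batch-major matrices:
# X steps are batch x inputDim slices of a window x inputDim x batch
# array.

initLSTMLayer <- function(inputDim, units) {
  list(Wx = glorotInit(c(inputDim, 4 * units), inputDim, 4 * units),
       Wh = glorotInit(c(units, 4 * units), units, 4 * units),
       b = rep(c(0, 1, 0, 0), each = units))   # forget bias 1
}

# X: window x inputDim x batch. Returns hidden sequence (batch x units
# x steps), final h and the caches for BPTT.
lstmForward <- function(p, X) {
  T <- dim(X)[1]; N <- dim(X)[3]
  H <- nrow(p$Wh)                              # units
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  hs <- array(0, c(N, H, T))
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    Xt <- t(matrix(X[t, , ], dim(X)[2], N))    # batch x inputDim
    Z <- Xt %*% p$Wx + h %*% p$Wh
    Z <- sweep(Z, 2, p$b, "+")
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, H + 1:H, drop = FALSE])
    g <- tanh(Z[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(Z[, 3 * H + 1:H, drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[, , t] <- h
    cache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                       cPrev = cPrev, c = cc, tc = tc)
  }
  list(hs = hs, hFinal = h, cache = cache)
}

# dHs: batch x units x steps gradient on the hidden sequence (may be
# non-zero only at the last step). Returns grads and the gradient on X.
lstmBackward <- function(p, X, fwd, dHs) {
  T <- dim(X)[1]; N <- dim(X)[3]; H <- nrow(p$Wh)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- X * 0
  dhNext <- matrix(0, N, H); dcNext <- matrix(0, N, H)
  for (t in rev(seq_len(T))) {
    ca <- fwd$cache[[t]]
    dh <- dhNext + matrix(dHs[, , t], N, H)
    dc <- dcNext + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g * ca$i * (1 - ca$i)
    df <- dc * ca$cPrev * ca$f * (1 - ca$f)
    dg <- dc * ca$i * (1 - ca$g^2)
    do <- dh * ca$tc * ca$o * (1 - ca$o)
    dZ <- cbind(di, df, dg, do)
    dWx <- dWx + t(ca$Xt) %*% dZ
    hPrev <- if (t == 1) matrix(0, N, H) else fwd$hs[, , t - 1, drop = FALSE]
    hPrev <- matrix(hPrev, N, H)
    dWh <- dWh + t(hPrev) %*% dZ
    db <- db + colSums(dZ)
    dhNext <- dZ %*% t(p$Wh)
    dcNext <- dc * ca$f
    dXt <- dZ %*% t(p$Wx)                      # batch x inputDim
    dX[t, , ] <- t(dXt)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

# Stacked forecaster: LSTM(16, sequences) > LSTM(8, final) >
# Dense(1, linear). X: window x channels x batch.
lstmForecasterForward <- function(params, X) {
  f1 <- lstmForward(params$L1, X)
  # feed layer-1 hidden sequence (batch x 16 x T) as window x 16 x batch
  X2 <- aperm(f1$hs, c(3, 2, 1))
  f2 <- lstmForward(params$L2, X2)
  emb <- f2$hFinal                              # batch x 8
  pred <- drop(emb %*% params$Wd) + params$bd
  list(pred = pred, emb = emb, cache = list(f1 = f1, f2 = f2, X2 = X2))
}

lstmForecasterBackward <- function(params, X, fwd, dPred) {
  f1 <- fwd$cache$f1; f2 <- fwd$cache$f2; X2 <- fwd$cache$X2
  N <- length(dPred)
  dWd <- t(fwd$emb) %*% matrix(dPred, ncol = 1)
  dbd <- sum(dPred)
  dEmb <- matrix(dPred, ncol = 1) %*% t(params$Wd)   # batch x 8
  T <- dim(X2)[1]
  dHs2 <- array(0, c(N, ncol(dEmb), T))
  dHs2[, , T] <- dEmb
  bw2 <- lstmBackward(params$L2, X2, f2, dHs2)
  dHs1 <- aperm(bw2$dX, c(3, 2, 1))                  # batch x 16 x T
  bw1 <- lstmBackward(params$L1, X, f1, dHs1)
  list(L1.Wx = bw1$Wx, L1.Wh = bw1$Wh, L1.b = bw1$b,
       L2.Wx = bw2$Wx, L2.Wh = bw2$Wh, L2.b = bw2$b,
       Wd = dWd, bd = dbd)
}

initLSTMForecaster <- function(nChannels, units1 = 16L, units2 = 8L) {
  list(L1 = initLSTMLayer(nChannels, units1),
       L2 = initLSTMLayer(units1, units2),
       Wd = glorotInit(c(units2, 1), units2, 1),
       bd = 0)
}

# Flat parameter list view so the generic optimizer can address nested
# LSTM weights by dotted name.
flattenLSTMParams <- function(params) {
  list(L1.Wx = params$L1$Wx, L1.Wh = params$L1$Wh, L1.b = params$L1$b,
       L2.Wx = params$L2$Wx, L2.Wh = params$L2$Wh, L2.b = params$L2$b,
       Wd = params$Wd, bd = params$bd)
}

unflattenLSTMParams <- function(flat) {
  list(L1 = list(Wx = flat$L1.Wx, Wh = flat$L1.Wh, b = flat$L1.b),
       L2 = list(Wx = flat$L2.Wx, Wh = flat$L2.Wh, b = flat$L2.b),
       Wd = flat$Wd, bd = flat$bd)
}
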