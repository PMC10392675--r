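#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Optimizers. State lives in an environment keyed by parameter name, so a
# single optimizer object follows one model through its whole training run.
# Constants follow the common framework defaults (rho 0.9, beta1 0.9,
# beta2 0.999, epsilon 1e-7).

makeOptimizer <- function(kind = c("rmsprop", "adam"), lr) {
  kind <- match.arg(kind)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  list(kind = kind, lr = lr, state = st)
}

optimizerStep <- function(opt, params, grads) {
  st <- opt$state
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (opt$kind == "rmsprop") {
      key <- paste0("v.", nm)
      v <- if (is.null(st[[key]])) g * 0 else st[[key]]
      v <- 0.9 * v + 0.1 * g^2
      st[[key]] <- v
      params[[nm]] <- params[[nm]] - opt$lr * g / (sqrt(v) + 1e-7)
    } else {
      mkey <- paste0("m.", nm); vkey <- paste0("v.", nm)
      m <- if (is.null(st[[mkey]])) g * 0 else st[[mkey]]
      v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
      m <- 0.9 * m + 0.1 * g
      v <- 0.999 * v + 0.001 * g^2
      st[[mkey]] <- m; st[[vkey]] <- v
      mhat <- m / (1 - 0.9^st$t)
      vhat <- v / (1 - 0.999^st$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + 1e-7)
    }
  }
  params
}

# ---------------------------------------------------------------------------
# Architecture forward/backward passes. Each forward returns the output
# plus the caches the matching backward needs; each backward returns the
# parameter gradients named like the parameters.

# cnn1d: Conv1D(16,k7) > ReLU > MaxPool1D(5) > Conv1D(16,k7) > ReLU >
#        GlobalMaxPool > Dense(1, sigmoid)
# X: cube frames x channels x batch
cnn1dForward <- function(params, X) {
  Z1 <- .conv1dForward(X, params$W1, params$b1)
  A1 <- reluFwd(Z1)
  P1 <- .maxpool1dForward(A1, params$pool)
  Z2 <- .conv1dForward(P1$out, params$W2, params$b2)
  A2 <- reluFwd(Z2)
  G <- .globalMaxpool1dForward(A2)
  emb <- t(G$out)                               # batch x filters
  logit <- drop(emb %*% params$Wd) + params$bd
  list(prob = sigmoid(logit), logit = logit, emb = emb, featureMap = A2,
       cache = list(X = X, Z1 = Z1, A1 = A1, P1 = P1, Z2 = Z2, A2 = A2,
                    G = G))
}

cnn1dBackward <- function(params, fwd, dLogit) {
  ca <- fwd$cache
  dWd <- t(fwd$emb) %*% matrix(dLogit, ncol = 1)
  dbd <- sum(dLogit)
  dG <- params$Wd %*% matrix(dLogit, nrow = 1)   # filters x batch
  dA2 <- .globalMaxpool1dBackward(ca$G$idx, dG, nrow(ca$A2))
  dZ2 <- dA2 * (ca$Z2 > 0)
  bw2 <- .conv1dBackward(ca$P1$out, params$W2, dZ2)
  dP1 <- .maxpool1dBackward(ca$P1$idx, bw2$dX, nrow(ca$A1))
  dZ1 <- dP1 * (ca$Z1 > 0)
  bw1 <- .conv1dBackward(ca$X, params$W1, dZ1)
  list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
       Wd = dWd, bd = dbd)
}

initCNN1D <- function(nChannels, filters = 16L, kernel = 7L, pool = 5L) {
  list(W1 = glorotInit(c(kernel, nChannels, filters),
                       kernel * nChannels, filters),
       b1 = numeric(filters),
       W2 = glorotInit(c(kernel, filters, filters),
                       kernel * filters, filters),
       b2 = numeric(filters),
       Wd = glorotInit(c(filters, 1), filters, 1),
       bd = 0,
       pool = pool)
}

# cnn2d: Conv2D(8,1x5) > ReLU > MaxPool(1x3) > Dropout(0.3) >
#        Conv2D(4,1x5) > ReLU > MaxPool(1x3) > Flatten > Dense(1, sigmoid)
# X: array channels x frames x 1 x batch (height = descriptor channels)
cnn2dForward <- function(params, X, train = FALSE, dropMask = NULL) {
  Z1 <- .conv2dForward(X, params$K1, params$b1)
  A1 <- reluFwd(Z1)
  P1 <- .maxpool2dForward(A1, 1L, 3L)
  Dp <- P1$out
  if (train && params$dropout > 0) {
    if (is.null(dropMask))
      dropMask <- array(runif(length(Dp)) >= params$dropout, dim(Dp))
    Dp <- Dp * dropMask / (1 - params$dropout)
  }
  Z2 <- .conv2dForward(Dp, params$K2, params$b2)
  A2 <- reluFwd(Z2)
  P2 <- .maxpool2dForward(A2, 1L, 3L)
  d2 <- dim(P2$out)
  flat <- matrix(P2$out, prod(d2[1:3]), d2[4])    # features x batch
  logit <- drop(t(flat) %*% params$Wd) + params$bd
  list(prob = sigmoid(logit), logit = logit, flat = flat,
       cache = list(X = X, Z1 = Z1, P1 = P1, Dp = Dp, Z2 = Z2, P2 = P2,
                    dropMask = dropMask, d2 = d2))
}

cnn2dBackward <- function(params, fwd, dLogit) {
  ca <- fwd$cache
  dWd <- fwd$flat %*% matrix(dLogit, ncol = 1)
  dbd <- sum(dLogit)
  dFlat <- params$Wd %*% matrix(dLogit, nrow = 1)
  dP2 <- array(dFlat, ca$d2)
  dA2 <- .maxpool2dBackward(ca$P2$idx, dP2, dim(ca$Z2))
  dZ2 <- dA2 * (ca$Z2 > 0)
  bw2 <- .conv2dBackward(ca$Dp, params$K2, dZ2)
  dDp <- bw2$dX
  if (!is.null(ca$dropMask))
    dDp <- dDp * ca$dropMask / (1 - params$dropout)
  dA1 <- .maxpool2dBackward(ca$P1$idx, dDp, dim(ca$Z1))
  dZ1 <- dA1 * (ca$Z1 > 0)
  bw1 <- .conv2dBackward(ca$X, params$K1, dZ1)
  list(K1 = bw1$dK, b1 = bw1$db, K2 = bw2$dK, b2 = bw2$db,
       Wd = dWd, bd = dbd)
}

initCNN2D <- function(nChannels, nFrames, dropout = 0.3) {
  w2 <- ((nFrames - 4L) %/% 3L - 4L) %/% 3L
  flatLen <- nChannels * w2 * 4L
  list(K1 = glorotInit(c(1, 5, 1, 8), 5, 8),
       b1 = numeric(8),
       K2 = glorotInit(c(1, 5, 8, 4), 5 * 8, 4),
       b2 = numeric(4),
       Wd = glorotInit(c(flatLen, 1), flatLen, 1),
       bd = 0,
       dropout = dropout)
}

# cnn2d_cam: 4 x [Conv2D(3x3) > ReLU > MaxPool(2x2)] with 128/64/32/16
# filters, then Flatten > Dense(256, ReLU) > Dense(1, sigmoid).
# X: array H x W x 1 x batch
camForward <- function(params, X) {
  ca <- list(X = X)
  cur <- X
  for (l in 1:4) {
    Z <- .conv2dForward(cur, params[[paste0("K", l)]],
                        params[[paste0("b", l)]])
    A <- reluFwd(Z)
    P <- .maxpool2dForward(A, 2L, 2L)
    ca[[paste0("Z", l)]] <- Z
    ca[[paste0("P", l)]] <- P
    cur <- P$out
  }
  d4 <- dim(cur)
  flat <- matrix(cur, prod(d4[1:3]), d4[4])
  Zd1 <- t(t(params$Wd1) %*% flat + params$bd1)   # batch x 256
  Ad1 <- reluFwd(Zd1)
  logit <- drop(Ad1 %*% params$Wd2) + params$bd2
  list(prob = sigmoid(logit), logit = logit, flat = flat, Zd1 = Zd1,
       Ad1 = Ad1, featureMap = cur,
       cache = c(ca, list(d4 = d4)))
}

camBackward <- function(params, fwd, dLogit) {
  ca <- fwd$cache
  dWd2 <- t(fwd$Ad1) %*% matrix(dLogit, ncol = 1)
  dbd2 <- sum(dLogit)
  dAd1 <- matrix(dLogit, ncol = 1) %*% t(params$Wd2)   # batch x 256
  dZd1 <- dAd1 * (fwd$Zd1 > 0)
  dWd1 <- fwd$flat %*% dZd1                             # features x 256
  dbd1 <- colSums(dZd1)
  dFlat <- params$Wd1 %*% t(dZd1)                       # features x batch
  grads <- list(Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2)
  dCur <- array(dFlat, ca$d4)
  for (l in 4:1) {
    P <- ca[[paste0("P", l)]]
    Z <- ca[[paste0("Z", l)]]
    dA <- .maxpool2dBackward(P$idx, dCur, dim(Z))
    dZ <- dA * (Z > 0)
    below <- if (l == 1) ca$X else ca[[paste0("P", l - 1)]]$out
    bw <- .conv2dBackward(below, params[[paste0("K", l)]], dZ)
    grads[[paste0("K", l)]] <- bw$dK
    grads[[paste0("b", l)]] <- bw$db
    dCur <- bw$dX
  }
  grads
}

camSpatialSizes <- function(inputSize) {
  s <- inputSize
  sizes <- integer(0)
  for (l in 1:4) {
    s <- s - 2L          # valid 3x3 conv
    sizes <- c(sizes, s)
    s <- s %/% 2L        # 2x2 pool
    sizes <- c(sizes, s)
  }
  sizes
}

initCNN2DCAM <- function(inputSize = 320L) {
  filt <- c(128L, 64L, 32L, 16L)
  p <- list()
  cin <- 1L
  for (l in 1:4) {
    p[[paste0("K", l)]] <- glorotInit(c(3, 3, cin, filt[l]),
                                      9 * cin, filt[l])
    p[[paste0("b", l)]] <- numeric(filt[l])
    cin <- filt[l]
  }
  s <- camSpatialSizes(inputSize)
  final <- s[length(s)]
  flatLen <- final * final * 16L
  p$Wd1 <- glorotInit(c(flatLen, 256), flatLen, 256)
  p$bd1 <- numeric(256)
  p$Wd2 <- glorotInit(c(256, 1), 256, 1)
  p$bd2 <- 0
  p$inputSize <- inputSize
  p
}

# cnn1d forecaster: Conv1D(16,k7) > ReLU > GlobalMaxPool > Dense(1, linear)
cnn1dRegForward <- function(params, X) {
  Z1 <- .conv1dForward(X, params$W1, params$b1)
  A1 <- reluFwd(Z1)
  G <- .globalMaxpool1dForward(A1)
  emb <- t(G$out)
  pred <- drop(emb %*% params$Wd) + params$bd
  list(pred = pred, emb = emb,
       cache = list(X = X, Z1 = Z1, A1 = A1, G = G))
}

cnn1dRegBackward <- function(params, fwd, dPred) {
  ca <- fwd$cache
  dWd <- t(fwd$emb) %*% matrix(dPred, ncol = 1)
  dbd <- sum(dPred)
  dG <- params$Wd %*% matrix(dPred, nrow = 1)
  dA1 <- .globalMaxpool1dBackward(ca$G$idx, dG, nrow(ca$A1))
  dZ1 <- dA1 * (ca$Z1 > 0)
  bw1 <- .conv1dBackward(ca$X, params$W1, dZ1)
  list(W1 = bw1$dW, b1 = bw1$db, Wd = dWd, bd = dbd)
}
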