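## Minimal neural-network engine used by the three stage models. Everything
## is batch-major base R: a batch of feature maps is a B x (C*H*W) matrix in
## "f-order" (channel fastest: f = c + C*(h-1) + C*H*(w-1)), convolutions are
## im2col + one BLAS matmul, gradients are hand-derived per layer, and
## optimization is Adam. Deliberately small: just the layers these models
## need, on CPU, deterministic given a seed.

## ---- initialization -------------------------------------------------------

nn_dense_init <- function(n_in, n_out) {
  ## He-style fan-in scaling suits the ReLU blocks used throughout.
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

## ---- index tables for im2col ---------------------------------------------

## 2-D convolution, valid padding, stride 1, K x K kernel over C channels of
## an H x W map. Rows r = c + C*((kh-1) + K*(kw-1)); columns enumerate output
## positions p = oh + OH*(ow-1). Entries are f-order feature indices.
im2col_idx2d <- function(C, H, W, K) {
  OH <- H - K + 1L
  OW <- W - K + 1L
  r <- expand.grid(c = seq_len(C), kh = seq_len(K), kw = seq_len(K))
  p <- expand.grid(oh = seq_len(OH), ow = seq_len(OW))
  idx <- matrix(0L, nrow(r), nrow(p))
  for (j in seq_len(nrow(p))) {
    h <- p$oh[j] + r$kh - 1L
    w <- p$ow[j] + r$kw - 1L
    idx[, j] <- r$c + C * ((h - 1L) + H * (w - 1L))
  }
  list(idx = idx, OH = OH, OW = OW, R = nrow(r), P = nrow(p))
}

## 1-D convolution over C channels of length-L maps, width-K kernel.
im2col_idx1d <- function(C, L, K) {
  OL <- L - K + 1L
  r <- expand.grid(c = seq_len(C), k = seq_len(K))
  idx <- matrix(0L, nrow(r), OL)
  for (p in seq_len(OL)) {
    idx[, p] <- r$c + C * (p + r$k - 2L)
  }
  list(idx = idx, OH = OL, OW = 1L, R = nrow(r), P = OL)
}

## ---- convolution forward/backward ----------------------------------------

## X: B x (C*H*W); W: (C*K*K) x Fout; returns list(out = B x (Fout*P), cache).
conv_forward <- function(X, Wt, b, ii) {
  B <- nrow(X)
  cols <- X[, as.vector(ii$idx), drop = FALSE]
  dim(cols) <- c(B, ii$R, ii$P)
  XP <- aperm(cols, c(1L, 3L, 2L))
  dim(XP) <- c(B * ii$P, ii$R)
  Y <- XP %*% Wt
  Y <- sweep(Y, 2L, b, "+")
  dim(Y) <- c(B, ii$P, ncol(Wt))
  out <- aperm(Y, c(1L, 3L, 2L))          # (B, Fout, P), channel fastest
  dim(out) <- c(B, ncol(Wt) * ii$P)
  list(out = out, XP = XP)
}

conv_backward <- function(dOut, Wt, ii, XP, n_feat_in) {
  B <- nrow(dOut)
  Fout <- ncol(Wt)
  dim(dOut) <- c(B, Fout, ii$P)
  dYm <- aperm(dOut, c(1L, 3L, 2L))
  dim(dYm) <- c(B * ii$P, Fout)
  dW <- crossprod(XP, dYm)
  db <- colSums(dYm)
  dXP <- dYm %*% t(Wt)                     # (B*P) x R
  dim(dXP) <- c(B, ii$P, ii$R)
  dX <- matrix(0, B, n_feat_in)
  for (r in seq_len(ii$R)) {
    cols <- ii$idx[r, ]
    dX[, cols] <- dX[, cols] + dXP[, , r]
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- 2x2 max pooling ------------------------------------------------------

pool_forward <- function(X, C, H, W) {
  B <- nrow(X)
  A <- X
  dim(A) <- c(B, C, H, W)
  ho <- seq(1L, H, 2L); he <- seq(2L, H, 2L)
  wo <- seq(1L, W, 2L); we <- seq(2L, W, 2L)
  s1 <- A[, , ho, wo, drop = FALSE]
  s2 <- A[, , he, wo, drop = FALSE]
  s3 <- A[, , ho, we, drop = FALSE]
  s4 <- A[, , he, we, drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  m1 <- s1 == out
  m2 <- (s2 == out) & !m1
  m3 <- (s3 == out) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  dim(out) <- c(B, C * (H %/% 2L) * (W %/% 2L))
  list(out = out, masks = list(m1, m2, m3, m4), C = C, H = H, W = W)
}

pool_backward <- function(dOut, cache) {
  B <- nrow(dOut)
  C <- cache$C; H <- cache$H; W <- cache$W
  dim(dOut) <- c(B, C, H %/% 2L, W %/% 2L)
  dA <- array(0, c(B, C, H, W))
  ho <- seq(1L, H, 2L); he <- seq(2L, H, 2L)
  wo <- seq(1L, W, 2L); we <- seq(2L, W, 2L)
  dA[, , ho, wo] <- dOut * cache$masks[[1L]]
  dA[, , he, wo] <- dA[, , he, wo, drop = FALSE] + dOut * cache$masks[[2L]]
  dA[, , ho, we] <- dA[, , ho, we, drop = FALSE] + dOut * cache$masks[[3L]]
  dA[, , he, we] <- dA[, , he, we, drop = FALSE] + dOut * cache$masks[[4L]]
  dim(dA) <- c(B, C * H * W)
  dA
}

## ---- simple layers --------------------------------------------------------

relu <- function(X) X * (X > 0)
relu_backward <- function(dY, X) dY * (X > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

dense_forward <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

## Row-wise softmax (classification head).
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Softmax over each 4-row column group of a B x (4*L) activation matrix
## (base index fastest). Returns same shape, every group summing to 1.
softmax_columns4 <- function(Z, L) {
  B <- nrow(Z)
  dim(Z) <- c(B, 4L, L)
  M <- apply(Z, c(1L, 3L), max)
  Z <- Z - aperm(array(M, c(B, L, 4L)), c(1L, 3L, 2L))
  E <- exp(Z)
  S <- colSums(aperm(E, c(2L, 1L, 3L)))    # B x L sums over the 4 bases
  Y <- E / aperm(array(S, c(B, L, 4L)), c(1L, 3L, 2L))
  dim(Y) <- c(B, 4L * L)
  Y
}

## Backward through the grouped softmax: dZ_i = y_i * (dY_i - sum_j dY_j y_j)
## within each 4-row group.
softmax_columns4_backward <- function(dY, Y, L) {
  B <- nrow(Y)
  dim(dY) <- c(B, 4L, L)
  dim(Y) <- c(B, 4L, L)
  S <- colSums(aperm(dY * Y, c(2L, 1L, 3L)))   # B x L
  dZ <- Y * (dY - aperm(array(S, c(B, L, 4L)), c(1L, 3L, 2L)))
  dim(dZ) <- c(B, 4L * L)
  dZ
}

## ---- Adam -----------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## Deterministic fingerprint of a parameter list (frozen-weights checks).
params_checksum <- function(params) {
  sum(vapply(params, function(p) sum(p * seq_along(p)), numeric(1)))
}
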