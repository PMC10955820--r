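## Numerical checks of the internal network engine: layer forwards against
## naive re-implementations and analytic gradients against finite
## differences. Everything here uses hybriclass's internal helpers.

naive_conv1d <- function(X, W, b, C, L, K) {
  ## X: single row (1 x C*L, channel fastest); W: (C*K) x F
  Fout <- ncol(W)
  OL <- L - K + 1
  out <- matrix(0, Fout, OL)
  xs <- matrix(X, C, L)
  for (p in seq_len(OL)) {
    patch <- as.vector(xs[, p:(p + K - 1)])
    out[, p] <- drop(crossprod(W, patch)) + b
  }
  out
}

test_that("im2col convolution equals a naive sliding window", {
  set.seed(501)
  C <- 3L; L <- 11L; K <- 4L; Fo <- 5L
  ii <- hybriclass:::im2col_idx1d(C, L, K)
  W <- matrix(rnorm(C * K * Fo), C * K, Fo)
  b <- rnorm(Fo)
  X <- matrix(rnorm(2 * C * L), 2, C * L)
  out <- hybriclass:::conv_forward(X, W, b, ii)$out
  for (r in 1:2) {
    naive <- naive_conv1d(X[r, , drop = FALSE], W, b, C, L, K)
    got <- matrix(out[r, ], Fo, L - K + 1)
    expect_equal(got, naive, tolerance = 1e-12)
  }
})

test_that("2x2 max pooling picks maxima and routes gradients to them", {
  set.seed(502)
  X <- matrix(rnorm(1 * 2 * 4 * 4), 1, 32)
  pc <- hybriclass:::pool_forward(X, 2L, 4L, 4L)
  A <- array(X, c(1, 2, 4, 4))
  expect_equal(pc$out[1, 1], max(A[1, 1, 1:2, 1:2]))
  dOut <- matrix(1, 1, 8)
  dX <- hybriclass:::pool_backward(dOut, pc)
  expect_equal(sum(dX), 8)                      # one unit per pooled cell
  expect_equal(sum(dX != 0), 8)
})

test_that("grouped column softmax normalizes and matches per-column softmax", {
  set.seed(503)
  L <- 7L
  Z <- matrix(rnorm(2 * 4 * L), 2, 4 * L)
  Y <- hybriclass:::softmax_columns4(Z, L)
  for (b in 1:2) {
    m <- matrix(Y[b, ], 4, L)
    expect_equal(colSums(m), rep(1, L), tolerance = 1e-12)
    zm <- matrix(Z[b, ], 4, L)
    ref <- apply(zm, 2, function(col) exp(col - max(col)) /
                   sum(exp(col - max(col))))
    expect_equal(m, ref, tolerance = 1e-12)
  }
})

test_that("predictor gradients agree with finite differences", {
  set.seed(504)
  model <- build_predictor(seed = 9, length = 15L)
  X <- matrix(runif(2 * 8 * 15), 2, 8 * 15)
  y0 <- c(0.2, 0.9)
  loss_of <- function(m) {
    fw <- hybriclass:::predictor_forward(m, X)
    sum((fw$yield - y0)^2)
  }
  fw <- hybriclass:::predictor_forward(model, X, keep_cache = TRUE)
  bw <- hybriclass:::predictor_backward(model, fw$cache,
                                        2 * (fw$yield - y0))
  eps <- 1e-6
  for (nm in c("W1", "W2", "W3", "W4", "b2", "b4")) {
    idx <- sample(length(model$params[[nm]]), min(4, length(model$params[[nm]])))
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s[%d]", nm, i))
    }
  }
  ## gradient w.r.t. the (soft) input: finite differences again
  idx <- sample(length(X), 6)
  for (i in idx) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    num <- (sum((hybriclass:::predictor_forward(model, Xp)$yield - y0)^2) -
              sum((hybriclass:::predictor_forward(model, Xm)$yield - y0)^2)) /
      (2 * eps)
    expect_equal(bw$dX[i], num, tolerance = 1e-4)
  }
})

test_that("encoder gradients agree with finite differences", {
  set.seed(505)
  enc <- build_encoder(seed = 10, hidden = 12L, length = 6L)
  FT <- matrix(rnorm(3 * 50), 3, 50)
  W <- matrix(rnorm(3 * 24), 3, 24)   # arbitrary linear readout of Y
  loss_of <- function(m) {
    Y <- hybriclass:::encoder_forward(m, FT)$Y
    sum(W * Y)
  }
  fw <- hybriclass:::encoder_forward(enc, FT, keep_cache = TRUE)
  g <- hybriclass:::encoder_backward(enc, fw$cache, W)
  eps <- 1e-6
  for (nm in names(enc$params)) {
    idx <- sample(length(enc$params[[nm]]), min(4, length(enc$params[[nm]])))
    for (i in idx) {
      mp <- enc; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- enc; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("Adam descends a simple quadratic", {
  params <- list(w = matrix(c(5, -3), 1))
  st <- hybriclass:::adam_state(params)
  for (i in 1:500) {
    g <- list(w = 2 * params$w)
    up <- hybriclass:::adam_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(max(abs(params$w)), 1e-3)
})
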