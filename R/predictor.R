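## Stage 2: a two-layer convolutional regressor that approximates the
## thermodynamic yield oracle on one-hot sequence pairs. Its only purpose is
## to make stage-3 encoder training differentiable; classification-time
## yields always come from the thermo backend.
##
## Input geometry: a pair (first, second) becomes an 8-channel length-L map,
## channels 1-4 the one-hot rows (A,T,C,G) of `first`, channels 5-8 the
## one-hot rows of reverse_complement(second). Soft base matrices are
## admitted in both slots so the encoder can feed its softmax output through
## unchanged.

#' Soft reverse complement of a base matrix
#'
#' Reverses the column order and swaps the A/T and C/G rows. On one-hot
#' matrices this coincides with the discrete reverse complement; on soft
#' matrices it is the natural continuous extension (and an involution), which
#' is what lets gradients flow through the second encoder call.
#'
#' @param m A 4 x L base matrix (rows A, T, C, G), hard or soft.
#' @return A 4 x L base matrix.
#' @export
soft_reverse_complement <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  out <- m[c(2L, 1L, 4L, 3L), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

as_base_matrix <- function(x) {
  if (is.character(x)) one_hot(x) else {
    stopifnot(is.matrix(x), nrow(x) == 4L)
    x
  }
}

#' Assemble a predictor input from a sequence pair
#'
#' @param first,second DNA sequences or 4 x L base matrices (soft matrices
#'   are allowed; the second slot is soft-reverse-complemented).
#' @return An 8 x L matrix: rows 1-4 the base matrix of `first`, rows 5-8
#'   the (soft) reverse complement of `second`.
#' @export
make_predictor_input <- function(first, second) {
  m1 <- as_base_matrix(first)
  m2 <- soft_reverse_complement(as_base_matrix(second))
  if (ncol(m1) != ncol(m2)) {
    stop("first and second must have equal length", call. = FALSE)
  }
  rbind(m1, m2)
}

## Batch one-hot builder: B x (8*L) matrix in channel-fastest order from two
## equal-length character vectors (second is reverse-complemented).
build_pred_inputs <- function(first, second, L) {
  B <- length(first)
  X <- matrix(0, B, 8L * L)
  off <- 8L * (seq_len(L) - 1L)
  for (i in seq_len(B)) {
    i1 <- match(strsplit(first[[i]], "", fixed = TRUE)[[1L]], DNA_BASES)
    i2 <- match(strsplit(reverse_complement(second[[i]]), "",
                         fixed = TRUE)[[1L]], DNA_BASES)
    X[i, i1 + off] <- 1
    X[i, i2 + 4L + off] <- 1
  }
  X
}

## Interleave two B x (4*L) soft batches into the 8-channel layout.
interleave_channels <- function(A, B4, L) {
  B <- nrow(A)
  X <- matrix(0, B, 8L * L)
  for (c in 1:4) {
    X[, c + 8L * (seq_len(L) - 1L)] <- A[, c + 4L * (seq_len(L) - 1L)]
    X[, c + 4L + 8L * (seq_len(L) - 1L)] <- B4[, c + 4L * (seq_len(L) - 1L)]
  }
  X
}

#' Build an untrained yield predictor
#'
#' Two 1-D convolutional layers over the 8 x L input (width-5 kernels, 32
#' channels each, ReLU): the first layer can realize base-pair match gates
#' at small strand offsets, the second contiguous-stack patterns. The feature maps are averaged over positions
#' (global average pooling -- duplex stability is a sum of local stack
#' contributions, so the head should aggregate, not memorize positions)
#' and passed through a small ReLU layer and a sigmoid-squashed scalar
#' head, so predictions are always a fraction in `[0, 1]`.
#'
#' @param seed Integer seed for deterministic initialization.
#' @param length Sequence length L (default 59).
#' @param kernels Widths of the two convolution kernels.
#' @param channels Channel counts of the two convolution layers.
#' @return An object of class `yield_predictor`.
#' @export
build_predictor <- function(seed = 1L, length = 59L, kernels = c(5L, 5L),
                            channels = c(32L, 32L)) {
  L <- as.integer(length)
  L1 <- L - kernels[1L] + 1L
  L2 <- L1 - kernels[2L] + 1L
  params <- with_seed(seed, {
    c1 <- nn_dense_init(8L * kernels[1L], channels[1L])
    c2 <- nn_dense_init(channels[1L] * kernels[2L], channels[2L])
    h1 <- nn_dense_init(channels[2L], 48L)
    h2 <- nn_dense_init(48L, 1L)
    list(W1 = c1$W, b1 = c1$b, W2 = c2$W, b2 = c2$b,
         W3 = h1$W, b3 = h1$b, W4 = h2$W, b4 = h2$b)
  })
  structure(list(params = params, length = L, L1 = L1, L2 = L2,
                 channels = channels,
                 ii1 = im2col_idx1d(8L, L, kernels[1L]),
                 ii2 = im2col_idx1d(channels[1L], L1, kernels[2L]),
                 trained = FALSE, seed = as.integer(seed),
                 loss_trace = numeric(0), holdout_mse = NA_real_,
                 holdout = integer(0)),
            class = "yield_predictor")
}

predictor_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  z1 <- conv_forward(X, p$W1, p$b1, model$ii1)
  a1 <- relu(z1$out)
  z2 <- conv_forward(a1, p$W2, p$b2, model$ii2)
  a2 <- relu(z2$out)
  L2 <- model$L2
  g <- a2
  dim(g) <- c(nrow(a2), model$channels[2L], L2)
  gap <- colMeans(aperm(g, c(3L, 1L, 2L)))   # B x 32 position average
  z3 <- dense_forward(gap, p$W3, p$b3)
  a3 <- relu(z3)
  z4 <- dense_forward(a3, p$W4, p$b4)
  y <- as.numeric(sigmoid(z4))
  out <- list(yield = y)
  if (keep_cache) {
    out$cache <- list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, gap = gap,
                      z3 = z3, a3 = a3, y = y)
  }
  out
}

## dLoss/dyield -> parameter grads and input grads (for stage 3).
predictor_backward <- function(model, cache, dy) {
  p <- model$params
  dz4 <- matrix(dy * cache$y * (1 - cache$y), ncol = 1L)
  d4 <- dense_backward(dz4, cache$a3, p$W4)
  dz3 <- relu_backward(d4$dX, cache$z3)
  d3 <- dense_backward(dz3, cache$gap, p$W3)
  L2 <- model$L2
  ch2 <- model$channels[2L]
  dgap <- array(d3$dX / L2, c(nrow(d3$dX), ch2, L2))  # spread over positions
  dim(dgap) <- c(nrow(d3$dX), ch2 * L2)
  dz2 <- relu_backward(dgap, cache$z2$out)
  d2 <- conv_backward(dz2, p$W2, model$ii2, cache$z2$XP,
                      model$channels[1L] * model$L1)
  dz1 <- relu_backward(d2$dX, cache$z1$out)
  d1 <- conv_backward(dz1, p$W1, model$ii1, cache$z1$XP, 8L * model$length)
  list(grads = list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db,
                    W3 = d3$dW, b3 = d3$db, W4 = d4$dW, b4 = d4$db),
       dX = d1$dX)
}

#' Train the yield predictor on labeled sequence pairs
#'
#' Minimizes the mean square error between predicted and labeled yields with
#' Adam. A random holdout split is carved off before training and its MSE is
#' reported; its row indices are kept on the model so rank-correlation
#' checks can reuse exactly the pairs the optimizer never saw.
#'
#' @param model A [build_predictor()] object.
#' @param pairs Data frame with columns `first`, `second`, `yield` (e.g. from
#'   [generate_pairs()]).
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param holdout_frac Fraction of pairs held out (default 0.1).
#' @param seed Seed for the split and shuffling (defaults to build seed).
#' @return The trained model with `holdout_mse`, `holdout` indices and a
#'   per-epoch `loss_trace`.
#' @export
train_predictor <- function(model, pairs, epochs = 10L, batch_size = 128L,
                            lr = 2e-3, holdout_frac = 0.1, seed = NULL) {
  stopifnot(inherits(model, "yield_predictor"))
  n <- nrow(pairs)
  if (is.null(n) || n == 0L) stop("empty training corpus", call. = FALSE)
  if (n < 100L) stop("need at least 100 pairs", call. = FALSE)
  if (is.null(seed)) seed <- model$seed + 1L

  with_seed(seed, {
    X <- build_pred_inputs(pairs$first, pairs$second, model$length)
    y <- pairs$yield
    ho <- sort(sample.int(n, max(1L, round(holdout_frac * n))))
    tr <- setdiff(seq_len(n), ho)
    params <- model$params
    st <- adam_state(params)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- tr[sample.int(length(tr))]
      tot <- 0
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(ord))]
        model$params <- params
        fw <- predictor_forward(model, X[bi, , drop = FALSE],
                                keep_cache = TRUE)
        resid <- fw$yield - y[bi]
        tot <- tot + sum(resid^2)
        bw <- predictor_backward(model, fw$cache, 2 * resid / length(bi))
        up <- adam_step(params, bw$grads, st, lr)
        params <- up$params
        st <- up$state
      }
      trace[ep] <- tot / length(ord)
    }
    model$params <- params
    model$trained <- TRUE
    model$loss_trace <- trace
    pred <- predictor_forward(model, X[ho, , drop = FALSE])$yield
    model$holdout_mse <- mean((pred - y[ho])^2)
    model$holdout <- ho
    model
  })
}

#' Predict hybridization yield for sequence pairs with the neural surrogate
#'
#' @param object A trained [yield_predictor].
#' @param first,second Equal-length character vectors of DNA sequences, or a
#'   single pair of soft 4 x L base matrices.
#' @param ... Unused.
#' @return Numeric vector of estimated yields in `[0, 1]`.
#' @export
predict.yield_predictor <- function(object, first, second, ...) {
  if (!object$trained) {
    warning("predictor has not been trained; outputs are arbitrary")
  }
  if (is.matrix(first) || is.matrix(second)) {
    inp <- make_predictor_input(first, second)
    X <- matrix(as.vector(inp), 1L)    # 8 x L column-major == channel-fastest
    return(predictor_forward(object, X)$yield)
  }
  stopifnot(length(first) == length(second))
  X <- build_pred_inputs(as.character(first), as.character(second),
                         object$length)
  out <- numeric(nrow(X))
  for (start in seq(1L, nrow(X), by = 512L)) {
    bi <- start:min(start + 511L, nrow(X))
    out[bi] <- predictor_forward(object, X[bi, , drop = FALSE])$yield
  }
  out
}

#' @export
print.yield_predictor <- function(x, ...) {
  cat(sprintf("Two-layer CNN yield predictor (L = %d)%s\n", x$length,
              if (x$trained) sprintf(" - trained, holdout MSE %.4f",
                                     x$holdout_mse) else " - untrained"))
  invisible(x)
}
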