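## Stage 3: the encoder maps 50-D feature vectors to soft 4 x 59 base
## matrices. Its loss couples column confidence (encoding loss) with
## similarity supervision (sequence loss): image pairs that are close in
## feature space and share a label should produce high predicted yield,
## distant different-label pairs low yield. The feature extractor and the
## yield predictor are frozen throughout.

#' Encoder loss configuration
#'
#' @param t1 Euclidean-distance threshold in raw FC2 units (default 16, the
#'   value used with MNIST features; see [calibrate_t1()] for other
#'   corpora).
#' @param t2 Yield threshold in `(0, 1)` (default 0.8).
#' @param confidence_threshold Column-confidence cutoff of the encoding loss
#'   (default 0.5).
#' @param mode `"surrogate"` (default: hinge relaxation of the 0/1 sequence
#'   loss, used for training) or `"literal"` (the exact 0/1 table, retained
#'   for fidelity checks; piecewise constant, so it provides no gradient).
#' @param margin Training margin added to the hinge targets: where high
#'   yield is desired the hinge pushes the predicted yield up to
#'   `min(t2 + margin, 1)`, where low yield is desired down to
#'   `max(t2 - margin, 0)`. With `margin = 0` the hinges sit exactly at
#'   `t2` and the surrogate vanishes wherever the literal loss vanishes;
#'   a positive margin keeps pushing past the decision threshold, which
#'   the yield-sum classifier needs because the surrogate's cliff is
#'   smoother than the oracle's (see the vignette).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(t1 = 16, t2 = 0.8, confidence_threshold = 0.5,
                        mode = c("surrogate", "literal"), margin = 0) {
  mode <- match.arg(mode)
  if (!(t1 > 0)) stop("t1 must be positive", call. = FALSE)
  if (!(t2 > 0 && t2 < 1)) stop("t2 must lie in (0, 1)", call. = FALSE)
  if (margin < 0 || margin > 1) stop("margin must lie in [0, 1]",
                                     call. = FALSE)
  structure(list(t1 = t1, t2 = t2,
                 confidence_threshold = confidence_threshold, mode = mode,
                 margin = margin),
            class = "loss_config")
}

#' Column-confidence (encoding) loss of a soft base matrix
#'
#' For each of the L columns `Y_i` of the encoder output: if
#' `max(Y_i) < confidence_threshold`, the column contributes the
#' cross-entropy between `Y_i` and the one-hot indicator of its own argmax
#' (ties resolved A < T < C < G); confident columns contribute 0, avoiding
#' an over-solid penalty once a column has committed to a base. The total is
#' the sum over columns, so a fully ambiguous uniform column contributes
#' `-log(1/4) = log 4`.
#'
#' @param m A soft 4 x L base matrix; every column must sum to 1.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar.
#' @export
encoding_loss <- function(m, cfg = loss_config()) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6) || any(m < -1e-12)) {
    stop("encoder output columns must be normalized (softmax)", call. = FALSE)
  }
  mx <- apply(m, 2L, max)
  active <- mx < cfg$confidence_threshold
  ## CE against one-hot(argmax) reduces to -log of the column maximum.
  sum(-log(pmax(mx[active], 1e-12)))
}

#' Similarity-supervision (sequence) loss for one image pair
#'
#' In `"literal"` mode, returns the 0/1 truth table over feature distance
#' `e`, predicted yield `yield` and the two labels: loss 1 when a close
#' same-label pair has low yield (`e < t1`, `yield < t2`, `l1 == l2`) or a
#' distant different-label pair has high yield (`e >= t1`, `yield >= t2`,
#' `l1 != l2`); loss 0 otherwise, including the close different-label
#' low-yield case (low yield for different labels is desirable regardless of
#' feature distance). In `"surrogate"` mode each loss-1 branch is replaced
#' by a hinge -- `max(0, t2 - yield)` where high yield is desired,
#' `max(0, yield - t2)` where low yield is desired -- which is continuous in
#' the yield and gives the training signal the 0/1 table cannot; with
#' `margin = 0` it vanishes exactly where the literal loss is 0, and a
#' positive `margin` moves the hinge targets past `t2` (see `margin`).
#'
#' @param e Feature-space Euclidean distance(s), non-negative.
#' @param yield Predicted yield(s) in `[0, 1]`.
#' @param l1,l2 Class labels.
#' @param cfg A [loss_config()]; `cfg$mode` selects the variant.
#' @return Numeric vector of losses.
#' @export
sequence_loss <- function(e, yield, l1, l2, cfg = loss_config()) {
  want_high <- (e < cfg$t1) & (l1 == l2)
  want_low <- (e >= cfg$t1) & (l1 != l2)
  if (cfg$mode == "literal") {
    as.numeric((want_high & yield < cfg$t2) | (want_low & yield >= cfg$t2))
  } else {
    hi <- min(cfg$t2 + cfg$margin, 1)
    lo <- max(cfg$t2 - cfg$margin, 0)
    want_high * pmax(0, hi - yield) + want_low * pmax(0, yield - lo)
  }
}

#' Total encoder loss for one image pair
#'
#' Encoding loss of both outputs of the double encoder call plus the
#' sequence loss of the pair.
#'
#' @param m1,m2 The two soft 4 x L encoder outputs.
#' @param e,yield,l1,l2 Pair context as in [sequence_loss()].
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
encoder_loss <- function(m1, m2, e, yield, l1, l2, cfg = loss_config()) {
  encoding_loss(m1, cfg) + encoding_loss(m2, cfg) +
    sequence_loss(e, yield, l1, l2, cfg)
}

#' Build an untrained feature-to-sequence encoder
#'
#' Two linear layers (50 -> `hidden` with ReLU, `hidden` -> 4L) with a
#' column-wise softmax, so each of the L output columns is a distribution
#' over the four bases.
#'
#' @param seed Integer seed for deterministic initialization.
#' @param hidden Width of the first linear layer (default 128).
#' @param length Output sequence length L (default 59).
#' @return An object of class `seq_encoder`.
#' @export
build_encoder <- function(seed = 1L, hidden = 128L, length = 59L) {
  L <- as.integer(length)
  params <- with_seed(seed, {
    f1 <- nn_dense_init(50L, hidden)
    f2 <- nn_dense_init(hidden, 4L * L)
    list(W1 = f1$W, b1 = f1$b, W2 = f2$W, b2 = f2$b)
  })
  structure(list(params = params, hidden = as.integer(hidden), length = L,
                 trained = FALSE, seed = as.integer(seed),
                 loss_trace = numeric(0), cfg = NULL),
            class = "seq_encoder")
}

encoder_forward <- function(model, FT, keep_cache = FALSE) {
  p <- model$params
  z1 <- dense_forward(FT, p$W1, p$b1)
  a1 <- relu(z1)
  z2 <- dense_forward(a1, p$W2, p$b2)
  Y <- softmax_columns4(z2, model$length)
  out <- list(Y = Y)
  if (keep_cache) out$cache <- list(FT = FT, z1 = z1, a1 = a1, Y = Y)
  out
}

## dY: grad wrt the softmax output; dZ_extra: grad applied directly at the
## logits (the encoding-loss shortcut (Y - T)).
encoder_backward <- function(model, cache, dY, dZ_extra = NULL) {
  p <- model$params
  dZ <- softmax_columns4_backward(dY, cache$Y, model$length)
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  d2 <- dense_backward(dZ, cache$a1, p$W2)
  da1 <- relu_backward(d2$dX, cache$z1)
  d1 <- dense_backward(da1, cache$FT, p$W1)
  list(W1 = d1$dW, b1 = d1$db, W2 = d2$dW, b2 = d2$db)
}

## Batched soft reverse complement of a B x (4*L) soft batch; self-adjoint.
softrc_batch <- function(Y, L) {
  B <- nrow(Y)
  dim(Y) <- c(B, 4L, L)
  Y <- Y[, c(2L, 1L, 4L, 3L), rev(seq_len(L)), drop = FALSE]
  dim(Y) <- c(B, 4L * L)
  Y
}

## Per-(pair, column) maxima and argmaxes of a B x (4*L) soft batch; ties
## take the lowest base index (A < T < C < G).
column_max_argmax <- function(Y, L) {
  B <- nrow(Y)
  dim(Y) <- c(B, 4L, L)
  M <- aperm(Y, c(1L, 3L, 2L))
  dim(M) <- c(B * L, 4L)
  amax <- max.col(M, ties.method = "first")
  list(mx = matrix(M[cbind(seq_len(B * L), amax)], B, L),
       amax = matrix(amax, B, L))
}

#' Calibrate the distance threshold T1 on a feature corpus
#'
#' The default threshold of 16 raw FC2 units is tied to the geometry MNIST
#' features happen to have; on another corpus the same number is
#' meaningless. T1's role in the sequence loss is to separate "visually
#' close" pairs (driven to high yield when labels agree) from "visually
#' far" pairs (driven to low yield when labels differ); pairs with
#' different labels closer than T1 receive no supervision at all, so a T1
#' placed above the typical between-class distance silently exempts whole
#' confusable class pairs from separation. With labels available the
#' threshold is therefore placed at the boundary between the two distance
#' distributions: the midpoint of the 90th percentile of within-class and
#' the 10th percentile of between-class distances. Without labels a low
#' percentile of all pairwise distances is used.
#'
#' @param features `N x 50` feature matrix (from [extract_features()]).
#' @param labels Optional class labels aligned with `features`.
#' @param prob Percentile of all pairwise distances used when `labels` is
#'   `NULL` (default 0.3).
#' @param n_pairs Number of random pairs sampled (default 20000).
#' @param seed Seed for the pair sample.
#' @return The calibrated threshold (scalar).
#' @export
calibrate_t1 <- function(features, labels = NULL, prob = 0.3,
                         n_pairs = 20000L, seed = 1L) {
  N <- nrow(features)
  stopifnot(N >= 2L)
  with_seed(seed, {
    i <- sample.int(N, n_pairs, replace = TRUE)
    j <- sample.int(N, n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- sqrt(rowSums((features[i, , drop = FALSE] -
                         features[j, , drop = FALSE])^2))
    if (is.null(labels)) return(as.numeric(quantile(d, prob)))
    same <- labels[i] == labels[j]
    if (!any(same) || all(same)) return(as.numeric(quantile(d, prob)))
    as.numeric(quantile(d[same], 0.9) + quantile(d[!same], 0.1)) / 2
  })
}

#' Train the encoder against frozen feature extractor and yield predictor
#'
#' Iterates over sampled image pairs. For each pair the (single) feature
#' extractor and encoder are called twice; the predictor input is assembled
#' from the first soft output and the soft reverse complement of the second;
#' the predicted yield, the feature distance and the labels enter the
#' encoder loss, and only encoder parameters are updated. Pair sampling
#' forces a same-label partner for half the pairs so both supervision
#' branches stay populated.
#'
#' @param feature_model Trained, frozen [feature_extractor].
#' @param predictor_model Trained, frozen [yield_predictor].
#' @param images `N x 28 x 28` array.
#' @param labels Integer labels, length `N`.
#' @param encoder A [build_encoder()] object (a fresh one is built when
#'   omitted).
#' @param cfg A [loss_config()]; `mode = "literal"` trains with the exact
#'   0/1 sequence loss, which is piecewise constant -- a warning is issued
#'   because only the encoding loss then provides gradient.
#' @param epochs,pairs_per_epoch,batch_size,lr Training hyperparameters.
#' @param same_frac Fraction of sampled pairs forced to share a label.
#' @param seed Seed for pair sampling.
#' @return The trained `seq_encoder`, with `loss_trace` and the `cfg` used.
#' @export
train_encoder <- function(feature_model, predictor_model, images, labels,
                          encoder = NULL, cfg = loss_config(), epochs = 3L,
                          pairs_per_epoch = 6000L, batch_size = 128L,
                          lr = 1e-3, same_frac = 0.5, seed = 1L) {
  stopifnot(inherits(feature_model, "feature_extractor"),
            inherits(predictor_model, "yield_predictor"),
            inherits(cfg, "loss_config"))
  if (!feature_model$trained || !predictor_model$trained) {
    stop("feature extractor and predictor must be trained (and frozen) first",
         call. = FALSE)
  }
  if (cfg$mode == "literal") {
    warning(paste("literal sequence loss is piecewise constant;",
                  "only the encoding loss provides gradient"))
  }
  labels <- as.integer(labels)
  if (is.null(encoder)) encoder <- build_encoder(seed = seed)
  L <- encoder$length
  stopifnot(predictor_model$length == L)

  FT_all <- extract_features(feature_model, images)
  by_label <- split(seq_along(labels), labels)

  with_seed(seed, {
    params <- encoder$params
    st <- adam_state(params)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      tot <- 0
      n_done <- 0L
      for (start in seq(1L, pairs_per_epoch, by = batch_size)) {
        B <- min(batch_size, pairs_per_epoch - start + 1L)
        i <- sample.int(nrow(FT_all), B, replace = TRUE)
        force_same <- runif(B) < same_frac
        j <- integer(B)
        for (b in seq_len(B)) {
          j[b] <- if (force_same[b]) {
            pool <- by_label[[as.character(labels[i[b]])]]
            pool[sample.int(length(pool), 1L)]
          } else sample.int(nrow(FT_all), 1L)
        }
        F1 <- FT_all[i, , drop = FALSE]
        F2 <- FT_all[j, , drop = FALSE]
        E <- sqrt(rowSums((F1 - F2)^2))
        l1 <- labels[i]; l2 <- labels[j]

        encoder$params <- params
        e1 <- encoder_forward(encoder, F1, keep_cache = TRUE)
        e2 <- encoder_forward(encoder, F2, keep_cache = TRUE)
        RC2 <- softrc_batch(e2$Y, L)
        X <- interleave_channels(e1$Y, RC2, L)
        pf <- predictor_forward(predictor_model, X, keep_cache = TRUE)
        Yh <- pf$yield

        sl <- sequence_loss(E, Yh, l1, l2, cfg)
        want_high <- (E < cfg$t1) & (l1 == l2)
        want_low <- (E >= cfg$t1) & (l1 != l2)
        hi <- min(cfg$t2 + cfg$margin, 1)
        lo <- max(cfg$t2 - cfg$margin, 0)
        dY <- if (cfg$mode == "literal") numeric(B) else {
          (-as.numeric(want_high & Yh < hi) +
             as.numeric(want_low & Yh > lo)) / B
        }

        ## encoding loss (both outputs) + logit-level gradients
        enc <- 0
        dZx <- list(NULL, NULL)
        Ys <- list(e1$Y, e2$Y)
        for (s in 1:2) {
          cm <- column_max_argmax(Ys[[s]], L)
          act <- cm$mx < cfg$confidence_threshold
          enc <- enc + sum(-log(pmax(cm$mx[act], 1e-12)))
          dZ <- matrix(0, B, 4L * L)
          if (any(act)) {
            wh <- which(act, arr.ind = TRUE)
            cols <- 4L * (wh[, 2L] - 1L)
            Ymat <- Ys[[s]]
            for (base in 1:4) {
              sel <- cbind(wh[, 1L], base + cols)
              tgt <- as.numeric(cm$amax[wh] == base)
              dZ[sel] <- (Ymat[sel] - tgt) / B
            }
          }
          dZx[[s]] <- dZ
        }

        tot <- tot + sum(sl) + enc
        n_done <- n_done + B

        bw <- predictor_backward(predictor_model, pf$cache, dY)
        dP1 <- matrix(0, B, 4L * L)
        dRC2 <- matrix(0, B, 4L * L)
        for (c in 1:4) {
          sel <- seq_len(L)
          dP1[, c + 4L * (sel - 1L)] <- bw$dX[, c + 8L * (sel - 1L)]
          dRC2[, c + 4L * (sel - 1L)] <- bw$dX[, c + 4L + 8L * (sel - 1L)]
        }
        dP2 <- softrc_batch(dRC2, L)

        g1 <- encoder_backward(encoder, e1$cache, dP1, dZx[[1L]])
        g2 <- encoder_backward(encoder, e2$cache, dP2, dZx[[2L]])
        g <- Map(`+`, g1, g2)
        up <- adam_step(params, g, st, lr)
        params <- up$params
        st <- up$state
      }
      trace[ep] <- tot / n_done
    }
    encoder$params <- params
    encoder$trained <- TRUE
    encoder$loss_trace <- trace
    encoder$cfg <- cfg
    encoder
  })
}

#' @export
predict.seq_encoder <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  Y <- encoder_forward(object, features)$Y
  L <- object$length
  out <- lapply(seq_len(nrow(Y)), function(b) {
    m <- matrix(Y[b, ], 4L, L, dimnames = list(DNA_BASES, NULL))
    m
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.seq_encoder <- function(x, ...) {
  cat(sprintf("Feature-to-DNA encoder (50 -> %d -> 4 x %d)%s\n", x$hidden,
              x$length, if (x$trained) " - trained" else " - untrained"))
  invisible(x)
}

#' Encode an image as a DNA sequence
#'
#' Feature extraction, encoder forward pass and argmax decoding in one step.
#' Deterministic: the same image always yields the same sequence.
#'
#' @param feature_model Trained [feature_extractor].
#' @param encoder_model Trained [seq_encoder].
#' @param images A single `28 x 28` matrix or an `N x 28 x 28` array.
#' @return Character vector of DNA sequences (length N).
#' @export
encode_image <- function(feature_model, encoder_model, images) {
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  FT <- extract_features(feature_model, images)
  Y <- encoder_forward(encoder_model, FT)$Y
  L <- encoder_model$length
  vapply(seq_len(nrow(Y)), function(b) {
    decode_base_matrix(matrix(Y[b, ], 4L, L))
  }, character(1))
}
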