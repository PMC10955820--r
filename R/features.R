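## Stage 1: LeNet-5-style convolutional feature extractor. Images are
## 28 x 28 single-channel grayscale in [0,1]; the second fully connected
## layer (FC2) is sized 50 and its output is the image's feature vector.
## After stage-1 classification training the parameters are frozen and the
## network is only ever used as a fixed feature map.

#' Build an untrained LeNet-5-style feature extractor
#'
#' Classic seven-layer topology: two convolution + max-pool blocks (6 then 16
#' feature maps, 5 x 5 kernels, inputs zero-padded from 28 x 28 to 32 x 32)
#' followed by three fully connected layers 400 -> 120 -> 50 -> `n_classes`,
#' with ReLU activations. The 50-unit second fully connected layer (FC2) is
#' the feature head. Initialization is deterministic given the seed.
#'
#' @param seed Integer seed for parameter initialization.
#' @param n_classes Size of the classification head (default 10).
#' @return An object of class `feature_extractor`.
#' @export
build_feature_extractor <- function(seed = 1L, n_classes = 10L) {
  params <- with_seed(seed, {
    c1 <- nn_dense_init(1L * 25L, 6L)
    c2 <- nn_dense_init(6L * 25L, 16L)
    f1 <- nn_dense_init(400L, 120L)
    f2 <- nn_dense_init(120L, 50L)
    f3 <- nn_dense_init(50L, n_classes)
    list(W1 = c1$W, b1 = c1$b, W2 = c2$W, b2 = c2$b,
         W3 = f1$W, b3 = f1$b, W4 = f2$W, b4 = f2$b, W5 = f3$W, b5 = f3$b)
  })
  structure(list(params = params, n_classes = as.integer(n_classes),
                 ii1 = im2col_idx2d(1L, 32L, 32L, 5L),
                 ii2 = im2col_idx2d(6L, 14L, 14L, 5L),
                 trained = FALSE, seed = as.integer(seed),
                 loss_trace = numeric(0), val_accuracy = NA_real_),
            class = "feature_extractor")
}

## images: array (N, 28, 28) in [0,1] -> padded B x 1024 matrix (f-order).
pad_images <- function(images) {
  if (length(dim(images)) != 3L || any(dim(images)[2:3] != 28L)) {
    stop("images must be an N x 28 x 28 array", call. = FALSE)
  }
  N <- dim(images)[1L]
  X <- array(0, c(N, 32L, 32L))
  X[, 3:30, 3:30] <- images
  dim(X) <- c(N, 1024L)
  X
}

lenet_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  z1 <- conv_forward(X, p$W1, p$b1, model$ii1)
  a1 <- relu(z1$out)
  p1 <- pool_forward(a1, 6L, 28L, 28L)
  z2 <- conv_forward(p1$out, p$W2, p$b2, model$ii2)
  a2 <- relu(z2$out)
  p2 <- pool_forward(a2, 16L, 10L, 10L)
  z3 <- dense_forward(p2$out, p$W3, p$b3)
  a3 <- relu(z3)
  z4 <- dense_forward(a3, p$W4, p$b4)
  feat <- relu(z4)
  scores <- dense_forward(feat, p$W5, p$b5)
  out <- list(scores = scores, features = feat)
  if (keep_cache) {
    out$cache <- list(X = X, z1 = z1, a1out = z1$out, p1 = p1, z2 = z2,
                      a2out = z2$out, p2 = p2, z3 = z3, a3 = a3, z4 = z4,
                      feat = feat)
  }
  out
}

lenet_backward <- function(model, cache, dscores) {
  p <- model$params
  g <- list()
  d5 <- dense_backward(dscores, cache$feat, p$W5)
  g$W5 <- d5$dW; g$b5 <- d5$db
  dfeat <- relu_backward(d5$dX, cache$z4)
  d4 <- dense_backward(dfeat, cache$a3, p$W4)
  g$W4 <- d4$dW; g$b4 <- d4$db
  da3 <- relu_backward(d4$dX, cache$z3)
  d3 <- dense_backward(da3, cache$p2$out, p$W3)
  g$W3 <- d3$dW; g$b3 <- d3$db
  da2 <- pool_backward(d3$dX, cache$p2)
  dz2 <- relu_backward(da2, cache$a2out)
  d2 <- conv_backward(dz2, p$W2, model$ii2, cache$z2$XP, 6L * 196L)
  g$W2 <- d2$dW; g$b2 <- d2$db
  da1 <- pool_backward(d2$dX, cache$p1)
  dz1 <- relu_backward(da1, cache$a1out)
  d1 <- conv_backward(dz1, p$W1, model$ii1, cache$z1$XP, 1024L)
  g$W1 <- d1$dW; g$b1 <- d1$db
  g
}

#' Train the feature extractor on labeled images
#'
#' Stage-1 cross-entropy classification training with Adam. After this stage
#' all parameters are frozen: downstream stages only read FC2 activations.
#'
#' @param model A [build_feature_extractor()] object.
#' @param images `N x 28 x 28` array of pixels in `[0, 1]`.
#' @param labels Integer class labels `0..n_classes-1`, length `N`.
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param seed Seed for shuffling (defaults to the model's build seed).
#' @param val_images,val_labels Optional held-out split for the reported
#'   accuracy; when omitted, a random 10% of the input is carved off before
#'   training.
#' @return The trained model, with `val_accuracy` and a per-epoch
#'   `loss_trace`.
#' @export
train_feature_extractor <- function(model, images, labels, epochs = 5L,
                                    batch_size = 64L, lr = 1e-3, seed = NULL,
                                    val_images = NULL, val_labels = NULL) {
  stopifnot(inherits(model, "feature_extractor"))
  N <- dim(images)[1L]
  if (N == 0L) stop("empty dataset", call. = FALSE)
  labels <- as.integer(labels)
  stopifnot(length(labels) == N)
  if (length(unique(labels)) < 2L) {
    stop("training requires at least 2 classes", call. = FALSE)
  }
  if (is.null(seed)) seed <- model$seed + 1L

  with_seed(seed, {
    if (is.null(val_images)) {
      idx <- sample.int(N)
      nval <- max(1L, round(0.1 * N))
      val_idx <- idx[seq_len(nval)]
      tr_idx <- idx[-seq_len(nval)]
      val_images <- images[val_idx, , , drop = FALSE]
      val_labels <- labels[val_idx]
      images <- images[tr_idx, , , drop = FALSE]
      labels <- labels[tr_idx]
      N <- length(tr_idx)
    }
    X <- pad_images(images)
    params <- model$params
    st <- adam_state(params)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tot <- 0
      for (start in seq(1L, N, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, N)]
        model$params <- params
        fw <- lenet_forward(model, X[bi, , drop = FALSE], keep_cache = TRUE)
        P <- softmax_rows(fw$scores)
        B <- length(bi)
        ii <- cbind(seq_len(B), labels[bi] + 1L)
        tot <- tot + sum(-log(pmax(P[ii], 1e-12)))
        dscores <- P
        dscores[ii] <- dscores[ii] - 1
        dscores <- dscores / B
        g <- lenet_backward(model, fw$cache, dscores)
        up <- adam_step(params, g, st, lr)
        params <- up$params
        st <- up$state
      }
      trace[ep] <- tot / N
    }
    model$params <- params
    model$trained <- TRUE
    model$loss_trace <- trace
    pv <- predict(model, val_images, type = "class")
    model$val_accuracy <- mean(pv == val_labels)
    model
  })
}

#' Extract 50-D feature vectors
#'
#' Forward pass to the FC2 activations; purely functional, no parameter
#' updates, identical results whether images are batched or passed one by
#' one.
#'
#' @param model A trained [feature_extractor].
#' @param images `N x 28 x 28` array (a single `28 x 28` matrix is accepted).
#' @return `N x 50` numeric matrix of feature vectors.
#' @export
extract_features <- function(model, images) {
  stopifnot(inherits(model, "feature_extractor"))
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  X <- pad_images(images)
  N <- nrow(X)
  out <- matrix(0, N, 50L)
  for (start in seq(1L, N, by = 256L)) {
    bi <- start:min(start + 255L, N)
    out[bi, ] <- lenet_forward(model, X[bi, , drop = FALSE])$features
  }
  out
}

#' @export
predict.feature_extractor <- function(object, newdata,
                                      type = c("class", "features", "scores"),
                                      ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- array(newdata, c(1L, dim(newdata)))
  if (type == "features") return(extract_features(object, newdata))
  X <- pad_images(newdata)
  N <- nrow(X)
  scores <- matrix(0, N, object$n_classes)
  for (start in seq(1L, N, by = 256L)) {
    bi <- start:min(start + 255L, N)
    scores[bi, ] <- lenet_forward(object, X[bi, , drop = FALSE])$scores
  }
  if (type == "scores") scores else max.col(scores, ties.method = "first") - 1L
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat("LeNet-5 feature extractor (FC2 = 50-D)",
      if (x$trained) sprintf("- trained, validation accuracy %.3f",
                             x$val_accuracy) else "- untrained", "\n")
  invisible(x)
}

#' Euclidean distance between two feature vectors
#'
#' Standard L2 distance on raw FC2 activations (no normalization); the
#' distance thresholds of the encoder loss are applied in these raw units.
#'
#' @param f1,f2 Numeric vectors of equal length (50-D feature vectors).
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop("feature vectors have different dimensions", call. = FALSE)
  }
  sqrt(sum((f1 - f2)^2))
}
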