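## Top-level fit: the whole three-stage pipeline behind one classical
## modelling call. hybriclass() trains the feature extractor on the labeled
## images, trains the yield predictor on a generated sequence-pair corpus,
## trains the encoder against both frozen models, encodes every training
## image into its class tube, and returns a classifier object with the
## usual print / summary / predict methods.

#' Control parameters for [hybriclass()]
#'
#' Defaults are the package's scaled-down study conditions: a 20,000-pair
#' training corpus for the yield surrogate, 59-nt sequences, and short Adam
#' schedules sized for a 10-class corpus of a few thousand images on one
#' CPU.
#'
#' @param pair_corpus_size Sequence pairs generated (and deduplicated) for
#'   predictor training.
#' @param pairs_per_bin Optional yield-balancing target per bin (10 bins).
#'   `NULL` (the default) trains on the natural mixture corpus: balancing
#'   reweights the label distribution conditional on sequence similarity
#'   and misplaces the surrogate's yield cliff, which the encoder then
#'   exploits (see the package vignette).
#' @param sequence_length Encoded sequence length (default 59).
#' @param backbone_epochs,backbone_batch,backbone_lr Stage-1 hyperparameters.
#' @param predictor_epochs,predictor_batch,predictor_lr Stage-2
#'   hyperparameters.
#' @param encoder_hidden,encoder_epochs,pairs_per_epoch,encoder_batch,encoder_lr
#'   Stage-3 hyperparameters; `encoder_epochs` is the length of each
#'   encoder training segment between surrogate refits.
#' @param surrogate_refits,refit_pairs,refit_epochs Alternating surrogate
#'   refitting: after each encoder segment, `refit_pairs` image pairs are
#'   sampled, hard-encoded with the current encoder, labeled by the
#'   thermodynamic oracle, and the predictor is retrained for
#'   `refit_epochs` on the base corpus plus these on-distribution pairs.
#'   Without this, stage 3 drifts into regions where the frozen surrogate
#'   is wrong and the encoded library collapses (see the vignette).
#' @param margin Hinge training margin passed to [loss_config()].
#' @param t1 Distance threshold for the sequence loss; `"auto"` calibrates
#'   it from the corpus's intra-/inter-class feature distance distributions
#'   (see [calibrate_t1()]; use 16 for MNIST features).
#' @param t2 Yield threshold of the sequence loss.
#' @param library_per_class Optional cap on instances per tube.
#' @return A list of class `hybriclass_control`.
#' @export
hybriclass_control <- function(pair_corpus_size = 20000L,
                               pairs_per_bin = NULL,
                               sequence_length = 59L,
                               backbone_epochs = 6L, backbone_batch = 64L,
                               backbone_lr = 1e-3,
                               predictor_epochs = 10L, predictor_batch = 128L,
                               predictor_lr = 2e-3,
                               encoder_hidden = 128L, encoder_epochs = 3L,
                               pairs_per_epoch = 6000L, encoder_batch = 128L,
                               encoder_lr = 1e-3,
                               surrogate_refits = 5L, refit_pairs = 5000L,
                               refit_epochs = 4L,
                               t1 = "auto", t2 = 0.8, margin = 0.79,
                               library_per_class = NULL) {
  out <- as.list(environment())
  class(out) <- "hybriclass_control"
  out
}

#' Fit a DNA instance-based image classifier
#'
#' Runs the full pipeline: (1) train the LeNet-5 feature extractor to
#' classify the images and freeze it; (2) generate, deduplicate and
#' yield-balance a sequence-pair corpus, label it with the thermodynamic
#' yield oracle, and train the convolutional yield predictor on it; (3)
#' train the encoder so that images that are close in feature space and
#' share a label map to sequence pairs with high predicted yield; finally
#' encode every training image and store it in its class tube. Prediction
#' hybridizes the reverse complement of a query's sequence against every
#' tube and returns the class with the highest yield sum.
#'
#' @param images `N x 28 x 28` array of grayscale training images in
#'   `[0, 1]`.
#' @param labels Integer class labels `0..9`, length `N`.
#' @param conditions A [hybridization_conditions()] object used both for
#'   corpus labeling and classification-time yields.
#' @param control A [hybriclass_control()] list.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param verbose Print stage progress?
#' @return An object of class `hybriclass` with components `feature_model`,
#'   `predictor_model`, `encoder_model`, `library`, `cfg` (the resolved
#'   [loss_config()]), `conditions` and stage diagnostics.
#' @seealso [predict.hybriclass()], [evaluate_classifier()]
#' @export
hybriclass <- function(images, labels,
                       conditions = hybridization_conditions(),
                       control = hybriclass_control(), seed = 1L,
                       verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  labels <- as.integer(labels)
  ctl <- control

  say("stage 1/3: training feature extractor (%d images)", length(labels))
  fe <- build_feature_extractor(seed = derive_seed(seed, "backbone"))
  fe <- train_feature_extractor(fe, images, labels,
                                epochs = ctl$backbone_epochs,
                                batch_size = ctl$backbone_batch,
                                lr = ctl$backbone_lr)
  say("  validation accuracy %.3f", fe$val_accuracy)

  say("stage 2/3: corpus of %d pairs", ctl$pair_corpus_size)
  pairs <- generate_pairs(ctl$pair_corpus_size,
                          length = ctl$sequence_length,
                          conditions = conditions,
                          seed = derive_seed(seed, "pairs"))
  pairs <- dedupe_pairs(pairs)
  if (!is.null(ctl$pairs_per_bin)) {
    pairs <- suppressWarnings(
      balance_by_yield(pairs, per_bin = ctl$pairs_per_bin,
                       seed = derive_seed(seed, "balance")))
  }
  say("  corpus: %d pairs; training predictor", nrow(pairs))
  pr <- build_predictor(seed = derive_seed(seed, "predictor"),
                        length = ctl$sequence_length)
  pr <- train_predictor(pr, pairs, epochs = ctl$predictor_epochs,
                        batch_size = ctl$predictor_batch,
                        lr = ctl$predictor_lr)
  say("  holdout MSE %.4f", pr$holdout_mse)

  t1 <- ctl$t1
  if (identical(t1, "auto")) {
    t1 <- calibrate_t1(extract_features(fe, images), labels,
                       seed = derive_seed(seed, "t1"))
    say("  calibrated T1 = %.2f", t1)
  }
  cfg <- loss_config(t1 = t1, t2 = ctl$t2, margin = ctl$margin)

  say("stage 3/3: training encoder (%d refit rounds)", ctl$surrogate_refits)
  st3 <- train_encoder_refitted(fe, pr, images, labels, pairs, cfg, ctl,
                                conditions, seed, say)
  en <- st3$encoder
  pr <- st3$predictor

  lib <- build_library(images, labels, fe, en,
                       per_class = ctl$library_per_class)
  say("library: %d instances in %d tubes", sum(lengths(lib$tubes)),
      length(lib$tubes))

  structure(list(feature_model = fe, predictor_model = pr,
                 encoder_model = en, library = lib, cfg = cfg,
                 conditions = conditions, control = ctl, seed = seed,
                 n_train = length(labels), call = match.call()),
            class = "hybriclass")
}

## Stage 3 with alternating surrogate refits. The encoder is trained in
## (surrogate_refits + 1) segments; between segments, image pairs are
## hard-encoded with the current encoder, labeled by the thermodynamic
## oracle, and the predictor is retrained on the base corpus plus these
## on-distribution pairs. A frozen surrogate alone is adversarially
## exploitable: the encoder drifts into input regions where the surrogate
## under-predicts the true yield and the encoded library collapses.
train_encoder_refitted <- function(fe, pr, images, labels, pairs, cfg, ctl,
                                   conditions, seed,
                                   say = function(...) invisible()) {
  en <- build_encoder(seed = derive_seed(seed, "encoder"),
                      hidden = ctl$encoder_hidden,
                      length = ctl$sequence_length)
  aug <- NULL
  for (round in seq_len(ctl$surrogate_refits + 1L)) {
    en <- train_encoder(fe, pr, images, labels, encoder = en, cfg = cfg,
                        epochs = ctl$encoder_epochs,
                        pairs_per_epoch = ctl$pairs_per_epoch,
                        batch_size = ctl$encoder_batch, lr = ctl$encoder_lr,
                        seed = derive_seed(seed, paste0("enc-", round)))
    if (round > ctl$surrogate_refits) break
    aug <- with_seed(derive_seed(seed, paste0("aug-", round)), {
      n <- ctl$refit_pairs
      i <- sample(length(labels), n, replace = TRUE)
      j <- ifelse(runif(n) < 0.5,
                  vapply(i, function(ii) {
                    pool <- which(labels == labels[ii])
                    pool[sample.int(length(pool), 1L)]
                  }, integer(1)),
                  sample(length(labels), n, replace = TRUE))
      e1 <- encode_image(fe, en, images[i, , , drop = FALSE])
      e2 <- encode_image(fe, en, images[j, , , drop = FALSE])
      new <- data.frame(first = e1, second = e2,
                        yield = yield_pairs(e1, e2, conditions),
                        stringsAsFactors = FALSE)
      rbind(if (!is.null(aug)) aug[sample(nrow(aug), min(nrow(aug), n)), ],
            new)
    })
    corpus <- with_seed(derive_seed(seed, paste0("corpus-", round)),
      rbind(pairs[sample(nrow(pairs), min(nrow(pairs), 10000L)), ], aug))
    pr <- train_predictor(pr, corpus, epochs = ctl$refit_epochs, lr = 1e-3,
                          seed = derive_seed(seed, paste0("refit-", round)))
    say("  refit %d: surrogate holdout MSE %.4f", round, pr$holdout_mse)
  }
  list(encoder = en, predictor = pr)
}

#' Classify new images with a fitted [hybriclass()] model
#'
#' @param object A fitted `hybriclass` object.
#' @param newdata A `28 x 28` matrix or `N x 28 x 28` array of query images.
#' @param type `"class"` (default) for predicted labels, `"yield_sums"` for
#'   the full query-by-class yield-sum matrix, `"sequence"` for the encoded
#'   query sequences.
#' @param ... Unused.
#' @return Per `type`: integer labels, a numeric matrix, or a character
#'   vector.
#' @export
predict.hybriclass <- function(object, newdata,
                               type = c("class", "yield_sums", "sequence"),
                               ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- array(newdata, c(1L, dim(newdata)))
  qseqs <- encode_image(object$feature_model, object$encoder_model, newdata)
  if (type == "sequence") return(qseqs)
  probes <- vapply(qseqs, reverse_complement, character(1))
  sc <- tube_yield_sums(probes, object$library, object$conditions)
  if (type == "yield_sums") return(sc$sums)
  sc$classes[max.col(sc$sums, ties.method = "first")]
}

#' @export
print.hybriclass <- function(x, ...) {
  cat("DNA instance-based classifier\n")
  cat(sprintf("  trained on %d images, %d tubes, %d instances of %d nt\n",
              x$n_train, length(x$library$tubes),
              sum(lengths(x$library$tubes)), x$library$length))
  cat(sprintf("  thresholds: T1 = %.2f, T2 = %.2f; backend '%s'\n",
              x$cfg$t1, x$cfg$t2, x$conditions$backend))
  invisible(x)
}

#' @export
summary.hybriclass <- function(object, ...) {
  x <- object
  cat("DNA instance-based classifier -- stage diagnostics\n")
  cat(sprintf("  stage 1 backbone:   validation accuracy %.3f\n",
              x$feature_model$val_accuracy))
  cat(sprintf("  stage 2 predictor:  holdout MSE %.4f (%d holdout pairs)\n",
              x$predictor_model$holdout_mse, length(x$predictor_model$holdout)))
  cat(sprintf("  stage 3 encoder:    loss trace %s\n",
              paste(sprintf("%.3f", x$encoder_model$loss_trace),
                    collapse = " -> ")))
  cat(sprintf("  tubes: %s\n",
              paste(sprintf("%s:%d", names(x$library$tubes),
                            lengths(x$library$tubes)), collapse = " ")))
  invisible(x)
}
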