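## The instance-based classifier. Every labeled image is encoded to a 59-nt
## sequence and stored in its class "tube"; a query is encoded, its reverse
## complement taken as the probe, and the probe's hybridization yield summed
## per tube. The query is assigned to the arg-max tube. Classification-time
## yields come from the thermodynamic backend (the simulated wet step), not
## from the neural predictor, which exists only to make stage-3 training
## differentiable.

#' Build a tube library from labeled images
#'
#' Encodes every image and groups the sequences by class label, preserving
#' input order within each tube (duplicate images yield duplicate sequences:
#' tubes have multiset semantics, mirroring strand concentrations).
#'
#' @param images `N x 28 x 28` array.
#' @param labels Integer class labels, length `N`.
#' @param feature_model Trained [feature_extractor].
#' @param encoder_model Trained [seq_encoder].
#' @param per_class Optional cap: keep only the first `per_class` instances
#'   of each class.
#' @return An object of class `tube_library`: `tubes` (label -> character
#'   vector of sequences) and `provenance` (label -> source row indices).
#' @export
build_library <- function(images, labels, feature_model, encoder_model,
                          per_class = NULL) {
  labels <- as.integer(labels)
  stopifnot(dim(images)[1L] == length(labels))
  keep <- seq_along(labels)
  if (!is.null(per_class)) {
    keep <- unlist(lapply(split(seq_along(labels), labels),
                          head, n = per_class), use.names = FALSE)
    keep <- sort(keep)
  }
  seqs <- encode_image(feature_model, encoder_model,
                       images[keep, , , drop = FALSE])
  tubes <- split(seqs, labels[keep])
  prov <- split(keep, labels[keep])
  if (any(!lengths(tubes))) warning("some classes have empty tubes")
  structure(list(tubes = tubes, provenance = prov,
                 length = nchar(seqs[[1L]])),
            class = "tube_library")
}

#' @export
print.tube_library <- function(x, ...) {
  cat(sprintf("Tube library: %d classes, %d instances of %d nt\n",
              length(x$tubes), sum(lengths(x$tubes)), x$length))
  invisible(x)
}

## All instances pooled, with their class labels and per-tube indices.
pool_library <- function(library) {
  labs <- rep(names(library$tubes), lengths(library$tubes))
  idx <- unlist(lapply(library$tubes, seq_along), use.names = FALSE)
  data.frame(id = sprintf("%s|%04d", labs, idx), class = as.integer(labs),
             seq = unlist(library$tubes, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Persist / load a tube library as FASTA
#'
#' Headers follow the `"classLabel|instanceIndex"` dialect so the library
#' round-trips exactly.
#'
#' @param library A [tube_library][build_library()].
#' @param path FASTA file.
#' @return `library_to_fasta`: `path` invisibly; `library_from_fasta`: a
#'   `tube_library`.
#' @export
library_to_fasta <- function(library, path) {
  pool <- pool_library(library)
  write_fasta(pool[, c("id", "seq")], path)
}

#' @rdname library_to_fasta
#' @export
library_from_fasta <- function(path) {
  recs <- read_fasta(path)
  parsed <- lapply(recs$id, parse_instance_id)
  cls <- vapply(parsed, `[[`, integer(1), "class")
  tubes <- split(recs$seq, cls)
  structure(list(tubes = tubes,
                 provenance = split(seq_along(cls), cls),
                 length = nchar(recs$seq[[1L]])),
            class = "tube_library")
}

## Shared scoring core: probes x instances yield matrix and per-tube sums.
tube_yield_sums <- function(probes, library, conditions, yield_fn = NULL) {
  pool <- pool_library(library)
  Y <- if (is.null(yield_fn)) {
    yield_matrix(probes, pool$seq, conditions)
  } else {
    matrix(vapply(pool$seq,
                  function(s) vapply(probes, function(p) yield_fn(p, s),
                                     numeric(1)),
                  numeric(length(probes))),
           nrow = length(probes))
  }
  classes <- sort(unique(pool$class))
  sums <- t(rowsum(t(Y), group = pool$class))    # probes x classes
  colnames(sums) <- as.character(classes)
  list(yields = Y, sums = sums, pool = pool, classes = classes)
}

#' Classify a query by summed hybridization yield
#'
#' Encodes the query, uses the reverse complement of its sequence as the
#' probe, computes the probe's yield against every instance, sums yields per
#' tube and returns the class with the highest sum. Ties are broken toward
#' the smallest class label, with a warning.
#'
#' @param query A `28 x 28` image matrix, or a DNA sequence string already
#'   encoded.
#' @param library A [tube_library][build_library()]; every class must be
#'   non-empty.
#' @param feature_model,encoder_model Trained stage models (not needed when
#'   `query` is already a sequence).
#' @param conditions A [hybridization_conditions()] object selecting the
#'   yield backend.
#' @param yield_fn Optional override: `function(probe, instance)` returning
#'   a yield, replacing the backend for this call.
#' @return An object of class `classification_result` with
#'   `predicted_label`, `per_class_yield_sum` and `query_sequence`.
#' @export
classify_query <- function(query, library, feature_model = NULL,
                           encoder_model = NULL,
                           conditions = hybridization_conditions(),
                           yield_fn = NULL) {
  if (any(!lengths(library$tubes))) {
    stop("every class tube must be non-empty", call. = FALSE)
  }
  qseq <- if (is.character(query)) query else {
    encode_image(feature_model, encoder_model, query)
  }
  if (nchar(qseq) != library$length) {
    stop("probe and instance sequence lengths differ", call. = FALSE)
  }
  probe <- reverse_complement(qseq)
  sc <- tube_yield_sums(probe, library, conditions, yield_fn)
  sums <- sc$sums[1L, ]
  best <- which(sums == max(sums))
  if (length(best) > 1L) {
    warning("yield-sum tie between classes; returning the smallest label")
  }
  structure(list(predicted_label = sc$classes[min(best)],
                 per_class_yield_sum = sums, query_sequence = qseq),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Predicted class: %d\n", x$predicted_label))
  cat("Per-class yield sums:\n")
  print(round(x$per_class_yield_sum, 3))
  invisible(x)
}

#' Evaluate the classifier on a query set
#'
#' Runs the yield-sum protocol for every query and reports overall accuracy,
#' per-class accuracy, the confusion matrix (rows = true, columns =
#' predicted) and the misclassified queries with their per-class yield sums.
#' Mean intra-class and inter-class instance yields are included since the
#' separation between them is what makes the protocol work.
#'
#' @param queries `N x 28 x 28` array of query images.
#' @param true_labels Integer labels aligned with `queries`.
#' @param library A [tube_library][build_library()].
#' @param feature_model,encoder_model Trained stage models.
#' @param conditions A [hybridization_conditions()] object.
#' @return A list of class `classifier_evaluation`.
#' @export
evaluate_classifier <- function(queries, true_labels, library, feature_model,
                                encoder_model,
                                conditions = hybridization_conditions()) {
  true_labels <- as.integer(true_labels)
  if (dim(queries)[1L] != length(true_labels)) {
    stop("queries and labels have different lengths", call. = FALSE)
  }
  qseqs <- encode_image(feature_model, encoder_model, queries)
  probes <- vapply(qseqs, reverse_complement, character(1))
  sc <- tube_yield_sums(probes, library, conditions)
  pred <- sc$classes[max.col(sc$sums, ties.method = "first")]

  classes <- sort(unique(c(true_labels, sc$classes)))
  conf <- table(factor(true_labels, levels = classes),
                factor(pred, levels = classes))
  per_class <- diag(conf) / pmax(rowSums(conf), 1L)
  mis <- which(pred != true_labels)
  inst_lab <- matrix(rep(sc$pool$class, each = length(probes)),
                     nrow = length(probes))
  intra <- inst_lab == true_labels
  structure(list(accuracy = mean(pred == true_labels),
                 per_class_accuracy = setNames(as.numeric(per_class),
                                               as.character(classes)),
                 confusion = conf,
                 predicted = pred,
                 misclassified = data.frame(query = mis,
                                            true = true_labels[mis],
                                            predicted = pred[mis]),
                 yield_sums = sc$sums,
                 mean_intra_yield = mean(sc$yields[intra]),
                 mean_inter_yield = mean(sc$yields[!intra])),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f (%d misclassified)\n", x$accuracy,
              nrow(x$misclassified)))
  cat("Per-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  cat(sprintf("Mean intra-class yield %.3f vs inter-class %.3f\n",
              x$mean_intra_yield, x$mean_inter_yield))
  invisible(x)
}

#' Top-k nearest instances of a query by hybridization yield
#'
#' Pools all instances across tubes, ranks them by the probe's yield
#' (descending, stable: ties keep pool order) and returns the top `k` with a
#' per-class composition summary.
#'
#' @param query Image matrix or DNA sequence string.
#' @param library A [tube_library][build_library()].
#' @param k Number of neighbors (values beyond the library size return the
#'   whole library, with a warning).
#' @param feature_model,encoder_model Trained stage models (optional when
#'   `query` is a sequence).
#' @param conditions A [hybridization_conditions()] object.
#' @return Data frame `(id, class, yield)` sorted by yield; the class
#'   fractions of the returned neighbors are attached as attribute
#'   `"composition"`.
#' @export
top_k_neighbors <- function(query, library, k, feature_model = NULL,
                            encoder_model = NULL,
                            conditions = hybridization_conditions()) {
  stopifnot(k >= 1L)
  qseq <- if (is.character(query)) query else {
    encode_image(feature_model, encoder_model, query)
  }
  probe <- reverse_complement(qseq)
  sc <- tube_yield_sums(probe, library, conditions)
  y <- sc$yields[1L, ]
  n <- length(y)
  if (k > n) {
    warning(sprintf("k = %d exceeds library size %d; returning all", k, n))
    k <- n
  }
  ord <- order(-y, seq_len(n))[seq_len(k)]
  out <- data.frame(id = sc$pool$id[ord], class = sc$pool$class[ord],
                    yield = y[ord], stringsAsFactors = FALSE)
  comp <- table(factor(out$class, levels = sc$classes)) / k
  attr(out, "composition") <- comp
  out
}
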