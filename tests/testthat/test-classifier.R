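## Fixture libraries are constructed directly from sequences so classifier
## semantics can be tested without trained models.
make_library <- function(tubes) {
  structure(list(tubes = tubes,
                 provenance = lapply(tubes, seq_along),
                 length = nchar(tubes[[1]][[1]])),
            class = "tube_library")
}

rand_seqs <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "T", "C", "G"), 59, TRUE), collapse = ""),
    character(1))
}

test_that("a tube of exact complements wins the yield sum", {
  q <- random_sequence(59, seed = 61)
  probe_mates <- rep(q, 10)   # instances identical to the query sequence
  lib <- make_library(list(`0` = rand_seqs(10, 1), `1` = probe_mates,
                           `2` = rand_seqs(10, 2)))
  res <- classify_query(q, lib)
  expect_s3_class(res, "classification_result")
  expect_identical(res$predicted_label, 1L)
  expect_gt(res$per_class_yield_sum[["1"]], 9.9)
  expect_lt(res$per_class_yield_sum[["0"]], 2)
  expect_identical(res$query_sequence, q)
  expect_identical(names(which.max(res$per_class_yield_sum)), "1")
})

test_that("ties break toward the smallest label, with a warning", {
  q <- random_sequence(59, seed = 62)
  tube <- rand_seqs(5, 3)
  lib <- make_library(list(`2` = tube, `7` = tube, `4` = tube))
  expect_warning(res <- classify_query(q, lib), "tie")
  expect_identical(res$predicted_label, 2L)
  single <- make_library(list(`5` = rand_seqs(4, 4)))
  expect_identical(classify_query(q, single)$predicted_label, 5L)
})

test_that("classification is invariant to instance and tube order", {
  q <- random_sequence(59, seed = 63)
  t0 <- rand_seqs(8, 5); t1 <- rand_seqs(8, 6)
  lib <- make_library(list(`0` = t0, `1` = t1))
  shuffled <- make_library(list(`1` = sample(t1), `0` = sample(t0)))
  r1 <- classify_query(q, lib)
  r2 <- classify_query(q, shuffled)
  expect_identical(r1$predicted_label, r2$predicted_label)
  expect_equal(r1$per_class_yield_sum[c("0", "1")],
               r2$per_class_yield_sum[c("0", "1")], tolerance = 1e-12)
  ## adding an instance never decreases its tube's sum
  bigger <- make_library(list(`0` = c(t0, rand_seqs(1, 7)), `1` = t1))
  r3 <- classify_query(q, bigger)
  expect_gte(r3$per_class_yield_sum[["0"]], r1$per_class_yield_sum[["0"]])
})

test_that("a custom yield function can replace the backend", {
  q <- strrep("ACGT", 15) |> substr(1, 59)
  lib <- make_library(list(`0` = rand_seqs(3, 8), `1` = rand_seqs(3, 9)))
  res <- suppressWarnings(
    classify_query(q, lib, yield_fn = function(p, s) 0.25))
  expect_equal(unname(res$per_class_yield_sum), c(0.75, 0.75))
})

test_that("top-k retrieval ranks a planted complement first", {
  q <- random_sequence(59, seed = 64)
  planted <- q                       # probe = revcomp(q) binds it perfectly
  lib <- make_library(list(`0` = rand_seqs(6, 10),
                           `1` = c(rand_seqs(3, 11), planted)))
  top <- top_k_neighbors(q, lib, k = 1)
  expect_identical(top$class, 1L)
  expect_identical(top$id, "1|0004")
  expect_gt(top$yield, 0.99)

  all10 <- top_k_neighbors(q, lib, k = 10)
  expect_identical(nrow(all10), 10L)
  expect_setequal(all10$id, c(sprintf("0|%04d", 1:6), sprintf("1|%04d", 1:4)))
  expect_true(all(diff(all10$yield) <= 1e-12))
  comp <- attr(all10, "composition")
  expect_equal(sum(comp), 1)
  expect_warning(top_k_neighbors(q, lib, k = 99), "exceeds")
})

test_that("evaluation counts accuracies exactly", {
  ## plant one perfect tube per class so classification is deterministic
  qs <- rand_seqs(6, 12)
  lib <- make_library(list(`0` = c(qs[1], qs[2]), `1` = c(qs[3], qs[4]),
                           `2` = c(qs[5], qs[6])))
  sums <- hybriclass:::tube_yield_sums(
    vapply(qs, reverse_complement, character(1)), lib,
    hybridization_conditions())
  pred <- sums$classes[max.col(sums$sums, ties.method = "first")]
  expect_identical(pred, c(0L, 0L, 1L, 1L, 2L, 2L))
  ## arithmetic identity: overall accuracy equals the count-weighted mean
  ## of per-class accuracies
  truth <- c(0L, 1L, 1L, 1L, 2L, 0L)
  acc <- mean(pred == truth)
  per <- vapply(split(pred == truth, truth), mean, numeric(1))
  w <- table(truth)
  expect_equal(acc, sum(per * as.numeric(w)) / sum(w))
})

test_that("a tube library survives the FASTA round trip", {
  lib <- make_library(list(`0` = rand_seqs(4, 13), `3` = rand_seqs(2, 14)))
  path <- withr::local_tempfile(fileext = ".fasta")
  library_to_fasta(lib, path)
  back <- library_from_fasta(path)
  expect_identical(back$tubes, lib$tubes)
  expect_identical(back$length, lib$length)
})
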