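## Training corpus for the yield predictor: homopolymer-free 59-nt sequence
## pairs labeled by the yield oracle, deduplicated and balanced so that
## labels cover the whole [0,1] range evenly.

## Vectorized homopolymer-free sampling: one uniform draw per position from
## the bases that do not extend a run of two (same distribution as
## random_sequence(forbid_homopolymer = TRUE), batched over n sequences).
random_sequences <- function(n, length) {
  M <- matrix(sample.int(4L, n * length, replace = TRUE), n, length)
  if (length >= 3L) {
    for (j in 3:length) {
      bad <- M[, j] == M[, j - 1L] & M[, j - 1L] == M[, j - 2L]
      while (any(bad)) {
        M[bad, j] <- sample.int(4L, sum(bad), replace = TRUE)
        bad <- M[, j] == M[, j - 1L] & M[, j - 1L] == M[, j - 2L]
      }
    }
  }
  apply(matrix(DNA_BASES[M], n, length), 1L, paste, collapse = "")
}

## Mutate `k` random positions of a homopolymer-free sequence (each mutated
## base uniform over the three alternatives). Runs of three introduced by
## the draw are repaired in a single left-to-right pass that resamples the
## run-extending base, so the result is always homopolymer-free (at the cost
## of an occasional extra substitution relative to exactly k).
mutate_sequence <- function(seq, k) {
  if (k == 0L) return(seq)
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  pos <- sample.int(length(idx), k)
  idx[pos] <- ((idx[pos] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
  for (j in seq_along(idx)[-(1:2)]) {
    if (idx[j] == idx[j - 1L] && idx[j] == idx[j - 2L]) {
      idx[j] <- ((idx[j] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    }
  }
  paste(DNA_BASES[idx], collapse = "")
}

#' Generate a yield-labeled sequence-pair corpus
#'
#' Draws `n` homopolymer-free pairs and labels each with the yield oracle at
#' the given conditions. Pairs come from a two-component mixture: (i)
#' independent random sequences, whose yields are overwhelmingly near 0, and
#' (ii) a random sequence paired with a `k`-point-mutated copy of its
#' reverse complement, `k` uniform on `0..length`, which populates the high-
#' and mid-yield range. Purely independent pairs could never give the even
#' yield coverage the balanced corpus needs.
#'
#' @param n Number of pairs.
#' @param length Sequence length (default 59).
#' @param conditions A [hybridization_conditions()] object.
#' @param seed Integer seed; the corpus is deterministic given it.
#' @param mutant_frac Probability of mixture component (ii) (default 0.5).
#' @return Data frame with columns `first`, `second`, `yield`.
#' @export
generate_pairs <- function(n, length = 59L,
                           conditions = hybridization_conditions(),
                           seed = 1L, mutant_frac = 0.5) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    first <- random_sequences(n, length)
    second <- random_sequences(n, length)
    use_mut <- which(runif(n) < mutant_frac)
    k_mut <- sample.int(length + 1L, base::length(use_mut),
                        replace = TRUE) - 1L
    for (w in seq_along(use_mut)) {
      i <- use_mut[w]
      second[i] <- mutate_sequence(reverse_complement(first[i]), k_mut[w])
    }
    data.frame(first = first, second = second,
               yield = yield_pairs(first, second, conditions),
               stringsAsFactors = FALSE)
  })
}

#' Remove duplicate pairs
#'
#' `(a, b)` and `(b, a)` count as the same pair; the first occurrence is
#' kept and order is otherwise preserved.
#'
#' @param pairs Data frame with columns `first`, `second` (and usually
#'   `yield`).
#' @return The deduplicated data frame.
#' @export
dedupe_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pmin(pairs$first, pairs$second),
               pmax(pairs$first, pairs$second), sep = "\r")
  pairs[!duplicated(key), , drop = FALSE]
}

#' Balance a pair corpus by yield
#'
#' Partitions `[0, 1]` into `n_bins` equal-width bins (the last bin is
#' right-closed, so a yield of exactly 1 falls in the top bin) and samples
#' without replacement up to `per_bin` pairs from each. Bins with too few
#' pairs contribute what they have, with a warning naming the shortfall.
#'
#' @param pairs Data frame with a `yield` column.
#' @param n_bins Number of equal-width bins (default 10).
#' @param per_bin Pairs to draw per bin.
#' @param seed Optional seed for the within-bin sampling.
#' @return The balanced data frame (row order follows the input).
#' @export
balance_by_yield <- function(pairs, n_bins = 10L, per_bin, seed = NULL) {
  stopifnot(per_bin >= 1L)
  if (!nrow(pairs)) {
    warning("empty pair corpus; nothing to balance")
    return(pairs)
  }
  if (any(pairs$yield < 0 | pairs$yield > 1)) {
    stop("yields must lie in [0, 1]", call. = FALSE)
  }
  bin <- pmin(floor(pairs$yield * n_bins) + 1L, n_bins)
  with_seed(seed, {
    keep <- integer(0)
    for (b in seq_len(n_bins)) {
      rows <- which(bin == b)
      if (length(rows) < per_bin) {
        warning(sprintf("yield bin %d/%d holds only %d of %d requested pairs",
                        b, n_bins, length(rows), per_bin))
        keep <- c(keep, rows)
      } else {
        keep <- c(keep, sample(rows, per_bin))
      }
    }
    pairs[sort(keep), , drop = FALSE]
  })
}

#' Write / read a yield-labeled pair corpus as TSV
#'
#' Columns `first_seq`, `second_seq`, `yield` (tab-separated, header row,
#' yields serialized with 6 decimals). Reading validates sequences and the
#' yield range and reports the offending row on failure.
#'
#' @param pairs Data frame with columns `first`, `second`, `yield`.
#' @param path File path.
#' @return `write_pairs_tsv`: `path` invisibly; `read_pairs_tsv`: the data
#'   frame (zero rows for a header-only file).
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- data.frame(first_seq = pairs$first, second_seq = pairs$second,
                    yield = sprintf("%.6f", pairs$yield),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric"))
  if (!identical(names(d), c("first_seq", "second_seq", "yield"))) {
    stop("expected columns first_seq, second_seq, yield", call. = FALSE)
  }
  if (!nrow(d)) {
    return(data.frame(first = character(), second = character(),
                      yield = numeric(), stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(d))) {
    ok <- tryCatch({
      validate_dna(d$first_seq[i])
      validate_dna(d$second_seq[i])
      !is.na(d$yield[i]) && d$yield[i] >= 0 && d$yield[i] <= 1
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop(sprintf("row %d: %s", i,
                   if (is.character(ok)) ok else "yield outside [0, 1]"),
           call. = FALSE)
    }
  }
  data.frame(first = d$first_seq, second = d$second_seq, yield = d$yield,
             stringsAsFactors = FALSE)
}
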