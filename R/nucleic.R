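## DNA sequence primitives shared by every other module. Sequences are plain
## uppercase character scalars over {A,T,C,G}; base matrices are 4 x L numeric
## matrices with fixed row order A, T, C, G (the order the encoder emits, not
## alphabetical).

DNA_BASES <- c("A", "T", "C", "G")

#' Validate a DNA sequence
#'
#' Checks that `seq` is a single non-empty string over the uppercase alphabet
#' `{A, T, C, G}`. Lowercase input is rejected rather than silently upcased so
#' that data errors surface at the boundary.
#'
#' @param seq Character scalar.
#' @return `seq`, invisibly, if valid; otherwise an error naming the first
#'   offending position.
#' @export
validate_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("DNA sequence must be a single character string", call. = FALSE)
  }
  if (nchar(seq) < 1L) {
    stop("DNA sequence must have length >= 1", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (alphabet is A,T,C,G)",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA sequence
#'
#' The natural binding partner of a strand: complement every base (A-T, C-G)
#' and reverse the order, so the result reads 5'->3' on the opposite strand.
#'
#' @param seq DNA sequence (character scalar over A,T,C,G).
#' @return Character scalar of the same length.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  validate_dna(seq)
  comp <- chartr("ATCG", "TAGC", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Detect homopolymer runs
#'
#' A homopolymer is a run of `min_run` or more identical consecutive bases
#' (e.g. `AAA`, `TTTT`). Predictor training pairs exclude such sequences for
#' synthesis realism.
#'
#' @param seq DNA sequence.
#' @param min_run Minimum run length counted as a homopolymer (default 3).
#' @return Logical scalar.
#' @export
has_homopolymer <- function(seq, min_run = 3L) {
  validate_dna(seq)
  if (min_run < 2L) stop("min_run must be >= 2", call. = FALSE)
  grepl(sprintf("([ATCG])\\1{%d,}", as.integer(min_run) - 1L), seq)
}

#' One-hot encode a DNA sequence
#'
#' @param seq DNA sequence of length L.
#' @return A hard 4 x L base matrix; rows ordered A, T, C, G; column j is the
#'   indicator of base j.
#' @export
one_hot <- function(seq) {
  validate_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  m <- matrix(0, nrow = 4L, ncol = length(chars),
              dimnames = list(DNA_BASES, NULL))
  m[cbind(idx, seq_along(idx))] <- 1
  m
}

#' Decode a base matrix to a DNA sequence
#'
#' Per column the base of the maximal row is emitted, so a soft (softmax)
#' encoder output becomes a discrete sequence. Ties are broken by row order
#' A < T < C < G, giving deterministic decoding.
#'
#' @param m A 4 x L numeric matrix (soft or hard), rows ordered A, T, C, G.
#' @return Character scalar of length L.
#' @export
decode_base_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4L || ncol(m) < 1L || !is.numeric(m)) {
    stop("base matrix must be a numeric 4 x L matrix with L >= 1",
         call. = FALSE)
  }
  ## max.col(ties.method = "first") on the transpose picks the lowest row
  ## index among ties, i.e. A < T < C < G.
  idx <- max.col(t(m), ties.method = "first")
  paste(DNA_BASES[idx], collapse = "")
}

#' Draw a uniform random DNA sequence
#'
#' Samples uniformly over all sequences of the given length. With
#' `forbid_homopolymer = TRUE` sampling is constructive: each base is drawn
#' uniformly from the bases that do not extend a run of two, so every
#' admissible sequence is reachable, no draw is rejected, and the output is
#' guaranteed homopolymer-free.
#'
#' @param length Sequence length (>= 1).
#' @param forbid_homopolymer Exclude runs of 3+ identical bases?
#' @param seed Optional integer seed; same seed gives the same sequence.
#' @return Character scalar.
#' @export
random_sequence <- function(length, forbid_homopolymer = FALSE, seed = NULL) {
  stopifnot(length >= 1L)
  with_seed(seed, {
    if (!forbid_homopolymer) {
      paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    } else {
      out <- character(length)
      run <- 0L
      prev <- ""
      for (i in seq_len(length)) {
        pool <- if (run >= 2L) setdiff(DNA_BASES, prev) else DNA_BASES
        b <- sample(pool, 1L)
        run <- if (identical(b, prev)) run + 1L else 1L
        prev <- b
        out[i] <- b
      }
      paste(out, collapse = "")
    }
  })
}

#' Read DNA records from a FASTA file
#'
#' Thin wrapper over [seqinr::read.fasta()] that enforces the package's
#' uppercase A,C,G,T alphabet. Headers written by this package follow the
#' `"classLabel|instanceIndex"` dialect so a tube library can be rebuilt from
#' disk (see [build_library()]).
#'
#' @param path FASTA file.
#' @return A data frame with columns `id` and `seq` (zero rows for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) %in% c(0L, NA_integer_)) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- vapply(recs, as.character, character(1))
  for (i in seq_along(seqs)) {
    tryCatch(validate_dna(seqs[[i]]),
             error = function(e) stop(sprintf("record '%s': %s", ids[[i]],
                                              conditionMessage(e)),
                                      call. = FALSE))
  }
  data.frame(id = unname(ids), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write DNA records to a FASTA file
#'
#' Sequences are written 5'->3' with 80-column wrapping.
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  lapply(records$seq, validate_dna)
  seqinr::write.fasta(as.list(records$seq), names = records$id,
                      file.out = path, nbchar = 80L)
  invisible(path)
}

#' Parse a "classLabel|instanceIndex" FASTA header
#'
#' @param id Header string such as `"3|0017"`.
#' @return List with integer fields `class` and `index`.
#' @export
parse_instance_id <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    stop(sprintf("header '%s' does not follow 'classLabel|instanceIndex'", id),
         call. = FALSE)
  }
  list(class = as.integer(parts[1L]), index = as.integer(parts[2L]))
}
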