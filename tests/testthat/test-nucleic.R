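test_that("reverse complement follows the definition and is an involution", {
  expect_identical(reverse_complement("ATGC"), "GCAT")
  expect_identical(reverse_complement("ACGT"), "ACGT")  # palindrome
  set.seed(101)
  for (i in 1:100) {
    s <- random_sequence(59)
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(nchar(reverse_complement(s)), nchar(s))
  }
})

test_that("reverse complement agrees with Biostrings", {
  set.seed(102)
  for (i in 1:25) {
    s <- random_sequence(sample(5:80, 1))
    expect_identical(
      reverse_complement(s),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("sequence validation names the offending position", {
  expect_error(validate_dna("ACGU"), "position 4")
  expect_error(validate_dna("acgt"), "position 1")  # lowercase rejected
  expect_error(validate_dna(""), "length >= 1")
  expect_error(validate_dna(c("AC", "GT")), "single character string")
})

test_that("homopolymer detection is exact for short runs", {
  expect_false(has_homopolymer("AATAAC"))
  expect_true(has_homopolymer("GAAAT"))
  expect_true(has_homopolymer("TTTTG"))
  for (base in c("A", "T", "C", "G")) {
    pad <- setdiff(c("A", "T", "C", "G"), base)[1:2]   # cannot extend the run
    for (k in 1:6) {
      run <- strrep(base, k)
      padded <- paste0(pad[1], pad[2], run, pad[2], pad[1])
      expect_identical(has_homopolymer(padded), k >= 3,
                       label = sprintf("run %s x %d (padded)", base, k))
      expect_identical(has_homopolymer(run), k >= 3,
                       label = sprintf("run %s x %d", base, k))
    }
  }
  expect_true(has_homopolymer("AAT", min_run = 2))
  expect_error(has_homopolymer("AAT", min_run = 1))
})

test_that("one-hot uses row order A,T,C,G and round-trips with decoding", {
  expect_equal(one_hot("A")[, 1], c(A = 1, T = 0, C = 0, G = 0))
  expect_equal(one_hot("G")[, 1], c(A = 0, T = 0, C = 0, G = 1))
  set.seed(103)
  for (i in 1:20) {
    s <- random_sequence(sample(1:70, 1))
    expect_identical(decode_base_matrix(one_hot(s)), s)
  }
})

test_that("base-matrix decoding takes the argmax and breaks ties A<T<C<G", {
  expect_identical(decode_base_matrix(matrix(c(0.1, 0.6, 0.2, 0.1))), "T")
  expect_identical(decode_base_matrix(matrix(rep(0.25, 4))), "A")
  expect_identical(decode_base_matrix(matrix(c(0.1, 0.4, 0.4, 0.1))), "T")
  expect_identical(decode_base_matrix(matrix(c(0.1, 0.1, 0.4, 0.4))), "C")
  soft <- matrix(runif(4 * 59), 4, 59)
  soft <- sweep(soft, 2, colSums(soft), "/")
  expect_identical(nchar(decode_base_matrix(soft)), 59L)
  expect_error(decode_base_matrix(matrix(numeric(0), 4, 0)))
})

test_that("random sequences are deterministic given a seed and uniform", {
  expect_identical(random_sequence(59, seed = 7), random_sequence(59, seed = 7))
  s <- random_sequence(59, forbid_homopolymer = TRUE, seed = 8)
  expect_false(has_homopolymer(s))
  for (i in 1:50) {
    expect_false(has_homopolymer(random_sequence(30, TRUE, seed = i)))
  }
  ## all 256 4-mers appear with uniform frequency (chi-square)
  draws <- vapply(1:10000, function(i) random_sequence(4, seed = NULL),
                  character(1))
  counts <- table(draws)
  expect_identical(length(counts), 256L)
  expect_gt(chisq.test(as.numeric(counts))$p.value, 1e-4)
})

test_that("FASTA records round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".fasta")
  recs <- data.frame(id = c("3|0017", "5|0002", "q1"),
                     seq = c(random_sequence(59, seed = 1),
                             random_sequence(120, seed = 2),
                             "ACGTACGT"))
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_identical(back, recs)
  hdr <- parse_instance_id(back$id[1])
  expect_identical(hdr, list(class = 3L, index = 17L))
  expect_error(parse_instance_id("noclass"), "classLabel")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_identical(nrow(read_fasta(empty)), 0L)

  badpath <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGNT"), badpath)
  expect_error(read_fasta(badpath), "invalid character")
})
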