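test_that("the bundled nearest-neighbor table loads and is stabilizing", {
  p <- nn_params()
  expect_s3_class(p, "nn_params")
  expect_setequal(names(p$stack_dH),
                  c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC",
                    "GG"))
  dg37 <- p$stack_dH - 310.15 * p$stack_dS / 1000
  expect_true(all(dg37 < 0))
  ## expansion covers all 16 dinucleotides via reverse-complement symmetry
  sm <- hybriclass:::stack_dg_matrix(p, 37)
  expect_false(anyNA(sm))
  expect_equal(sm["A", "A"], sm["T", "T"])
  expect_equal(sm["C", "A"], sm["T", "G"])
})

test_that("reaction conditions are validated", {
  cond <- hybridization_conditions()
  expect_equal(cond$temperature_celsius, 25)
  expect_equal(cond$initial_concentration_molar, 1e-9)
  expect_identical(cond$max_complex_size, 2L)
  expect_error(hybridization_conditions(temperature_celsius = 150), "100")
  expect_error(hybridization_conditions(initial_concentration_molar = 0),
               "> 0")
  expect_error(hybridization_conditions(adapter = "not a function"),
               "function")
})

test_that("a perfect duplex energy is the stack sum plus initiation", {
  p <- nn_params()
  s <- "ATCGGATCCGAT"   # fixed 12-nt regression sequence
  tk <- 25 + 273.15
  sm <- hybriclass:::stack_dg_matrix(p, 25)
  chars <- strsplit(s, "")[[1]]
  hand <- p$init_dH - tk * p$init_dS / 1000 +
    sum(vapply(1:11, function(i) sm[chars[i], chars[i + 1]], numeric(1)))
  expect_equal(duplex_free_energy(s, reverse_complement(s)), hand,
               tolerance = 1e-10)
})

test_that("strands with no complementary pair give the no-binding sentinel", {
  expect_identical(duplex_free_energy(strrep("A", 10), strrep("A", 10)), Inf)
  expect_identical(duplex_free_energy("A", "T"), Inf)  # below minimum length
  expect_equal(predict_yield(strrep("A", 10), strrep("A", 10)), 0)
})

test_that("the duplex DP matches brute-force enumeration on short pairs", {
  set.seed(301)
  p <- nn_params()
  for (i in 1:200) {
    na <- sample(2:12, 1)
    nb <- sample(2:12, 1)
    a <- random_sequence(na)
    b <- random_sequence(nb)
    dp <- duplex_free_energy(a, b, p)
    bf <- brute_force_duplex_dg(a, b, p)
    expect_equal(dp, bf, tolerance = 1e-9,
                 label = sprintf("pair %s / %s", a, b))
    ## loops can only help relative to the best ungapped registration
    expect_lte(dp, ungapped_offset_dg(a, b, p) + 1e-9)
  }
})

test_that("equilibrium yield solves the two-state mass action exactly", {
  cond <- hybridization_conditions()
  ## K * c0 = 1  =>  y = (3 - sqrt(5)) / 2
  tk <- 25 + 273.15
  dg1 <- 1.98720425864083e-3 * tk * log(cond$initial_concentration_molar)
  expect_equal(equilibrium_yield(dg1, cond), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  for (dg in seq(-80, 10, by = 2.5)) {
    expect_lt(abs(equilibrium_yield(dg, cond) - bisection_yield(dg, cond)),
              1e-9, label = sprintf("dG = %g", dg))
  }
  expect_equal(equilibrium_yield(Inf, cond), 0)
  expect_equal(equilibrium_yield(-1e6, cond), 1)  # complete-binding limit
})

test_that("yield is monotone in free energy and concentration", {
  dgs <- seq(-40, 5, by = 0.5)
  y <- equilibrium_yield(dgs, hybridization_conditions())
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(diff(y) <= 1e-12))
  y_lo <- equilibrium_yield(-12, hybridization_conditions(
    initial_concentration_molar = 1e-10))
  y_hi <- equilibrium_yield(-12, hybridization_conditions(
    initial_concentration_molar = 1e-8))
  expect_gt(y_hi, y_lo)
})

test_that("predict_yield is symmetric and bounded", {
  set.seed(302)
  cond <- hybridization_conditions()
  for (i in 1:40) {
    a <- random_sequence(sample(6:59, 1))
    b <- random_sequence(sample(6:59, 1))
    ya <- predict_yield(a, b, cond)
    expect_equal(ya, predict_yield(b, a, cond), tolerance = 1e-12)
    expect_gte(ya, 0); expect_lte(ya, 1)
  }
})

test_that("perfect complements bind, unrelated strands mostly do not", {
  set.seed(303)
  cond <- hybridization_conditions()
  for (i in 1:10) {
    s <- random_sequence(59)
    expect_gt(predict_yield(s, reverse_complement(s), cond), 0.99)
  }
  rnd <- vapply(1:50, function(i)
    predict_yield(random_sequence(59), random_sequence(59), cond), numeric(1))
  expect_lt(median(rnd), 0.05)
})

test_that("yield_matrix agrees with elementwise prediction", {
  set.seed(304)
  cond <- hybridization_conditions()
  q <- vapply(1:3, function(i) random_sequence(20), character(1))
  t <- vapply(1:5, function(i) random_sequence(20), character(1))
  M <- yield_matrix(q, t, cond)
  expect_identical(dim(M), c(3L, 5L))
  expect_equal(M[2, 4], predict_yield(q[2], t[4], cond), tolerance = 1e-12)
  expect_equal(yield_matrix(q[1], t[1], cond)[1, 1],
               predict_yield(q[1], t[1], cond))
  S <- yield_matrix(q, q, cond)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  expect_error(yield_matrix(character(0), t), "non-empty")
})

test_that("the external adapter contract is enforced and honoured", {
  expect_error(
    predict_yield("ACGT", "ACGT",
                  hybridization_conditions(backend = "external_adapter")),
    "no adapter registered")
  calls <- new.env(); calls$n <- 0L
  adapter <- function(a, b, conditions) { calls$n <- calls$n + 1L; 0.42 }
  cond <- hybridization_conditions(backend = "external_adapter",
                                   adapter = adapter)
  expect_equal(predict_yield("ACGT", "TTTT", cond), 0.42)
  M <- yield_matrix(c("ACGT", "GGCC"), c("TTAA"), cond)
  expect_equal(as.numeric(M), c(0.42, 0.42))
  expect_identical(calls$n, 3L)
})
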