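test_that("the literal sequence loss reproduces the full truth table", {
  cfg <- loss_config(t1 = 16, t2 = 0.8, mode = "literal")
  lo_e <- 10; hi_e <- 20; lo_y <- 0.5; hi_y <- 0.9
  cases <- expand.grid(e = c(lo_e, hi_e), y = c(lo_y, hi_y),
                       same = c(TRUE, FALSE))
  expected <- with(cases, ifelse(e < 16 & y < 0.8 & same, 1,
                          ifelse(e >= 16 & y >= 0.8 & !same, 1, 0)))
  got <- mapply(function(e, y, same)
    sequence_loss(e, y, 1L, if (same) 1L else 2L, cfg),
    cases$e, cases$y, cases$same)
  expect_equal(unname(got), expected)
  ## the four named branches, spelled out
  expect_equal(sequence_loss(10, 0.5, 1, 1, cfg), 1)  # close, low yield, same
  expect_equal(sequence_loss(20, 0.9, 1, 2, cfg), 1)  # far, high yield, diff
  expect_equal(sequence_loss(20, 0.9, 1, 1, cfg), 0)  # far, high yield, same
  expect_equal(sequence_loss(10, 0.5, 1, 2, cfg), 0)  # close, low, diff
  ## boundary semantics: E = T1 counts as far, Y = T2 as high
  expect_equal(sequence_loss(16, 0.8, 1, 2, cfg), 1)
  expect_equal(sequence_loss(16, 0.79, 1, 2, cfg), 0)
})

test_that("the hinge surrogate is continuous and vanishes with the literal", {
  cfg <- loss_config()          # surrogate by default
  lit <- loss_config(mode = "literal")
  expect_equal(sequence_loss(10, 0.5, 1, 1, cfg), 0.3)  # max(0, 0.8 - 0.5)
  expect_equal(sequence_loss(20, 0.9, 1, 2, cfg), 0.1, tolerance = 1e-12)
  set.seed(601)
  for (i in 1:200) {
    e <- runif(1, 0, 40); y <- runif(1)
    l1 <- sample(0:9, 1); l2 <- sample(0:9, 1)
    s <- sequence_loss(e, y, l1, l2, cfg)
    expect_gte(s, 0)
    if (sequence_loss(e, y, l1, l2, lit) == 0) {
      expect_equal(s, 0, label = sprintf("e=%.2f y=%.2f", e, y))
    }
  }
})

test_that("encoding loss penalizes only under-confident columns", {
  cfg <- loss_config()
  conf <- one_hot(random_sequence(59, seed = 9)) * 0.94 + 0.015
  expect_equal(encoding_loss(conf, cfg), 0)
  m <- conf
  m[, 3] <- rep(0.25, 4)
  expect_equal(encoding_loss(m, cfg), log(4), tolerance = 1e-12)
  m2 <- conf
  m2[, 10] <- c(0.49, 0.17, 0.17, 0.17)
  expect_equal(encoding_loss(m2, cfg), -log(0.49), tolerance = 1e-12)
  ## 0 iff all columns confident; strictly positive otherwise
  expect_gt(encoding_loss(m, cfg), 0)
  expect_error(encoding_loss(conf * 2, cfg), "normalized")
})

test_that("encoder loss adds both encoding terms and the sequence term", {
  cfg <- loss_config(mode = "literal")
  conf <- one_hot(random_sequence(59, seed = 10)) * 0.94 + 0.015
  unif <- matrix(0.25, 4, 59)
  expect_equal(encoder_loss(conf, conf, e = 10, yield = 0.9, 1, 1, cfg), 0)
  expect_equal(encoder_loss(conf, conf, e = 10, yield = 0.5, 1, 1, cfg), 1)
  expect_equal(encoder_loss(unif, conf, e = 10, yield = 0.9, 1, 1, cfg),
               59 * log(4), tolerance = 1e-9)
})

test_that("the encoder emits normalized 4 x 59 soft matrices", {
  enc <- build_encoder(seed = 20)
  FT <- matrix(rnorm(3 * 50), 3, 50)
  out <- predict(enc, FT)
  expect_length(out, 3L)
  expect_identical(dim(out[[1]]), c(4L, 59L))
  expect_equal(colSums(out[[1]]), rep(1, 59), tolerance = 1e-6)
  expect_identical(build_encoder(seed = 20)$params, enc$params)
  single <- predict(enc, FT[1, ])
  expect_equal(single, out[[1]])
})

test_that("stage-3 training updates only encoder parameters", {
  ds <- tiny_corpus()
  fe <- train_feature_extractor(build_feature_extractor(seed = 21),
                                ds$train$images, ds$train$labels,
                                epochs = 2, seed = 22)
  pr <- train_predictor(build_predictor(seed = 23),
                        generate_pairs(300, seed = 50), epochs = 1,
                        seed = 24)
  fe_sum <- hybriclass:::params_checksum(fe$params)
  pr_sum <- hybriclass:::params_checksum(pr$params)
  enc0 <- build_encoder(seed = 25)
  t1 <- calibrate_t1(extract_features(fe, ds$train$images), seed = 26)
  enc <- train_encoder(fe, pr, ds$train$images, ds$train$labels,
                       encoder = enc0, cfg = loss_config(t1 = t1),
                       epochs = 1, pairs_per_epoch = 256, seed = 27)
  expect_true(enc$trained)
  expect_false(identical(enc$params, enc0$params))
  expect_identical(hybriclass:::params_checksum(fe$params), fe_sum)
  expect_identical(hybriclass:::params_checksum(pr$params), pr_sum)
  ## reproducible loss trace
  enc2 <- train_encoder(fe, pr, ds$train$images, ds$train$labels,
                        encoder = build_encoder(seed = 25),
                        cfg = loss_config(t1 = t1),
                        epochs = 1, pairs_per_epoch = 256, seed = 27)
  expect_identical(enc$loss_trace, enc2$loss_trace)
  ## literal mode runs but warns about the flat loss
  expect_warning(
    train_encoder(fe, pr, ds$train$images, ds$train$labels,
                  encoder = build_encoder(seed = 25),
                  cfg = loss_config(t1 = t1, mode = "literal"),
                  epochs = 1, pairs_per_epoch = 64, seed = 28),
    "piecewise")
  ## untrained upstream models are refused
  expect_error(train_encoder(build_feature_extractor(seed = 1), pr,
                             ds$train$images, ds$train$labels),
               "trained")

  ## encode_image: deterministic 59-nt sequences over ACGT
  s1 <- encode_image(fe, enc, ds$train$images[1, , ])
  s2 <- encode_image(fe, enc, ds$train$images[1, , ])
  expect_identical(s1, s2)
  expect_identical(nchar(s1), 59L)
  expect_silent(validate_dna(s1))
})

test_that("T1 calibration tracks the requested distance percentile", {
  set.seed(602)
  FT <- matrix(rnorm(200 * 50), 200, 50)
  t1 <- calibrate_t1(FT, prob = 0.3, n_pairs = 5000, seed = 1)
  d <- as.numeric(dist(FT))
  expect_equal(t1, unname(quantile(d, 0.3)), tolerance = 0.25)
  expect_identical(calibrate_t1(FT, seed = 2), calibrate_t1(FT, seed = 2))
})
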