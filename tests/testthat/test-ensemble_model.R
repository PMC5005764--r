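test_that("downsampling draws seeded subsets of the requested geometry", {
  set.seed(41)
  neg <- random_peptides(60, prefix = "n")
  subs <- downsample_negatives(neg, n_subsets = 5, subset_size = 12, seed = 9)
  expect_length(subs, 5L)
  expect_true(all(vapply(subs, nrow, integer(1)) == 12L))
  for (s in subs) {
    expect_false(anyDuplicated(s$sequence) > 0)  # without replacement
    expect_true(all(s$sequence %in% neg$sequence))
  }
  # determinism and seed sensitivity
  subs2 <- downsample_negatives(neg, 5, 12, seed = 9)
  expect_identical(lapply(subs, `[[`, "id"), lapply(subs2, `[[`, "id"))
  subs3 <- downsample_negatives(neg, 5, 12, seed = 10)
  expect_false(identical(lapply(subs, `[[`, "id"), lapply(subs3, `[[`, "id")))

  # subset_size equal to the pool returns the full set every time
  full <- downsample_negatives(neg, 3, nrow(neg), seed = 1)
  for (s in full) expect_equal(s$sequence, neg$sequence)

  expect_error(downsample_negatives(neg, 2, nrow(neg) + 1), "exceeds")
})

test_that("a submodel separates a motif benchmark and honours a one-cell grid", {
  # every positive carries the motif, no negative does: separable by design
  bench <- generate_benchmark(benchmark_spec(n_pos = 40, n_neg = 60,
                                             motif_rate = 1), seed = 43)
  sub <- downsample_negatives(bench$negatives, 1, 40, seed = 1)[[1]]
  m <- train_submodel(bench$positives, sub, "DPC", svm_config = fast_cfg,
                      seed = 2)
  expect_gte(m$cv_accuracy, 0.95)
  expect_equal(m$cost, 8)
  expect_equal(m$gamma, 2^-3)

  fm <- encode_peptides(bench$positives, dpc_descriptors())
  p <- sbpred:::predict_submodel(m, fm)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p), 0.7)
})

test_that("no-signal data yields chance-level cross-validated accuracy", {
  set.seed(44)
  pool <- random_peptides(100)
  idx <- sample(nrow(pool), 50)
  fake_pos <- peptide_set(pool$sequence[idx], label = "positive")
  fake_neg <- peptide_set(pool$sequence[-idx], label = "negative")
  m <- train_submodel(fake_pos, fake_neg, "AAC", svm_config = fast_cfg,
                      seed = 3)
  expect_lte(abs(m$cv_accuracy - 0.5), 0.12)
})

test_that("overlapping training sets are refused", {
  pos <- peptide_set(c("HPQA", "HPQC"))
  neg <- peptide_set(c("HPQA", "WWWW"))
  expect_error(train_submodel(pos, neg, "AAC", svm_config = fast_cfg),
               "overlap")
  expect_error(train_ensemble(pos, neg, "AAC", svm_config = fast_cfg),
               "overlap")
})

test_that("ensemble predictions average submodels, count votes and threshold on tp", {
  bench <- tiny_benchmark(n_pos = 30, n_neg = 90, seed = 45)
  model <- train_ensemble(bench$positives, bench$negatives, "AAC",
                          svm_config = fast_cfg, n_subsets = 4, seed = 6)
  expect_length(model$submodels, 4L)
  expect_equal(model$metadata$seed, 6L)

  query <- peptide_set(c(bench$positives$sequence[1:10],
                         bench$negatives$sequence[1:10]))
  pr <- predict(model, query)
  probs <- attr(pr, "submodel_probabilities")
  expect_equal(pr$mean_probability, unname(rowMeans(probs)))
  expect_equal(pr$votes, unname(as.integer(rowSums(probs >= 0.5))))
  expect_true(all(pr$call %in% c("SBP", "non-SBP")))

  # votes are invariant to tp; calls are monotone in tp
  thresholds <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  calls <- lapply(thresholds, function(tp) predict(model, query, tp = tp))
  for (i in seq_along(thresholds)) {
    expect_equal(calls[[i]]$votes, pr$votes)
    if (i > 1) {
      called_high <- calls[[i]]$id[calls[[i]]$call == "SBP"]
      called_low <- calls[[i - 1]]$id[calls[[i - 1]]$call == "SBP"]
      expect_true(all(called_high %in% called_low))
    }
  }
  # boundary: mean exactly at tp is called SBP
  expect_equal(ifelse(pr$mean_probability >= 0.5, "SBP", "non-SBP"), pr$call)
})

test_that("a one-subset ensemble is prediction-identical to its lone submodel", {
  bench <- tiny_benchmark(n_pos = 25, n_neg = 50, seed = 46)
  model <- train_ensemble(bench$positives, bench$negatives, "AAC",
                          svm_config = fast_cfg, n_subsets = 1, seed = 7)
  pr <- predict(model, bench$positives)
  fm <- encode_peptides(bench$positives, aac_descriptors())
  solo <- sbpred:::predict_submodel(model$submodels[[1]], fm)
  expect_equal(pr$mean_probability, unname(solo))
  expect_equal(pr$votes, as.integer(solo >= 0.5))
})

test_that("training is reproducible under a fixed seed", {
  bench <- tiny_benchmark(n_pos = 25, n_neg = 50, seed = 47)
  m1 <- train_ensemble(bench$positives, bench$negatives, "AAC",
                       svm_config = fast_cfg, n_subsets = 2, seed = 11)
  m2 <- train_ensemble(bench$positives, bench$negatives, "AAC",
                       svm_config = fast_cfg, n_subsets = 2, seed = 11)
  pr1 <- predict(m1, bench$negatives)
  pr2 <- predict(m2, bench$negatives)
  expect_identical(pr1$mean_probability, pr2$mean_probability)
  expect_identical(lapply(m1$submodels, `[[`, "negative_ids"),
                   lapply(m2$submodels, `[[`, "negative_ids"))
})

test_that("manual RBF decision values agree with the fitted library model", {
  set.seed(48)
  bench <- tiny_benchmark(n_pos = 30, n_neg = 40, seed = 48)
  sub <- downsample_negatives(bench$negatives, 1, 30, seed = 1)[[1]]
  fm <- sbpred:::encode_pair(bench$positives, sub, "DPC")
  y <- attr(fm, "labels")
  fit <- sbpred:::fit_rbf(unclass(fm), y, 8, 2^-3)
  dec_lib <- sbpred:::decision_values(fit, unclass(fm))
  dec_man <- sbpred:::rbf_decision(unclass(fm), unname(as.matrix(fit$SV)),
                                   as.numeric(fit$coefs), as.numeric(fit$rho),
                                   2^-3, sbpred:::model_orientation(fit))
  expect_equal(dec_man, dec_lib, tolerance = 1e-10)
})

test_that("model files round-trip bit-for-bit and reject corrupt input", {
  bench <- tiny_benchmark(n_pos = 25, n_neg = 50, seed = 49)
  model <- train_ensemble(bench$positives, bench$negatives, "OAAC",
                          svm_config = fast_cfg, n_subsets = 2, seed = 12)
  query <- random_peptides(100, prefix = "q")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)

  pr1 <- predict(model, query)
  pr2 <- predict(back, query)
  expect_identical(pr1$mean_probability, pr2$mean_probability)
  expect_identical(pr1$votes, pr2$votes)
  expect_identical(pr1$call, pr2$call)
  expect_equal(back$metadata$seed, 12L)
  expect_equal(back$consensus_features, model$consensus_features)

  # truncated file fails loudly
  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[seq_len(length(txt) %/% 2)], trunc)
  expect_error(load_model(trunc), "corrupt|truncated|parse")

  # version mismatch fails loudly
  vers <- withr::local_tempfile(fileext = ".json")
  writeLines(sub('"version": "1.0"', '"version": "9.9"', txt), vers)
  expect_error(load_model(vers), "version")

  expect_error(load_model(withr::local_tempfile(fileext = ".json")), "not found")
})

test_that("unencodable peptides get per-record notes instead of crashing", {
  bench <- tiny_benchmark(n_pos = 25, n_neg = 50, seed = 50)
  model <- train_ensemble(bench$positives, bench$negatives, "DPC",
                          svm_config = fast_cfg, n_subsets = 2, seed = 13)
  query <- peptide_set(c("HPQHPQ", "A", "AXKP"))
  pr <- predict(model, query)
  expect_equal(nrow(pr), 3L)
  expect_false(is.na(pr$call[1]))
  expect_true(is.na(pr$call[2]) && is.na(pr$call[3]))
  expect_match(pr$note[2], "shorter")
  expect_match(pr$note[3], "alphabet")
})
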