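test_that("confusion counts tabulate the 2x2 outcomes", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(cc2$FN, 1L)
  expect_equal(cc2$FP, 1L)
  expect_error(confusion_counts(c(1, 0, 1), c(1, 0)), "length")

  set.seed(51)
  truth <- runif(10) > 0.5
  calls <- runif(10) > 0.5
  cc3 <- confusion_counts(truth, calls)
  # brute-force tally
  expect_equal(cc3$TP, sum(truth & calls))
  expect_equal(cc3$FP, sum(!truth & calls))
  expect_equal(cc3$TN, sum(!truth & !calls))
  expect_equal(cc3$FN, sum(truth & !calls))
  expect_equal(cc3$TP + cc3$FP + cc3$TN + cc3$FN, 10L)
})

test_that("metric formulas reproduce worked examples and the brute-force oracle", {
  m <- classification_metrics(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(m$Acc, 1)
  expect_equal(m$MCC, 1)
  m2 <- classification_metrics(list(TP = 0, TN = 0, FP = 1, FN = 1))
  expect_equal(m2$MCC, -1)
  m3 <- classification_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m3$Sn, 0.6)
  expect_equal(m3$Sp, 0.8)
  expect_equal(m3$Acc, 0.7)
  expect_equal(m3$MCC, 10 / sqrt(600))

  set.seed(52)
  for (i in 1:200) {
    tb <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (sum(unlist(tb)) == 0) next
    got <- classification_metrics(tb)
    want <- brute_metrics(tb$TP, tb$FP, tb$TN, tb$FN)
    expect_equal(got$Acc, want$Acc)
    expect_equal(got$MCC, want$MCC)
    if (!is.nan(want$Sn)) expect_equal(got$Sn, want$Sn)
    if (!is.nan(want$Sp)) expect_equal(got$Sp, want$Sp)
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  # boundary behaviours
  expect_equal(roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_curve(runif(4), c(1, 1, 1, 1)), "both classes")

  set.seed(53)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n), 1)  # coarse scores force ties
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, mw_auc(scores, labels))
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[nrow(roc$points)], 1)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  scores <- runif(40)
  labels <- runif(40) > 0.4
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation separates a motif benchmark and not shuffled labels", {
  # every positive carries the motif: a cleanly separable pair
  bench <- generate_benchmark(benchmark_spec(n_pos = 40, n_neg = 80,
                                             motif_rate = 1), seed = 55)
  sub <- downsample_negatives(bench$negatives, 1, 40, seed = 1)[[1]]
  cv <- cross_validate(bench$positives, sub, "DPC", svm_config = fast_cfg,
                       seed = 2)
  expect_gte(cv$acc_mean, 0.95)
  expect_gte(cv$auc, 0.98)
  expect_equal(length(cv$fold_accuracies), 5L)
  expect_equal(cv$metrics$Acc,
               (cv$confusion$TP + cv$confusion$TN) / 80)

  set.seed(3)
  pool <- random_peptides(80)
  idx <- sample(nrow(pool), 40)
  cv0 <- cross_validate(peptide_set(pool$sequence[idx]),
                        peptide_set(pool$sequence[-idx]),
                        "AAC", svm_config = fast_cfg, seed = 4)
  expect_gte(cv0$acc_mean, 0.35)
  expect_lte(cv0$acc_mean, 0.65)
})

test_that("leave-one-out is a working degenerate case", {
  bench <- tiny_benchmark(n_pos = 8, n_neg = 16, seed = 56)
  sub <- downsample_negatives(bench$negatives, 1, 8, seed = 1)[[1]]
  cv <- cross_validate(bench$positives, sub, "AAC", svm_config = fast_cfg,
                       k = 16L, seed = 2)
  expect_length(cv$fold_accuracies, 16L)
})

test_that("nested selection mode runs and reports per-fold choices", {
  bench <- tiny_benchmark(n_pos = 15, n_neg = 30, seed = 57)
  sub <- downsample_negatives(bench$negatives, 1, 15, seed = 1)[[1]]
  cv <- cross_validate(bench$positives, sub, "OAAC", svm_config = fast_cfg,
                       k = 3L, seed = 2, nested = TRUE)
  expect_length(cv$selected, 3L)     # one token set per fold
  expect_length(cv$cost, 3L)
  expect_gte(cv$acc_mean, 0.5)
})

test_that("permutation p-values behave at the boundaries", {
  bench <- tiny_benchmark(n_pos = 20, n_neg = 40, seed = 58)
  sub <- downsample_negatives(bench$negatives, 1, 20, seed = 1)[[1]]
  res <- permutation_test(bench$positives, sub, "DPC", svm_config = fast_cfg,
                          n_permutations = 19, seed = 2)
  expect_true(res$p_is_upper_bound)
  expect_equal(res$p_value, 0)
  expect_output(print(res), "p < ")
  expect_equal(res$p_value, res$n_exceeding / res$n_permutations)
  expect_error(permutation_test(bench$positives, sub, "DPC",
                                n_permutations = 0), "at least 1")
})

test_that("positive rate reproduces simple fractions", {
  recs <- data.frame(call = rep(c("SBP", "non-SBP"), c(3, 7)))
  expect_equal(positive_rate(recs), 30)
  expect_equal(positive_rate(data.frame(call = rep("non-SBP", 5))), 0)
  expect_error(positive_rate(data.frame(call = character(0))), "no prediction")
  expect_warning(positive_rate(data.frame(call = c("SBP", NA))), "excluded")
})

test_that("chi-square comparison matches hand-computed expected counts", {
  # a = 8/10 vs b = 2/10; all marginals 10 so every expected count is 5
  cmp <- compare_rates(c(8, 10), c(2, 10))
  expect_equal(cmp$chi_square_statistic, (9 + 9 + 9 + 9) / 5)
  expect_equal(cmp$p_value,
               stats::pchisq(7.2, df = 1, lower.tail = FALSE))

  # identical rates give a null result
  same <- compare_rates(c(10, 100), c(20, 200))
  expect_equal(same$chi_square_statistic, 0)
  expect_equal(same$p_value, 1)

  # row swap leaves the statistic unchanged
  ab <- compare_rates(c(8, 10), c(2, 10))
  ba <- compare_rates(c(2, 10), c(8, 10))
  expect_equal(ab$chi_square_statistic, ba$chi_square_statistic)

  # degenerate table: nobody called positive anywhere
  expect_warning(zero <- compare_rates(c(0, 10), c(0, 20)), "degenerate")
  expect_equal(zero$chi_square_statistic, 0)
  expect_equal(zero$p_value, 1)
})

test_that("ROC points export as TSV", {
  roc <- roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roc(roc, path)
  back <- read.delim(path)
  expect_equal(back$fpr, roc$points$fpr)
  expect_equal(back$tpr, roc$points$tpr)
})
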