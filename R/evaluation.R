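to_binary <- function(x, what = "labels") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    stopifnot(all(x %in% c(0, 1)))
    return(x == 1)
  }
  x <- as.character(x)
  if (all(x %in% c("SBP", "non-SBP"))) return(x == "SBP")
  if (all(x %in% c("positive", "negative"))) return(x == "positive")
  stop("cannot interpret ", what, " as binary (use logical, 0/1, ",
       "\"positive\"/\"negative\" or \"SBP\"/\"non-SBP\")")
}

#' Cross-tabulate true labels against predicted calls
#'
#' @param truth True labels: logical, 0/1, or "positive"/"negative".
#' @param calls Predicted calls in any of the same encodings (including
#'   "SBP"/"non-SBP").
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(truth, calls) {
  truth <- to_binary(truth, "truth")
  calls <- to_binary(calls, "calls")
  if (length(truth) != length(calls)) {
    stop("truth and calls have different lengths (", length(truth), " vs ",
         length(calls), ")")
  }
  structure(list(TP = sum(truth & calls), FP = sum(!truth & calls),
                 TN = sum(!truth & !calls), FN = sum(truth & !calls)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' Sn = TP/(TP+FN), Sp = TN/(FP+TN), Acc = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' factor of the MCC denominator is zero the MCC is defined as 0 (the
#' no-information value).
#'
#' @param cc A `confusion_counts` object (or anything coercible: a list with
#'   fields TP, FP, TN, FN).
#' @return An object of class `classification_metrics` with fields `Sn`,
#'   `Sp`, `Acc`, `MCC`.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
classification_metrics <- function(cc) {
  TP <- as.numeric(cc$TP); FP <- as.numeric(cc$FP)
  TN <- as.numeric(cc$TN); FN <- as.numeric(cc$FN)
  total <- TP + FP + TN + FN
  if (total <= 0) stop("empty confusion table")
  den_factors <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(den_factors == 0)) 0 else
    (TP * TN - FP * FN) / sqrt(prod(den_factors))
  structure(list(Sn = TP / (TP + FN), Sp = TN / (FP + TN),
                 Acc = (TP + TN) / total, MCC = mcc),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("Sn = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.2f\n",
              100 * x$Sn, 100 * x$Sp, 100 * x$Acc, x$MCC))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over all distinct scores (equal scores are
#' grouped into one step) and integrates by the trapezoidal rule, which
#' equals the Mann-Whitney statistic: concordant score pairs plus half the
#' ties, over all positive/negative pairs.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (logical, 0/1 or "positive"/"negative"); both
#'   classes must be present.
#' @return An object of class `roc_curve`: list with `points` (data frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))$auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- to_binary(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into single threshold steps
  last_in_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(y)[last_in_group] / n_pos)
  fpr <- c(0, cumsum(!y)[last_in_group] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

# Core k-fold evaluation of one labelled matrix: grid search over the config,
# then held-out decision values at the winning (c, g). Shared by
# cross_validate() and the permutation trials.
cv_core <- function(X, y, config, k) {
  folds <- make_stratified_folds(y, k)
  best <- grid_search(X, y, config, folds)
  cvd <- cv_decision_values(X, y, best$cost, best$gamma, folds)
  list(cost = best$cost, gamma = best$gamma,
       fold_accuracies = cvd$fold_accuracies,
       decision_values = cvd$decision_values)
}

#' Cross-validate a classifier on one balanced pair
#'
#' Stratified k-fold cross-validation of an RBF-SVM on one
#' positive/negative pair. For the optimized feature kinds the default
#' protocol runs feature selection once on the whole pair before the
#' cross-validation (the evaluation the published accuracies use); with
#' `nested = TRUE` selection and tuning are instead re-run inside every
#' training fold, which avoids selection leakage and gives the statistically
#' honest (usually lower) estimate.
#'
#' @inheritParams train_submodel
#' @param k Number of folds (default 5).
#' @param nested Re-run feature selection within each training fold
#'   (default FALSE; see Details).
#' @return An object of class `cv_report`: per-fold accuracies, their mean
#'   and sd, pooled confusion counts and `classification_metrics`, the
#'   pooled `roc_curve` and its AUC, the selected tokens (optimized kinds),
#'   and the chosen (c, g).
#' @export
cross_validate <- function(positives, negative_subset,
                           feature_kind = c("ODPC", "DPC", "AAC", "OAAC"),
                           svm_config = svm_config_reduced(),
                           selection_config = svm_config_selection(),
                           k = 5L, seed = NULL, nested = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.null(seed)) set.seed(seed)
  fm <- encode_pair(positives, negative_subset, feature_kind)
  y <- fm_labels(fm)
  optimized <- feature_kind %in% c("OAAC", "ODPC")

  if (!nested) {
    tokens <- if (optimized) select_features(fm, selection_config, k)$selected
              else colnames(fm)
    core <- cv_core(select_columns(fm, tokens), y, svm_config, k)
    dec <- core$decision_values
    fold_acc <- core$fold_accuracies
    cost <- core$cost; gamma <- core$gamma
  } else {
    folds <- make_stratified_folds(y, k)
    dec <- numeric(length(y))
    fold_acc <- numeric(k)
    cost <- gamma <- rep(NA_real_, k)
    tokens <- vector("list", k)
    for (f in seq_len(k)) {
      test <- folds[[f]]
      fm_tr <- structure(fm[-test, , drop = FALSE], class = class(fm),
                         kind = attr(fm, "kind"), labels = y[-test])
      tk <- if (optimized) select_features(fm_tr, selection_config, k)$selected
            else colnames(fm)
      tokens[[f]] <- tk
      Xtr <- select_columns(fm_tr, tk)
      best <- grid_search(Xtr, y[-test], svm_config,
                          make_stratified_folds(y[-test], k))
      fit <- fit_rbf(Xtr, y[-test], best$cost, best$gamma)
      dec[test] <- decision_values(fit, fm[test, tk, drop = FALSE])
      fold_acc[f] <- mean((dec[test] >= 0) == y[test])
      cost[f] <- best$cost; gamma[f] <- best$gamma
    }
  }

  cc <- confusion_counts(y, dec >= 0)
  roc <- roc_curve(dec, y)
  structure(list(feature_kind = feature_kind,
                 nested = nested,
                 selected = if (optimized) tokens else NULL,
                 cost = cost, gamma = gamma,
                 fold_accuracies = fold_acc,
                 acc_mean = mean(fold_acc),
                 acc_sd = sd(fold_acc),
                 confusion = cc,
                 metrics = classification_metrics(cc),
                 roc = roc,
                 auc = roc$auc,
                 decision_values = dec,
                 labels = y),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s %d-fold cross-validation (%s)\n", x$feature_kind,
              length(x$fold_accuracies),
              if (x$nested) "nested selection" else "selection on full pair"))
  cat(sprintf("  accuracy: %.2f%% +/- %.2f%% | pooled ", 100 * x$acc_mean,
              100 * x$acc_sd))
  print(x$metrics)
  cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Cross-validate the full downsampling ensemble
#'
#' Draws the ensemble's negative subsets, runs [cross_validate()] on each of
#' the balanced pairs, and summarizes across pairs: mean and sd of the
#' per-pair accuracy, sensitivity, specificity and MCC, the mean per-pair
#' AUC, a pooled ROC over all held-out decision values, and (for optimized
#' kinds) the consensus features selected in at least half of the pairs.
#'
#' @inheritParams train_ensemble
#' @inheritParams cross_validate
#' @return An object of class `ensemble_cv_report` with elements `per_pair`
#'   (list of `cv_report`), `summary` (data frame of mean/sd per metric),
#'   `pooled_roc`, `pooled_auc`, `consensus_features`.
#' @export
ensemble_cv <- function(positives, negatives,
                        feature_kind = c("ODPC", "DPC", "AAC", "OAAC"),
                        svm_config = svm_config_reduced(),
                        selection_config = svm_config_selection(),
                        n_subsets = 10L, subset_size = NULL, k = 5L,
                        seed = NULL, nested = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (is.null(subset_size)) subset_size <- nrow(positives)
  if (!is.null(seed)) set.seed(seed)
  subsets <- downsample_negatives(negatives, n_subsets, subset_size)
  pair_seeds <- sample.int(.Machine$integer.max, n_subsets)

  per_pair <- lapply(seq_len(n_subsets), function(i) {
    cross_validate(positives, subsets[[i]], feature_kind,
                   svm_config = svm_config,
                   selection_config = selection_config,
                   k = k, seed = pair_seeds[i], nested = nested)
  })

  pull <- function(f) vapply(per_pair, f, numeric(1))
  summ <- data.frame(
    metric = c("Sn", "Sp", "Acc", "MCC", "AUC"),
    mean = c(mean(pull(function(r) r$metrics$Sn)),
             mean(pull(function(r) r$metrics$Sp)),
             mean(pull(function(r) r$acc_mean)),
             mean(pull(function(r) r$metrics$MCC)),
             mean(pull(function(r) r$auc))),
    sd = c(sd(pull(function(r) r$metrics$Sn)),
           sd(pull(function(r) r$metrics$Sp)),
           sd(pull(function(r) r$acc_mean)),
           sd(pull(function(r) r$metrics$MCC)),
           sd(pull(function(r) r$auc))))

  dec_all <- unlist(lapply(per_pair, `[[`, "decision_values"))
  lab_all <- unlist(lapply(per_pair, `[[`, "labels"))
  pooled <- roc_curve(dec_all, lab_all)

  consensus <- NULL
  if (feature_kind %in% c("OAAC", "ODPC")) {
    all_tokens <- unlist(lapply(per_pair, function(r)
      if (is.list(r$selected)) unique(unlist(r$selected)) else r$selected))
    tab <- table(all_tokens)
    consensus <- sort(names(tab)[tab >= ceiling(n_subsets / 2)])
  }

  structure(list(feature_kind = feature_kind, per_pair = per_pair,
                 summary = summ, pooled_roc = pooled, pooled_auc = pooled$auc,
                 consensus_features = consensus),
            class = "ensemble_cv_report")
}

#' @export
print.ensemble_cv_report <- function(x, ...) {
  cat(sprintf("%s ensemble cross-validation over %d pairs\n", x$feature_kind,
              length(x$per_pair)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    scale <- if (s$metric[i] %in% c("MCC", "AUC")) 1 else 100
    unit <- if (scale == 100) "%" else ""
    cat(sprintf("  %-4s %6.2f%s +/- %.2f%s\n", s$metric[i],
                scale * s$mean[i], unit, scale * s$sd[i], unit))
  }
  cat(sprintf("  pooled AUC = %.4f\n", x$pooled_auc))
  if (!is.null(x$consensus_features)) {
    cat("  consensus features: ", paste(x$consensus_features, collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Label-permutation significance test
#'
#' Shuffles the positive/negative labels of the pair and repeats the full
#' cross-validation for each permutation; the p-value is the fraction of
#' permuted accuracies strictly larger than the observed one. A count of
#' zero is reported as an upper bound (p < 1/n_permutations).
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label permutations (default 1000).
#' @return An object of class `permutation_result`: `observed_acc`,
#'   `n_permutations`, `n_exceeding`, `p_value`, `p_is_upper_bound`,
#'   `perm_accuracies`.
#' @export
permutation_test <- function(positives, negative_subset,
                             feature_kind = c("DPC", "AAC", "ODPC", "OAAC"),
                             svm_config = svm_config_reduced(),
                             selection_config = svm_config_selection(),
                             n_permutations = 1000L, k = 5L, seed = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  fm <- encode_pair(positives, negative_subset, feature_kind)
  y <- fm_labels(fm)
  optimized <- feature_kind %in% c("OAAC", "ODPC")

  run_cv <- function(labels) {
    fmx <- structure(unclass(fm), class = class(fm), kind = attr(fm, "kind"),
                     labels = labels)
    tokens <- if (optimized) select_features(fmx, selection_config, k)$selected
              else colnames(fmx)
    mean(cv_core(select_columns(fmx, tokens), labels, svm_config, k)$fold_accuracies)
  }

  observed <- run_cv(y)
  perm_acc <- vapply(seq_len(n_permutations), function(i) run_cv(sample(y)),
                     numeric(1))
  n_exceed <- sum(perm_acc > observed)
  structure(list(observed_acc = observed,
                 n_permutations = as.integer(n_permutations),
                 n_exceeding = as.integer(n_exceed),
                 p_value = n_exceed / n_permutations,
                 p_is_upper_bound = n_exceed == 0L,
                 perm_accuracies = perm_acc),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  p <- if (x$p_is_upper_bound) sprintf("p < %g", 1 / x$n_permutations)
       else sprintf("p = %g", x$p_value)
  cat(sprintf("permutation test: observed accuracy %.2f%%, %d permutations, %s\n",
              100 * x$observed_acc, x$n_permutations, p))
  invisible(x)
}

#' Positive rate of a prediction table
#'
#' @param records A `sbp_predictions` data frame (or any data frame with a
#'   `call` column of "SBP"/"non-SBP"). Records with NA calls (encoding
#'   failures) are excluded with a warning.
#' @return Percentage of records called "SBP" (0-100).
#' @export
positive_rate <- function(records) {
  stopifnot(is.data.frame(records), "call" %in% names(records))
  if (nrow(records) == 0L) stop("no prediction records")
  calls <- records$call
  if (anyNA(calls)) {
    warning(sum(is.na(calls)), " record(s) without a call excluded")
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0L) stop("no prediction records with a call")
  }
  100 * mean(calls == "SBP")
}

#' Chi-square comparison of two positive rates
#'
#' Pearson chi-square (1 degree of freedom, no continuity correction,
#' two-sided) on the 2x2 table of positive/negative calls in two prediction
#' batches, as used to compare the positive rate on peptides panned with
#' streptavidin in the system against peptides panned without it.
#'
#' @param counts_a,counts_b Numeric pairs `c(positives, total)`.
#' @return An object of class `rate_comparison`: the two counts and rates
#'   (percent), `chi_square_statistic`, `df`, `p_value`.
#' @examples
#' compare_rates(c(208, 1711), c(1169, 13272))
#' @export
compare_rates <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L,
            counts_a[2] > 0, counts_b[2] > 0,
            counts_a[1] <= counts_a[2], counts_b[1] <= counts_b[2])
  tbl <- rbind(c(counts_a[1], counts_a[2] - counts_a[1]),
               c(counts_b[1], counts_b[2] - counts_b[1]))
  if (any(colSums(tbl) == 0)) {
    warning("degenerate table (a zero marginal); statistic 0, p = 1")
    stat <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(counts_a = as.numeric(counts_a),
                 counts_b = as.numeric(counts_b),
                 rate_a = 100 * counts_a[1] / counts_a[2],
                 rate_b = 100 * counts_b[1] / counts_b[2],
                 chi_square_statistic = stat,
                 df = 1L,
                 p_value = p),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("positive rates: %.2f%% (%.0f/%.0f) vs %.2f%% (%.0f/%.0f)\n",
              x$rate_a, x$counts_a[1], x$counts_a[2],
              x$rate_b, x$counts_b[1], x$counts_b[2]))
  cat(sprintf("chi-square = %.4f (df = %d), p = %.4g\n",
              x$chi_square_statistic, x$df, x$p_value))
  invisible(x)
}

#' Export ROC points as TSV
#'
#' @param roc A `roc_curve`.
#' @param path Output file path.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  write.table(roc$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
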