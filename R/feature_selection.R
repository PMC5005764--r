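#' Score every feature on its own
#'
#' First step of accuracy-ranked forward selection: each descriptor column is
#' evaluated in isolation by stratified k-fold cross-validated accuracy of an
#' RBF-SVM trained on that single column. Features are returned sorted by
#' decreasing solo accuracy; ties are broken lexicographically by token so
#' the ranking is deterministic.
#'
#' @param fm A labelled `feature_matrix` (see [encode_peptides()]) with at
#'   least two samples per class.
#' @param config An [svm_config()] used to evaluate each feature. The default
#'   is a fixed single cell (c = 8, g = 2^-3); passing a multi-cell grid
#'   re-runs the grid search for every feature.
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Optional seed; the fold partition is drawn once and reused for
#'   every feature so solo accuracies are comparable.
#' @return Data frame of class `ranked_features` with columns `token`,
#'   `kind`, `solo_accuracy`, sorted as described.
#' @export
score_single_features <- function(fm, config = svm_config_selection(),
                                  cv_folds = 5L, seed = NULL) {
  y <- fm_labels(fm)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(sum(y), sum(!y)) < 2L) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  folds <- make_stratified_folds(y, cv_folds)

  acc <- vapply(seq_len(ncol(fm)), function(j) {
    grid_search(fm[, j, drop = FALSE], y, config, folds)$accuracy
  }, numeric(1))

  out <- data.frame(token = colnames(fm), kind = attr(fm, "kind"),
                    solo_accuracy = acc, stringsAsFactors = FALSE)
  out <- out[order(-out$solo_accuracy, out$token), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Grow a feature set in ranked order and keep the best prefix
#'
#' Second and third steps of the selection procedure: features are added to
#' an initially empty set in decreasing order of solo accuracy; after each
#' addition the whole set is evaluated by stratified k-fold cross-validated
#' accuracy, and the smallest prefix attaining the maximum accuracy is
#' selected.
#'
#' @param ranked A `ranked_features` data frame from
#'   [score_single_features()]; tokens must be columns of `fm`.
#' @param fm The labelled `feature_matrix` the ranking was computed on.
#' @inheritParams score_single_features
#' @param max_prefix Optional cap on the number of prefixes evaluated
#'   (default all).
#' @return An object of class `selection_trace`: list with `ranked`,
#'   `prefix_accuracies` (one per evaluated prefix), `selected` (character
#'   tokens of the winning prefix), and `selected_accuracy`
#'   (`= max(prefix_accuracies)` exactly).
#' @export
forward_select <- function(ranked, fm, config = svm_config_selection(),
                           cv_folds = 5L, seed = NULL, max_prefix = NULL) {
  stopifnot(inherits(ranked, "ranked_features"), nrow(ranked) >= 1L,
            all(ranked$token %in% colnames(fm)))
  y <- fm_labels(fm)
  if (!is.null(seed)) set.seed(seed)
  folds <- make_stratified_folds(y, cv_folds)

  n_prefix <- if (is.null(max_prefix)) nrow(ranked) else min(max_prefix, nrow(ranked))
  prefix_acc <- numeric(n_prefix)
  for (p in seq_len(n_prefix)) {
    Xp <- select_columns(fm, ranked$token[seq_len(p)])
    prefix_acc[p] <- grid_search(Xp, y, config, folds)$accuracy
  }
  best <- which.max(prefix_acc)  # first maximum = smallest prefix
  structure(list(ranked = ranked,
                 prefix_accuracies = prefix_acc,
                 selected = ranked$token[seq_len(best)],
                 selected_accuracy = prefix_acc[best]),
            class = "selection_trace")
}

#' Rank features and select the best prefix in one call
#'
#' Runs [score_single_features()] then [forward_select()] under one seeded
#' RNG stream, producing the optimized feature subset (OAAC from the 20 AAC
#' components, ODPC from the 400 DPC components).
#'
#' @inheritParams forward_select
#' @return A `selection_trace`; `$selected` holds the optimized tokens.
#' @export
select_features <- function(fm, config = svm_config_selection(),
                            cv_folds = 5L, seed = NULL, max_prefix = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ranked <- score_single_features(fm, config, cv_folds)
  forward_select(ranked, fm, config, cv_folds, max_prefix = max_prefix)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("feature selection: ", length(x$prefix_accuracies), " prefixes evaluated\n",
      "selected ", length(x$selected), " feature(s): ",
      paste(x$selected, collapse = " "), "\n",
      sprintf("cross-validated accuracy of selected set: %.4f\n",
              x$selected_accuracy), sep = "")
  invisible(x)
}

#' Write a selection trace as TSV for audit
#'
#' One row per ranked feature: `rank`, `token`, `solo_accuracy`,
#' `prefix_accuracy` (NA for prefixes beyond `max_prefix`), `selected`.
#'
#' @param trace A `selection_trace`.
#' @param path Output file path.
#' @export
write_selection_trace <- function(trace, path) {
  n <- nrow(trace$ranked)
  pa <- c(trace$prefix_accuracies,
          rep(NA_real_, n - length(trace$prefix_accuracies)))
  df <- data.frame(rank = seq_len(n),
                   token = trace$ranked$token,
                   solo_accuracy = trace$ranked$solo_accuracy,
                   prefix_accuracy = pa,
                   selected = trace$ranked$token %in% trace$selected)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
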