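MODEL_FORMAT <- "sbpred-ensemble"
MODEL_FORMAT_VERSION <- "1.0"

#' Draw balanced negative subsets by downsampling
#'
#' Handles the strong class imbalance between the few known binders and the
#' many non-binders: `n_subsets` subsets of size `subset_size` are drawn from
#' the negative set, each a uniform sample without replacement, the subsets
#' themselves drawn independently (a negative peptide may appear in several
#' subsets). Each subset is later paired with the full positive set to train
#' one submodel.
#'
#' @param negatives A preprocessed [peptide_set()] of negative peptides.
#' @param n_subsets Number of subsets (default 10).
#' @param subset_size Size of each subset; typically the positive-set size.
#' @param seed Optional seed for reproducible draws.
#' @return List of `n_subsets` [peptide_set()] objects labelled "negative".
#' @examples
#' neg <- peptide_set(replicate(50, paste(sample(c("A","G","S","T"), 8,
#'                                               TRUE), collapse = "")))
#' subs <- downsample_negatives(neg, n_subsets = 3, subset_size = 10, seed = 1)
#' lengths(lapply(subs, `[[`, "id"))
#' @export
downsample_negatives <- function(negatives, n_subsets = 10L, subset_size,
                                 seed = NULL) {
  stopifnot(inherits(negatives, "peptide_set"), n_subsets >= 1L)
  if (subset_size > nrow(negatives)) {
    stop("subset_size (", subset_size, ") exceeds the negative set size (",
         nrow(negatives), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_subsets), function(i) {
    idx <- sample(nrow(negatives), subset_size, replace = FALSE)
    out <- negatives[sort(idx), , drop = FALSE]
    class(out) <- c("peptide_set", "data.frame")
    attr(out, "label") <- "negative"
    out
  })
}

# Encode a positive/negative pair as one labelled feature matrix over the
# full base composition of the requested feature kind.
encode_pair <- function(positives, negative_subset, feature_kind) {
  base <- if (feature_kind %in% c("AAC", "OAAC")) aac_descriptors() else dpc_descriptors()
  combined <- rbind(as.data.frame(positives), as.data.frame(negative_subset))
  combined$id <- make_unique_ids(combined$id)
  set <- peptide_set(combined$sequence, id = combined$id,
                     topology = combined$topology)
  encode_peptides(set, base,
                  labels = rep(c(TRUE, FALSE),
                               c(nrow(positives), nrow(negative_subset))))
}

#' Train one RBF-SVM submodel on a balanced pair
#'
#' Encodes the pair with the requested feature kind, optionally runs
#' accuracy-ranked forward selection (feature kinds OAAC/ODPC), grid-searches
#' (c, g) by stratified cross-validated accuracy, fits the final classifier
#' on the whole pair, and fits a Platt sigmoid on cross-validated decision
#' values so the submodel outputs calibrated probabilities.
#'
#' @param positives Preprocessed positive [peptide_set()].
#' @param negative_subset Preprocessed negative [peptide_set()], disjoint
#'   from `positives` (an overlap is an error).
#' @param feature_kind One of "AAC", "OAAC", "DPC", "ODPC".
#' @param svm_config [svm_config()] for the (c, g) grid search (default the
#'   reduced grid, [svm_config_reduced()]).
#' @param selection_config [svm_config()] used inside feature selection;
#'   default a fixed single cell (see [select_features()]).
#' @param cv_folds Folds for grid search, selection and calibration
#'   (default 5).
#' @param seed Optional seed making the whole fit reproducible.
#' @param index Submodel index within an ensemble (default 1).
#' @return An object of class `sbp_submodel` holding the selected tokens,
#'   chosen (c, g), support vectors, dual coefficients, calibration
#'   parameters and the ids of its negative subset.
#' @export
train_submodel <- function(positives, negative_subset,
                           feature_kind = c("ODPC", "DPC", "AAC", "OAAC"),
                           svm_config = svm_config_reduced(),
                           selection_config = svm_config_selection(),
                           cv_folds = 5L, seed = NULL, index = 1L) {
  feature_kind <- match.arg(feature_kind)
  if (any(positives$sequence %in% negative_subset$sequence)) {
    stop("positive and negative sets overlap; run remove_overlap() first")
  }
  if (!is.null(seed)) set.seed(seed)

  fm <- encode_pair(positives, negative_subset, feature_kind)
  y <- fm_labels(fm)

  trace <- NULL
  if (feature_kind %in% c("OAAC", "ODPC")) {
    trace <- select_features(fm, selection_config, cv_folds)
    tokens <- trace$selected
  } else {
    tokens <- colnames(fm)
  }
  X <- select_columns(fm, tokens)

  folds <- make_stratified_folds(y, cv_folds)
  best <- grid_search(X, y, svm_config, folds)

  fit <- fit_rbf(X, y, best$cost, best$gamma)
  calib <- cv_decision_values(X, y, best$cost, best$gamma,
                              make_stratified_folds(y, cv_folds))
  platt <- platt_fit(calib$decision_values, y)

  structure(list(index = as.integer(index),
                 feature_kind = feature_kind,
                 tokens = tokens,
                 cost = best$cost,
                 gamma = best$gamma,
                 cv_accuracy = best$accuracy,
                 SV = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs),
                 rho = as.numeric(fit$rho),
                 orientation = model_orientation(fit),
                 platt = platt,
                 negative_ids = negative_subset$id,
                 selection = trace,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "sbp_submodel")
}

# Probability of being a binder for each row of a base-composition feature
# matrix, from the stored dual expansion and sigmoid.
predict_submodel <- function(sub, fm) {
  X <- select_columns(fm, sub$tokens)
  dec <- rbf_decision(unclass(X), sub$SV, sub$coefs, sub$rho, sub$gamma,
                      sub$orientation)
  unname(platt_predict(sub$platt, dec))
}

#' Train the downsampling voting ensemble
#'
#' Draws `n_subsets` balanced negative subsets ([downsample_negatives()]),
#' trains one submodel per subset ([train_submodel()]), and aggregates them:
#' a prediction is the arithmetic mean of the submodel probabilities plus a
#' vote count. For the optimized feature kinds, the ensemble also reports the
#' consensus features — tokens selected in at least half of the submodels.
#'
#' @inheritParams train_submodel
#' @param negatives Full preprocessed negative [peptide_set()].
#' @param n_subsets Number of negative subsets / submodels (default 10).
#' @param subset_size Size of each negative subset; defaults to the
#'   positive-set size (balanced pairs).
#' @return An object of class `sbp_ensemble`.
#' @export
train_ensemble <- function(positives, negatives,
                           feature_kind = c("ODPC", "DPC", "AAC", "OAAC"),
                           svm_config = svm_config_reduced(),
                           selection_config = svm_config_selection(),
                           n_subsets = 10L, subset_size = NULL,
                           cv_folds = 5L, seed = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (any(positives$sequence %in% negatives$sequence)) {
    stop("positive and negative sets overlap; run remove_overlap() first")
  }
  if (is.null(subset_size)) subset_size <- nrow(positives)
  if (!is.null(seed)) set.seed(seed)
  subsets <- downsample_negatives(negatives, n_subsets, subset_size)
  sub_seeds <- sample.int(.Machine$integer.max, n_subsets)

  submodels <- lapply(seq_len(n_subsets), function(i) {
    train_submodel(positives, subsets[[i]], feature_kind,
                   svm_config = svm_config,
                   selection_config = selection_config,
                   cv_folds = cv_folds, seed = sub_seeds[i], index = i)
  })

  consensus <- NULL
  if (feature_kind %in% c("OAAC", "ODPC")) {
    all_tokens <- unlist(lapply(submodels, `[[`, "tokens"))
    tab <- table(all_tokens)
    consensus <- sort(names(tab)[tab >= ceiling(n_subsets / 2)])
  }

  structure(list(submodels = submodels,
                 feature_kind = feature_kind,
                 default_tp = 0.5,
                 consensus_features = consensus,
                 metadata = list(format = MODEL_FORMAT,
                                 version = MODEL_FORMAT_VERSION,
                                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                                 n_positives = nrow(positives),
                                 n_negatives = nrow(negatives),
                                 subset_size = as.integer(subset_size),
                                 n_subsets = as.integer(n_subsets))),
            class = "sbp_ensemble")
}

#' @export
print.sbp_ensemble <- function(x, ...) {
  md <- x$metadata
  cat("sbp_ensemble: ", length(x$submodels), " RBF-SVM submodel(s), feature kind ",
      x$feature_kind, "\n", sep = "")
  cat("  trained on ", md$n_positives, " positives vs ", md$n_subsets,
      " negative subsets of ", md$subset_size, " (from ", md$n_negatives,
      " negatives), seed ", md$seed, "\n", sep = "")
  if (!is.null(x$consensus_features)) {
    cat("  consensus features: ", paste(x$consensus_features, collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Predict streptavidin binding for a peptide set
#'
#' Each submodel outputs a calibrated probability; the record's
#' `mean_probability` is their arithmetic mean, `votes` counts submodels with
#' probability at least 0.5 (independent of `tp`), and the binary `call` is
#' "SBP" when the mean reaches the threshold `tp`. Peptides the encoder
#' cannot handle (shorter than 2 residues for dipeptide features, or with
#' residues outside the 20-letter alphabet) yield a record with NA values and
#' an explanatory `note` instead of an error.
#'
#' @param object An `sbp_ensemble` from [train_ensemble()].
#' @param peptides A preprocessed [peptide_set()].
#' @param tp Decision threshold on the mean probability, in \[0, 1\]
#'   (default 0.5). Lower it to cast a wider net when excluding suspected
#'   streptavidin binders; raise it to shortlist high-confidence binders.
#' @param ... Unused.
#' @return A data frame of class `sbp_predictions` with columns `id`,
#'   `sequence`, `mean_probability`, `votes`, `call`, `note`, and the
#'   per-submodel probability matrix in attribute
#'   `"submodel_probabilities"`.
#' @export
predict.sbp_ensemble <- function(object, peptides, tp = 0.5, ...) {
  stopifnot(inherits(peptides, "peptide_set"), nrow(peptides) > 0L,
            tp >= 0, tp <= 1)
  min_len <- if (object$feature_kind %in% c("AAC", "OAAC")) 1L else 2L
  valid_alpha <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                       peptides$sequence)
  ok <- valid_alpha & nchar(peptides$sequence) >= min_len

  n <- nrow(peptides)
  n_sub <- length(object$submodels)
  probs <- matrix(NA_real_, n, n_sub,
                  dimnames = list(peptides$id, paste0("submodel", seq_len(n_sub))))
  if (any(ok)) {
    sub_set <- peptides[ok, , drop = FALSE]
    class(sub_set) <- c("peptide_set", "data.frame")
    base <- if (min_len == 1L) aac_descriptors() else dpc_descriptors()
    fm <- encode_peptides(sub_set, base)
    for (j in seq_len(n_sub)) {
      probs[ok, j] <- predict_submodel(object$submodels[[j]], fm)
    }
  }
  mean_p <- rowMeans(probs)
  votes <- as.integer(rowSums(probs >= 0.5))
  note <- ifelse(ok, "",
                 ifelse(!valid_alpha, "residues outside the 20-letter alphabet",
                        paste0("shorter than ", min_len, " residues")))
  out <- data.frame(id = peptides$id,
                    sequence = peptides$sequence,
                    mean_probability = mean_p,
                    votes = votes,
                    call = ifelse(is.na(mean_p), NA_character_,
                                  ifelse(mean_p >= tp, "SBP", "non-SBP")),
                    note = note,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "submodel_probabilities") <- probs
  attr(out, "tp") <- tp
  class(out) <- c("sbp_predictions", "data.frame")
  out
}

num2str <- function(x) sprintf("%.17g", x)
str2num <- function(x) as.numeric(x)

submodel_to_list <- function(sub) {
  list(index = sub$index,
       feature_kind = sub$feature_kind,
       tokens = as.list(sub$tokens),
       cost = num2str(sub$cost),
       gamma = num2str(sub$gamma),
       cv_accuracy = num2str(sub$cv_accuracy),
       sv_rows = nrow(sub$SV),
       sv_values = num2str(as.numeric(sub$SV)),
       coefs = num2str(sub$coefs),
       rho = num2str(sub$rho),
       orientation = sub$orientation,
       platt_a = num2str(sub$platt[["A"]]),
       platt_b = num2str(sub$platt[["B"]]),
       negative_ids = as.list(sub$negative_ids),
       seed = sub$seed)
}

submodel_from_list <- function(x) {
  sv <- matrix(str2num(x$sv_values), nrow = x$sv_rows)
  structure(list(index = as.integer(x$index),
                 feature_kind = x$feature_kind,
                 tokens = unlist(x$tokens),
                 cost = str2num(x$cost),
                 gamma = str2num(x$gamma),
                 cv_accuracy = str2num(x$cv_accuracy),
                 SV = sv,
                 coefs = str2num(x$coefs),
                 rho = str2num(x$rho),
                 orientation = as.numeric(x$orientation),
                 platt = c(A = str2num(x$platt_a), B = str2num(x$platt_b)),
                 negative_ids = unlist(x$negative_ids),
                 selection = NULL,
                 seed = as.integer(x$seed)),
            class = "sbp_submodel")
}

#' Save / load an ensemble model
#'
#' The model file is versioned structured text (JSON) containing, per
#' submodel, the selected feature tokens, the chosen (c, g), the support
#' vectors and dual coefficients, and the sigmoid calibration parameters.
#' Doubles are stored with 17 significant digits, so a loaded model
#' reproduces the saved model's predictions bit for bit.
#'
#' @param model An `sbp_ensemble`.
#' @param path File path for the model.
#' @return `load_model()` returns the restored `sbp_ensemble`;
#'   `save_model()` returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sbp_ensemble"))
  payload <- list(format = MODEL_FORMAT,
                  version = MODEL_FORMAT_VERSION,
                  feature_kind = model$feature_kind,
                  default_tp = num2str(model$default_tp),
                  consensus_features = as.list(model$consensus_features),
                  metadata = model$metadata,
                  submodels = lapply(model$submodels, submodel_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) stop("cannot parse model file '",
                                               path, "' (corrupt or truncated): ",
                                               conditionMessage(e)))
  if (!identical(payload$format, MODEL_FORMAT)) {
    stop("not an ensemble model file: ", path)
  }
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model file version '", payload$version,
         "' (this build reads version ", MODEL_FORMAT_VERSION, ")")
  }
  md <- payload$metadata
  md$seed <- if (is.null(md$seed)) NA_integer_ else as.integer(md$seed)
  structure(list(submodels = lapply(payload$submodels, submodel_from_list),
                 feature_kind = payload$feature_kind,
                 default_tp = str2num(payload$default_tp),
                 consensus_features = if (length(payload$consensus_features))
                   unlist(payload$consensus_features) else NULL,
                 metadata = md),
            class = "sbp_ensemble")
}
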