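#' Amino acid composition of a peptide
#'
#' Fraction of each of the 20 residues in the sequence: component i is
#' (count of residue i) / (peptide length). Components are ordered
#' alphabetically by one-letter code (see [aac_descriptors()]) and sum to 1.
#'
#' @param sequence A single peptide sequence (character) or a one-row
#'   [peptide_set()].
#' @return Named numeric vector of 20 fractions.
#' @examples
#' compute_aac("HPQ")[c("H", "P", "Q")]
#' @export
compute_aac <- function(sequence) {
  s <- as_single_sequence(sequence)
  if (nchar(s) < 1L) stop("cannot compute amino acid composition of an empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  check_alphabet(chars)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars), AA_ALPHABET)
}

#' Dipeptide composition of a peptide
#'
#' Fraction of each of the 400 residue pairs among the L - 1 overlapping
#' adjacent pairs of the sequence: component j is (count of dipeptide j) /
#' (L - 1). Components are ordered alphabetically (AA, AC, ..., YY; see
#' [dpc_descriptors()]) and sum to 1. The sequence is read linearly; circular
#' peptides are linearized during preprocessing, so no wrap-around pair is
#' counted.
#'
#' @inheritParams compute_aac
#' @return Named numeric vector of 400 fractions.
#' @examples
#' v <- compute_dpc("HPQ")
#' v[v > 0]
#' @export
compute_dpc <- function(sequence) {
  s <- as_single_sequence(sequence)
  L <- nchar(s)
  if (L < 2L) stop("dipeptide composition requires length >= 2, got \"", s, "\"")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  check_alphabet(chars)
  pairs <- paste0(chars[-L], chars[-1])
  counts <- table(factor(pairs, levels = DPC_TOKENS))
  stats::setNames(as.numeric(counts) / (L - 1L), DPC_TOKENS)
}

as_single_sequence <- function(sequence) {
  if (inherits(sequence, "peptide_set")) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  toupper(sequence)
}

check_alphabet <- function(chars) {
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("sequence contains characters outside the 20-residue alphabet: ",
         paste(bad, collapse = ", "), " (run preprocess_peptides() first)")
  }
}

#' Encode a peptide set as a feature matrix
#'
#' Computes the full amino acid (AAC) and/or dipeptide (DPC) composition of
#' every peptide and then selects and orders columns exactly as listed in
#' `descriptors`. Normalization is always over the full 20- or 400-token
#' space, so a matrix restricted to a selected subset has row sums at most 1.
#'
#' @param set A preprocessed [peptide_set()].
#' @param descriptors Character vector of descriptor tokens: one-letter codes
#'   for AAC components, two-letter pairs for DPC components. Mixed lists are
#'   permitted. Defaults to the full dipeptide composition.
#' @param labels Optional binary labels (logical, or the strings
#'   "positive"/"negative") attached to the rows; defaults to the set's label
#'   attribute applied to all rows when present.
#' @return A numeric matrix of class `feature_matrix` with one row per
#'   peptide (rownames = peptide ids, colnames = descriptor tokens) and
#'   attributes `kind` (per-column "AAC"/"DPC") and `labels` (logical,
#'   TRUE = positive, or NULL).
#' @examples
#' s <- peptide_set(c("HPQF", "AGSW"))
#' encode_peptides(s, c("HP", "PQ", "H"))
#' @export
encode_peptides <- function(set, descriptors = dpc_descriptors(), labels = NULL) {
  stopifnot(inherits(set, "peptide_set"), nrow(set) > 0L)
  descriptors <- toupper(as.character(descriptors))
  kind <- descriptor_kind(descriptors)

  cols <- vector("list", length(descriptors))
  if (any(kind == "AAC")) {
    aac <- t(vapply(set$sequence, function(s) compute_aac(s),
                    numeric(20), USE.NAMES = FALSE))
    colnames(aac) <- AA_ALPHABET
    cols[kind == "AAC"] <- lapply(descriptors[kind == "AAC"],
                                  function(tk) aac[, tk])
  }
  if (any(kind == "DPC")) {
    dpc <- t(vapply(set$sequence, function(s) compute_dpc(s),
                    numeric(400), USE.NAMES = FALSE))
    colnames(dpc) <- DPC_TOKENS
    cols[kind == "DPC"] <- lapply(descriptors[kind == "DPC"],
                                  function(tk) dpc[, tk])
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(set$id, descriptors)

  if (is.null(labels)) {
    lab <- attr(set, "label")
    if (!is.null(lab) && lab != "unknown") {
      labels <- rep(lab == "positive", nrow(set))
    }
  } else if (is.character(labels)) {
    stopifnot(all(labels %in% c("positive", "negative")))
    labels <- labels == "positive"
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(m), is.logical(labels))

  structure(m, class = c("feature_matrix", class(m)),
            kind = kind, labels = labels)
}

descriptor_kind <- function(descriptors) {
  nc <- nchar(descriptors)
  kind <- ifelse(nc == 1L, "AAC", ifelse(nc == 2L, "DPC", NA_character_))
  known <- (kind == "AAC" & descriptors %in% AA_ALPHABET) |
           (kind == "DPC" & descriptors %in% DPC_TOKENS)
  if (anyNA(kind) || !all(known)) {
    stop("unknown descriptor token(s): ",
         paste(descriptors[is.na(kind) | !known], collapse = ", "))
  }
  if (anyDuplicated(descriptors)) stop("duplicate descriptor tokens")
  kind
}

# column subset that preserves feature_matrix attributes
select_columns <- function(fm, tokens) {
  idx <- match(tokens, colnames(fm))
  stopifnot(!anyNA(idx))
  structure(fm[, idx, drop = FALSE],
            class = class(fm),
            kind = attr(fm, "kind")[idx],
            labels = attr(fm, "labels"))
}

fm_labels <- function(fm) {
  lab <- attr(fm, "labels")
  if (is.null(lab)) stop("feature matrix carries no labels")
  lab
}

#' Export a feature matrix as TSV
#'
#' One row per peptide: `id`, then one column per descriptor token, plus a
#' `label` column when labels are attached.
#'
#' @param fm A `feature_matrix` from [encode_peptides()].
#' @param path Output file path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  lab <- attr(fm, "labels")
  if (!is.null(lab)) df$label <- ifelse(lab, "positive", "negative")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
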