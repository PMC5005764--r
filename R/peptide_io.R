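#' Construct a peptide set
#'
#' A `peptide_set` is a data frame with columns `id`, `sequence` and
#' `topology` ("linear" or "circular") and an optional set-level `label`
#' attribute ("positive", "negative" or "unknown"). Sequences are uppercased
#' on construction; validation beyond that (alphabet, length, duplicates) is
#' the job of [preprocess_peptides()].
#'
#' @param sequence Character vector of peptide sequences.
#' @param id Optional character vector of identifiers; sequential ids
#'   `pep1, pep2, ...` are assigned where missing. Duplicate ids are
#'   disambiguated with a numeric suffix rather than dropped.
#' @param topology "linear" or "circular", recycled to the number of peptides.
#'   Circular peptides are the ones displayed with a disulfide-bridged
#'   cysteine clamp (e.g. the C7C library); the clamp cysteines are removed by
#'   [preprocess_peptides()].
#' @param label Optional set-level label: "positive", "negative" or "unknown".
#' @return An object of class `peptide_set`.
#' @examples
#' peptide_set(c("CHPQC", "AGSW"), topology = c("circular", "linear"))
#' @export
peptide_set <- function(sequence, id = NULL, topology = "linear", label = NULL) {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (is.null(id)) {
    id <- paste0("pep", seq_len(n))
  } else {
    id <- as.character(id)
    missing_id <- is.na(id) | id == ""
    id[missing_id] <- paste0("pep", which(missing_id))
  }
  if (length(id) != n) stop("`id` and `sequence` lengths differ")
  id <- make_unique_ids(id)
  topology <- match.arg(topology, c("linear", "circular"), several.ok = TRUE)
  topology <- rep_len(topology, n)
  out <- data.frame(id = id, sequence = sequence, topology = topology,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  if (!is.null(label)) {
    attr(out, "label") <- match.arg(label, c("positive", "negative", "unknown"))
  }
  out
}

# suffix duplicate ids with _2, _3, ... keeping the first occurrence untouched
make_unique_ids <- function(id) {
  dup <- duplicated(id)
  if (!any(dup)) return(id)
  counts <- new.env(parent = emptyenv())
  vapply(id, function(x) {
    k <- if (is.null(counts[[x]])) 1L else counts[[x]] + 1L
    counts[[x]] <- k
    if (k == 1L) x else paste0(x, "_", k)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.peptide_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat("peptide_set: ", nrow(x), " peptide(s)",
      if (!is.null(lab)) paste0(", label = ", lab), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

set_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "unknown" else lab
}

#' Read peptides from FASTA or plain text
#'
#' FASTA files are read with Biostrings; a record whose description line
#' contains the word `circular` (case-insensitive) is flagged as a circular
#' peptide. The plain format is one sequence per line with an optional leading
#' `id<TAB>` field; blank lines are skipped and records without an id get
#' sequential synthetic ids.
#'
#' @param path Path to the input file.
#' @param format "auto" (default; FASTA when the first non-blank character is
#'   `>`), "fasta" or "plain".
#' @param default_topology Topology assigned to records that carry no
#'   annotation of their own ("linear" by default).
#' @param label Optional set label passed to [peptide_set()].
#' @return A [peptide_set()] with all records in file order.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "plain"),
                          default_topology = "linear", label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read peptide file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(trimws(first[1]), ">")) "fasta" else "plain"
  }
  if (format == "fasta") {
    seqs <- tryCatch(Biostrings::readAAStringSet(path),
                     error = function(e) stop("FASTA parse error in '", path,
                                              "': ", conditionMessage(e)))
    if (length(seqs) == 0L) stop("no peptides in file: ", path)
    headers <- names(seqs)
    ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
    circ <- grepl("(^|[ \t])circular([ \t]|$)", headers, ignore.case = TRUE)
    topo <- ifelse(circ, "circular", default_topology)
    peptide_set(as.character(seqs), id = ids, topology = topo, label = label)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no peptides in file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    has_id <- lengths(parts) >= 2L
    ids <- ifelse(has_id, vapply(parts, `[`, character(1), 1L), NA_character_)
    seqs <- trimws(ifelse(has_id,
                          vapply(parts, `[`, character(1), 2L),
                          vapply(parts, `[`, character(1), 1L)))
    peptide_set(seqs, id = ids, topology = default_topology, label = label)
  }
}

#' Preprocess a peptide set
#'
#' Applies, in order: (i) for peptides flagged circular, removal of one
#' leading and/or one trailing clamp cysteine; (ii) removal of exact duplicate
#' sequences, keeping the first occurrence; (iii) removal of peptides
#' containing an ambiguous residue (X, B, Z), a letter outside the 20-residue
#' alphabet (J, O, U) or any non-alphabetic character; (iv) removal of
#' peptides shorter than `min_length`. The operation is idempotent: a
#' preprocessed set passes through unchanged.
#'
#' @param set A [peptide_set()].
#' @param strip_circular_cysteines Remove the terminal cysteines of circular
#'   peptides (default TRUE). At most one C is removed per end, and only from
#'   records flagged circular; a circular peptide with a C at one end only
#'   loses that one C.
#' @param min_length Minimum surviving length (default 3).
#' @return A list with elements `peptides` (the surviving [peptide_set()],
#'   topology reset to linear for stripped records) and `log`, a
#'   `preprocess_log` of counts: `n_input`, `n_cysteine_stripped` (peptides
#'   trimmed, not removed), `n_duplicates_removed`, `n_ambiguous_removed`,
#'   `n_too_short_removed`, `n_overlap_removed` (always 0 here; see
#'   [remove_overlap()]). `n_input` equals the surviving count plus all
#'   `*_removed` counts.
#' @examples
#' s <- peptide_set(c("CHPQC", "AXKP", "HPQF", "HPQF", "AG"),
#'                  topology = c("circular", rep("linear", 4)))
#' preprocess_peptides(s)$log
#' @export
preprocess_peptides <- function(set, strip_circular_cysteines = TRUE,
                                min_length = 3L) {
  stopifnot(inherits(set, "peptide_set"))
  if (nrow(set) == 0L) stop("empty peptide set")
  n_input <- nrow(set)
  seqs <- set$sequence
  topo <- set$topology

  n_stripped <- 0L
  if (strip_circular_cysteines) {
    circ <- topo == "circular"
    had_c <- circ & (startsWith(seqs, "C") | endsWith(seqs, "C"))
    seqs[circ] <- sub("^C", "", seqs[circ])
    seqs[circ] <- sub("C$", "", seqs[circ])
    n_stripped <- sum(had_c)
    topo[circ] <- "linear"  # linearized from here on
  }

  dup <- duplicated(seqs)
  ambiguous <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs)
  too_short <- nchar(seqs) < min_length
  # counts follow the stated order: duplicates, then ambiguous, then length
  n_dup <- sum(dup)
  n_amb <- sum(ambiguous & !dup)
  n_short <- sum(too_short & !ambiguous & !dup)
  keep <- !(dup | ambiguous | too_short)

  if (!any(keep)) stop("empty set after preprocessing")
  out <- set[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  out$topology <- topo[keep]
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "label") <- attr(set, "label")
  log <- structure(list(n_input = n_input,
                        n_cysteine_stripped = n_stripped,
                        n_duplicates_removed = n_dup,
                        n_ambiguous_removed = n_amb,
                        n_too_short_removed = n_short,
                        n_overlap_removed = 0L),
                   class = "preprocess_log")
  list(peptides = out, log = log)
}

#' @export
print.preprocess_log <- function(x, ...) {
  cat("preprocess log:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Remove peptides whose sequence occurs in a reference set
#'
#' Exact sequence matching on preprocessed sets; used to purge an independent
#' test set of peptides that also occur in the training data.
#'
#' @param set_a A [peptide_set()] to filter.
#' @param reference A [peptide_set()]; any sequence present here is dropped
#'   from `set_a`.
#' @return List with `peptides` (the filtered set, possibly empty) and
#'   `n_removed`.
#' @export
remove_overlap <- function(set_a, reference) {
  stopifnot(inherits(set_a, "peptide_set"), inherits(reference, "peptide_set"))
  drop <- set_a$sequence %in% reference$sequence
  out <- set_a[!drop, , drop = FALSE]
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "label") <- attr(set_a, "label")
  list(peptides = out, n_removed = sum(drop))
}

#' Write a prediction table
#'
#' Tab-separated table with a header row and columns `id`, `sequence`,
#' `mean_probability` (6 decimals), `votes` and `call` ("SBP" / "non-SBP").
#'
#' @param records A `sbp_predictions` data frame from
#'   [predict.sbp_ensemble()].
#' @param path Output file path.
#' @export
write_predictions <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  out <- data.frame(id = records$id,
                    sequence = records$sequence,
                    mean_probability = sprintf("%.6f", records$mean_probability),
                    votes = records$votes,
                    call = records$call,
                    stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back a prediction table written by [write_predictions()]
#'
#' @param path Path to a TSV prediction table.
#' @return Data frame with the written columns, `mean_probability` numeric.
#' @export
read_predictions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
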