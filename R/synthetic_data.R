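#' Specification of a synthetic peptide benchmark
#'
#' Describes seeded benchmark data that mimics the structure of
#' phage-display biopanning collections: short peptides with lengths from a
#' rounded normal distribution (mean 9, sd 3.5, truncated at `min_length`),
#' a positive class carrying the canonical streptavidin-binding tripeptide
#' motif His-Pro-Gln ("HPQ") in most sequences plus a first-order enrichment
#' of the dipeptides repeatedly reported as discriminative for streptavidin
#' binding (HP, PQ, PP, LP, PL, PS, SP, TP), and a negative class uniform
#' over the 20 residues with the motif excluded outright so the benchmark's
#' class signal is controlled.
#'
#' @param n_pos,n_neg Set sizes (defaults 199 and 1990, a 1:10 imbalance
#'   matching ten balanced downsampled pairs).
#' @param length_mean,length_std Parameters of the length distribution
#'   (defaults 9 and 3.5).
#' @param min_length Minimum peptide length (default 3).
#' @param motif Motif inserted into positives (default "HPQ").
#' @param motif_rate Fraction of positives carrying the motif (default 0.9).
#' @param enriched_dipeptides Residue pairs oversampled in the positive
#'   background chain.
#' @param enrichment_weight Multiplier (>= 1) on the transition probability
#'   of each enriched pair (default 3).
#' @param seed Optional default seed used by the generators.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_pos = 199L, n_neg = 1990L,
                           length_mean = 9, length_std = 3.5,
                           min_length = 3L, motif = "HPQ", motif_rate = 0.9,
                           enriched_dipeptides = c("HP", "PQ", "PP", "LP",
                                                   "PL", "PS", "SP", "TP"),
                           enrichment_weight = 3, seed = NULL) {
  motif <- toupper(motif)
  stopifnot(n_pos >= 1L, n_neg >= 1L, length_std > 0,
            motif_rate >= 0, motif_rate <= 1, enrichment_weight >= 1,
            nchar(motif) >= 1L,
            all(strsplit(motif, "")[[1]] %in% AA_ALPHABET),
            all(nchar(enriched_dipeptides) == 2L),
            all(enriched_dipeptides %in% DPC_TOKENS))
  if (length_mean < min_length) {
    stop("length_mean below min_length makes the requested lengths impossible")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_mean = length_mean, length_std = length_std,
                 min_length = as.integer(min_length),
                 motif = motif, motif_rate = motif_rate,
                 enriched_dipeptides = toupper(enriched_dipeptides),
                 enrichment_weight = enrichment_weight,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "benchmark_spec")
}

draw_lengths <- function(n, spec, floor_len) {
  pmax(floor_len, as.integer(round(rnorm(n, spec$length_mean, spec$length_std))))
}

# first-order transition matrix with enriched pairs oversampled
transition_matrix <- function(spec) {
  tm <- matrix(1, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (dp in spec$enriched_dipeptides) {
    a <- substr(dp, 1, 1); b <- substr(dp, 2, 2)
    tm[a, b] <- tm[a, b] * spec$enrichment_weight
  }
  tm / rowSums(tm)
}

chain_sequence <- function(len, tm) {
  s <- character(len)
  s[1] <- sample(AA_ALPHABET, 1L)
  for (i in seq_len(len - 1L)) {
    s[i + 1L] <- sample(AA_ALPHABET, 1L, prob = tm[s[i], ])
  }
  paste(s, collapse = "")
}

uniform_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# draw sequences until n unique ones satisfying `accept` are collected
draw_unique <- function(n, draw1, accept, max_tries = 1000L) {
  seqs <- character(0)
  for (round in seq_len(max_tries)) {
    cand <- vapply(seq_len(n - length(seqs)), function(i) draw1(), character(1))
    cand <- cand[accept(cand)]
    seqs <- unique(c(seqs, cand))
    if (length(seqs) >= n) return(seqs[seq_len(n)])
  }
  stop("could not generate ", n, " unique sequences under the given constraints")
}

#' Generate motif-free negative peptides
#'
#' Sequences are i.i.d. uniform over the 20-residue alphabet; any draw that
#' happens to contain the motif is regenerated, so the negative set contains
#' the motif zero times by construction. Sequences are unique within the
#' set, so the output passes [preprocess_peptides()] with no removals.
#'
#' @param spec A [benchmark_spec()].
#' @param n Number of peptides (default `spec$n_neg`).
#' @param seed Seed (default `spec$seed`).
#' @return A [peptide_set()] labelled "negative".
#' @export
generate_negatives <- function(spec, n = spec$n_neg, seed = spec$seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function() uniform_sequence(draw_lengths(1L, spec, spec$min_length))
  seqs <- draw_unique(n, draw1, function(s) !grepl(spec$motif, s, fixed = TRUE))
  peptide_set(seqs, id = paste0("neg", seq_len(n)), label = "negative")
}

#' Generate motif-carrying positive peptides
#'
#' Background residues follow a first-order chain in which the enriched
#' dipeptides are oversampled by `enrichment_weight`; a fraction
#' `motif_rate` of the sequences additionally carries the motif, overwritten
#' at a uniformly random position. Sequences are unique within the set.
#'
#' @inheritParams generate_negatives
#' @param n Number of peptides (default `spec$n_pos`).
#' @return A [peptide_set()] labelled "positive".
#' @export
generate_positives <- function(spec, n = spec$n_pos, seed = spec$seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (!is.null(seed)) set.seed(seed)
  tm <- transition_matrix(spec)
  mlen <- nchar(spec$motif)
  floor_len <- max(spec$min_length, mlen)
  draw1 <- function() {
    len <- draw_lengths(1L, spec, floor_len)
    s <- chain_sequence(len, tm)
    if (runif(1) < spec$motif_rate) {
      pos <- sample.int(len - mlen + 1L, 1L)
      substr(s, pos, pos + mlen - 1L) <- spec$motif
    }
    s
  }
  seqs <- draw_unique(n, draw1, function(s) rep(TRUE, length(s)))
  peptide_set(seqs, id = paste0("pos", seq_len(n)), label = "positive")
}

#' Generate a complete benchmark pair
#'
#' Convenience wrapper drawing positives and negatives with zero sequence
#' overlap between the two sets (negatives colliding with a positive
#' sequence are redrawn; with the motif excluded from negatives, collisions
#' can only involve the motif-free minority of positives).
#'
#' @inheritParams generate_negatives
#' @param seed Seed for the whole draw (default `spec$seed`).
#' @return List with `positives` and `negatives`, both [peptide_set()]s.
#' @examples
#' bench <- generate_benchmark(benchmark_spec(n_pos = 20, n_neg = 50), seed = 1)
#' bench$positives
#' @export
generate_benchmark <- function(spec = benchmark_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (!is.null(seed)) set.seed(seed)
  positives <- generate_positives(spec, seed = NULL)
  negatives <- generate_negatives(spec, seed = NULL)
  clash <- negatives$sequence %in% positives$sequence
  while (any(clash)) {
    replacement <- draw_unique(sum(clash),
                               function() uniform_sequence(draw_lengths(1L, spec, spec$min_length)),
                               function(s) !grepl(spec$motif, s, fixed = TRUE) &
                                           !(s %in% positives$sequence) &
                                           !(s %in% negatives$sequence[!clash]))
    negatives$sequence[clash] <- replacement
    clash <- negatives$sequence %in% positives$sequence
  }
  list(positives = positives, negatives = negatives)
}

#' Write a benchmark to FASTA plus a manifest
#'
#' Writes `positives.fasta`, `negatives.fasta` and `manifest.json` (all
#' generator parameters and the seed) into a directory.
#'
#' @param bench A list with `positives` and `negatives` from
#'   [generate_benchmark()].
#' @param spec The [benchmark_spec()] used.
#' @param dir Output directory (created if missing).
#' @param seed The seed that produced `bench`, recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, spec, dir, seed = spec$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta <- function(set, path) {
    writeLines(paste0(">", set$id, "\n", set$sequence), path)
  }
  write_fasta(bench$positives, file.path(dir, "positives.fasta"))
  write_fasta(bench$negatives, file.path(dir, "negatives.fasta"))
  manifest <- unclass(spec)
  manifest$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
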