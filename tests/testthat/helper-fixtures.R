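# Shared fixtures: all data is generated in code, no files shipped.

# single-cell SVM configuration: no grid search, fastest honest fit
fast_cfg <- svm_config(c_grid = 8, g_grid = 2^-3)

# small seeded motif benchmark for quick end-to-end tests
tiny_benchmark <- function(n_pos = 40, n_neg = 120, seed = 42) {
  generate_benchmark(benchmark_spec(n_pos = n_pos, n_neg = n_neg), seed = seed)
}

# peptide set of uniform random sequences (no class signal)
random_peptides <- function(n, len_min = 5, len_max = 12, prefix = "rnd") {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(aac_descriptors(), sample(len_min:len_max, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  peptide_set(unique(seqs), id = paste0(prefix, seq_along(unique(seqs))))
}

# write a character vector to a temp file, return path
write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force Mann-Whitney AUC: concordant pairs + half ties over all
# positive/negative pairs
mw_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent arithmetic for the confusion-based metrics
brute_metrics <- function(TP, FP, TN, FN) {
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  list(Sn = TP / (TP + FN),
       Sp = TN / (FP + TN),
       Acc = (TP + TN) / (TP + FP + TN + FN),
       MCC = if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den))
}
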