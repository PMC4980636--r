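# Shared fixture builders: everything is generated in code at test time.

# Random adenosine-centered windows (valid unless perturbed by the test).
random_windows <- function(n, l = 41L, seed = 1L, prefix = "w") {
  stopifnot(l %% 2L == 1L)
  center <- (l + 1L) %/% 2L
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      ch <- sample(c("A", "C", "G", "U"), l, replace = TRUE)
      ch[center] <- "A"
      paste(ch, collapse = "")
    }, character(1))
  })
  tibble::tibble(id = sprintf("%s%04d", prefix, seq_len(n)), seq = seqs,
                 label = NA_character_)
}

write_tmp_fasta <- function(records, name = "tmp.fa") {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  write_fasta(records, path)
  path
}

# Small SVM configuration used throughout the unit tests: a 2 x 2 grid is
# enough to exercise selection, tie-breaking and determinism.
tiny_config <- function(seed = 7L) {
  svm_config(C_grid = c(1, 8), gamma_grid = c(2^-5, 2^-3),
             inner_cv_folds = 3L, seed = seed)
}

# Compact separable dataset: short windows, deterministic flanking signal.
tiny_dataset <- function(n = 12L, l = 11L, seed = 3L,
                         signal_strength = 1, tag = "tiny") {
  spec <- synthetic_spec(n_pos = n, n_neg = n, window_length = l,
                         signal_strength = signal_strength, seed = seed)
  generate_dataset(spec, tag = tag)
}

# Independent Mann-Whitney AUROC oracle: mean pairwise concordance with half
# credit for ties.
auroc_pairwise <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
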