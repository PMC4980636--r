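#' Sampling plan for repeated balanced negative draws
#'
#' The negative candidate pool is typically far larger than the positive set,
#' so model training uses balanced datasets built from repeated random draws
#' of negatives (ten repeats by default) to show the model is insensitive to
#' which negatives were drawn.
#'
#' @param n_negatives Number of negatives per repeat.
#' @param n_repeats Number of independent draws (default 10).
#' @param seed Base seed; repeat `i` uses `seed + i` so all draws are
#'   reproducible from one value.
#' @return An object of class `m1a_sampling_plan`.
#' @export
sampling_plan <- function(n_negatives, n_repeats = 10L, seed = 1L) {
  if (n_negatives < 1L) stop("`n_negatives` must be positive", call. = FALSE)
  if (n_repeats < 1L) stop("`n_repeats` must be positive", call. = FALSE)
  structure(list(n_negatives = as.integer(n_negatives),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "m1a_sampling_plan")
}

#' Remove redundant windows above a sequence-identity threshold
#'
#' Greedy incremental clustering in input order: a window is retained iff its
#' identity to every previously retained window is `<= threshold`. Because all
#' windows are equal-length and anchored on the center adenosine, identity is
#' computed position-wise (ungapped): matching positions / length. The default
#' threshold 0.8 removes windows sharing more than 80% identity; identity
#' exactly at the threshold is retained.
#'
#' @param records Records tibble; all sequences must share one length.
#' @param threshold Identity fraction in (0, 1].
#' @return The retained records, in original order.
#' @export
reduce_redundancy <- function(records, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(records)
  if (n <= 1L) return(records)
  len <- nchar(records$seq)
  if (length(unique(len)) != 1L) {
    stop(sprintf("length error: records mix window lengths (%s)",
                 paste(sort(unique(len)), collapse = ", ")), call. = FALSE)
  }
  l <- len[1L]
  M <- matrix(unlist(strsplit(records$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = l, byrow = TRUE)
  kept <- 1L
  for (i in 2:n) {
    v <- M[i, ]
    ident <- rowMeans(M[kept, , drop = FALSE] ==
                        matrix(v, nrow = length(kept), ncol = l, byrow = TRUE))
    if (all(ident <= threshold)) kept <- c(kept, i)
  }
  records[kept, , drop = FALSE]
}

#' Draw repeated balanced negative sets from a candidate pool
#'
#' Each repeat is a uniform sample without replacement of `plan$n_negatives`
#' windows; repeats use derived seeds `plan$seed + i`, so the same pool and
#' plan always reproduce the same sets. Within each repeat, records keep their
#' pool order.
#'
#' @param pool Validated records tibble (center A, correct length).
#' @param plan A [sampling_plan()].
#' @return A list of `plan$n_repeats` record tibbles.
#' @export
sample_negatives <- function(pool, plan) {
  stopifnot(inherits(plan, "m1a_sampling_plan"))
  if (plan$n_negatives > nrow(pool)) {
    stop(sprintf("sampling error: requested %d negatives from a pool of %d",
                 plan$n_negatives, nrow(pool)), call. = FALSE)
  }
  lapply(seq_len(plan$n_repeats), function(i) {
    idx <- with_seed(plan$seed + i,
                     sort(sample.int(nrow(pool), plan$n_negatives)))
    pool[idx, , drop = FALSE]
  })
}

#' Assemble a labeled benchmark dataset from positive and negative windows
#'
#' Positives and negatives are expected to be balanced (a warning, not an
#' error, is raised otherwise, since class imbalance distorts
#' accuracy-centric evaluation). A sequence occurring verbatim in both
#' classes is treated as contamination and rejected.
#'
#' @param positives,negatives Records tibbles.
#' @param tag Provenance tag (species / cell line).
#' @param window_length Odd window length.
#' @return An `m1a_dataset` with positives first.
#' @export
assemble_dataset <- function(positives, negatives, tag = "",
                             window_length = 41L) {
  positives <- validate_windows(positives, window_length)
  negatives <- validate_windows(negatives, window_length)
  shared <- intersect(positives$seq, negatives$seq)
  if (length(shared) > 0L) {
    pid <- positives$id[match(shared, positives$seq)]
    nid <- negatives$id[match(shared, negatives$seq)]
    stop(sprintf(
      "contamination error: %d sequence(s) occur in both classes (e.g. '%s' / '%s')",
      length(shared), pid[1L], nid[1L]
    ), call. = FALSE)
  }
  if (nrow(positives) != nrow(negatives)) {
    warning(sprintf("class imbalance: %d positives vs %d negatives",
                    nrow(positives), nrow(negatives)), call. = FALSE)
  }
  positives$label <- "positive"
  negatives$label <- "negative"
  window_dataset(rbind(positives, negatives), window_length, tag)
}

#' Write a dataset manifest
#'
#' Tab-separated manifest of one or more datasets (e.g. the ten
#' negative-resampling repeats): columns `id`, `label`, `tag`, `repeat_index`.
#'
#' @param datasets A single `m1a_dataset` or a list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(datasets, path) {
  if (inherits(datasets, "m1a_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    data.frame(id = d$id, label = d$label, tag = dataset_tag(d),
               repeat_index = i, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
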