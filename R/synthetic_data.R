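BASES <- c("A", "C", "G", "U")

# Default positive-class signal: a composition bias at six positions flanking
# the center adenosine, each fully committed to one base. The weakest
# structure sufficient to give the classifier a recoverable positional
# signal; it makes no claim about real m1A sequence context.
default_signal_positions <- function() {
  offsets <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  bases <- c("G", "G", "C", "G", "C", "C")
  lapply(seq_along(offsets), function(i) {
    p <- stats::setNames(numeric(4), BASES)
    p[bases[i]] <- 1
    list(offset = offsets[i], probs = p)
  })
}

#' Specification of a synthetic window benchmark
#'
#' Describes a generator of adenosine-centered labeled windows with known,
#' controllable signal. Negatives are drawn i.i.d. from `background_freqs` at
#' every non-center position. Positives use, at each signal position, the
#' mixture `(1 - signal_strength) * background + signal_strength * signal`;
#' at `signal_strength = 0` the two classes are exchangeable, at 1 the signal
#' positions follow the signal distribution exactly. The center position is
#' always A in both classes.
#'
#' @param n_pos,n_neg Windows per class (default 500 each).
#' @param window_length Odd window length (default 41).
#' @param background_freqs Probability 4-vector over A, C, G, U (default
#'   uniform).
#' @param signal_positions List of `list(offset, probs)` pairs; offsets are
#'   relative to the center (nonzero); default: six deterministic positions
#'   flanking the center.
#' @param signal_strength Mixing fraction in \[0, 1\] (default 1).
#' @param seed Seed (default 1).
#' @return An object of class `m1a_synth_spec`.
#' @export
synthetic_spec <- function(n_pos = 500L, n_neg = 500L, window_length = 41L,
                           background_freqs = c(A = 0.25, C = 0.25,
                                                G = 0.25, U = 0.25),
                           signal_positions = default_signal_positions(),
                           signal_strength = 1, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) {
    stop("configuration error: n_pos and n_neg must be positive",
         call. = FALSE)
  }
  if (window_length < 3L || window_length %% 2L == 0L) {
    stop("configuration error: window_length must be an odd integer >= 3",
         call. = FALSE)
  }
  check_probs <- function(p, what) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("configuration error: %s must be a probability 4-vector",
                   what), call. = FALSE)
    }
  }
  check_probs(background_freqs, "background_freqs")
  center <- (window_length + 1L) %/% 2L
  for (sp in signal_positions) {
    if (!is.list(sp) || is.null(sp$offset) || is.null(sp$probs)) {
      stop("configuration error: signal_positions entries need $offset and $probs",
           call. = FALSE)
    }
    check_probs(sp$probs, sprintf("signal probs at offset %d", sp$offset))
    pos <- center + sp$offset
    if (sp$offset == 0L || pos < 1L || pos > window_length) {
      stop(sprintf("configuration error: signal offset %d outside the window",
                   sp$offset), call. = FALSE)
    }
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("configuration error: signal_strength must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_length = as.integer(window_length),
                 background_freqs = background_freqs,
                 signal_positions = signal_positions,
                 signal_strength = signal_strength,
                 seed = as.integer(seed)),
            class = "m1a_synth_spec")
}

sample_class <- function(n, l, center, pos_probs, prefix) {
  M <- matrix("A", nrow = n, ncol = l)
  for (j in seq_len(l)) {
    if (j == center) next
    M[, j] <- sample(BASES, n, replace = TRUE, prob = pos_probs[[j]])
  }
  new_records(sprintf("%s_%05d", prefix, seq_len(n)),
              apply(M, 1L, paste, collapse = ""))
}

#' Generate synthetic positive and negative windows
#'
#' @param spec An [synthetic_spec()].
#' @return List with `positives` and `negatives` record tibbles (labels
#'   filled in); deterministic given `spec$seed`.
#' @export
generate_windows <- function(spec) {
  stopifnot(inherits(spec, "m1a_synth_spec"))
  l <- spec$window_length
  center <- (l + 1L) %/% 2L
  bg <- lapply(seq_len(l), function(j) spec$background_freqs)
  mixed <- bg
  for (sp in spec$signal_positions) {
    j <- center + sp$offset
    mixed[[j]] <- (1 - spec$signal_strength) * spec$background_freqs +
      spec$signal_strength * sp$probs
  }
  with_seed(spec$seed, {
    pos <- sample_class(spec$n_pos, l, center, mixed, "pos")
    neg <- sample_class(spec$n_neg, l, center, bg, "neg")
  })
  pos$label <- "positive"
  neg$label <- "negative"
  list(positives = pos, negatives = neg)
}

#' Generate a synthetic dataset directly
#'
#' Convenience wrapper: [generate_windows()] followed by
#' [assemble_dataset()].
#'
#' @param spec An [synthetic_spec()].
#' @param tag Provenance tag.
#' @return An `m1a_dataset`.
#' @export
generate_dataset <- function(spec, tag = "synthetic") {
  w <- generate_windows(spec)
  assemble_dataset(w$positives, w$negatives, tag = tag,
                   window_length = spec$window_length)
}

#' Generate two related synthetic domains
#'
#' Fixture for cross cell line / cross species experiments: two datasets
#' generated from independent seeds that either share the positive-class
#' signal positions (`shared = TRUE`, emulating domains with a common
#' sequence determinant) or use disjoint signal positions (`shared = FALSE`,
#' emulating domains with nothing in common beyond the centered adenosine).
#'
#' @param specA,specB [synthetic_spec()]s with equal window lengths.
#' @param shared Copy A's signal positions into B (default TRUE); otherwise
#'   B's signal is re-drawn on offsets disjoint from A's, under B's seed.
#' @param tags Length-2 character vector of dataset tags.
#' @return List of two `m1a_dataset`s named by `tags`.
#' @export
generate_two_domains <- function(specA, specB, shared = TRUE,
                                 tags = c("domainA", "domainB")) {
  if (specA$window_length != specB$window_length) {
    stop("configuration error: the two domains must share one window length",
         call. = FALSE)
  }
  if (shared) {
    specB$signal_positions <- specA$signal_positions
  } else {
    center <- (specB$window_length + 1L) %/% 2L
    used <- vapply(specA$signal_positions, `[[`, integer(1), "offset")
    avail <- setdiff(seq_len(specB$window_length) - center, c(0L, used))
    k <- length(specB$signal_positions)
    if (length(avail) < k) {
      stop("configuration error: not enough free positions for disjoint signal",
           call. = FALSE)
    }
    specB$signal_positions <- with_seed(specB$seed + 10007L, {
      offs <- sort(sample(avail, k))
      lapply(offs, function(o) {
        p <- stats::setNames(numeric(4), BASES)
        p[sample(BASES, 1L)] <- 1
        list(offset = o, probs = p)
      })
    })
  }
  out <- list(generate_dataset(specA, tag = tags[1L]),
              generate_dataset(specB, tag = tags[2L]))
  names(out) <- tags
  out
}

#' Write a generated benchmark to FASTA plus a spec-echo JSON
#'
#' @param spec An [synthetic_spec()].
#' @param prefix Output path prefix; writes `<prefix>_pos.fa`,
#'   `<prefix>_neg.fa` and `<prefix>_spec.json`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_synthetic <- function(spec, prefix) {
  w <- generate_windows(spec)
  paths <- c(positives = paste0(prefix, "_pos.fa"),
             negatives = paste0(prefix, "_neg.fa"),
             spec = paste0(prefix, "_spec.json"))
  write_fasta(w$positives, paths[["positives"]])
  write_fasta(w$negatives, paths[["negatives"]])
  echo <- unclass(spec)
  echo$signal_positions <- lapply(spec$signal_positions, function(sp) {
    list(offset = sp$offset, probs = as.list(sp$probs))
  })
  jsonlite::write_json(list(spec = echo, provenance = provenance(spec$seed)),
                       paths[["spec"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
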