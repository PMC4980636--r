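# Chemical-property coordinates per base: x = ring structure (purines A,G
# have two rings), y = hydrogen-bond strength (G:C pairs are strong), z =
# chemical functionality (A,C carry the amino group; G,U the keto group).
NCP_TABLE <- matrix(
  c(1, 1, 1,   # A
    0, 0, 1,   # C
    1, 0, 0,   # G
    0, 1, 0),  # U
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), c("x", "y", "z"))
)

# Canonical channel order and the mask vocabulary.
FEATURE_CHANNELS <- c(ring = "x", hbond = "y", functionality = "z",
                      density = "d")

#' Chemical-property triple of a nucleotide
#'
#' Returns the fixed (x, y, z) code of a base: ring structure, hydrogen-bond
#' strength, chemical functionality. A maps to (1,1,1), C to (0,0,1), G to
#' (1,0,0), U to (0,1,0).
#'
#' @param base A single character, one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return Named numeric vector `c(x, y, z)`.
#' @examples
#' encode_ncp("A")
#' @export
encode_ncp <- function(base) {
  if (!is.character(base) || length(base) != 1L ||
      !(base %in% rownames(NCP_TABLE))) {
    stop(sprintf("alphabet error: no chemical-property code for '%s'",
                 as.character(base)[1L]), call. = FALSE)
  }
  NCP_TABLE[base, ]
}

#' Cumulative nucleotide density along a sequence
#'
#' The density at position i is the frequency of the base occupying position
#' i within the prefix ending at i: (occurrences of `seq[i]` among positions
#' 1..i) / i. The first position therefore always has density 1, and a
#' homopolymer has density 1 everywhere. This channel carries the local
#' nucleotide composition surrounding the candidate site.
#'
#' @param seq A nonempty normalized RNA string.
#' @return Numeric vector of length `nchar(seq)`, values in (0, 1].
#' @examples
#' encode_density("ACGU")  # 1, 1/2, 1/3, 1/4
#' @export
encode_density <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("`seq` must be a single nonempty string", call. = FALSE)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(ch, rownames(NCP_TABLE))
  if (anyNA(idx)) {
    stop(sprintf("alphabet error: character '%s' outside {A,C,G,U}",
                 ch[which(is.na(idx))[1L]]), call. = FALSE)
  }
  counts <- vapply(seq_len(4L), function(b) cumsum(idx == b),
                   numeric(length(ch)))
  counts <- matrix(counts, nrow = length(ch))
  counts[cbind(seq_along(ch), idx)] / seq_along(ch)
}

check_mask <- function(mask) {
  if (is.null(mask)) mask <- names(FEATURE_CHANNELS)
  if (!is.character(mask) || length(mask) == 0L ||
      !all(mask %in% names(FEATURE_CHANNELS)) || anyDuplicated(mask)) {
    stop(sprintf(
      "invalid feature mask: choose a subset of {%s}",
      paste(names(FEATURE_CHANNELS), collapse = ", ")
    ), call. = FALSE)
  }
  # canonical order regardless of how the user spelled the subset
  names(FEATURE_CHANNELS)[names(FEATURE_CHANNELS) %in% mask]
}

#' Encode one window as a numeric feature vector
#'
#' Concatenates, position by position (position-major), the enabled feature
#' channels in the fixed order x (ring), y (hydrogen bond), z (chemical
#' functionality), d (density). Under the full mask a 41-nt window yields
#' exactly 4 x 41 = 164 features; single-channel masks drive the
#' feature-ablation analysis.
#'
#' @param seq A normalized RNA string (any positive length; window-length
#'   validation is a separate gate, see [validate_windows()]).
#' @param mask Character subset of
#'   `c("ring", "hbond", "functionality", "density")`; `NULL` means all four.
#' @return Named numeric vector of length `length(mask) * nchar(seq)`.
#' @examples
#' length(encode_window(strrep("A", 41)))  # 164
#' @export
encode_window <- function(seq, mask = NULL) {
  mask <- check_mask(mask)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(ch, rownames(NCP_TABLE))
  if (anyNA(idx)) {
    stop(sprintf("alphabet error: character '%s' outside {A,C,G,U}",
                 ch[which(is.na(idx))[1L]]), call. = FALSE)
  }
  l <- length(ch)
  full <- cbind(NCP_TABLE[idx, , drop = FALSE], d = encode_density(seq))
  sel <- full[, FEATURE_CHANNELS[mask], drop = FALSE]
  out <- as.vector(t(sel))
  names(out) <- paste0("p", formatC(rep(seq_len(l), each = length(mask)),
                                    width = 2, flag = "0"),
                       "_", rep(FEATURE_CHANNELS[mask], times = l))
  out
}

#' Encode a set of windows as a feature matrix
#'
#' @param records A records tibble or `m1a_dataset`.
#' @param mask Feature mask, as in [encode_window()].
#' @return Numeric matrix, one row per window, with row names taken from
#'   record ids.
#' @export
encode_windows <- function(records, mask = NULL) {
  mask <- check_mask(mask)
  if (nrow(records) == 0L) {
    return(matrix(numeric(), nrow = 0L, ncol = 0L))
  }
  X <- t(vapply(records$seq, encode_window,
                numeric(length(mask) * nchar(records$seq[1L])), mask = mask))
  rownames(X) <- records$id
  X
}

#' Write a feature matrix as TSV
#'
#' The header line records the mask and window length so a matrix is
#' self-describing.
#'
#' @param X Matrix from [encode_windows()].
#' @param path Output path.
#' @param mask Mask used to build `X`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, mask = NULL) {
  mask <- check_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mask=%s l=%d", paste(mask, collapse = "+"),
                     ncol(X) %/% length(mask)), con)
  utils::write.table(data.frame(id = rownames(X), X, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pseudo dinucleotide composition (PseDNC) baseline encoder ----

DINUCLEOTIDES <- as.vector(outer(rownames(NCP_TABLE), rownames(NCP_TABLE),
                                 paste0))

#' Read a PseDNC physicochemical property table
#'
#' Long-format TSV with columns `dinucleotide`, `property`, `value`, covering
#' all 16 RNA dinucleotides for every property (e.g. enthalpy, entropy, free
#' energy). Each property is standardized to mean 0, sd 1 across the 16
#' dinucleotides at load, so the encoder is invariant to the units of the
#' source table. An example table is shipped at
#' `system.file("extdata", "psednc_properties_example.tsv",
#' package = "m1Apred")`.
#'
#' @param path TSV path.
#' @return Numeric matrix, 16 rows (dinucleotides) x properties.
#' @export
read_psednc_properties <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dinucleotide", "property", "value")
  if (!all(need %in% names(tab))) {
    stop("configuration error: property table needs columns dinucleotide, property, value",
         call. = FALSE)
  }
  tab$dinucleotide <- chartr("T", "U", toupper(tab$dinucleotide))
  props <- unique(tab$property)
  M <- matrix(NA_real_, nrow = 16L, ncol = length(props),
              dimnames = list(DINUCLEOTIDES, props))
  M[cbind(match(tab$dinucleotide, DINUCLEOTIDES),
          match(tab$property, props))] <- tab$value
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "configuration error: property '%s' missing a value for dinucleotide '%s'",
      colnames(M)[miss[2L]], rownames(M)[miss[1L]]
    ), call. = FALSE)
  }
  scale(M)[, , drop = FALSE]
}

#' PseDNC encoder configuration
#'
#' @param lambda Number of correlation tiers (non-negative integer); must be
#'   smaller than `l - 1` for every sequence encoded.
#' @param w Weight of the pseudo components, in \[0, 1\].
#' @param property_table Standardized property matrix from
#'   [read_psednc_properties()].
#' @return An object of class `m1a_psednc_config`.
#' @export
psednc_config <- function(lambda = 2L, w = 0.5, property_table) {
  if (lambda < 0L) stop("`lambda` must be non-negative", call. = FALSE)
  if (w < 0 || w > 1) stop("`w` must lie in [0, 1]", call. = FALSE)
  if (!is.matrix(property_table) ||
      !identical(rownames(property_table), DINUCLEOTIDES)) {
    stop("configuration error: `property_table` must come from read_psednc_properties()",
         call. = FALSE)
  }
  structure(list(lambda = as.integer(lambda), w = w,
                 property_table = property_table),
            class = "m1a_psednc_config")
}

#' Pseudo dinucleotide composition of a window
#'
#' Baseline encoding: the 16 dinucleotide frequencies augmented with `lambda`
#' tiered sequence-order correlation terms. The correlation between two
#' dinucleotides is the mean squared difference of their standardized
#' property values; tier j averages that correlation over all pairs j apart.
#' All 16 + lambda components are normalized by `1 + w * sum(theta)`, so the
#' vector sums to 1.
#'
#' @param seq Normalized RNA string of length at least `lambda + 2`.
#' @param config A [psednc_config()].
#' @return Numeric vector of length `16 + lambda`.
#' @export
encode_psednc <- function(seq, config) {
  stopifnot(inherits(config, "m1a_psednc_config"))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  l <- length(ch)
  if (config$lambda >= l - 1L) {
    stop(sprintf("parameter error: lambda = %d requires sequence length > %d",
                 config$lambda, config$lambda + 1L), call. = FALSE)
  }
  dinucs <- paste0(ch[-l], ch[-1L])
  di_idx <- match(dinucs, DINUCLEOTIDES)
  if (anyNA(di_idx)) {
    stop("alphabet error: sequence contains characters outside {A,C,G,U}",
         call. = FALSE)
  }
  f <- tabulate(di_idx, nbins = 16L) / (l - 1L)
  P <- config$property_table
  theta <- numeric(config$lambda)
  if (config$lambda > 0L) {
    for (j in seq_len(config$lambda)) {
      i <- seq_len(l - 1L - j)
      theta[j] <- mean(rowMeans((P[di_idx[i], , drop = FALSE] -
                                   P[di_idx[i + j], , drop = FALSE])^2))
    }
  }
  denom <- 1 + config$w * sum(theta)
  out <- c(f, config$w * theta) / denom
  names(out) <- c(DINUCLEOTIDES,
                  if (config$lambda > 0L) paste0("theta", seq_len(config$lambda)))
  out
}
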