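#' Normalize an RNA/DNA sequence string
#'
#' Uppercases and transliterates thymine to uracil, so DNA-alphabet input
#' (common when windows were extracted from genome coordinates) is accepted
#' transparently. Normalization is idempotent.
#'
#' @param seq Character vector of sequences.
#' @return Character vector over `{A,C,G,U}` (unvalidated; see
#'   [check_alphabet()]).
#' @export
normalize_seq <- function(seq) {
  chartr("T", "U", toupper(seq))
}

# First offending character (post-normalization) or NA if clean.
first_bad_char <- function(seq) {
  m <- regexpr("[^ACGU]", seq)
  ifelse(m > 0L, substring(seq, m, m), NA_character_)
}

#' Check that sequences use only the unambiguous RNA alphabet
#'
#' Ambiguity codes (N, R, Y, ...) are rejected rather than imputed: the
#' chemical-property encoder defines coordinates only for A, C, G and U.
#'
#' @param records A records tibble (columns `id`, `seq`).
#' @return The input, invisibly, if clean; otherwise an error naming the
#'   record and the offending character.
#' @export
check_alphabet <- function(records) {
  bad <- first_bad_char(records$seq)
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop(sprintf(
      "alphabet error: record '%s' contains character '%s' outside {A,C,G,U}",
      records$id[i], bad[i]
    ), call. = FALSE)
  }
  invisible(records)
}

new_records <- function(id = character(), seq = character(),
                        label = NA_character_) {
  tibble::tibble(id = as.character(id), seq = as.character(seq),
                 label = if (length(id)) as.character(label) else character())
}

#' Read sequence windows from a FASTA file
#'
#' Sequences are normalized (uppercased, `T` transliterated to `U`) and must
#' then contain only A, C, G, U. Record identifiers are the first
#' whitespace-delimited token of each header and must be unique within the
#' file.
#'
#' @param path Path to a FASTA file (wrapped or single-line sequences).
#' @param label Optional class label (`"positive"` or `"negative"`) assigned
#'   to every record in the file.
#' @return A tibble with columns `id`, `seq`, `label`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTACG"), fa)
#' read_fasta(fa)  # T is transliterated to U
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(new_records())
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf(
      "FASTA parse error at line %d of '%s': expected a '>' header line",
      nonblank[1L], path
    ), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop(sprintf("FASTA parse error in '%s': empty record identifier", path),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate-id error in '%s': %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  seqs <- as.character(set)
  rec <- new_records(ids, seqs)
  # validate on the raw characters so the reported offender is the user's own
  bad <- first_bad_char(toupper(seqs))
  bad[!is.na(bad) & bad == "T"] <- NA_character_
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    raw_m <- regexpr("[^ACGUTacgut]", seqs[i])
    ch <- substring(seqs[i], raw_m, raw_m)
    stop(sprintf(
      "alphabet error: record '%s' contains character '%s' outside {A,C,G,U,T}",
      ids[i], ch
    ), call. = FALSE)
  }
  rec$seq <- normalize_seq(rec$seq)
  if (!is.null(label)) {
    label <- match.arg(label, c("positive", "negative"))
    rec$label <- label
  }
  rec
}

#' Write sequence records to FASTA
#'
#' Sequences are written single-line so that `read_fasta(write_fasta(x))`
#' round-trips ids and sequences exactly.
#'
#' @param records Records tibble (columns `id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) {
    ok <- file.create(path)
    if (!ok) stop(sprintf("cannot write '%s'", path), call. = FALSE)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  width <- max(nchar(records$seq)) + 1L
  tryCatch(
    Biostrings::writeXStringSet(set, path, width = width),
    error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  invisible(path)
}

#' Validate adenosine-centered windows
#'
#' Gate applied before encoding or dataset insertion: every sequence must have
#' exactly `window_length` nucleotides (odd) and an A at the center position
#' `(window_length + 1) / 2` (1-based).
#'
#' @param records Records tibble with normalized sequences.
#' @param window_length Odd window length (default 41).
#' @return The input records, unchanged, if all pass.
#' @export
validate_windows <- function(records, window_length = 41L) {
  if (window_length < 1L || window_length %% 2L == 0L) {
    stop("`window_length` must be an odd positive integer", call. = FALSE)
  }
  check_alphabet(records)
  len <- nchar(records$seq)
  if (any(len != window_length)) {
    i <- which(len != window_length)[1L]
    stop(sprintf(
      "length error: record '%s' has %d nt, expected %d",
      records$id[i], len[i], window_length
    ), call. = FALSE)
  }
  center <- (window_length + 1L) %/% 2L
  base <- substring(records$seq, center, center)
  if (any(base != "A")) {
    i <- which(base != "A")[1L]
    stop(sprintf(
      "center-base error: record '%s' has '%s' at position %d, expected 'A'",
      records$id[i], base[i], center
    ), call. = FALSE)
  }
  records
}

#' Construct a labeled window dataset
#'
#' A window dataset is a tibble of validated, equal-length, adenosine-centered
#' windows carrying a `label` column plus `window_length` and `tag`
#' (provenance: species / cell line) attributes.
#'
#' @param records Records tibble with a `label` column filled with
#'   `"positive"` / `"negative"`.
#' @param window_length Odd window length.
#' @param tag Free-text provenance tag.
#' @return An object of class `m1a_dataset`.
#' @export
window_dataset <- function(records, window_length = 41L, tag = "") {
  records <- validate_windows(records, window_length)
  if (nrow(records) > 0L &&
      !all(records$label %in% c("positive", "negative"))) {
    stop("every record in a dataset must be labeled positive or negative",
         call. = FALSE)
  }
  structure(records, class = c("m1a_dataset", class(records)),
            window_length = as.integer(window_length), tag = tag)
}

#' @export
print.m1a_dataset <- function(x, ...) {
  cat(sprintf("<m1a_dataset> %d windows (%d positive, %d negative), l = %d%s\n",
              nrow(x), sum(x$label == "positive"),
              sum(x$label == "negative"), attr(x, "window_length"),
              if (nzchar(attr(x, "tag"))) paste0(", tag: ", attr(x, "tag"))
              else ""))
  NextMethod()
}

dataset_window_length <- function(dataset) attr(dataset, "window_length")
dataset_tag <- function(dataset) attr(dataset, "tag")
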