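#' Normalize nucleotide sequences
#'
#' Uppercases, maps `U` to `T`, and enforces the `{A,C,G,T,N}` alphabet.
#' Any other character is an error (strict by design: silent masking would
#' hide format corruption).
#'
#' @param x Character vector of sequences.
#' @param context Label used in error messages (e.g. the source file).
#' @return Character vector of normalized sequences.
#' @export
#' @examples
#' normalize_seq(c("acgu", "NNAA"))
normalize_seq <- function(x, context = "sequence") {
  if (!is.character(x)) abort("`x` must be a character vector of sequences.")
  x <- chartr("U", "T", toupper(x))
  bad <- which(!grepl("^[ACGTN]+$", x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s %s is empty or contains characters outside A/C/G/T/N (after U->T and case folding).",
      context, paste(head(bad, 5), collapse = ", ")
    ))
  }
  x
}

#' Reverse complement
#'
#' @param x Character vector of normalized DNA sequences (may contain `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce reads input (tibble with a `seq` column, or a bare character
# vector) into the canonical read tibble: read_id, seq, qual.
as_read_tbl <- function(reads, normalize = TRUE) {
  if (is.character(reads)) {
    reads <- tibble(
      read_id = paste0("read", seq_along(reads)),
      seq = reads,
      qual = NA_character_
    )
  }
  if (!is.data.frame(reads) || !"seq" %in% names(reads)) {
    abort("`reads` must be a data frame with a `seq` column or a character vector.")
  }
  reads <- as_tibble(reads)
  if (!"read_id" %in% names(reads)) reads$read_id <- paste0("read", seq_len(nrow(reads)))
  if (!"qual" %in% names(reads)) reads$qual <- NA_character_
  if (normalize && nrow(reads) > 0) reads$seq <- normalize_seq(reads$seq, "read")
  reads
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(p)
}

check_count <- function(n, name, min = 0) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < min || n != floor(n)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.integer(n))
}

# Maximal run length of `base` in each sequence (0 if absent).
max_run_length <- function(seqs, base) {
  m <- gregexpr(paste0(base, "+"), seqs, perl = TRUE)
  vapply(m, function(mi) {
    len <- attr(mi, "match.length")
    if (length(len) == 1 && mi[1] == -1L) 0L else max(len)
  }, integer(1))
}
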