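#' Build a k-mer index over a reference sequence
#'
#' The index is the set of all k-mers of the reference and of its reverse
#' complement; k-mers containing `N` are excluded so ambiguous bases never
#' match. This is a deliberately simple desk-scale surrogate for an external
#' aligner such as Bowtie2, not a reproduction of its scoring.
#'
#' @param reference Nucleotide string (length >= k).
#' @param k K-mer length (>= 8). Default 15: long enough that chance matches
#'   are rare, short enough that a 50-nt read with one substitution still
#'   carries several intact reference k-mers.
#' @return A list of class `kmer_index`: `kmers` (character set), `k`.
#' @export
build_kmer_index <- function(reference, k = 15L) {
  k <- check_count(k, "k", min = 8)
  reference <- normalize_seq(reference, "reference")
  if (k > nchar(reference)) abort("`k` exceeds the reference length.")
  fwd <- seq_kmers(reference, k)
  rev <- seq_kmers(revcomp(reference), k)
  kmers <- unique(c(fwd, rev))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  structure(list(kmers = kmers, k = k), class = "kmer_index")
}

seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %d distinct %d-mers (both strands)\n",
              length(x$kmers), x$k))
  invisible(x)
}

#' Classify reads as mapped or unmapped against a k-mer index
#'
#' A read is `mapped` iff it contains at least `min_hits` k-mer positions
#' whose k-mer is present in the index; reads shorter than k are unmapped by
#' definition, and k-mers containing `N` never match.
#'
#' @param reads Read tibble or character vector.
#' @param index A [build_kmer_index()] result.
#' @param min_hits Minimum matching k-mer positions. Default 2.
#' @return Character vector, `"mapped"`/`"unmapped"`, one per read.
#' @export
classify_reads <- function(reads, index, min_hits = 2L) {
  stopifnot(inherits(index, "kmer_index"))
  min_hits <- check_count(min_hits, "min_hits", min = 1)
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) return(character(0))
  kmer_list <- lapply(reads$seq, seq_kmers, k = index$k)
  pooled <- unlist(kmer_list, use.names = FALSE)
  hit <- pooled %in% index$kmers
  hits_per_read <- vapply(
    split(hit, rep.int(seq_len(nrow(reads)), lengths(kmer_list))),
    sum, integer(1))
  counts <- integer(nrow(reads))
  counts[as.integer(names(hits_per_read))] <- hits_per_read
  ifelse(counts >= min_hits, "mapped", "unmapped")
}

#' Triage reads against one or more references
#'
#' Exactly partitions the input into unmapped reads and reads mapped to one
#' of the references. A read matching several references is assigned to the
#' first one in order (ties logged); every read appears exactly once.
#'
#' @param reads Read tibble (unique `read_id`s) or character vector.
#' @param references Named character vector of reference sequences (>= 1).
#' @param k,min_hits See [build_kmer_index()] and [classify_reads()].
#' @return A list of class `triage_result`: `assignments` (tibble `read_id`,
#'   `status`, `reference`), `counts` (tibble `reference`, `n`; unmapped row
#'   included), `params`.
#' @export
triage_reads <- function(reads, references, k = 15L, min_hits = 2L) {
  reads <- as_read_tbl(reads)
  if (length(references) < 1) abort("At least one reference is required.")
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  if (anyDuplicated(reads$read_id)) {
    abort("Duplicate read ids in input; triage requires unique ids.")
  }
  assignment <- rep(NA_character_, nrow(reads))
  multi <- 0L
  for (ref_name in names(references)) {
    idx <- build_kmer_index(references[[ref_name]], k = k)
    cls <- classify_reads(reads, idx, min_hits = min_hits)
    hit <- cls == "mapped"
    multi <- multi + sum(hit & !is.na(assignment))
    assignment[hit & is.na(assignment)] <- ref_name
  }
  if (multi > 0) {
    inform(sprintf(
      "%d read(s) matched more than one reference; assigned to the first in order.",
      multi))
  }
  assignments <- tibble(
    read_id = reads$read_id,
    status = ifelse(is.na(assignment), "unmapped", "mapped"),
    reference = assignment
  )
  counts <- dplyr::count(assignments,
                         reference = dplyr::coalesce(.data$reference, "unmapped"))
  structure(
    list(assignments = assignments, counts = counts,
         params = list(k = k, min_hits = min_hits,
                       references = names(references))),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  n <- nrow(x$assignments)
  n_un <- sum(x$assignments$status == "unmapped")
  cat(sprintf("<triage_result> %d reads: %d mapped, %d unmapped (k = %d, min_hits = %d)\n",
              n, n - n_un, n_un, x$params$k, x$params$min_hits))
  invisible(x)
}

#' @describeIn triage_reads Per-read assignments as a tibble.
#' @param x A `triage_result`.
#' @param ... Unused.
#' @export
tidy.triage_result <- function(x, ...) x$assignments

#' @describeIn triage_reads One-row summary (totals and parameters).
#' @export
glance.triage_result <- function(x, ...) {
  tibble(
    n_reads = nrow(x$assignments),
    n_mapped = sum(x$assignments$status == "mapped"),
    n_unmapped = sum(x$assignments$status == "unmapped"),
    k = x$params$k,
    min_hits = x$params$min_hits
  )
}

#' Keep only unmapped reads from a triage result
#'
#' @param reads The read tibble that was triaged.
#' @param triage A [triage_reads()] result.
#' @return The subset of `reads` whose ids were unmapped, in input order.
#' @export
unmapped_reads <- function(reads, triage) {
  stopifnot(inherits(triage, "triage_result"))
  reads <- as_read_tbl(reads)
  ids <- triage$assignments$read_id[triage$assignments$status == "unmapped"]
  reads[reads$read_id %in% ids, ]
}
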