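#' Simulate a protein-primed reverse-transcription read set
#'
#' Generates a labeled mixture of poly(dA)-core "product" reads and
#' contaminant reads drawn from a reference, emulating the read structure
#' expected from a DRT-style reverse transcriptase that polymerizes dATP and
#' whose terminal transferase activity appends stochastic 3' poly-C tails.
#'
#' A product read is a poly(A) core of geometric length (support >= 1, mean
#' `mu_core`), optionally followed (probability `p_tail`) by a poly(C) tail
#' of geometric length (mean `mu_tail`). A contaminant read is a substring of
#' `contaminant_reference` of fixed length `contaminant_read_length` (a
#' sequencer-style read length: contaminant host reads come off the machine
#' at full read length, while product molecules are short) at a uniform
#' start. After assembly, each
#' base is substituted with probability `sub_error_rate` (to a uniformly
#' chosen different base) and then replaced by `N` with probability `n_rate`,
#' so the truth labels always refer to the pre-noise read structure.
#'
#' @param n_reads Number of reads.
#' @param product_fraction Probability a read is a product read.
#' @param mu_core Mean of the geometric poly(A) core length law (nt, >= 1).
#' @param p_tail Probability a product read carries a 3' poly(C) tail.
#' @param mu_tail Mean tail length (nt, >= 1).
#' @param sub_error_rate Per-base substitution error probability.
#' @param n_rate Per-base probability of replacement by `N` (applied after
#'   substitutions).
#' @param contaminant_reference Nucleotide string contaminant reads are drawn
#'   from. Required whenever `product_fraction < 1`.
#' @param contaminant_read_length Length of contaminant reads (nt); truncated
#'   at the reference length and `read_length_cap`.
#' @param read_length_cap Maximum emitted read length (nt); longer assembled
#'   reads are truncated at the 3' end.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A tibble with columns `read_id`, `seq`, `qual` (uniform `"I"`;
#'   qualities are carried, never used analytically), and truth columns
#'   `label` (`"product"`/`"contaminant"`), `core_len`, `tail_len` (pre-noise,
#'   post-cap lengths; `NA` core/tail for contaminants).
#' @seealso [write_fastx()] to emit FASTQ, [write_read_truth()] for the truth
#'   TSV, [triage_reads()] for the downstream classifier.
#' @export
#' @examples
#' simulate_product_read_set(5, product_fraction = 1, sub_error_rate = 0,
#'                           n_rate = 0, p_tail = 0, seed = 1)
simulate_product_read_set <- function(n_reads,
                                      product_fraction = 0.8,
                                      mu_core = 30,
                                      p_tail = 0.3,
                                      mu_tail = 8,
                                      sub_error_rate = 0.01,
                                      n_rate = 0.001,
                                      contaminant_reference = NULL,
                                      contaminant_read_length = 100L,
                                      read_length_cap = 150L,
                                      seed = NULL) {
  n_reads <- check_count(n_reads, "n_reads", min = 0)
  check_probability(product_fraction, "product_fraction")
  check_probability(p_tail, "p_tail")
  check_probability(sub_error_rate, "sub_error_rate")
  check_probability(n_rate, "n_rate")
  if (mu_core < 1) abort("`mu_core` must be >= 1 nt.")
  if (mu_tail < 1) abort("`mu_tail` must be >= 1 nt.")
  if (product_fraction < 1 &&
      (is.null(contaminant_reference) || nchar(contaminant_reference) == 0)) {
    abort("`contaminant_reference` is required when `product_fraction` < 1.")
  }
  if (!is.null(contaminant_reference)) {
    contaminant_reference <- normalize_seq(contaminant_reference, "contaminant_reference")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  out <- tibble(
    read_id = sprintf("sim%06d", seq_len(n_reads)),
    seq = character(n_reads),
    qual = character(n_reads),
    label = character(n_reads),
    core_len = NA_integer_,
    tail_len = NA_integer_
  )
  if (n_reads == 0) return(out)

  is_product <- runif(n_reads) < product_fraction
  # geometric with support {1, 2, ...} and mean mu: p = 1/mu
  rgeom1 <- function(n, mu) rgeom(n, 1 / mu) + 1L

  seqs <- character(n_reads)
  np <- sum(is_product)
  if (np > 0) {
    core <- rgeom1(np, mu_core)
    tailed <- runif(np) < p_tail
    tail <- ifelse(tailed, rgeom1(np, mu_tail), 0L)
    # truncate at the 3' end: tail first, then core
    over <- pmax(core + tail - read_length_cap, 0L)
    tail_cap <- pmax(tail - over, 0L)
    core_cap <- pmin(core, read_length_cap)
    seqs[is_product] <- paste0(strrep("A", core_cap), strrep("C", tail_cap))
    out$core_len[is_product] <- core_cap
    out$tail_len[is_product] <- tail_cap
    out$label[is_product] <- "product"
  }
  nc <- sum(!is_product)
  if (nc > 0) {
    ref_len <- nchar(contaminant_reference)
    len <- rep(min(contaminant_read_length, ref_len, read_length_cap), nc)
    start <- floor(runif(nc) * (ref_len - len + 1)) + 1L
    seqs[!is_product] <- substring(contaminant_reference, start, start + len - 1L)
    out$label[!is_product] <- "contaminant"
  }

  seqs <- apply_read_noise(seqs, sub_error_rate, n_rate)
  out$seq <- seqs
  out$qual <- strrep("I", nchar(seqs))
  out
}

# Substitution errors then N masking, vectorized over the pooled bases.
apply_read_noise <- function(seqs, sub_error_rate, n_rate) {
  if (sub_error_rate == 0 && n_rate == 0) return(seqs)
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  pooled <- unlist(chars, use.names = FALSE)
  n <- length(pooled)
  if (sub_error_rate > 0) {
    hit <- which(runif(n) < sub_error_rate & pooled != "N")
    if (length(hit) > 0) {
      bases <- c("A", "C", "G", "T")
      # uniformly one of the three other bases
      offset <- sample.int(3, length(hit), replace = TRUE)
      cur <- match(pooled[hit], bases)
      pooled[hit] <- bases[(cur - 1L + offset) %% 4L + 1L]
    }
  }
  if (n_rate > 0) {
    pooled[runif(n) < n_rate] <- "N"
  }
  unname(vapply(split(pooled, rep.int(seq_along(lens), lens)),
                paste, character(1), collapse = ""))
}

#' Write the simulator truth table
#'
#' Emits a TSV with one row per simulated read: `read_id`, `label`,
#' `core_len`, `tail_len`.
#'
#' @param reads Tibble from [simulate_product_read_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_read_truth <- function(reads, path) {
  stopifnot(all(c("read_id", "label") %in% names(reads)))
  readr::write_tsv(reads[, c("read_id", "label", "core_len", "tail_len")], path)
  invisible(path)
}

#' Simulate a random contaminant reference sequence
#'
#' Uniform-composition DNA used as the default contaminant source in the
#' examples, tests, and pipeline; stands in for host-genome-derived reads.
#'
#' @param length Sequence length (nt).
#' @param seed Integer seed.
#' @return A single nucleotide string.
#' @export
simulate_reference <- function(length = 2000L, seed = NULL) {
  length <- check_count(length, "length", min = 1)
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}
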