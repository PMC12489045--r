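# Independent oracles and small fixture builders shared across tests.

# Quadratic brute-force homopolymer-run enumerator: for every start
# position, extend while the base repeats; report maximal A/C/G/T runs.
# Deliberately naive and independent of the rle-based implementation.
brute_force_runs <- function(seq, min_len = 1L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  base <- character(0); start <- integer(0); len <- integer(0)
  i <- 1L
  for (s in seq_len(n)) {
    if (s > 1 && ch[s] == ch[s - 1]) next  # not maximal on the left
    e <- s
    while (e < n && ch[e + 1] == ch[s]) e <- e + 1L
    if (ch[s] != "N" && (e - s + 1L) >= min_len) {
      base[i] <- ch[s]; start[i] <- s; len[i] <- e - s + 1L
      i <- i + 1L
    }
  }
  tibble::tibble(base = base, start = start, length = len)
}

# Hash-free multiset tally: count copies of each distinct sequence by
# pairwise comparison against the sorted unique values.
naive_tally <- function(seqs) {
  uniq <- sort(unique(seqs))
  counts <- vapply(uniq, function(u) sum(seqs == u), integer(1))
  ord <- order(-counts, uniq)
  tibble::tibble(representative = uniq[ord], n_copies = counts[ord])
}

random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Small labeled mixture used by several modules.
fixture_reads <- function(n = 2000, seed = 42, ...) {
  ref <- drtkit::simulate_reference(1000, seed = seed + 1)
  list(
    reference = ref,
    reads = drtkit::simulate_product_read_set(
      n, contaminant_reference = ref, seed = seed, ...)
  )
}
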