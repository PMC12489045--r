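#' Find maximal homopolymer runs in a sequence
#'
#' Scans one normalized sequence for maximal stretches of consecutive
#' identical nucleotides (A, C, G or T). `N` never forms a run and breaks
#' runs on either side.
#'
#' @param seq A single normalized sequence.
#' @param min_len Minimum reported run length (nt, >= 1).
#' @return Tibble with columns `base`, `start` (1-based), `length`, in
#'   position order.
#' @export
#' @examples
#' find_runs("AAAACGGGT", min_len = 2)
find_runs <- function(seq, min_len = 1L) {
  min_len <- check_count(min_len, "min_len", min = 1)
  if (length(seq) != 1 || !is.character(seq)) {
    abort("`seq` must be a single sequence string.")
  }
  seq <- normalize_seq(seq, "seq")
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$values != "N" & r$lengths >= min_len
  tibble(base = r$values[keep], start = start[keep], length = r$lengths[keep])
}

#' Homopolymer prevalence spectrum of a read set
#'
#' For each base and each length threshold, the percentage of reads that
#' contain at least one maximal run of that base with length at or above the
#' threshold. A read counts at most once per (base, threshold) cell
#' regardless of how many qualifying runs it carries (read-level counting;
#' the denominator is the total read count). `count = "runs"` instead counts
#' qualifying runs per 100 reads, a diagnostic that can exceed 100.
#'
#' @param reads Read tibble or character vector (>= 1 read).
#' @param thresholds Ordered run-length thresholds (nt).
#' @param count `"reads"` (default) or `"runs"`.
#' @return A tibble of class `hp_spectrum` with columns `base`, `threshold`,
#'   `n_reads` (qualifying reads or runs), `percent`; attributes
#'   `total_reads` and `count_mode`.
#' @export
#' @examples
#' homopolymer_spectrum(c("AAAAA", "CCCCC"), thresholds = 5)
homopolymer_spectrum <- function(reads,
                                 thresholds = c(5, 10, 15, 20, 25, 30, 35, 40),
                                 count = c("reads", "runs")) {
  count <- match.arg(count)
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) abort("`reads` must contain at least one read.")
  if (any(thresholds < 1)) abort("`thresholds` must be >= 1 nt.")
  thresholds <- sort(unique(as.integer(thresholds)))
  bases <- c("A", "C", "G", "T")
  total <- nrow(reads)
  cells <- lapply(bases, function(b) {
    if (count == "reads") {
      mx <- max_run_length(reads$seq, b)
      vapply(thresholds, function(t) sum(mx >= t), integer(1))
    } else {
      m <- gregexpr(paste0(b, "+"), reads$seq, perl = TRUE)
      lens <- unlist(lapply(m, function(mi) {
        if (mi[1] == -1L) integer(0) else attr(mi, "match.length")
      }), use.names = FALSE)
      vapply(thresholds, function(t) sum(lens >= t), integer(1))
    }
  })
  out <- tibble(
    base = rep(bases, each = length(thresholds)),
    threshold = rep(thresholds, times = length(bases)),
    n_reads = unlist(cells),
    percent = unlist(cells) / total * 100
  )
  structure(out, class = c("hp_spectrum", class(out)),
            total_reads = total, count_mode = count)
}

#' @describeIn homopolymer_spectrum Spectrum cells as a plain tibble.
#' @param x An `hp_spectrum`.
#' @param ... Unused.
#' @export
tidy.hp_spectrum <- function(x, ...) as_tibble(unclass(x))

#' @describeIn homopolymer_spectrum One-row summary: total reads and the
#'   dominant base at the lowest threshold.
#' @export
glance.hp_spectrum <- function(x, ...) {
  lo <- x[x$threshold == min(x$threshold), ]
  top <- lo[which.max(lo$percent), ]
  tibble(
    total_reads = attr(x, "total_reads"),
    count_mode = attr(x, "count_mode"),
    top_base = top$base,
    top_base_percent = top$percent
  )
}

#' Trim 3'-terminal poly(C) tails from reads
#'
#' Removes, from each read, the longest 3'-terminal window of length at
#' least `min_tail` that contains at most `max_mismatch` non-C bases and
#' ends in C (i.e. the read's terminal base is C); reads without such a
#' window are unchanged. Such tails are the signature of reverse
#' transcriptase terminal transferase activity. A read whose whole sequence
#' qualifies as tail is flagged all-tail and dropped (with a counted
#' warning) rather than emptied. Qualities are trimmed alongside sequences.
#' The operation is idempotent: by maximality the base preceding a trimmed
#' tail is never C, so the trimmed read never ends in a qualifying window.
#'
#' `end = "5p"` instead trims leading poly(G) heads, the mirror artifact
#' seen in reverse-complemented libraries.
#'
#' @param reads Read tibble or character vector.
#' @param min_tail Minimum tail length (nt, >= 1). Default 5.
#' @param max_mismatch Maximum non-C bases tolerated inside the tail.
#'   Default 1.
#' @param end `"3p"` (default) or `"5p"`.
#' @return The trimmed read tibble (all-tail reads removed) with an added
#'   `tail_removed` column (nt), and a `trim_report` attribute; see
#'   [trim_report()].
#' @export
#' @examples
#' trim_polyc_tail("ACGTACGTCCCCC", min_tail = 5, max_mismatch = 0)
trim_polyc_tail <- function(reads, min_tail = 5L, max_mismatch = 1L,
                            end = c("3p", "5p")) {
  end <- match.arg(end)
  min_tail <- check_count(min_tail, "min_tail", min = 1)
  max_mismatch <- check_count(max_mismatch, "max_mismatch", min = 0)
  reads <- as_read_tbl(reads)
  seqs <- if (end == "5p") revcomp(reads$seq) else reads$seq

  tail_len <- vapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    n <- length(ch)
    if (ch[n] != "C") return(0L)
    mm <- cumsum(rev(ch) != "C")
    L <- sum(mm <= max_mismatch)
    if (L >= min_tail) L else 0L
  }, integer(1))

  comp_before <- if (nrow(reads) > 0) base_composition(reads) else NULL
  all_tail <- tail_len >= nchar(reads$seq)
  n_dropped <- sum(all_tail)
  if (n_dropped > 0) {
    warn(sprintf("%d all-tail read(s) dropped (entire sequence qualified as poly-C tail).",
                 n_dropped))
  }

  keep_len <- nchar(reads$seq) - tail_len
  out <- reads
  if (end == "3p") {
    out$seq <- substr(out$seq, 1L, keep_len)
    out$qual <- ifelse(is.na(out$qual), out$qual, substr(out$qual, 1L, keep_len))
  } else {
    lo <- tail_len + 1L
    out$seq <- substr(out$seq, lo, nchar(out$seq))
    out$qual <- ifelse(is.na(out$qual), out$qual,
                       substr(out$qual, lo, nchar(out$qual)))
  }
  out$tail_removed <- tail_len
  out <- out[!all_tail, ]

  report <- list(
    n_input = nrow(reads),
    reads_trimmed = sum(tail_len > 0 & !all_tail),
    bases_removed = sum(tail_len[!all_tail]),
    reads_dropped_all_tail = n_dropped,
    composition_before = comp_before,
    composition_after = if (nrow(out) > 0) base_composition(out) else NULL,
    params = list(min_tail = min_tail, max_mismatch = max_mismatch, end = end)
  )
  attr(out, "trim_report") <- report
  out
}

#' Retrieve the trim report attached by [trim_polyc_tail()]
#'
#' @param x A tibble returned by [trim_polyc_tail()].
#' @return A list: input/trimmed/dropped counts, bases removed, pooled base
#'   composition before and after trimming, and the trimming parameters.
#' @export
trim_report <- function(x) {
  rep <- attr(x, "trim_report")
  if (is.null(rep)) abort("`x` carries no trim report; was it produced by trim_polyc_tail()?")
  rep
}

#' Pooled base composition of a read set
#'
#' Fractions of A/C/G/T/N over all bases pooled across reads (so longer
#' reads weigh more, matching a per-base rather than per-read average).
#'
#' @param reads Read tibble or character vector (>= 1 non-empty read).
#' @return Tibble with columns `base`, `count`, `fraction` (sums to 1).
#' @export
#' @examples
#' base_composition(c("AC", "GT"))
base_composition <- function(reads) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0 || sum(nchar(reads$seq)) == 0) {
    abort("`reads` must contain at least one base.")
  }
  bases <- c("A", "C", "G", "T", "N")
  counts <- vapply(bases, function(b) {
    sum(stringr::str_count(reads$seq, stringr::fixed(b)))
  }, numeric(1))
  counts <- unname(counts)
  tibble(base = bases, count = as.integer(counts),
         fraction = counts / sum(counts))
}

#' Ambiguous-base (N) counts per million reads
#'
#' Counts `N` bases per read and normalizes the total as counts per million
#' based on total read number (a read-count denominator, not a base-count
#' denominator), so duplicating every read leaves the CPM unchanged.
#'
#' @param reads Read tibble or character vector (>= 1 read).
#' @return One-row tibble: `total_n`, `total_reads`, `cpm`.
#' @export
#' @examples
#' n_count_cpm(c("ACGTN", "ACGT"))
n_count_cpm <- function(reads) {
  reads <- as_read_tbl(reads)
  if (nrow(reads) == 0) abort("`reads` must contain at least one read.")
  total_n <- sum(stringr::str_count(reads$seq, stringr::fixed("N")))
  tibble(total_n = total_n, total_reads = nrow(reads),
         cpm = total_n / nrow(reads) * 1e6)
}

#' Per-position base frequency matrix
#'
#' Base composition at each position from the 5' end of every read, up to
#' `max_pos`; the frequency at a position is normalized by the number of
#' reads covering that position.
#'
#' @param reads Read tibble or character vector.
#' @param max_pos Last position profiled (nt). Default 122.
#' @return A tibble of class `positional_freq` with columns `position`,
#'   `base` (A/C/G/T/N), `count`, `coverage`, `freq` (`NaN` where coverage
#'   is 0). At every covered position the five frequencies sum to 1.
#' @export
positional_frequency <- function(reads, max_pos = 122L) {
  max_pos <- check_count(max_pos, "max_pos", min = 1)
  reads <- as_read_tbl(reads)
  bases <- c("A", "C", "G", "T", "N")
  lens <- nchar(reads$seq)
  rows <- lapply(seq_len(max_pos), function(p) {
    at <- substr(reads$seq, p, p)
    at <- at[lens >= p]
    cnt <- unname(vapply(bases, function(b) sum(at == b), integer(1)))
    tibble(position = p, base = bases, count = cnt,
           coverage = length(at), freq = cnt / length(at))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("positional_freq", class(out)),
            total_reads = nrow(reads))
}

#' @describeIn positional_frequency Positional counts as a plain tibble.
#' @param x A `positional_freq`.
#' @param ... Unused.
#' @export
tidy.positional_freq <- function(x, ...) as_tibble(unclass(x))
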