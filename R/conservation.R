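#' Extract the upstream region of a genomic feature
#'
#' Strand-aware extraction of `length` nucleotides upstream of a feature —
#' the standard way to pull candidate non-coding RNA loci that sit just
#' 5' of the gene they partner. Feature coordinates are BED-convention:
#' 0-based half-open `[feature_start, feature_end)`. On the `+` strand the
#' upstream region is `[feature_start - length, feature_start)`; on the `-`
#' strand it is the reverse complement of `[feature_end, feature_end +
#' length)`. Regions running off the contig are truncated with a warning.
#'
#' @param genome A single contig sequence.
#' @param feature_start,feature_end 0-based half-open feature coordinates.
#' @param strand `"+"` or `"-"`.
#' @param length Upstream length (nt, >= 1). Default 300.
#' @return The upstream sequence (plus-strand orientation of the feature's
#'   own strand).
#' @export
#' @examples
#' extract_upstream("AAAACCCC", 4, 8, "+", length = 4)
extract_upstream <- function(genome, feature_start, feature_end, strand,
                             length = 300L) {
  genome <- normalize_seq(genome, "genome")
  length <- check_count(length, "length", min = 1)
  L <- nchar(genome)
  if (feature_start < 0 || feature_end > L || feature_start >= feature_end) {
    abort("Feature must lie within the genome with start < end (0-based half-open).")
  }
  if (!strand %in% c("+", "-")) abort("`strand` must be \"+\" or \"-\".")
  if (strand == "+") {
    lo <- feature_start - length
    if (lo < 0) {
      warn(sprintf("Upstream region truncated at the contig start (%d of %d nt available).",
                   feature_start, length))
      lo <- 0
    }
    if (lo == feature_start) return("")
    substr(genome, lo + 1, feature_start)
  } else {
    hi <- feature_end + length
    if (hi > L) {
      warn(sprintf("Upstream region truncated at the contig end (%d of %d nt available).",
                   L - feature_end, length))
      hi <- L
    }
    if (hi == feature_end) return("")
    revcomp(substr(genome, feature_end + 1, hi))
  }
}

#' Read a BED-like feature table
#'
#' Tab-separated, no header required beyond the standard BED order:
#' `chrom`, `start`, `end`, `name`, `score`, `strand` (0-based half-open
#' coordinates).
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  out <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(out) < 6) abort("BED-like input needs 6 columns (chrom, start, end, name, score, strand).")
  out <- out[, 1:6]
  names(out) <- cols
  out
}

#' Read an aligned FASTA into an alignment tibble
#'
#' @param path Aligned FASTA (gap character `-`).
#' @return Tibble `id`, `seq` (uppercased, U mapped to T, gaps kept); all
#'   rows equal width.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- chartr("U", "T", toupper(as.character(x)))
  bad <- which(!grepl("^[ACGTN-]+$", seqs))
  if (length(bad) > 0) {
    abort(sprintf("Alignment record %s contains characters outside A/C/G/T/N/-.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  aln <- tibble(id = sub("\\s.*$", "", names(x)), seq = unname(seqs))
  check_alignment(aln)
  aln
}

check_alignment <- function(aln) {
  if (!is.data.frame(aln) || !all(c("id", "seq") %in% names(aln))) {
    abort("An alignment is a data frame with `id` and `seq` columns.")
  }
  if (nrow(aln) == 0) abort("Alignment is empty.")
  if (length(unique(nchar(aln$seq))) != 1) {
    abort("All aligned sequences must have equal (gapped) length.")
  }
  invisible(aln)
}

#' Remove alignment columns where the reference has a gap
#'
#' Keeps exactly the columns in which the reference row is ungapped, so the
#' output column count equals the ungapped reference length and columns map
#' one-to-one onto reference positions. Idempotent.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param reference_id Id of the reference row.
#' @return The column-filtered alignment tibble.
#' @export
#' @examples
#' strip_reference_gaps(tibble::tibble(id = c("r", "o"), seq = c("A-C", "AGC")), "r")
strip_reference_gaps <- function(aln, reference_id) {
  check_alignment(aln)
  ref_row <- which(aln$id == reference_id)
  if (length(ref_row) != 1) {
    abort(sprintf("Reference id %s absent (or duplicated) in the alignment.",
                  dQuote(reference_id)))
  }
  ref_chars <- strsplit(aln$seq[ref_row], "", fixed = TRUE)[[1]]
  keep <- which(ref_chars != "-")
  aln$seq <- vapply(strsplit(aln$seq, "", fixed = TRUE),
                    function(ch) paste(ch[keep], collapse = ""), character(1))
  aln
}

#' Per-column conservation profile of an alignment
#'
#' For every column: frequencies of A/C/G/T over the non-gap, non-N symbols
#' in the column; the gap fraction (reported separately, following the
#' sequence-logo convention of excluding gaps from the frequency
#' denominator); and the information content `IC = 2 + sum(p * log2 p)`
#' bits, with `0 * log 0 = 0`. Columns with no A/C/G/T symbol are flagged
#' (`NA` frequencies, IC 0 by convention).
#'
#' @param aln Alignment tibble, typically [strip_reference_gaps()] output.
#' @return A tibble of class `conservation_profile`: `column`, `p_a`, `p_c`,
#'   `p_g`, `p_t`, `gap_frac`, `n_bases`, `consensus`, `consensus_freq`,
#'   `ic` (bits, in `[0, 2]`).
#' @export
column_profile <- function(aln) {
  check_alignment(aln)
  mat <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  ncols <- ncol(mat)
  counts <- vapply(bases, function(b) colSums(mat == b), numeric(ncols))
  if (ncols == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, bases))
  n_bases <- rowSums(counts)
  gap_frac <- colSums(mat == "-") / nrow(mat)
  p <- counts / ifelse(n_bases == 0, NA, n_bases)
  plogp <- ifelse(is.na(p) | p == 0, 0, p * log2(p))
  ic <- ifelse(n_bases == 0, 0, 2 + rowSums(plogp))
  top <- apply(p, 1, function(row) {
    if (all(is.na(row))) NA_integer_ else which.max(row)
  })
  out <- tibble(
    column = seq_len(ncols),
    p_a = p[, 1], p_c = p[, 2], p_g = p[, 3], p_t = p[, 4],
    gap_frac = gap_frac,
    n_bases = as.integer(n_bases),
    consensus = ifelse(is.na(top), NA_character_, bases[top]),
    consensus_freq = vapply(seq_len(ncols), function(i) {
      if (is.na(top[i])) NA_real_ else p[i, top[i]]
    }, numeric(1)),
    ic = pmin(pmax(ic, 0), 2)
  )
  base::structure(out, class = c("conservation_profile", class(out)),
                  n_sequences = nrow(aln))
}

#' @describeIn column_profile Profile as a plain tibble.
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @export
tidy.conservation_profile <- function(x, ...) as_tibble(unclass(x))

#' @describeIn column_profile One-row summary: columns, mean IC, fully
#'   conserved column count.
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(
    n_columns = nrow(x),
    n_sequences = attr(x, "n_sequences") %||% NA_integer_,
    mean_ic = mean(x$ic),
    n_full_ic = sum(x$ic >= 2 - 1e-12)
  )
}

#' Detect conserved tracts in a conservation profile
#'
#' Maximal runs of at least `min_len` consecutive columns whose top-base
#' frequency reaches `min_consensus` — the machine version of "these
#' adjacent residues are highly conserved across homologs". With
#' `rna = TRUE`, consensus letters report T as U.
#'
#' @param profile A [column_profile()] result.
#' @param min_consensus Minimum top-base frequency per column.
#' @param min_len Minimum tract length (columns).
#' @param rna Report consensus in RNA alphabet. Default `FALSE` (internal
#'   alphabet is DNA throughout; this maps display only).
#' @return Tibble `start`, `end` (1-based columns, inclusive), `length`,
#'   `consensus`.
#' @export
conserved_tracts <- function(profile, min_consensus = 0.95, min_len = 4L,
                             rna = FALSE) {
  min_len <- check_count(min_len, "min_len", min = 1)
  stopifnot(is.data.frame(profile),
            all(c("column", "consensus", "consensus_freq") %in% names(profile)))
  qualifies <- !is.na(profile$consensus_freq) &
    profile$consensus_freq >= min_consensus
  r <- rle(qualifies)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  out <- tibble(
    start = profile$column[starts[keep]],
    end = profile$column[ends[keep]],
    length = r$lengths[keep],
    consensus = vapply(keep, function(i) {
      cons <- paste(profile$consensus[starts[i]:ends[i]], collapse = "")
      if (rna) chartr("T", "U", cons) else cons
    }, character(1))
  )
  out
}

#' Write an alignment tibble as aligned FASTA
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  check_alignment(aln)
  x <- Biostrings::BStringSet(aln$seq)
  names(x) <- aln$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Recommended external MAFFT invocation
#'
#' The package profiles alignments but does not compute them; this returns
#' the standard external command for aligning extracted upstream regions
#' with the reference ncRNA.
#'
#' @param fasta_path Input FASTA of sequences to align.
#' @param out_path Output aligned FASTA.
#' @return The command string.
#' @export
mafft_command <- function(fasta_path, out_path = "aligned.fasta") {
  sprintf("mafft --auto %s > %s", fasta_path, out_path)
}
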