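#' Simulate a ncRNA homolog family with a conserved tract
#'
#' Generates `n_seqs` homologs of a reference non-coding RNA (stored as DNA;
#' display can map T to U) by i.i.d. substitution at `sub_rate` everywhere
#' except the `conserved_mask` positions, which are never mutated. This
#' emulates a family of DRT ncRNA orthologs sharing an invariant uracil
#' tract near the catalytic pocket. Optionally inserts extra alignment
#' columns (gap in the reference, random base in the homologs) so the
#' reference-gap-stripping step can be validated against the true column
#' map.
#'
#' @param reference Reference sequence; `NULL` generates a random 188-nt
#'   sequence whose `conserved_mask` positions are set to `T` (a uracil
#'   tract in RNA space).
#' @param n_seqs Number of homolog sequences (the reference is additionally
#'   included as the first alignment row).
#' @param sub_rate Per-position substitution probability outside the mask.
#' @param conserved_mask Integer positions (1-based, in the reference) that
#'   are never mutated. Default `124:127`, a four-uracil tract.
#' @param n_insert_cols Number of inserted alignment columns (gap in the
#'   reference row).
#' @param seed Integer seed.
#' @return A list of class `ncrna_family`:
#'   `alignment` (tibble `id`, `seq`, gapped, equal widths),
#'   `reference_id` (`"reference"`),
#'   `column_map` (integer per alignment column: reference position, or `NA`
#'   for inserted columns), and `params`.
#' @export
#' @examples
#' fam <- simulate_ncrna_family(n_seqs = 5, sub_rate = 0.2, seed = 1)
#' head(fam$alignment)
simulate_ncrna_family <- function(reference = NULL, n_seqs = 100L,
                                  sub_rate = 0.3,
                                  conserved_mask = 124:127,
                                  n_insert_cols = 0L,
                                  seed = NULL) {
  n_seqs <- check_count(n_seqs, "n_seqs", min = 1)
  check_probability(sub_rate, "sub_rate")
  n_insert_cols <- check_count(n_insert_cols, "n_insert_cols", min = 0)
  if (!is.null(seed)) withr::local_seed(seed)

  if (is.null(reference)) {
    if (length(conserved_mask) > 0 &&
        (any(conserved_mask < 1) || any(conserved_mask > 188))) {
      abort("`conserved_mask` positions must lie within the reference.")
    }
    ref_chars <- sample(c("A", "C", "G", "T"), 188, replace = TRUE)
    ref_chars[conserved_mask] <- "T"
    reference <- paste(ref_chars, collapse = "")
  }
  reference <- normalize_seq(reference, "reference")
  L <- nchar(reference)
  if (length(conserved_mask) > 0 &&
      (any(conserved_mask < 1) || any(conserved_mask > L))) {
    abort("`conserved_mask` positions must lie within the reference.")
  }

  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  mutable <- setdiff(seq_len(L), conserved_mask)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    ch <- ref_chars
    hit <- mutable[runif(length(mutable)) < sub_rate]
    if (length(hit) > 0) {
      cur <- match(ch[hit], bases)
      offset <- sample.int(3, length(hit), replace = TRUE)
      ch[hit] <- bases[(cur - 1L + offset) %% 4L + 1L]
    }
    paste(ch, collapse = "")
  }, character(1))

  ids <- c("reference", sprintf("homolog%03d", seq_len(n_seqs)))
  rows <- c(reference, seqs)
  column_map <- seq_len(L)

  if (n_insert_cols > 0) {
    # insertion slots between reference positions (including both ends)
    slot <- sort(sample.int(L + 1, n_insert_cols, replace = TRUE))
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out_cols <- vector("list", L + 1)
    for (j in seq_len(L + 1)) {
      k <- sum(slot == j)
      ins <- if (k > 0) {
        rbind(matrix("-", 1, k),
              matrix(sample(bases, k * n_seqs, replace = TRUE), n_seqs, k))
      } else NULL
      ref_col <- if (j <= L) mat[, j, drop = FALSE] else NULL
      out_cols[[j]] <- cbind(ins, ref_col)
    }
    full <- do.call(cbind, out_cols)
    map <- integer(0)
    for (j in seq_len(L + 1)) {
      map <- c(map, rep(NA_integer_, sum(slot == j)), if (j <= L) j)
    }
    rows <- apply(full, 1, paste, collapse = "")
    column_map <- map
  }

  structure(
    list(
      alignment = tibble(id = ids, seq = unname(rows)),
      reference_id = "reference",
      column_map = column_map,
      params = list(n_seqs = n_seqs, sub_rate = sub_rate,
                    conserved_mask = conserved_mask,
                    n_insert_cols = n_insert_cols,
                    reference = reference)
    ),
    class = "ncrna_family"
  )
}

#' @export
print.ncrna_family <- function(x, ...) {
  cat(sprintf(
    "<ncrna_family> %d homologs + reference, %d alignment columns, sub_rate = %g, %d masked positions\n",
    x$params$n_seqs, nchar(x$alignment$seq[1]), x$params$sub_rate,
    length(x$params$conserved_mask)
  ))
  invisible(x)
}
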