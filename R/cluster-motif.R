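#' Filter reads containing a poly(A) run
#'
#' Retains reads with at least one maximal A-run of length `min_run` or
#' more; the same run definition as [find_runs()] and
#' [homopolymer_spectrum()], so the retained count equals the spectrum's
#' A-at-threshold cell.
#'
#' @param reads Read tibble or character vector.
#' @param min_run Minimum qualifying A-run length (nt, >= 1). Default 10.
#' @return The qualifying subset of `reads`, input order preserved.
#' @export
filter_polya <- function(reads, min_run = 10L) {
  min_run <- check_count(min_run, "min_run", min = 1)
  reads <- as_read_tbl(reads)
  reads[max_run_length(reads$seq, "A") >= min_run, ]
}

#' Cluster reads by exact sequence identity
#'
#' Groups reads whose sequences are identical (full-length, exact); copy
#' counts conserve the input total. Clusters are ordered by descending copy
#' count, ties broken lexicographically by representative sequence.
#'
#' @param reads Read tibble or character vector.
#' @return A tibble of class `cluster_table` with columns `representative`,
#'   `n_copies`, `member_ids` (list column); attribute `total_reads`.
#' @export
#' @examples
#' cluster_identical(c("AAAA", "AAAA", "ACGT"))
cluster_identical <- function(reads) {
  reads <- as_read_tbl(reads)
  out <- reads |>
    dplyr::group_by(representative = .data$seq) |>
    dplyr::summarise(n_copies = dplyr::n(),
                     member_ids = list(.data$read_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_copies), .data$representative)
  structure(out, class = c("cluster_table", class(out)),
            total_reads = nrow(reads))
}

#' Retain clusters with at least a minimum copy number
#'
#' @param clusters A [cluster_identical()] table.
#' @param min_copies Minimum copies for retention (>= 1). Default 10,
#'   keeping only sequences observed as at least ten identical copies.
#' @return The retained subset, order preserved.
#' @export
retain_min_copies <- function(clusters, min_copies = 10L) {
  min_copies <- check_count(min_copies, "min_copies", min = 1)
  stopifnot(is.data.frame(clusters),
            all(c("representative", "n_copies") %in% names(clusters)))
  clusters[clusters$n_copies >= min_copies, ]
}

#' Export retained cluster representatives as motif-discovery input FASTA
#'
#' One record per representative, with ids of the form
#' `cluster{i}_n{count}` so copy numbers survive into downstream motif
#' tools. The recommended external MEME invocation (ZOOPS model, motif
#' width 35-40) is attached as an attribute and returned by
#' [meme_command()]; MEME itself is never executed.
#'
#' @param clusters A (typically [retain_min_copies()]-filtered) cluster
#'   table.
#' @param path Output FASTA path.
#' @return `path`, invisibly; warns (and writes an empty, valid file) when
#'   no clusters were retained.
#' @export
export_meme_fasta <- function(clusters, path) {
  stopifnot(is.data.frame(clusters),
            all(c("representative", "n_copies") %in% names(clusters)))
  if (anyDuplicated(clusters$representative)) {
    abort("Cluster representatives must be pairwise distinct.")
  }
  if (nrow(clusters) == 0) {
    warn("No clusters retained; writing an empty FASTA.")
    file.create(path)
    return(invisible(path))
  }
  ids <- sprintf("cluster%d_n%d", seq_len(nrow(clusters)), clusters$n_copies)
  write_fastx(tibble(read_id = ids, seq = clusters$representative), path,
              format = "fasta")
  invisible(path)
}

#' Recommended MEME Suite invocation for the exported FASTA
#'
#' Returns (and optionally logs) the external command line used for de novo
#' motif discovery on the exported representatives: ZOOPS model (zero or
#' one motif occurrence per sequence), motif width 35-40 bp, DNA alphabet.
#'
#' @param fasta_path Path of the exported FASTA.
#' @param minw,maxw Motif width range (bp).
#' @return The command string.
#' @export
meme_command <- function(fasta_path, minw = 35L, maxw = 40L) {
  sprintf("meme %s -dna -mod zoops -minw %d -maxw %d -oc meme_out",
          fasta_path, minw, maxw)
}

#' @export
print.cluster_table <- function(x, ...) {
  total <- attr(x, "total_reads") %||% sum(x$n_copies)
  cat(sprintf("<cluster_table> %d clusters over %d reads (largest: %d copies)\n",
              nrow(x), total, if (nrow(x) > 0) max(x$n_copies) else 0L))
  NextMethod()
}
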