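#' Read FASTA or FASTQ into a read tibble
#'
#' Format is auto-detected from the first non-empty character (`>` FASTA,
#' `@` FASTQ). Sequences are normalized (uppercase, U to T, strict
#' `{A,C,G,T,N}` alphabet); malformed records error with the offending
#' record index.
#'
#' @param path File path.
#' @return Tibble with columns `read_id`, `seq`, `qual` (`NA` for FASTA).
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- substr(trimws(readLines(path, n = 1)), 1, 1)
  if (length(first) == 0 || is.na(first)) {
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                abort(sprintf("Cannot auto-detect format of %s: first character %s",
                              path, dQuote(first))))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt,
                               with.qualities = (fmt == "fastq")),
    error = function(e) abort(sprintf("Malformed %s in %s: %s",
                                      toupper(fmt), path, conditionMessage(e)))
  )
  qual <- if (fmt == "fastq") {
    tryCatch(unname(as.character(S4Vectors::mcols(x)$qualities)),
             error = function(e) abort(sprintf("Malformed FASTQ in %s: %s",
                                               path, conditionMessage(e))))
  } else {
    rep(NA_character_, length(x))
  }
  seqs <- unname(as.character(x))
  if (fmt == "fastq") {
    mismatch <- which(nchar(qual) != nchar(seqs))
    if (length(mismatch) > 0) {
      abort(sprintf("FASTQ record %s: sequence/quality length mismatch.",
                    paste(head(mismatch, 5), collapse = ", ")))
    }
  }
  bad <- which(!grepl("^[ACGTNU]+$", toupper(seqs)))
  if (length(bad) > 0) {
    abort(sprintf("Record %s in %s contains characters outside A/C/G/T/N/U.",
                  paste(head(bad, 5), collapse = ", "), path))
  }
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = normalize_seq(seqs, "record"),
    qual = qual
  )
}

#' Write a read tibble as FASTA or FASTQ
#'
#' Round-trips with [read_fastx()] on id, sequence and quality.
#'
#' @param reads Read tibble (`read_id`, `seq`, optional `qual`) or character
#'   vector.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param wrap Line width for FASTA sequence lines (no wrapping for FASTQ).
#' @param qual_fill Optional single quality character used to fill missing
#'   qualities when writing FASTQ; without it, missing qualities error.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(reads, path, format = c("fasta", "fastq"),
                        wrap = 60L, qual_fill = NULL) {
  format <- match.arg(format)
  reads <- as_read_tbl(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = wrap)
  } else {
    qual <- reads$qual
    miss <- is.na(qual)
    if (any(miss)) {
      if (is.null(qual_fill)) {
        abort("FASTQ output requested but some records lack qualities; supply `qual_fill`.")
      }
      qual[miss] <- strrep(qual_fill, nchar(reads$seq[miss]))
    }
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

#' Read primary SAM records (minimal fields)
#'
#' Parses the text SAM fields needed for read triage: QNAME, FLAG, SEQ,
#' QUAL. Secondary (0x100) and supplementary (0x800) records are dropped so
#' every read appears once. Records whose FLAG has the reverse bit (0x10)
#' set are reverse-complemented back to original orientation (defensive;
#' aligners leave unmapped reads unreversed).
#'
#' @param path SAM file path (header optional).
#' @param unmapped_only If `TRUE`, return only records with the unmapped
#'   FLAG bit (0x4) set.
#' @return Read tibble with columns `read_id`, `seq`, `qual`, `flag`,
#'   `mapped`.
#' @export
read_sam <- function(path, unmapped_only = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), seq = character(),
                  qual = character(), flag = integer(), mapped = logical()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11)
  if (length(short) > 0) {
    abort(sprintf("SAM record %s has fewer than 11 fields.",
                  paste(head(short, 5), collapse = ", ")))
  }
  flag_chr <- vapply(fields, `[[`, character(1), 2)
  flag <- suppressWarnings(as.integer(flag_chr))
  if (anyNA(flag)) {
    abort(sprintf("SAM record %s has a non-integer FLAG field.",
                  paste(head(which(is.na(flag)), 5), collapse = ", ")))
  }
  keep <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  fields <- fields[keep]
  flag <- flag[keep]
  seq <- vapply(fields, `[[`, character(1), 10)
  qual <- vapply(fields, `[[`, character(1), 11)
  qual[qual == "*"] <- NA_character_
  seq <- normalize_seq(seq, "SAM record")
  rev <- bitwAnd(flag, 0x10) != 0
  if (any(rev)) {
    seq[rev] <- revcomp(seq[rev])
    qual[rev] <- vapply(strsplit(qual[rev], "", fixed = TRUE),
                        function(ch) paste(rev(ch), collapse = ""), character(1))
  }
  out <- tibble(
    read_id = vapply(fields, `[[`, character(1), 1),
    seq = seq, qual = qual, flag = flag,
    mapped = bitwAnd(flag, 0x4) == 0
  )
  if (unmapped_only) out[!out$mapped, ] else out
}

#' Extract unmapped reads from a SAM file
#'
#' Convenience wrapper around [read_sam()] returning exactly the primary
#' records whose FLAG has the unmapped bit (0x4) set.
#'
#' @inheritParams read_sam
#' @return Read tibble (`read_id`, `seq`, `qual`, `flag`, `mapped`).
#' @export
read_sam_unmapped <- function(path) read_sam(path, unmapped_only = TRUE)

#' Load a structure model from PDB or mmCIF
#'
#' Reads atomic coordinates via bio3d and reduces them to one representative
#' atom per residue: C-alpha for amino acids, P for nucleotides. Residues
#' lacking their representative atom are skipped with a warning. Chains are
#' keyed by author chain id.
#'
#' @param path `.pdb` or `.cif` file.
#' @return Structure tibble: `chain`, `resno`, `resname`, `x`, `y`, `z`,
#'   ordered by chain then residue number.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)),
    error = function(e) abort(sprintf("Cannot parse structure %s: %s",
                                      path, conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort(sprintf("No ATOM records in %s.", path))
  rep_atom <- at$elety %in% c("CA", "P")
  all_res <- unique(at[, c("chain", "resno")])
  sel <- at[rep_atom, , drop = FALSE]
  sel <- sel[!duplicated(sel[, c("chain", "resno")]), , drop = FALSE]
  n_missing <- nrow(all_res) - nrow(unique(sel[, c("chain", "resno")]))
  if (n_missing > 0) {
    warn(sprintf("%d residue(s) lack a representative atom (CA/P) and were skipped.",
                 n_missing))
  }
  if (nrow(sel) == 0) abort(sprintf("No CA/P representative atoms in %s.", path))
  out <- tibble(chain = sel$chain, resno = sel$resno, resname = sel$resid,
                x = sel$x, y = sel$y, z = sel$z)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort(sprintf("Non-finite coordinates in %s.", path))
  }
  dplyr::arrange(out, .data$chain, .data$resno)
}

#' Write a structure tibble as minimal mmCIF
#'
#' Emits a single-model `atom_site` loop with one pseudo-C-alpha per
#' residue, one author chain per unit; round-trips through
#' [read_structure()].
#'
#' @param structure Structure tibble (`chain`, `resno`, `resname`, `x`,
#'   `y`, `z`).
#' @param path Output `.cif` path.
#' @param data_name mmCIF data block name.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(structure, path, data_name = "synthetic_assembly") {
  req <- c("chain", "resno", "x", "y", "z")
  if (!all(req %in% names(structure))) {
    abort("`structure` must have columns chain, resno, x, y, z.")
  }
  resname <- if ("resname" %in% names(structure)) structure$resname else "ALA"
  n <- nrow(structure)
  header <- c(
    paste0("data_", data_name),
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.6f %.6f %.6f 1.00 0.00 ? %d %s %s CA 1",
    seq_len(n), resname, structure$chain, structure$resno,
    structure$x, structure$y, structure$z,
    structure$resno, resname, structure$chain
  )
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}
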