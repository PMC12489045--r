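test_that("upstream extraction is strand-aware with 0-based half-open features", {
  expect_equal(extract_upstream("AAAACCCC", 4, 8, "+", length = 4), "AAAA")
  # minus strand: downstream-in-plus-coordinates, reverse complemented
  expect_equal(extract_upstream("AAAACCCC", 0, 4, "-", length = 4), "GGGG")
  expect_warning(out <- extract_upstream("AAAACCCC", 4, 8, "-", length = 2),
                 "truncated")
  expect_equal(out, "")
  expect_warning(out2 <- extract_upstream("TTAAAACC", 4, 6, "+", length = 10),
                 "truncated")
  expect_equal(out2, "TTAA")
  expect_error(extract_upstream("ACGT", 2, 8, "+"), "within the genome")
  expect_error(extract_upstream("ACGT", 0, 2, "*"), "strand")
})

test_that("extraction is self-consistent under genome strand flip", {
  set.seed(7)
  for (i in 1:20) {
    g <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    s <- sample(50:120, 1); e <- s + sample(10:40, 1)
    len <- sample(5:40, 1)
    plus <- extract_upstream(g, s, e, "+", length = len)
    # mirroring the feature onto the reverse-complemented genome recovers
    # the same physical upstream sequence
    minus <- extract_upstream(revcomp(g), 200 - e, 200 - s, "-", length = len)
    expect_equal(minus, plus)
  }
})

test_that("reference-gap stripping keeps exactly the reference-ungapped columns", {
  aln <- tibble::tibble(id = c("ref", "other"), seq = c("A-C", "AGC"))
  out <- strip_reference_gaps(aln, "ref")
  expect_equal(out$seq, c("AC", "AC"))

  gapfree <- tibble::tibble(id = c("ref", "o"), seq = c("ACGT", "A-GT"))
  expect_equal(strip_reference_gaps(gapfree, "ref"), gapfree)

  # idempotent, and column count equals the ungapped reference length
  fam <- simulate_ncrna_family(n_seqs = 20, sub_rate = 0.2, n_insert_cols = 15,
                               seed = 3)
  stripped <- strip_reference_gaps(fam$alignment, fam$reference_id)
  expect_equal(nchar(stripped$seq[1]), 188)
  expect_equal(stripped$seq[1], fam$params$reference)
  expect_equal(strip_reference_gaps(stripped, "reference"), stripped)
  # the removed columns are exactly the inserted ones in the true column map
  expect_equal(which(is.na(fam$column_map)),
               which(strsplit(fam$alignment$seq[1], "")[[1]] == "-"))

  expect_error(strip_reference_gaps(aln, "missing"), "absent")
})

test_that("column profiles have closed-form information content endpoints", {
  aln <- tibble::tibble(id = c("a", "b", "c", "d"),
                        seq = c("AAG-", "ACG-", "AGGN", "ATG-"))
  prof <- column_profile(aln)
  expect_equal(prof$ic[1], 2)            # all A
  expect_equal(prof$p_a[1], 1)
  expect_equal(prof$ic[2], 0)            # uniform A/C/G/T
  expect_equal(prof$ic[3], 2)            # all G
  expect_equal(prof$ic[4], 0)            # no A/C/G/T symbol: flagged, IC 0
  expect_true(is.na(prof$consensus[4]))
  expect_equal(prof$gap_frac[4], 0.75)
  expect_true(all(prof$ic >= 0 & prof$ic <= 2))
})

test_that("simulated families recover per-column conservation rates", {
  fam <- simulate_ncrna_family(n_seqs = 100, sub_rate = 0.3, seed = 11)
  # profile homologs only: the included reference row would bias the rate
  aln <- fam$alignment[fam$alignment$id != "reference", ]
  prof <- column_profile(aln)
  masked <- fam$params$conserved_mask
  expect_equal(prof$consensus_freq[masked], rep(1, 4))
  expect_equal(prof$consensus[masked], rep("T", 4))
  # unmasked columns: the reference base survives at rate 1 - sub_rate
  ref_chars <- strsplit(fam$params$reference, "")[[1]]
  unmasked <- setdiff(seq_len(188), masked)
  match_rate <- mean(mapply(function(col, b) {
    prof[[paste0("p_", tolower(b))]][col]
  }, unmasked, ref_chars[unmasked]))
  se <- sqrt(0.3 * 0.7 / (100 * length(unmasked)))
  expect_lt(abs(match_rate - 0.7), 3 * se + 0.01)
  expect_true(all(prof$ic >= 0 & prof$ic <= 2 + 1e-12))
})

test_that("conserved tract detection finds the masked tract and only it", {
  fam <- simulate_ncrna_family(n_seqs = 100, sub_rate = 0.3, seed = 13)
  prof <- column_profile(strip_reference_gaps(fam$alignment, "reference"))
  tracts <- conserved_tracts(prof, min_consensus = 0.95, min_len = 4)
  expect_equal(nrow(tracts), 1)
  expect_equal(tracts$start, 124L)
  expect_equal(tracts$end, 127L)
  expect_equal(tracts$consensus, "TTTT")
  expect_equal(conserved_tracts(prof, min_consensus = 0.95, min_len = 4,
                                rna = TRUE)$consensus, "UUUU")

  # an impossible consensus threshold yields no tracts
  expect_equal(nrow(conserved_tracts(prof, min_consensus = 1.01, min_len = 1)), 0)

  # a uniform random alignment has no conserved tract at 0.9 consensus
  set.seed(17)
  rand <- tibble::tibble(id = paste0("s", 1:100),
                         seq = random_seqs(100, 60, seed = 19))
  rand_prof <- column_profile(rand)
  expect_equal(nrow(conserved_tracts(rand_prof, 0.9, 2)), 0)
})

test_that("sub_rate 0 or a full mask reproduce the reference exactly", {
  fam0 <- simulate_ncrna_family(n_seqs = 10, sub_rate = 0, seed = 23)
  expect_true(all(fam0$alignment$seq == fam0$params$reference))
  fam1 <- simulate_ncrna_family(n_seqs = 10, sub_rate = 1,
                                conserved_mask = 1:188, seed = 29)
  expect_true(all(fam1$alignment$seq == fam1$params$reference))
  expect_error(simulate_ncrna_family(n_seqs = 5, conserved_mask = 500),
               "within the reference")
})

test_that("alignment round-trips through aligned FASTA", {
  fam <- simulate_ncrna_family(n_seqs = 8, sub_rate = 0.2, n_insert_cols = 5,
                               seed = 31)
  path <- withr::local_tempfile(fileext = ".afa")
  write_alignment(fam$alignment, path)
  expect_equal(read_alignment(path), fam$alignment)
  expect_match(mafft_command("in.fa"), "mafft")
})
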