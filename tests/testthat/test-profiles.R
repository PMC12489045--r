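test_that("find_runs matches hand-worked examples", {
  expect_equal(find_runs("AAAAA", min_len = 5),
               tibble::tibble(base = "A", start = 1L, length = 5L))
  expect_equal(nrow(find_runs("ACGTN", min_len = 2)), 0)
  # N breaks runs and never forms one
  runs <- find_runs("AANAA", min_len = 1)
  expect_equal(runs$base, c("A", "A"))
  expect_equal(runs$start, c(1L, 4L))
  expect_error(find_runs("AAAA", min_len = 0), "min_len")
})

test_that("find_runs equals the quadratic brute-force enumerator on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    alphabet <- if (i %% 3 == 0) c("A", "C", "G", "T", "N", "N") else c("A", "C", "G", "T")
    s <- paste(sample(alphabet, 100, replace = TRUE), collapse = "")
    expect_equal(find_runs(s, min_len = 1), brute_force_runs(s, 1), info = s)
    expect_equal(find_runs(s, min_len = 3), brute_force_runs(s, 3), info = s)
  }
  # homopolymer-heavy cases
  for (s in c(strrep("A", 100), paste0(strrep("A", 50), strrep("T", 50)),
              paste0("N", strrep("G", 98), "N"))) {
    expect_equal(find_runs(s, min_len = 5), brute_force_runs(s, 5))
  }
})

test_that("spectrum counts each read once per cell and is monotone in threshold", {
  sp <- homopolymer_spectrum(c("AAAAA", "CCCCC"), thresholds = 5)
  d <- tidy(sp)
  expect_equal(d$percent[d$base == "A"], 50)
  expect_equal(d$percent[d$base == "C"], 50)
  expect_equal(d$percent[d$base %in% c("G", "T")], c(0, 0))

  # a 10xA read counts once in the >=5 cell and once in the >=10 cell
  sp2 <- tidy(homopolymer_spectrum("AAAAAAAAAA", thresholds = c(5, 10)))
  expect_equal(sp2$n_reads[sp2$base == "A"], c(1L, 1L))

  # monotone non-increasing along thresholds for every base, on simulated data
  fx <- fixture_reads(3000, seed = 31)
  d3 <- tidy(homopolymer_spectrum(fx$reads))
  by_base <- split(d3[order(d3$threshold), ], d3$base[order(d3$threshold)])
  for (b in by_base) expect_true(all(diff(b$percent) <= 0))

  expect_error(homopolymer_spectrum(character(0)), "at least one")
})

test_that("run-level counting can exceed read-level counting", {
  reads <- c("AAAAACAAAAA", "AAAAA")  # 3 qualifying runs in 2 reads
  by_read <- tidy(homopolymer_spectrum(reads, thresholds = 5))
  by_run <- tidy(homopolymer_spectrum(reads, thresholds = 5, count = "runs"))
  expect_equal(by_read$n_reads[by_read$base == "A"], 2L)
  expect_equal(by_run$n_reads[by_run$base == "A"], 3L)
})

test_that("poly-C tail trimming follows the window rule and is idempotent", {
  out <- trim_polyc_tail("ACGTACGTCCCCC", min_tail = 5, max_mismatch = 0)
  expect_equal(out$seq, "ACGTACGT")
  expect_equal(out$tail_removed, 5L)

  untouched <- trim_polyc_tail("ACGTACGT", min_tail = 5, max_mismatch = 0)
  expect_equal(untouched$seq, "ACGTACGT")
  expect_equal(untouched$tail_removed, 0L)

  # read not ending in C is never trimmed even with a long internal C run
  expect_equal(trim_polyc_tail("AACCCCCCCCAA")$seq, "AACCCCCCCCAA")

  # all-tail reads are dropped with a warning, not emptied
  expect_warning(dropped <- trim_polyc_tail("CCCCCCCC"), "all-tail")
  expect_equal(nrow(dropped), 0)

  # idempotence over simulated tailed reads
  reads <- simulate_product_read_set(1000, product_fraction = 1, p_tail = 0.8,
                                     mu_tail = 12, seed = 41)
  once <- suppressWarnings(trim_polyc_tail(reads))
  twice <- suppressWarnings(trim_polyc_tail(once[, c("read_id", "seq", "qual")]))
  expect_equal(twice$seq, once$seq)
  expect_true(all(twice$tail_removed == 0))

  # qualities stay aligned with sequences; with one mismatch allowed the
  # window crosses the T, with none it stops at the C run
  fq <- tibble::tibble(read_id = "r", seq = "ACGTCCCCC", qual = "ABCDEFGHI")
  tr <- trim_polyc_tail(fq)
  expect_equal(nchar(tr$qual), nchar(tr$seq))
  expect_equal(tr$seq, "ACG")
  expect_equal(tr$qual, "ABC")
  tr0 <- trim_polyc_tail(fq, max_mismatch = 0)
  expect_equal(tr0$seq, "ACGT")
  expect_equal(tr0$qual, "ABCD")
})

test_that("trimming reduces pooled C fraction on tailed sets and reports it", {
  reads <- simulate_product_read_set(2000, product_fraction = 1, p_tail = 0.6,
                                     mu_tail = 10, seed = 43)
  tr <- suppressWarnings(trim_polyc_tail(reads))
  rep <- trim_report(tr)
  c_before <- rep$composition_before$fraction[rep$composition_before$base == "C"]
  c_after <- rep$composition_after$fraction[rep$composition_after$base == "C"]
  expect_lt(c_after, c_before)
  expect_gte(rep$bases_removed, rep$reads_trimmed)  # each trim removes >= min_tail

  clean <- simulate_product_read_set(500, product_fraction = 1, p_tail = 0,
                                     sub_error_rate = 0, n_rate = 0, seed = 44)
  tr2 <- trim_polyc_tail(clean)
  expect_equal(tr2$seq, clean$seq)
  expect_equal(trim_report(tr2)$reads_trimmed, 0L)
})

test_that("5' trimming mirrors 3' trimming on reverse-complemented reads", {
  reads <- simulate_product_read_set(300, product_fraction = 1, p_tail = 0.7,
                                     mu_tail = 10, seed = 45)
  fwd <- suppressWarnings(trim_polyc_tail(reads))
  rc <- tibble::tibble(read_id = reads$read_id, seq = revcomp(reads$seq))
  back <- suppressWarnings(trim_polyc_tail(rc, end = "5p"))
  shared <- intersect(fwd$read_id, back$read_id)
  expect_equal(revcomp(back$seq[match(shared, back$read_id)]),
               fwd$seq[match(shared, fwd$read_id)])
})

test_that("pooled base composition sums to one and weighs bases, not reads", {
  comp <- base_composition(c("AC", "GT"))
  expect_equal(comp$fraction, rep(0.25, 5)[1:5] * c(1, 1, 1, 1, 0))
  expect_equal(sum(comp$fraction), 1)
  expect_equal(base_composition("AAAA")$fraction[1], 1)
  # pooled, not per-read averaged: ["A", "CCCC"] gives A = 1/5
  expect_equal(base_composition(c("A", "CCCC"))$fraction[1], 0.2)
  expect_error(base_composition(character(0)), "at least one")
})

test_that("N CPM uses a read-count denominator and is duplication-invariant", {
  reads <- c(rep("ACGT", 995), rep("NACGT", 5))
  expect_equal(n_count_cpm(reads)$cpm, 5000)
  expect_equal(n_count_cpm("ACGT")$cpm, 0)
  fx <- fixture_reads(500, seed = 51, n_rate = 0.01)
  once <- n_count_cpm(fx$reads)
  doubled <- n_count_cpm(rbind(fx$reads, fx$reads))
  expect_equal(doubled$cpm, once$cpm)
  expect_equal(doubled$total_n, 2L * once$total_n)
})

test_that("positional frequencies are 5'-anchored and sum to one where covered", {
  pf <- tidy(positional_frequency(rep("ACGT", 3), max_pos = 6))
  expect_equal(pf$freq[pf$position == 1 & pf$base == "A"], 1)
  expect_equal(pf$freq[pf$position == 4 & pf$base == "T"], 1)
  expect_equal(pf$coverage[pf$position == 5], rep(0L, 5))

  pf2 <- tidy(positional_frequency(c("AA", "AC"), max_pos = 2))
  expect_equal(pf2$freq[pf2$position == 2 & pf2$base == "A"], 0.5)
  expect_equal(pf2$freq[pf2$position == 2 & pf2$base == "C"], 0.5)

  fx <- fixture_reads(5000, seed = 53)
  d <- tidy(positional_frequency(fx$reads))
  covered <- d[d$coverage > 0, ]
  sums <- tapply(covered$freq, covered$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
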