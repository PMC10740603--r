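test_that("mismatch counting is positionwise and reports 1-based positions", {
  expect_equal(count_mismatches("ACGT", "ACGT"), list(count = 0L, positions = integer()))
  # reverse-primer 3' decamer vs blocker 5' decamer: the single host-specific
  # position, 7th base of the window
  cm <- count_mismatches("TCTTGATYRA", "TCTTGACTAA")
  expect_equal(cm$count, 1L)
  expect_equal(cm$positions, 7L)
  expect_equal(count_mismatches("NNNN", "GTCA")$count, 0L)
  expect_error(count_mismatches("ACGT", "ACG"), "length")
})

test_that("planted primer sites are found with sense-strand coordinates", {
  fwd <- fixture_pair()$forward
  fwd_exp <- expand_degenerate(fwd)[1]
  ref <- paste0("AAAA", fwd_exp, "AAAA")
  hits <- find_primer_sites(ref, fwd, max_mismatch = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5L) # planted at 0-based offset 4
  expect_equal(hits$end, 5L + nchar(fwd_exp) - 1L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  # the same site on the reverse-complemented reference appears as a - hit
  rc <- revcomp_iupac(ref)
  hits_rc <- find_primer_sites(rc, fwd, max_mismatch = 1)
  expect_equal(nrow(hits_rc), 1L)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$mismatches, 0L)
  expect_equal(hits_rc$start, nchar(ref) - hits$end + 1L)
  # a single-mismatch site disappears at max_mismatch = 0
  ref_mm <- ref
  substr(ref_mm, 10, 10) <- if (substr(ref_mm, 10, 10) == "A") "C" else "A"
  expect_equal(nrow(find_primer_sites(ref_mm, fwd, max_mismatch = 0)), 0L)
  expect_equal(nrow(find_primer_sites(ref_mm, fwd, max_mismatch = 1)), 1L)
  # reference shorter than the primer yields no sites, not an error
  expect_equal(nrow(find_primer_sites("ACGT", fwd)), 0L)
})

test_that("site search agrees with the naive oracle and is monotone in k", {
  set.seed(7)
  for (rep in 1:30) {
    seq <- random_seq(60)
    prm <- random_iupac_primer(10)
    mm_p <- oracle_mm_vector(seq, prm)
    mm_m <- oracle_mm_vector(seq, oracle_revcomp(prm))
    prev <- 0L
    for (k in 0:2) {
      hits <- find_primer_sites(seq, prm, max_mismatch = k)
      expect_identical(sort(hits$start[hits$strand == "+"]),
                       which(mm_p <= k))
      expect_identical(sort(hits$start[hits$strand == "-"]),
                       which(mm_m <= k))
      expect_gte(nrow(hits), prev) # monotone growth of the site set
      prev <- nrow(hits)
    }
  }
})

test_that("amplicon extraction pairs the best sites under length bounds", {
  pair <- fixture_pair()
  fwd_exp <- expand_degenerate(pair$forward)[1]
  rev_exp <- expand_degenerate(pair$reverse)[1]
  rc_rev <- revcomp_iupac(rev_exp)
  set.seed(3)
  insert <- random_seq(60)
  ref <- paste0("GG", fwd_exp, insert, rc_rev, "GG")
  db <- refdb("toy", ref, "Eukaryota;Test")
  amps <- extract_amplicons(db, pair, min_len = 50, max_len = 200, quiet = TRUE)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 20L + 60L + 18L) # both primer sites included
  expect_equal(amps$fwd_mm, 0L)
  expect_equal(amps$rev_mm, 0L)
  expect_equal(amps$start, 3L)
  expect_identical(amps$sequence, substr(ref, amps$start, amps$end))
  # a record in the opposite orientation yields the same amplicon sequence
  db_rc <- refdb("toy_rc", revcomp_iupac(ref), "Eukaryota;Test")
  amps_rc <- extract_amplicons(db_rc, pair, min_len = 50, max_len = 200,
                               quiet = TRUE)
  expect_identical(amps_rc$sequence, amps$sequence)
  expect_identical(amps_rc$strand, "-")
  # forward site alone gives no amplicon
  db_f <- refdb("fonly", paste0("GG", fwd_exp, insert), "Eukaryota;Test")
  expect_equal(nrow(extract_amplicons(db_f, pair, min_len = 50, max_len = 200,
                                      quiet = TRUE)), 0L)
  expect_identical(attr(extract_amplicons(db_f, pair, min_len = 50,
                                          max_len = 200, quiet = TRUE),
                        "skipped"), "fonly")
})

test_that("of two reverse sites only the in-range one is used", {
  pair <- fixture_pair()
  fwd_exp <- expand_degenerate(pair$forward)[1]
  rc_rev <- revcomp_iupac(expand_degenerate(pair$reverse)[1])
  set.seed(5)
  ref <- paste0(fwd_exp, random_seq(60), rc_rev, random_seq(300), rc_rev)
  db <- refdb("two_rev", ref, "Eukaryota;Test")
  amps <- extract_amplicons(db, pair, min_len = 50, max_len = 200, quiet = TRUE)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 98L) # the distal site would give ~416 nt
  # with a wide window the nearer (leftmost) compatible site still wins
  amps_wide <- extract_amplicons(db, pair, min_len = 50, max_len = 500,
                                 quiet = TRUE)
  expect_equal(amps_wide$length, 98L)
})

test_that("every extracted amplicon respects the length bounds (property)", {
  db <- simulate_refdb(sim_config(seed = 9, n_host = 10, n_non_target = 10,
                                  n_decoy = 3, n_metazoa = 2))
  amps <- extract_amplicons(db, fixture_pair(), quiet = TRUE)
  expect_true(all(amps$length >= 200 & amps$length <= 600))
  expect_identical(amps$length, nchar(amps$sequence))
})

test_that("amplicon FASTA/TSV sidecar round-trips the table", {
  db <- simulate_refdb(sim_config(seed = 2, n_host = 3, n_non_target = 3,
                                  n_decoy = 1, n_metazoa = 1,
                                  ancestor_len = 700, insert_len = 300,
                                  fwd_offset = 60))
  amps <- extract_amplicons(db, fixture_pair(), quiet = TRUE)
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_amplicons(amps, fa, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(amps))
  expect_identical(tab$ref_id, amps$ref_id)
  fasta_ids <- sub(" .*$", "", sub("^>", "", grep("^>", readLines(fa), value = TRUE)))
  expect_identical(fasta_ids, sprintf("%s/%d-%d", amps$ref_id, amps$start, amps$end))
})
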