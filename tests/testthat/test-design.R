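test_that("host consensus takes the majority base with deterministic ties", {
  blk <- terminal_block(host = c("AAAG", "AAAG", "ACAG", "AACG"), W = 4)
  cons <- host_consensus(blk)
  expect_identical(cons$consensus, "AAAG")
  expect_equal(cons$conservation, c(1, 0.75, 0.75, 1))
  # tie -> lexicographically smallest, flagged
  blk_tie <- terminal_block(host = c("AG", "CG"), W = 2)
  cons_tie <- host_consensus(blk_tie)
  expect_identical(substr(cons_tie$consensus, 1, 1), "A")
  expect_true(cons_tie$tie[1])
  expect_equal(cons_tie$conservation[1], 0.5)
  # identical rows: consensus equals the row, conservation 1 everywhere
  blk_id <- terminal_block(host = rep("ACGTT", 5), W = 5)
  expect_identical(host_consensus(blk_id)$consensus, "ACGTT")
  expect_true(all(host_consensus(blk_id)$conservation == 1))
  # gap-padded columns: all-gap -> gap consensus, conservation 0
  blk_gap <- terminal_block(host = c("ACG", "ACG"), W = 5)
  expect_identical(substr(host_consensus(blk_gap)$consensus, 1, 2), "--")
  expect_equal(host_consensus(blk_gap)$conservation[1:2], c(0, 0))
})

test_that("the published blocker overlaps the reverse primer by 10 bp", {
  ps <- snail_primer_set()
  expect_identical(
    compute_primer_overlap(ps$blocker_18SV4, ps$pair_18SV4$reverse,
                           max_mismatch = 1),
    10L
  )
  # every suffix/prefix alignment of this pair carries at least one
  # mismatch (the host-specific position), so a strict overlap is 0
  expect_identical(
    compute_primer_overlap(ps$blocker_18SV4, ps$pair_18SV4$reverse,
                           max_mismatch = 0),
    0L
  )
  expect_identical(compute_primer_overlap("ACGTACGT", "ACGTACGT", 0), 8L)
  expect_identical(compute_primer_overlap(strrep("G", 12),
                                          "ACTTTCGTTCTTGATYRA", 0), 0L)
})

test_that("overlap orientation is reverse-primer suffix vs blocker prefix", {
  # a blocker built from the reverse primer's 3' suffix overlaps fully in the
  # documented orientation but not with the roles swapped
  set.seed(77)
  rev <- "ACTTTCGTTCTTGATCAA"
  blocker <- paste0(substr(rev, 9, 18), random_seq(14))
  expect_gte(compute_primer_overlap(blocker, rev, 0), 10L)
  expect_lt(compute_primer_overlap(rev, blocker, 0), 10L)
})

test_that("enumeration recovers the planted conserved host window", {
  db <- simulate_refdb(sim_config(seed = 4, n_host = 30, n_non_target = 30,
                                  n_decoy = 3, n_metazoa = 3))
  pair <- fixture_pair()
  fit <- design_blocker(db, pair, "Heterobranchia", "Metazoa", quiet = TRUE)
  expect_gt(nrow(fit$candidates), 0)
  top <- fit$top$candidate
  # the top candidate is cut from the planted terminal region of the host
  # amplicons: its annealing site is a substring of every host amplicon
  site <- revcomp_iupac(top$sequence)
  expect_true(all(vapply(fit$host_amplicons$sequence,
                         function(a) grepl(site, a, fixed = TRUE), logical(1))))
  expect_equal(top$host_blocked, 1)
  expect_equal(top$off_target_blocked, 0)
  # every emitted candidate passes the independent validator
  expect_true(isTRUE(validate_candidates(fit$candidates, pair,
                                         fit$constraints, fit$tm)))
})

test_that("clonal hosts give conservation 1 and an impossible Tm window is empty", {
  db <- simulate_refdb(sim_config(seed = 6, n_host = 12, n_non_target = 12,
                                  n_decoy = 0, n_metazoa = 0, d_host = 0))
  pair <- fixture_pair()
  fit <- design_blocker(db, pair, "Heterobranchia", "Metazoa", quiet = TRUE)
  expect_true(all(fit$candidates$conservation == 1))
  # Wallace Tm of any ACGT oligo is even, the pair-mean reference is x.5:
  # a zero-width tolerance admits nothing and the diagnostics say why
  fit0 <- design_blocker(db, pair, "Heterobranchia", "Metazoa",
                         constraints = design_constraints(tm_tolerance = 0),
                         tm = tm_model("wallace"), quiet = TRUE)
  expect_equal(nrow(fit0$candidates), 0L)
  diag <- attr(fit0$candidates, "diagnostics")
  expect_gt(nrow(diag), 0)
  expect_true(any(diag$reason == "Tm outside tolerance"))
})

test_that("constraint constructor rejects inconsistent geometry", {
  expect_error(design_constraints(length_range = c(8, 6)))
  expect_error(design_constraints(length_range = c(8, 32),
                                  overlap_range = c(8, 12)))
  expect_silent(design_constraints())
})

test_that("synthesis notes carry the spacer and protocol metadata", {
  note <- annotate_synthesis(snail_primer_set()$blocker_18SV4)
  expect_true(note$spacer_C3)
  expect_identical(note$blocking_to_target_ratio, "1.5:1")
  expect_equal(note$final_concentration_uM, 1.2)
  expect_match(note$order_string, "/3SpC3/")
})
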