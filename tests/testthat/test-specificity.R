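make_amps <- function(seqs, lineages = NULL, prefix = "a") {
  n <- length(seqs)
  if (is.null(lineages)) lineages <- rep("Eukaryota;SAR;Alveolata", n)
  structure(
    data.frame(ref_id = paste0(prefix, seq_len(n)), lineage = lineages,
               start = 1L, end = nchar(seqs), strand = "+",
               length = nchar(seqs), fwd_mm = 0L, rev_mm = 0L,
               sequence = seqs, stringsAsFactors = FALSE),
    class = c("amplicon_set", "data.frame")
  )
}

test_that("block calls match the annealing-site construction", {
  set.seed(19)
  blocker <- random_seq(16)
  site <- revcomp_iupac(blocker) # the blocker's footprint on the amplicon
  amp <- paste0(random_seq(40), site, random_seq(10))
  expect_true(is_blocked(amp, blocker, k_block = 0))
  # three substitutions planted inside the footprint (site spans 41..56)
  mutated <- amp
  for (p in 40 + c(3, 8, 14)) {
    old <- substr(mutated, p, p)
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_false(is_blocked(mutated, blocker, k_block = 2))
  expect_true(is_blocked(mutated, blocker, k_block = 3))
  # blocker longer than the amplicon: skipped, not an error
  expect_message(res <- is_blocked("ACGTACGT", blocker), "skipped")
  expect_false(res)
})

test_that("block calls agree with the naive oracle and grow with k (property)", {
  set.seed(23)
  bad <- 0L
  for (i in 1:40) {
    blocker <- random_seq(10)
    amp <- random_seq(60)
    prev <- FALSE
    for (k in 0:2) {
      mine <- is_blocked(amp, blocker, k_block = k)
      if (!identical(mine, oracle_blocked(amp, blocker, k))) bad <- bad + 1L
      if (prev && !mine) bad <- bad + 1L # monotonicity in k
      prev <- mine
    }
  }
  expect_identical(bad, 0L)
})

test_that("specificity fractions and the clade breakdown are exact", {
  set.seed(29)
  blocker <- random_seq(14)
  site <- revcomp_iupac(blocker)
  hit <- function() paste0(random_seq(30), site, random_seq(6))
  miss <- function() random_seq(50)
  hosts <- make_amps(c(hit(), hit(), hit(), miss()), prefix = "h")
  # 200 non-targets, one planted holozoan hit
  nt_seqs <- c(hit(), replicate(199, miss()))
  nt_lin <- c("Eukaryota;Opisthokonta;Holozoa;Ichthyosporea",
              rep("Eukaryota;SAR;Alveolata;Ciliophora", 199))
  nts <- make_amps(nt_seqs, nt_lin, prefix = "nt")
  rep <- evaluate_specificity(blocker, hosts, nts, k_block = 0, clade_depth = 3)
  expect_equal(rep$host$fraction, 0.75)
  expect_equal(rep$non_target$fraction, 0.005)
  expect_identical(rep$blocked_ids, "nt1")
  expect_identical(rep$clade_table$clade, "Holozoa")
  expect_equal(rep$clade_table$n_blocked, 1L)
  # brute-force identity and exact partition of the blocked set
  expect_equal(rep$host$n_blocked, sum(is_blocked(hosts, blocker, 0)))
  expect_equal(sum(rep$clade_table$n_blocked), rep$non_target$n_blocked)
  expect_error(evaluate_specificity(blocker, hosts[0, ], nts), "host")
  expect_error(evaluate_specificity(blocker, hosts, nts[0, ]), "non-target")
})

test_that("an all-N blocker blocks everything under the subset rule", {
  set.seed(31)
  hosts <- make_amps(replicate(4, random_seq(50)), prefix = "h")
  nts <- make_amps(replicate(5, random_seq(50)), prefix = "n")
  rep <- evaluate_specificity(strrep("N", 20), hosts, nts, k_block = 0)
  expect_equal(rep$host$fraction, 1)
  expect_equal(rep$non_target$fraction, 1)
})

test_that("read-partition summaries normalize per sample", {
  counts <- data.frame(sample = c("s1", "s2"),
                       host_reads = c(100L, 100L),
                       microeuk_reads = c(100L, 100L),
                       other_reads = c(0L, 0L))
  res <- coamplification_summary(counts)
  expect_equal(unlist(res$per_sample[1, -1], use.names = FALSE), c(0.5, 0.5, 0))
  expect_equal(res$summary$sd, c(0, 0, 0)) # identical samples
  expect_equal(rowSums(res$per_sample[, -1]), c(1, 1), ignore_attr = TRUE)
  counts$host_reads[2] <- 0L
  counts$microeuk_reads[2] <- 0L
  counts$other_reads[2] <- 0L
  expect_error(coamplification_summary(counts), "s2")
  # mean/sd across unequal samples (n-1 denominator)
  c2 <- data.frame(sample = c("a", "b"), host_reads = c(80L, 20L),
                   microeuk_reads = c(20L, 80L), other_reads = c(0L, 0L))
  r2 <- coamplification_summary(c2)
  expect_equal(r2$summary$mean[1:2], c(0.5, 0.5))
  expect_equal(r2$summary$sd[1], sd(c(0.8, 0.2)))
})
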