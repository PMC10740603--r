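write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("reading normalizes RNA/case and parses Silva lineages", {
  f <- write_tmp_fasta(c(">X1 Eukaryota;Mollusca;Heterobranchia", "ACGU"))
  db <- read_fasta_taxonomy(f)
  expect_equal(nrow(db), 1L)
  expect_identical(db$sequence, "ACGT")
  expect_identical(split_lineage(db$lineage)[[1]],
                   c("Eukaryota", "Mollusca", "Heterobranchia"))
  # tab-separated header and lowercase sequence
  f2 <- write_tmp_fasta(c(">X2\tEukaryota;SAR", "acgtu"))
  expect_identical(read_fasta_taxonomy(f2)$sequence, "ACGTT")
  # plain dialect: no lineage
  expect_identical(read_fasta_taxonomy(f, dialect = "plain")$lineage, "")
})

test_that("reader enforces the FASTA and uniqueness contracts", {
  f_empty <- tempfile(fileext = ".fasta")
  file.create(f_empty)
  expect_equal(nrow(read_fasta_taxonomy(f_empty)), 0L)
  f_bad <- write_tmp_fasta(c("ACGT", ">x1 A;B", "ACGT"))
  expect_error(read_fasta_taxonomy(f_bad), "line 1")
  f_dup <- write_tmp_fasta(c(">x1 A;B", "ACGT", ">x1 C;D", "GGCC"))
  expect_error(read_fasta_taxonomy(f_dup), "duplicate")
  f_alien <- write_tmp_fasta(c(">x1 A;B", "ACXT"))
  expect_error(read_fasta_taxonomy(f_alien), "non-IUPAC")
})

test_that("write/read round-trip preserves id, sequence and lineage", {
  set.seed(11)
  db <- refdb(
    id = sprintf("R%02d", 1:8),
    sequence = replicate(8, random_seq(sample(30:80, 1))),
    lineage = rep(c("Eukaryota;Opisthokonta;Metazoa;Mollusca;Heterobranchia",
                    "Eukaryota;SAR;Alveolata", "", "Bacteria;Proteobacteria"), 2)
  )
  f <- tempfile(fileext = ".fasta")
  write_fasta_taxonomy(db, f)
  back <- read_fasta_taxonomy(f)
  expect_identical(back$id, db$id)
  expect_identical(back$sequence, db$sequence)
  expect_identical(back$lineage, db$lineage)
})

test_that("partitioning routes host, excluded and non-target records", {
  db <- refdb(
    id = c("snail", "fly", "ciliate"),
    sequence = c("ACGT", "ACGT", "ACGT"),
    lineage = c("Eukaryota;Metazoa;Mollusca;Heterobranchia",
                "Eukaryota;Metazoa;Arthropoda",
                "Eukaryota;Alveolata;Ciliophora")
  )
  parts <- partition_by_taxonomy(db, "Heterobranchia", "Metazoa")
  expect_identical(parts$host$id, "snail")       # host wins over exclusion
  expect_identical(parts$excluded$id, "fly")
  expect_identical(parts$non_target$id, "ciliate")
  # case-insensitive, exact whole-rank matching (no substring hits)
  parts2 <- partition_by_taxonomy(db, "heterobranchia", "metazoa")
  expect_identical(parts2$host$id, "snail")
  db_sub <- refdb("x", "ACGT", "Eukaryota;Metazoan-like")
  expect_warning(p3 <- partition_by_taxonomy(db_sub, "Heterobranchia", "Metazoa"),
                 "not found")
  expect_identical(p3$non_target$id, "x")
  # empty database partitions into three empty sets
  p0 <- partition_by_taxonomy(refdb(), "Heterobranchia", "Metazoa")
  expect_equal(vapply(p0, nrow, integer(1)), c(host = 0L, non_target = 0L,
                                               excluded = 0L))
})

test_that("partition is exact for random databases (property)", {
  set.seed(42)
  clades <- c("Heterobranchia", "Metazoa", "Alveolata", "Fungi", "Holozoa")
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    lineages <- vapply(seq_len(n), function(i) {
      paste(c("Eukaryota", sample(clades, sample(1:4, 1))), collapse = ";")
    }, character(1))
    db <- refdb(sprintf("r%03d", seq_len(n)),
                vapply(seq_len(n), function(i) random_seq(20), character(1)),
                lineages)
    host <- sample(clades, 1)
    excl <- sample(clades, sample(0:2, 1))
    parts <- suppressWarnings(partition_by_taxonomy(db, host, excl))
    ids <- sort(unlist(lapply(parts, `[[`, "id"), use.names = FALSE))
    expect_identical(ids, sort(db$id))                       # union is exact
    expect_equal(sum(vapply(parts, nrow, integer(1))), n)    # disjoint
  }
})

test_that("clade subsetting preserves order and handles absent clades", {
  db <- refdb(c("a", "b", "c"), c("ACGT", "ACGT", "ACGT"),
              c("Eukaryota;Biomphalaria", "Eukaryota;SAR",
                "Eukaryota;Mollusca;Biomphalaria"))
  expect_identical(subset_to_clade(db, "Biomphalaria")$id, c("a", "c"))
  expect_identical(subset_to_clade(db, "Eukaryota")$id, db$id)
  expect_equal(nrow(subset_to_clade(db, "Bacteria")), 0L)
})

test_that("partition TSV export lists every record with its label", {
  db <- refdb(c("a", "b"), c("ACGT", "ACGT"),
              c("Eukaryota;Heterobranchia", "Eukaryota;SAR"))
  parts <- partition_by_taxonomy(db, "Heterobranchia", "Metazoa")
  f <- tempfile(fileext = ".tsv")
  export_partition_tsv(parts, f)
  tab <- read.delim(f)
  expect_setequal(tab$id, db$id)
  expect_identical(tab$partition[tab$id == "a"], "host")
})
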