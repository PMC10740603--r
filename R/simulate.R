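# Seeded simulator of Silva-like reference databases with controlled
# structure: a conserved-ancestor host clade sharing the primer sites and a
# conserved 3'-terminal design region, divergent non-target lineages,
# metazoan bystanders, and decoys lacking primer sites.

# The host-conserved 22-nt design region planted immediately upstream of the
# reverse-primer site (sense strand). It is a synthetic stand-in for the
# AT-rich 3' flank of the snail 18S V4 amplicon: the reverse complement of
# the published blocker's 3' 18-mer plus 4 pad bases, so a simulated
# database always contains a designable window with primer-compatible Tm
# (as the real system does).
DEFAULT_TERMINAL_TAIL <- "AATTTTGTCAAGAATGTTTTCA"

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulation configuration
#'
#' Defaults emulate the study conditions this package is tested under: a
#' nearly clonal host clade (0.005 substitutions/site), strongly divergent
#' non-target lineages (0.15 substitutions/site), conserved primer sites, a
#' host-conserved 3'-terminal design region, and one fixed host-specific
#' transition at the 4th position from the reverse primer's 3' end -- the
#' "one mismatch" that distinguishes the host clade from the universal
#' primer.
#'
#' @param seed RNG seed; the same seed yields a byte-identical database.
#' @param n_host,n_non_target,n_decoy,n_metazoa record counts per set.
#' @param ancestor_len length of the ancestral sequence (nt).
#' @param insert_len length between the two primer-binding sites (nt).
#' @param fwd_offset 0-based offset of the forward-primer site.
#' @param d_host,d_nt per-site substitution divergence of host and
#'   non-target records (`[0, 1)`).
#' @param conserve_terminal keep the last `terminal_len` nt of the host
#'   amplicon free of substitutions.
#' @param terminal_len length of the conserved 3'-terminal region (nt).
#' @param host_site_variant plant the fixed host transition in the
#'   reverse-primer site of every host record.
#' @param site_mismatch_rate per-host-record probability of one additional
#'   random substitution inside a primer site.
#' @param conserve_nt_primer_sites keep non-target (and metazoan) primer
#'   sites substitution-free so they amplify.
#' @param host_lineage,metazoa_lineage,decoy_lineage taxonomy templates.
#' @param non_target_lineages recycled over non-target records.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L, n_host = 100L, n_non_target = 100L,
                       n_decoy = 10L, n_metazoa = 5L,
                       ancestor_len = 1800L, insert_len = 330L,
                       fwd_offset = 400L,
                       d_host = 0.005, d_nt = 0.15,
                       conserve_terminal = TRUE, terminal_len = 40L,
                       host_site_variant = TRUE, site_mismatch_rate = 0,
                       conserve_nt_primer_sites = TRUE,
                       host_lineage = "Eukaryota;Opisthokonta;Metazoa;Mollusca;Heterobranchia;Biomphalaria",
                       non_target_lineages = c(
                         "Eukaryota;SAR;Alveolata;Ciliophora;Tetrahymena",
                         "Eukaryota;Opisthokonta;Holozoa;Ichthyosporea;Sphaeroforma",
                         "Eukaryota;Archaeplastida;Chloroplastida;Embryophyceae;Lactuca",
                         "Eukaryota;Amoebozoa;Lobosa;Tubulinea;Arcella"),
                       metazoa_lineage = "Eukaryota;Opisthokonta;Metazoa;Arthropoda;Drosophila",
                       decoy_lineage = "Eukaryota;Opisthokonta;Nucletmycea;Fungi;Saccharomyces") {
  stopifnot(d_host >= 0, d_host < 1, d_nt >= 0, d_nt < 1,
            n_host >= 0, n_non_target >= 0, n_decoy >= 0, n_metazoa >= 0,
            site_mismatch_rate >= 0, site_mismatch_rate <= 1,
            terminal_len >= 1, insert_len >= 1, fwd_offset >= 0)
  structure(as.list(environment()), class = "sim_config")
}

mutate_chars <- function(chars, rate, protect) {
  if (rate <= 0) return(list(chars = chars, positions = integer()))
  eligible <- setdiff(which(chars %in% BASES), protect)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  if (length(hit)) {
    alt <- matrix(c("C", "G", "T",  "A", "G", "T",  "A", "C", "T",  "A", "C", "G"),
                  nrow = 3, dimnames = list(NULL, BASES))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- alt[cbind(pick, match(chars[hit], BASES))]
  }
  list(chars = chars, positions = hit)
}

#' Simulate a Silva-like reference database
#'
#' An ancestor is drawn uniformly over ACGT with one fixed concrete
#' expansion of each primer site embedded at fixed offsets and the fixed
#' design tail planted upstream of the reverse-primer site. Host records
#' substitute at `d_host` outside the primer sites (and outside the
#' 3'-terminal region when conserved) and carry the host-specific primer
#' variant; non-target and metazoan records substitute at `d_nt` outside
#' the primer sites; decoys are unrelated random sequences without primer
#' sites. Deterministic under `config$seed`.
#'
#' @param config a [sim_config].
#' @param pair the amplification [primer_pair] (default: the bundled 18S V4
#'   pair).
#' @return A [refdb] with a `truth` attribute (data frame: `id`, `set`,
#'   `n_substitutions`, `injected_site_positions`) and a `sim_info`
#'   attribute describing the planted geometry.
#' @export
simulate_refdb <- function(config, pair = snail_primer_set()$pair_18SV4) {
  stopifnot(inherits(config, "sim_config"), inherits(pair, "primer_pair"))
  fwd_concrete <- expand_degenerate(pair$forward)[1]
  rev_concrete <- expand_degenerate(pair$reverse)[1]
  m_f <- nchar(fwd_concrete)
  m_r <- nchar(rev_concrete)
  amp_len <- m_f + config$insert_len + m_r
  need <- config$fwd_offset + amp_len + 20L
  if (config$ancestor_len < need) {
    stop("ancestor_len = ", config$ancestor_len, " too short to hold both ",
         "primer sites plus the configured insert (need >= ", need, ")")
  }
  set.seed(config$seed)

  # sense-strand coordinates of the planted geometry (1-based)
  f_start <- config$fwd_offset + 1L
  f_end <- f_start + m_f - 1L
  r_start <- f_end + config$insert_len + 1L
  r_end <- r_start + m_r - 1L
  amp_start <- f_start
  amp_end <- r_end

  ancestor <- sample(BASES, config$ancestor_len, replace = TRUE)
  ancestor[f_start:f_end] <- strsplit(fwd_concrete, "")[[1]]
  rev_site_sense <- strsplit(revcomp_iupac(rev_concrete), "")[[1]]
  ancestor[r_start:r_end] <- rev_site_sense
  tail_chars <- strsplit(DEFAULT_TERMINAL_TAIL, "")[[1]]
  tail_len <- length(tail_chars)
  ancestor[(r_start - tail_len):(r_start - 1L)] <- tail_chars

  # host variant: a transition at the 4th position from the reverse
  # primer's 3' end, i.e. a genuine mismatch against the primer symbol there
  variant_primer_pos <- m_r - 3L
  base_at <- substr(rev_concrete, variant_primer_pos, variant_primer_pos)
  var_base <- TRANSITION[[base_at]]
  psym <- substr(pair$reverse$sequence, variant_primer_pos, variant_primer_pos)
  if (iupac_match(psym, var_base)) {
    var_base <- setdiff(BASES, iupac_bases(psym))[1]
  }
  rev_concrete_host <- rev_concrete
  substr(rev_concrete_host, variant_primer_pos, variant_primer_pos) <- var_base
  rev_site_sense_host <- strsplit(revcomp_iupac(rev_concrete_host), "")[[1]]

  site_idx <- c(f_start:f_end, r_start:r_end)
  terminal_idx <- (amp_end - config$terminal_len + 1L):amp_end

  ids <- character()
  seqs <- character()
  lineages <- character()
  sets <- character()
  nsub <- integer()
  injected <- character()
  add_record <- function(id, chars, lineage, set, positions, inj = integer()) {
    ids <<- c(ids, id)
    seqs <<- c(seqs, paste(chars, collapse = ""))
    lineages <<- c(lineages, lineage)
    sets <<- c(sets, set)
    nsub <<- c(nsub, length(positions))
    injected <<- c(injected, paste(inj, collapse = ";"))
  }

  for (i in seq_len(config$n_host)) {
    chars <- ancestor
    if (config$host_site_variant) chars[r_start:r_end] <- rev_site_sense_host
    protect <- if (config$conserve_terminal) c(site_idx, terminal_idx) else site_idx
    mut <- mutate_chars(chars, config$d_host, protect)
    chars <- mut$chars
    inj <- integer()
    if (config$site_mismatch_rate > 0 &&
        stats::runif(1) < config$site_mismatch_rate) {
      pos <- sample(site_idx, 1L)
      chars[pos] <- sample(setdiff(BASES, chars[pos]), 1L)
      inj <- pos
    }
    add_record(sprintf("HOST_%04d", i), chars, config$host_lineage, "host",
               mut$positions, inj)
  }
  for (i in seq_len(config$n_metazoa)) {
    protect <- if (config$conserve_nt_primer_sites) site_idx else integer()
    mut <- mutate_chars(ancestor, config$d_nt, protect)
    add_record(sprintf("MET_%04d", i), mut$chars, config$metazoa_lineage,
               "metazoa", mut$positions)
  }
  for (i in seq_len(config$n_non_target)) {
    protect <- if (config$conserve_nt_primer_sites) site_idx else integer()
    mut <- mutate_chars(ancestor, config$d_nt, protect)
    lin <- config$non_target_lineages[((i - 1L) %% length(config$non_target_lineages)) + 1L]
    add_record(sprintf("NT_%04d", i), mut$chars, lin, "non_target",
               mut$positions)
  }
  for (i in seq_len(config$n_decoy)) {
    chars <- sample(BASES, config$ancestor_len, replace = TRUE)
    add_record(sprintf("DECOY_%04d", i), chars, config$decoy_lineage, "decoy",
               integer())
  }

  db <- refdb(id = ids, sequence = seqs, lineage = lineages,
              source_label = sprintf("simulated (seed %d)", config$seed))
  attr(db, "truth") <- data.frame(id = ids, set = sets,
                                  n_substitutions = nsub,
                                  injected_site_positions = injected,
                                  stringsAsFactors = FALSE)
  attr(db, "sim_info") <- list(
    fwd_concrete = fwd_concrete, rev_concrete = rev_concrete,
    rev_concrete_host = rev_concrete_host,
    variant_primer_pos = variant_primer_pos,
    amp_start = amp_start, amp_end = amp_end, amp_len = amp_len,
    terminal_tail = DEFAULT_TERMINAL_TAIL, config = config
  )
  db
}

#' Write the simulation truth table as TSV
#'
#' @param db a simulated [refdb] (carrying a `truth` attribute).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(db, path) {
  truth <- attr(db, "truth")
  if (is.null(truth)) stop("refdb carries no simulation truth table")
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Small bundled snail fixture
#'
#' A deterministic miniature database (simulated with a fixed internal
#' seed), the published 18S V4 primer pair, and the published 28-nt blocking
#' oligo, for quick examples and overlap/Tm/length checks.
#'
#' @return A list with `db` ([refdb]), `pair` ([primer_pair]) and `blocker`
#'   ([primer]).
#' @export
snail_fixture <- function() {
  ps <- snail_primer_set()
  cfg <- sim_config(seed = 20L, n_host = 6L, n_non_target = 9L, n_decoy = 2L,
                    n_metazoa = 2L, ancestor_len = 700L, insert_len = 300L,
                    fwd_offset = 80L)
  list(db = simulate_refdb(cfg, ps$pair_18SV4),
       pair = ps$pair_18SV4, blocker = ps$blocker_18SV4)
}
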