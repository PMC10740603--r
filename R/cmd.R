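# Command-style orchestration of the pipeline stages. Each cmd_*() function
# is a thin, reproducible wrapper over the package functions: it resolves a
# declarative configuration (defaults < config file < arguments), runs one
# stage, writes plain-text outputs into a directory, and echoes the fully
# resolved configuration next to them. A dispatcher script for shell use is
# installed under `system.file("scripts", "hostblockr", package = "hostblockr")`.

default_run_config <- function() {
  list(
    forward_primer = "CCAGCASCYGCGGTAATTCC",
    reverse_primer = "ACTTTCGTTCTTGATYRA",
    marker = "18SV4",
    max_mismatch = 1L, min_len = 200L, max_len = 600L,
    W = 40L, entropy_base = 2,
    host_clade = "Heterobranchia", exclude_clades = "Metazoa",
    design_clade = NULL,
    length_min = 24L, length_max = 32L, overlap_min = 8L, overlap_max = 12L,
    tm_tolerance = 3, tm_reference = "pair_mean", min_conservation = 0.90,
    lambda = 10, off_target_ceiling = 0.01, overlap_max_mismatch = 1L,
    k_block = 0L, clade_depth = 3L, both_orientations = FALSE,
    tm_method = "nearest_neighbor", Na_mM = 50, primer_uM = 0.25,
    expand_cap = 64L,
    seed = 1L
  )
}

#' Resolve a run configuration
#'
#' Starts from the package defaults, overlays a YAML config file (if any),
#' then overlays explicit arguments. Unknown keys are rejected so typos do
#' not silently fall back to defaults.
#'
#' @param config_file optional YAML file of key-value overrides.
#' @param overrides named list of final overrides.
#' @return The resolved configuration (named list).
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  cfg <- default_run_config()
  apply_over <- function(cfg, new, origin) {
    unknown <- setdiff(names(new), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(new)] <- new
    cfg
  }
  if (!is.null(config_file)) {
    cfg <- apply_over(cfg, yaml::read_yaml(config_file), config_file)
  }
  apply_over(cfg, overrides, "arguments")
}

config_pair <- function(cfg) {
  primer_pair(primer(paste0(cfg$marker, "-F"), cfg$forward_primer, "forward"),
              primer(paste0(cfg$marker, "-R"), cfg$reverse_primer, "reverse"),
              marker_name = cfg$marker)
}

config_constraints <- function(cfg) {
  design_constraints(
    length_range = c(cfg$length_min, cfg$length_max),
    overlap_range = c(cfg$overlap_min, cfg$overlap_max),
    tm_tolerance = cfg$tm_tolerance, tm_reference = cfg$tm_reference,
    min_conservation = cfg$min_conservation, k_block = cfg$k_block,
    off_target_ceiling = cfg$off_target_ceiling, lambda = cfg$lambda,
    overlap_max_mismatch = cfg$overlap_max_mismatch
  )
}

config_tm_model <- function(cfg) {
  tm_model(method = cfg$tm_method, Na_mM = cfg$Na_mM,
           primer_uM = cfg$primer_uM, expand_cap = cfg$expand_cap)
}

echo_config <- function(cfg, out_dir) {
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))
}

prep_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

read_db_checked <- function(db_fasta) {
  db <- read_fasta_taxonomy(db_fasta)
  if (!nrow(db)) stop("no records in '", db_fasta, "'")
  db
}

partition_and_extract <- function(db, cfg) {
  pair <- config_pair(cfg)
  parts <- partition_by_taxonomy(db, cfg$host_clade, cfg$exclude_clades)
  host_db <- if (!is.null(cfg$design_clade)) {
    subset_to_clade(parts$host, cfg$design_clade)
  } else parts$host
  list(
    pair = pair, parts = parts,
    host = extract_amplicons(host_db, pair, cfg$max_mismatch,
                             cfg$min_len, cfg$max_len, quiet = TRUE),
    non_target = extract_amplicons(parts$non_target, pair, cfg$max_mismatch,
                                   cfg$min_len, cfg$max_len, quiet = TRUE)
  )
}

#' Simulate a reference database (command)
#'
#' Writes `db.fasta` (Silva header dialect), `truth.tsv` and
#' `config_used.yaml` into `out_dir`.
#'
#' @param out_dir output directory.
#' @param config_file optional YAML file of [sim_config] keys.
#' @param ... [sim_config] overrides (e.g. `seed`, `n_host`).
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config_file = NULL, ...) {
  args <- list(...)
  if (!is.null(config_file)) {
    file_args <- yaml::read_yaml(config_file)
    args <- utils::modifyList(file_args, args)
  }
  cfg <- do.call(sim_config, args)
  db <- simulate_refdb(cfg)
  prep_dir(out_dir)
  fasta <- file.path(out_dir, "db.fasta")
  truth <- file.path(out_dir, "truth.tsv")
  write_fasta_taxonomy(db, fasta)
  write_truth_tsv(db, truth)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_used.yaml"))
  invisible(c(fasta = fasta, truth = truth))
}

#' Extract in-silico amplicons (command)
#'
#' Writes `amplicons.fasta`, `amplicons.tsv` and `config_used.yaml`.
#'
#' @param db_fasta input reference FASTA (Silva dialect).
#' @param out_dir output directory.
#' @param config_file optional YAML configuration.
#' @param ... configuration overrides (see [run_config()]).
#' @return Named vector of written paths, invisibly.
#' @export
cmd_extract <- function(db_fasta, out_dir, config_file = NULL, ...) {
  cfg <- run_config(config_file, list(...))
  db <- read_db_checked(db_fasta)
  amps <- extract_amplicons(db, config_pair(cfg), cfg$max_mismatch,
                            cfg$min_len, cfg$max_len, quiet = TRUE)
  prep_dir(out_dir)
  fasta <- file.path(out_dir, "amplicons.fasta")
  tsv <- file.path(out_dir, "amplicons.tsv")
  write_amplicons(amps, fasta, tsv)
  echo_config(cfg, out_dir)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Entropy-profile the terminal region (command)
#'
#' Partitions the database, extracts host and non-target amplicons, and
#' writes `entropy.tsv`, `window_report.tsv` and `config_used.yaml`.
#'
#' @inheritParams cmd_extract
#' @return Named vector of written paths, invisibly.
#' @export
cmd_entropy <- function(db_fasta, out_dir, config_file = NULL, ...) {
  cfg <- run_config(config_file, list(...))
  db <- read_db_checked(db_fasta)
  px <- partition_and_extract(db, cfg)
  block <- terminal_block(px$host, px$non_target, W = cfg$W)
  profiles <- entropy_profiles(block, base = cfg$entropy_base)
  report <- design_window_report(profiles$host, profiles$non_target,
                                 nchar(px$pair$reverse$sequence))
  prep_dir(out_dir)
  ent <- file.path(out_dir, "entropy.tsv")
  win <- file.path(out_dir, "window_report.tsv")
  write_entropy_tsv(profiles, ent)
  utils::write.table(report, win, sep = "\t", quote = FALSE, row.names = FALSE)
  echo_config(cfg, out_dir)
  invisible(c(entropy = ent, window_report = win))
}

#' Run the full blocking-primer design (command)
#'
#' Writes `candidates.tsv`, `diagnostics.tsv`, `entropy.tsv`, `report.txt`,
#' `config_used.yaml` and -- when a candidate passes -- `top_blocker.fasta`
#' (with the `/3SpC3/` synthesis annotation) plus the specificity files of
#' the top candidate.
#'
#' @inheritParams cmd_extract
#' @return The `blocker_fit`, invisibly.
#' @export
cmd_design <- function(db_fasta, out_dir, config_file = NULL, ...) {
  cfg <- run_config(config_file, list(...))
  db <- read_db_checked(db_fasta)
  fit <- design_blocker(
    db, config_pair(cfg), host_clade = cfg$host_clade,
    exclude_clades = cfg$exclude_clades, design_clade = cfg$design_clade,
    W = cfg$W, max_mismatch = cfg$max_mismatch,
    amplicon_length = c(cfg$min_len, cfg$max_len),
    constraints = config_constraints(cfg), tm = config_tm_model(cfg),
    entropy_base = cfg$entropy_base, clade_depth = cfg$clade_depth,
    quiet = TRUE
  )
  prep_dir(out_dir)
  utils::write.table(as.data.frame(fit$candidates),
                     file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(fit$candidates, "diagnostics"),
                     file.path(out_dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_entropy_tsv(fit$profiles, file.path(out_dir, "entropy.tsv"))
  if (!is.null(fit$top)) {
    top <- Biostrings::BStringSet(fit$top$primer$sequence)
    names(top) <- paste(fit$top$primer$name, "blocking primer /3SpC3/")
    Biostrings::writeXStringSet(top, file.path(out_dir, "top_blocker.fasta"))
    write_specificity(fit$top$specificity, out_dir)
  }
  report <- utils::capture.output(print(fit))
  if (!is.null(fit$top)) {
    report <- c(report, "", utils::capture.output(print(fit$top$specificity)))
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  echo_config(cfg, out_dir)
  invisible(fit)
}

#' Audit a blocking oligo against a database (command)
#'
#' Standalone in-silico specificity evaluation of any user-supplied blocker
#' (for instance a published one against a reference snapshot). Writes the
#' specificity TSV/text files and `config_used.yaml`.
#'
#' @param blocker blocking oligo as an IUPAC string or [primer].
#' @inheritParams cmd_extract
#' @return The `specificity_report`, invisibly.
#' @export
cmd_evaluate <- function(blocker, db_fasta, out_dir, config_file = NULL, ...) {
  cfg <- run_config(config_file, list(...))
  blk <- if (inherits(blocker, "primer")) blocker else {
    primer("user-blocker", blocker, role = "blocking",
           modification_3prime = "spacer_C3")
  }
  db <- read_db_checked(db_fasta)
  px <- partition_and_extract(db, cfg)
  if (!nrow(px$host)) stop("no host amplicons to evaluate against")
  if (!nrow(px$non_target)) stop("no non-target amplicons to evaluate against")
  report <- evaluate_specificity(blk, px$host, px$non_target,
                                 k_block = cfg$k_block,
                                 clade_depth = cfg$clade_depth,
                                 both_orientations = cfg$both_orientations)
  prep_dir(out_dir)
  write_specificity(report, out_dir)
  echo_config(cfg, out_dir)
  invisible(report)
}

#' Summarize per-sample read partitions (command)
#'
#' Reads a TSV with a `sample` column and per-category read counts and
#' writes `proportions.tsv` (per sample) and `summary.tsv` (mean and sd per
#' category).
#'
#' @param counts_tsv input TSV.
#' @param out_dir output directory.
#' @return The `coamplification_summary`, invisibly.
#' @export
cmd_summarize <- function(counts_tsv, out_dir) {
  counts <- utils::read.delim(counts_tsv, stringsAsFactors = FALSE)
  res <- coamplification_summary(counts)
  prep_dir(out_dir)
  utils::write.table(res$per_sample, file.path(out_dir, "proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
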