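# In-silico specificity of a blocking oligo: binary blocked calls on
# amplicons, host / non-target blocked fractions with a per-clade breakdown,
# and bookkeeping for empirical read-partition tables.

#' Is an amplicon predicted to be blocked?
#'
#' An amplicon is called blocked when the full-length blocker anneals
#' somewhere on it with at most `k_block` mismatches under the IUPAC
#' set-subset rule. The blocker is written 5' to 3' on the strand competing
#' with the reverse primer, so on the amplicon as written the search pattern
#' is the blocker's reverse complement; `both_orientations = TRUE` also
#' searches the written orientation for safety audits.
#'
#' @param amplicon amplicon sequence(s): character vector or an
#'   `amplicon_set` data frame.
#' @param blocker a [primer] or IUPAC string.
#' @param k_block tolerated mismatches (0 by default: a strict block call).
#' @param both_orientations also search the blocker as written.
#' @return Logical vector, one call per amplicon. Amplicons shorter than the
#'   blocker are `FALSE` (with a logged skip note).
#' @export
is_blocked <- function(amplicon, blocker, k_block = 0L,
                       both_orientations = FALSE) {
  seqs <- if (is.data.frame(amplicon)) amplicon$sequence else as.character(amplicon)
  bseq <- primer_sequence(blocker)
  patterns <- list(encode_iupac(revcomp_iupac(bseq)))
  if (isTRUE(both_orientations)) patterns <- c(patterns, list(encode_iupac(bseq)))
  m <- nchar(bseq)
  short <- nchar(seqs) < m
  if (any(short)) {
    message("is_blocked: skipped ", sum(short),
            " amplicon(s) shorter than the blocker")
  }
  vapply(seqs, function(s) {
    if (nchar(s) < m) return(FALSE)
    tc <- encode_iupac(toupper(s), allow_gap = TRUE)
    any(vapply(patterns, function(p) {
      length(scan_encoded(tc, p, k_block)$start) > 0L
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

clade_at_depth <- function(lineage, depth) {
  vapply(split_lineage(lineage), function(r) {
    if (!length(r) || !any(nzchar(r))) return("(unclassified)")
    r[min(depth, length(r))]
  }, character(1))
}

#' In-silico specificity report for a blocking oligo
#'
#' Predicted-blocked fractions for the host and non-target amplicon sets,
#' the blocked non-target ids, and a breakdown of blocked non-targets by the
#' clade at a chosen lineage depth.
#'
#' @param blocker a [primer] or IUPAC string.
#' @param host_amplicons,non_target_amplicons non-empty `amplicon_set` data
#'   frames.
#' @param k_block tolerated mismatches in the block call.
#' @param clade_depth lineage rank (1 = root) used for the breakdown.
#' @param both_orientations passed to [is_blocked()].
#' @return A `specificity_report` object.
#' @export
evaluate_specificity <- function(blocker, host_amplicons, non_target_amplicons,
                                 k_block = 0L, clade_depth = 3L,
                                 both_orientations = FALSE) {
  if (!NROW(host_amplicons)) stop("host amplicon set is empty")
  if (!NROW(non_target_amplicons)) stop("non-target amplicon set is empty")
  h <- is_blocked(host_amplicons, blocker, k_block, both_orientations)
  nt <- is_blocked(non_target_amplicons, blocker, k_block, both_orientations)
  clades <- clade_at_depth(non_target_amplicons$lineage, clade_depth)
  blocked_clades <- clades[nt]
  clade_table <- if (length(blocked_clades)) {
    tab <- sort(table(blocked_clades), decreasing = TRUE)
    data.frame(clade = names(tab),
               n_blocked = as.integer(tab),
               n_total = as.integer(table(clades)[names(tab)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(clade = character(), n_blocked = integer(), n_total = integer(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(
      blocker = primer_sequence(blocker), k_block = as.integer(k_block),
      host = list(n_total = length(h), n_blocked = sum(h), fraction = mean(h)),
      non_target = list(n_total = length(nt), n_blocked = sum(nt),
                        fraction = mean(nt)),
      clade_table = clade_table,
      blocked_ids = non_target_amplicons$ref_id[nt]
    ),
    class = "specificity_report"
  )
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("In-silico blocking specificity\n",
      "  blocker:    5'-", x$blocker, "-3' (k_block = ", x$k_block, ")\n",
      sprintf("  host:       %d/%d amplicons predicted blocked (%.1f%%)\n",
              x$host$n_blocked, x$host$n_total, 100 * x$host$fraction),
      sprintf("  non-target: %d/%d amplicons predicted blocked (%.2f%%)\n",
              x$non_target$n_blocked, x$non_target$n_total,
              100 * x$non_target$fraction), sep = "")
  if (nrow(x$clade_table)) {
    cat("  blocked non-targets by clade:\n")
    for (i in seq_len(nrow(x$clade_table))) {
      cat(sprintf("    %-30s %d/%d\n", x$clade_table$clade[i],
                  x$clade_table$n_blocked[i], x$clade_table$n_total[i]))
    }
  }
  invisible(x)
}

#' Write a specificity report (TSV + text + blocked ids)
#'
#' @param report a `specificity_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_specificity <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_df <- data.frame(
    set = c("host", "non_target"),
    n_total = c(report$host$n_total, report$non_target$n_total),
    n_blocked = c(report$host$n_blocked, report$non_target$n_blocked),
    fraction = c(report$host$fraction, report$non_target$fraction)
  )
  utils::write.table(summary_df, file.path(dir, "specificity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$clade_table, file.path(dir, "clade_breakdown.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$blocked_ids, file.path(dir, "blocked_ids.txt"))
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' Per-sample read-partition proportions
#'
#' Pure bookkeeping for empirical co-amplification tables: per-sample
#' proportions of each read category plus across-sample mean and sd (sample
#' sd, n-1 denominator -- these tables are typically small).
#'
#' @param sample_counts data frame with a `sample` column and one or more
#'   non-negative numeric count columns (e.g. `host_reads`,
#'   `microeuk_reads`, `other_reads`).
#' @return A `coamplification_summary` list with `per_sample` proportions
#'   and a `summary` (mean, sd per category).
#' @export
coamplification_summary <- function(sample_counts) {
  stopifnot(is.data.frame(sample_counts), "sample" %in% names(sample_counts))
  num_cols <- setdiff(names(sample_counts), "sample")
  counts <- as.matrix(sample_counts[, num_cols, drop = FALSE])
  if (any(counts < 0)) stop("negative read counts")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("sample '", sample_counts$sample[which(totals == 0)[1]],
         "' has zero reads in every category")
  }
  props <- counts / totals
  per_sample <- data.frame(sample = sample_counts$sample, props,
                           stringsAsFactors = FALSE)
  summ <- data.frame(
    category = num_cols,
    mean = colMeans(props),
    sd = apply(props, 2, stats::sd),
    row.names = NULL
  )
  structure(list(per_sample = per_sample, summary = summ),
            class = "coamplification_summary")
}

#' @export
print.coamplification_summary <- function(x, ...) {
  cat("Read-partition summary (", nrow(x$per_sample), " samples)\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-16s %5.1f%% (+/- %.1f%%)\n", x$summary$category[i],
                100 * x$summary$mean[i], 100 * x$summary$sd[i]))
  }
  invisible(x)
}
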