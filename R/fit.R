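# The central design pipeline: partition -> in-silico PCR -> terminal block
# -> entropy profiles -> candidate enumeration -> specificity of the top
# candidate, returned as one classed object.

#' Design a blocking primer against a host clade
#'
#' Runs the full design pipeline on a taxonomically annotated reference
#' database: records are partitioned into host, excluded and non-target
#' sets; amplicons are extracted by mismatch-tolerant in-silico PCR with the
#' amplification pair; the right-anchored 3'-terminal block and its
#' host/non-target entropy profiles are computed; candidate blocking oligos
#' are enumerated over the host consensus under the design constraints; and
#' the in-silico specificity of the top-ranked candidate is evaluated.
#'
#' @param db a [refdb].
#' @param pair the amplification [primer_pair].
#' @param host_clade clade defining the host set (e.g. `"Heterobranchia"`).
#' @param exclude_clades clades removed from the non-target set (e.g.
#'   `"Metazoa"`).
#' @param design_clade optional narrower clade the blocker is designed from
#'   (e.g. `"Biomphalaria"`); the host blocked fraction is still reported
#'   against the full host set.
#' @param W terminal-block window (nt).
#' @param max_mismatch per-primer mismatch tolerance of the in-silico PCR.
#' @param amplicon_length length bounds `c(min, max)` of accepted amplicons.
#' @param constraints a [design_constraints].
#' @param tm a [tm_model].
#' @param entropy_base entropy logarithm base (2 = bits).
#' @param clade_depth lineage depth for the specificity breakdown.
#' @param quiet suppress stage log messages.
#' @return A `blocker_fit` object with components `counts`, `block`,
#'   `profiles`, `window_report`, `consensus`, `candidates`, `top` (list:
#'   `candidate`, `primer`, `synthesis`, `specificity`; `NULL` when no
#'   candidate passed the constraints).
#' @examples
#' fx <- snail_fixture()
#' fit <- design_blocker(fx$db, fx$pair, host_clade = "Heterobranchia",
#'                       exclude_clades = "Metazoa", quiet = TRUE)
#' fit
#' @export
design_blocker <- function(db, pair, host_clade, exclude_clades = "Metazoa",
                           design_clade = NULL, W = 40L, max_mismatch = 1L,
                           amplicon_length = c(200L, 600L),
                           constraints = design_constraints(),
                           tm = tm_model(), entropy_base = 2,
                           clade_depth = 3L, quiet = FALSE) {
  stopifnot(inherits(db, "refdb"), inherits(pair, "primer_pair"))
  parts <- partition_by_taxonomy(db, host_clade, exclude_clades)
  host_db <- if (!is.null(design_clade)) {
    subset_to_clade(parts$host, design_clade)
  } else parts$host
  if (!nrow(host_db)) stop("no host records to design from")
  if (!nrow(parts$non_target)) stop("no non-target records to screen against")
  host_amps <- extract_amplicons(host_db, pair, max_mismatch,
                                 amplicon_length[1], amplicon_length[2],
                                 quiet = quiet)
  nt_amps <- extract_amplicons(parts$non_target, pair, max_mismatch,
                               amplicon_length[1], amplicon_length[2],
                               quiet = quiet)
  if (!nrow(host_amps)) stop("no host amplicons under the primer pair")
  if (!nrow(nt_amps)) stop("no non-target amplicons under the primer pair")
  block <- terminal_block(host_amps, nt_amps, W = W)
  profiles <- entropy_profiles(block, base = entropy_base)
  window_report <- design_window_report(profiles$host, profiles$non_target,
                                        nchar(pair$reverse$sequence))
  consensus <- host_consensus(block)
  candidates <- enumerate_candidates(block, host_amps, nt_amps, pair,
                                     constraints, tm)
  top <- NULL
  if (nrow(candidates)) {
    cand <- candidates[1, ]
    blocker <- primer(paste0(pair$marker_name, "BP-candidate"), cand$sequence,
                      role = "blocking", modification_3prime = "spacer_C3")
    top <- list(
      candidate = cand,
      primer = blocker,
      synthesis = annotate_synthesis(blocker),
      specificity = evaluate_specificity(blocker, host_amps, nt_amps,
                                         k_block = constraints$k_block,
                                         clade_depth = clade_depth)
    )
  }
  structure(
    list(
      call = match.call(),
      pair = pair, host_clade = host_clade, exclude_clades = exclude_clades,
      design_clade = design_clade,
      counts = c(n_records = nrow(db), n_host = nrow(parts$host),
                 n_excluded = nrow(parts$excluded),
                 n_non_target = nrow(parts$non_target),
                 n_host_design = nrow(host_db),
                 n_host_amplicons = nrow(host_amps),
                 n_non_target_amplicons = nrow(nt_amps)),
      host_amplicons = host_amps, non_target_amplicons = nt_amps,
      block = block, profiles = profiles, window_report = window_report,
      consensus = consensus, candidates = candidates, top = top,
      constraints = constraints, tm = tm
    ),
    class = "blocker_fit"
  )
}

#' @export
print.blocker_fit <- function(x, ...) {
  cat("Blocking-primer design (", x$pair$marker_name, ")\n", sep = "")
  cat(sprintf("  host clade: %s%s; excluded: %s\n", x$host_clade,
              if (!is.null(x$design_clade)) {
                paste0(" (designed from ", x$design_clade, ")")
              } else "",
              paste(x$exclude_clades, collapse = ", ")))
  cat(sprintf("  records: %d total -> %d host / %d excluded / %d non-target\n",
              x$counts["n_records"], x$counts["n_host"],
              x$counts["n_excluded"], x$counts["n_non_target"]))
  cat(sprintf("  amplicons: %d host, %d non-target\n",
              x$counts["n_host_amplicons"], x$counts["n_non_target_amplicons"]))
  cat(sprintf("  candidates passing constraints: %d\n", nrow(x$candidates)))
  if (!is.null(x$top)) {
    c1 <- x$top$candidate
    cat(sprintf("  top candidate: 5'-%s-3'\n", c1$sequence))
    cat(sprintf("    length %d nt, overlap %d bp, Tm %.1f C (dTm %+.1f)\n",
                c1$length, c1$overlap, c1$tm, c1$delta_tm))
    cat(sprintf("    host blocked %.1f%%, off-target blocked %.2f%%\n",
                100 * c1$host_blocked, 100 * c1$off_target_blocked))
  } else {
    cat("  no candidate passed; see attr(fit$candidates, 'diagnostics')\n")
  }
  invisible(x)
}

#' @export
summary.blocker_fit <- function(object, n_show = 5L, ...) {
  structure(list(fit = object, n_show = n_show), class = "summary.blocker_fit")
}

#' @export
print.summary.blocker_fit <- function(x, ...) {
  print(x$fit)
  cands <- x$fit$candidates
  if (nrow(cands)) {
    cat("\nTop candidates:\n")
    print(utils::head(as.data.frame(cands), x$n_show), digits = 4)
  }
  if (!is.null(x$fit$top)) {
    cat("\n")
    print(x$fit$top$specificity)
    cat("\n")
    print(x$fit$top$synthesis)
  }
  invisible(x)
}

#' Plot the entropy profiles of a blocker fit
#'
#' Host (blue) and non-target (red) per-column entropies over the terminal
#' block, with the reverse-primer boundary dashed and the top candidate's
#' footprint shaded.
#'
#' @param x a `blocker_fit`.
#' @param ... passed to [plot_entropy_profiles()].
#' @return Invisibly, `x`.
#' @export
plot.blocker_fit <- function(x, ...) {
  rev_len <- nchar(x$pair$reverse$sequence)
  plot_entropy_profiles(x$profiles, primer_site_len = rev_len,
                        main = paste("Terminal-region entropy,",
                                     x$pair$marker_name), ...)
  if (!is.null(x$top)) {
    W <- x$block$W
    c1 <- x$top$candidate
    left <- W - rev_len - (c1$length - c1$overlap) + 1L
    right <- W - rev_len + c1$overlap
    graphics::rect(left - 0.5, graphics::par("usr")[3], right + 0.5,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey50", alpha.f = 0.15),
                   border = NA)
  }
  invisible(x)
}
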