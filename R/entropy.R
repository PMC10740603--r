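# The right-anchored 3'-terminal block of amplicons and its per-column
# Shannon-entropy profiles. The block is anchored positionally at the
# reverse-primer terminus -- the region is primer-anchored by construction,
# so no multiple sequence alignment is performed (a pre-aligned FASTA of the
# region can be supplied instead via read_fasta_taxonomy + terminal_block).

#' Build the right-anchored 3'-terminal block
#'
#' Each row holds the last `min(W, length)` symbols of one amplicon,
#' right-justified; shorter rows are left-padded with `-`. Column `W` is the
#' amplicon's final base (the 5' end of the reverse primer's written
#' sequence).
#'
#' @param host,non_target `amplicon_set` data frames or character vectors of
#'   sequences; `non_target` may be `NULL` for a single-set block.
#' @param W window length in nt (40 by default: the reverse-primer site plus
#'   the design region upstream of it).
#' @return A `terminal_block`: list with `W`, `rows` (character matrix),
#'   `ref_id`, `set`.
#' @export
terminal_block <- function(host, non_target = NULL, W = 40L) {
  stopifnot(W >= 1L)
  seqs_of <- function(x) {
    if (is.null(x)) return(character())
    if (is.data.frame(x)) x$sequence else as.character(x)
  }
  ids_of <- function(x, prefix) {
    if (is.null(x)) return(character())
    if (is.data.frame(x)) x$ref_id else paste0(prefix, seq_along(x))
  }
  hseq <- seqs_of(host)
  ntseq <- seqs_of(non_target)
  if (length(hseq) + length(ntseq) == 0L) stop("no amplicons to build a terminal block from")
  all_seq <- c(hseq, ntseq)
  rows <- t(vapply(all_seq, function(s) {
    n <- nchar(s)
    tail_s <- substr(toupper(s), max(1L, n - W + 1L), n)
    pad <- W - nchar(tail_s)
    strsplit(paste0(strrep("-", pad), tail_s), "", fixed = TRUE)[[1]]
  }, character(W), USE.NAMES = FALSE))
  structure(
    list(W = as.integer(W), rows = rows,
         ref_id = c(ids_of(host, "host_"), ids_of(non_target, "nt_")),
         set = c(rep("host", length(hseq)), rep("non_target", length(ntseq)))),
    class = "terminal_block"
  )
}

#' @export
print.terminal_block <- function(x, ...) {
  cat(sprintf("<terminal_block> W=%d, %d host row(s), %d non-target row(s)\n",
              x$W, sum(x$set == "host"), sum(x$set == "non_target")))
  invisible(x)
}

SYMBOL_CLASSES <- c("A", "C", "G", "T", "other", "gap")

classify_symbols <- function(chars) {
  out <- ifelse(chars %in% BASES, chars, ifelse(chars == "-", "gap", "other"))
  factor(out, levels = SYMBOL_CLASSES)
}

# 6 x W matrix of per-column symbol-class counts.
block_counts <- function(rows) {
  apply(rows, 2, function(col) table(classify_symbols(col)))
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum(f_b log2 f_b)` over symbol classes with positive frequency,
#' gaps excluded from the frequencies. A column holding only gaps has no
#' defined entropy and yields `NA` (not 0).
#'
#' @param counts named counts, e.g. `c(A = 3, T = 1)`; a `gap` element is
#'   ignored.
#' @param base logarithm base; 2 (bits) is the oligotyping convention.
#' @return Entropy (bits for `base = 2`), or `NA` for an all-gap column.
#' @examples
#' column_entropy(c(A = 5, C = 5, G = 5, T = 5)) # 2 bits
#' @export
column_entropy <- function(counts, base = 2) {
  counts <- counts[setdiff(names(counts), "gap")]
  total <- sum(counts)
  if (total < 1) return(NA_real_)
  f <- counts[counts > 0] / total
  -sum(f * log(f, base = base))
}

profile_one <- function(rows, set, base) {
  counts <- block_counts(rows)
  H <- apply(counts, 2, column_entropy, base = base)
  out <- data.frame(column = seq_len(ncol(counts)), t(counts), H = H,
                    row.names = NULL)
  names(out) <- c("column", SYMBOL_CLASSES, "H")
  class(out) <- c("entropy_profile", "data.frame")
  attr(out, "set") <- set
  attr(out, "base") <- base
  out
}

#' Per-column entropy profiles of host and non-target sets
#'
#' Two independent per-column profiles over the terminal block, one per set.
#'
#' @param block a [terminal_block] containing at least one row per set.
#' @param base entropy logarithm base (2 = bits).
#' @return A list of two `entropy_profile` data frames, `host` and
#'   `non_target`, each with per-column symbol counts and entropy `H`.
#' @export
entropy_profiles <- function(block, base = 2) {
  stopifnot(inherits(block, "terminal_block"))
  out <- lapply(c("host", "non_target"), function(s) {
    idx <- which(block$set == s)
    if (!length(idx)) stop("no rows for set '", s, "' in the terminal block")
    profile_one(block$rows[idx, , drop = FALSE], s, base)
  })
  names(out) <- c("host", "non_target")
  out
}

#' Per-column design-window report
#'
#' Tabulates host and non-target entropies, their difference, and whether a
#' column lies inside the reverse-primer binding site (the last
#' `primer_site_len` columns), for locating a window that is conserved in
#' the host but variable among non-targets.
#'
#' @param host_profile,non_target_profile `entropy_profile` data frames of
#'   equal length.
#' @param primer_site_len length of the reverse primer (nt).
#' @return Data frame (`column`, `host_H`, `non_target_H`, `delta_H`,
#'   `inside_reverse_primer_site`); `delta_H` is non-target minus host.
#' @export
design_window_report <- function(host_profile, non_target_profile,
                                 primer_site_len) {
  if (nrow(host_profile) != nrow(non_target_profile)) {
    stop("profiles have unequal length (", nrow(host_profile), " vs ",
         nrow(non_target_profile), ")")
  }
  W <- nrow(host_profile)
  data.frame(
    column = host_profile$column,
    host_H = host_profile$H,
    non_target_H = non_target_profile$H,
    delta_H = non_target_profile$H - host_profile$H,
    inside_reverse_primer_site = host_profile$column > W - primer_site_len
  )
}

#' Plot host vs non-target entropy profiles
#'
#' Host in blue, non-target in red; a dashed line marks the 5' boundary of
#' the reverse-primer binding site when `primer_site_len` is given.
#'
#' @param profiles result of [entropy_profiles()].
#' @param primer_site_len reverse primer length (optional).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `profiles`.
#' @export
plot_entropy_profiles <- function(profiles, primer_site_len = NULL, ...) {
  W <- nrow(profiles$host)
  graphics::matplot(profiles$host$column,
                    cbind(profiles$host$H, profiles$non_target$H),
                    type = "l", lty = 1, lwd = 2, col = c("blue", "red"),
                    xlab = "terminal-block column (3' anchored)",
                    ylab = "Shannon entropy (bits)", ...)
  if (!is.null(primer_site_len)) {
    graphics::abline(v = W - primer_site_len + 0.5, lty = 2, col = "grey40")
  }
  graphics::legend("topleft", legend = c("host", "non-target"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  invisible(profiles)
}

#' Write entropy profiles as TSV
#'
#' One row per (set, column) with symbol-class counts and entropy.
#'
#' @param profiles result of [entropy_profiles()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(s) {
    p <- profiles[[s]]
    cbind(data.frame(set = s), as.data.frame(p))
  }))
  names(rows)[names(rows) == "H"] <- "H_bits"
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
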