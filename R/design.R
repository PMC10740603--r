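# Constrained enumeration of candidate blocking oligos over the host
# 3'-terminal consensus: length ~28 nt, ~10 nt overlap with the reverse
# primer, melting temperature similar to the amplification primer set, high
# host conservation, minimal off-target blocking.

#' Design constraints for blocking-oligo enumeration
#'
#' @param length_range candidate length bounds in nt (the published design
#'   used 28).
#' @param overlap_range bounds on the overlap between the candidate's 5'
#'   prefix and the reverse primer's 3' suffix (published design: 10 nt).
#' @param tm_tolerance maximal `|Tm(candidate) - Tm(reference)|` in degrees C.
#' @param tm_reference what the candidate Tm is compared against: the mean of
#'   the forward and reverse primer Tms (`"pair_mean"`, matching the aim of a
#'   Tm similar to the targeted primer set), or a single primer.
#' @param min_conservation minimal mean host consensus conservation over the
#'   candidate columns upstream of the reverse-primer site.
#' @param k_block mismatches tolerated when calling an amplicon blocked.
#' @param off_target_ceiling maximal tolerated off-target blocked fraction.
#' @param lambda weight of the off-target blocked fraction in the ranking
#'   score `host_blocked - lambda * off_target_blocked`; large by default
#'   because off-target safety outranks host coverage.
#' @param overlap_max_mismatch mismatches tolerated in the overlap
#'   computation (1 by default: hosts may differ from the universal primer at
#'   one position, and the blocker should carry the host base there).
#' @return A `design_constraints` object.
#' @export
design_constraints <- function(length_range = c(24L, 32L),
                               overlap_range = c(8L, 12L),
                               tm_tolerance = 3,
                               tm_reference = c("pair_mean", "reverse", "forward"),
                               min_conservation = 0.90,
                               k_block = 0L,
                               off_target_ceiling = 0.01,
                               lambda = 10,
                               overlap_max_mismatch = 1L) {
  tm_reference <- match.arg(tm_reference)
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            length(overlap_range) == 2L, overlap_range[1] <= overlap_range[2],
            length_range[1] >= overlap_range[1] + 1L,
            tm_tolerance >= 0, min_conservation >= 0, min_conservation <= 1,
            k_block >= 0L, off_target_ceiling >= 0, off_target_ceiling <= 1)
  structure(list(length_range = as.integer(length_range),
                 overlap_range = as.integer(overlap_range),
                 tm_tolerance = tm_tolerance, tm_reference = tm_reference,
                 min_conservation = min_conservation, k_block = as.integer(k_block),
                 off_target_ceiling = off_target_ceiling, lambda = lambda,
                 overlap_max_mismatch = as.integer(overlap_max_mismatch)),
            class = "design_constraints")
}

#' Host consensus of the terminal block
#'
#' Per column, the most frequent concrete base among the host rows (ties
#' broken to the lexicographically smallest base and flagged); conservation
#' is that base's frequency among non-gap symbols. All-gap columns yield a
#' gap consensus with conservation 0.
#'
#' @param block a [terminal_block] with at least one host row.
#' @return A list with `consensus` (string of length `W`), `conservation`
#'   (numeric) and `tie` (logical).
#' @export
host_consensus <- function(block) {
  stopifnot(inherits(block, "terminal_block"))
  idx <- which(block$set == "host")
  if (!length(idx)) stop("terminal block contains no host rows")
  rows <- block$rows[idx, , drop = FALSE]
  W <- block$W
  consensus <- character(W)
  conservation <- numeric(W)
  tie <- logical(W)
  for (j in seq_len(W)) {
    col <- rows[, j]
    base_counts <- table(factor(col[col %in% BASES], levels = BASES))
    n_nongap <- sum(col != "-")
    if (n_nongap == 0L || sum(base_counts) == 0L) {
      consensus[j] <- "-"
      conservation[j] <- 0
      tie[j] <- FALSE
      next
    }
    top <- max(base_counts)
    winners <- names(base_counts)[base_counts == top]
    consensus[j] <- winners[1] # BASES order is lexicographic
    conservation[j] <- top / n_nongap
    tie[j] <- length(winners) > 1L
  }
  list(consensus = paste(consensus, collapse = ""),
       conservation = conservation, tie = tie)
}

#' Overlap between a blocking oligo and the reverse primer
#'
#' The maximal `n` such that the length-`n` 3' suffix of the reverse primer
#' matches the length-`n` 5' prefix of the blocker under the IUPAC
#' set-subset rule with at most `max_mismatch` mismatches; 0 if no such `n`.
#' The orientation matters: both oligos are written 5' to 3' on the strand
#' competing with the reverse primer.
#'
#' @param blocker,reverse_primer [primer] objects or IUPAC strings.
#' @param max_mismatch tolerated mismatches inside the overlap.
#' @return Integer overlap length in bp.
#' @examples
#' ps <- snail_primer_set()
#' compute_primer_overlap(ps$blocker_18SV4, ps$pair_18SV4$reverse) # 10
#' @export
compute_primer_overlap <- function(blocker, reverse_primer, max_mismatch = 1L) {
  b <- primer_sequence(blocker)
  r <- primer_sequence(reverse_primer)
  nb <- nchar(b)
  nr <- nchar(r)
  for (n in seq(min(nb, nr), 1L)) {
    suffix <- substr(r, nr - n + 1L, nr)
    prefix <- substr(b, 1L, n)
    if (count_mismatches(suffix, prefix)$count <= max_mismatch) return(n)
  }
  0L
}

# Fraction of encoded amplicons carrying a full-length match of the
# (already reverse-complemented and encoded) blocker pattern with <= k
# mismatches anywhere. `codes` is a list of integer vectors.
blocked_fraction_encoded <- function(codes, pattern_codes, k) {
  hits <- vapply(codes, function(tc) {
    length(scan_encoded(tc, pattern_codes, k)$start) > 0L
  }, logical(1))
  list(fraction = mean(hits), blocked = hits)
}

#' Enumerate and rank candidate blocking oligos
#'
#' For every (length, overlap) geometry allowed by the constraints the host
#' consensus window ending `overlap` nt inside the reverse-primer site is
#' reverse-complemented into a candidate oligo (written 5' to 3' like the
#' reverse primer). Candidates are filtered on mean host conservation (over
#' the columns upstream of the primer site), Tm distance to the reference,
#' realized overlap, and the off-target ceiling, then ranked by
#' `host_blocked - lambda * off_target_blocked` with ties broken by smaller
#' `|dTm|` and larger overlap.
#'
#' @param host_block a [terminal_block] with host rows.
#' @param host_amplicons,non_target_amplicons `amplicon_set` data frames
#'   used for the blocking fractions.
#' @param pair the amplification [primer_pair].
#' @param constraints a [design_constraints].
#' @param tm a [tm_model].
#' @return A `blocker_candidates` data frame (`sequence`, `length`,
#'   `overlap`, `tm`, `delta_tm`, `host_blocked`, `off_target_blocked`,
#'   `conservation`, `score`), ranked; a `diagnostics` attribute tabulates
#'   every enumerated geometry with the filter it failed, which is the place
#'   to look when no candidate passes.
#' @export
enumerate_candidates <- function(host_block, host_amplicons,
                                 non_target_amplicons, pair,
                                 constraints = design_constraints(),
                                 tm = tm_model()) {
  stopifnot(inherits(host_block, "terminal_block"),
            inherits(pair, "primer_pair"),
            inherits(constraints, "design_constraints"))
  cons <- host_consensus(host_block)
  W <- host_block$W
  rev_len <- nchar(pair$reverse$sequence)
  if (W <= rev_len) stop("terminal block (W=", W,
                         ") does not extend past the reverse-primer site")
  stopifnot(inherits(tm, "tm_model"))
  tm_fwd <- melting_temperature(pair$forward, tm)
  tm_rev <- melting_temperature(pair$reverse, tm)
  ref_tm <- switch(constraints$tm_reference,
                   pair_mean = (tm_fwd + tm_rev) / 2,
                   reverse = tm_rev, forward = tm_fwd)
  host_codes <- lapply(host_amplicons$sequence, encode_iupac, allow_gap = TRUE)
  nt_codes <- lapply(non_target_amplicons$sequence, encode_iupac, allow_gap = TRUE)
  cons_chars <- strsplit(cons$consensus, "", fixed = TRUE)[[1]]

  combos <- expand.grid(
    length = seq(constraints$length_range[1], constraints$length_range[2]),
    overlap = seq(constraints$overlap_range[1], constraints$overlap_range[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  diag_rows <- list()
  cand_rows <- list()
  for (i in seq_len(nrow(combos))) {
    L <- combos$length[i]
    O <- combos$overlap[i]
    rec <- data.frame(length = L, overlap_geometry = O, sequence = NA_character_,
                      overlap = NA_integer_, tm = NA_real_, delta_tm = NA_real_,
                      conservation = NA_real_, host_blocked = NA_real_,
                      off_target_blocked = NA_real_, kept = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (L <= O || O > rev_len || (L - O) > (W - rev_len)) {
      rec$reason <- "geometry does not fit the terminal block"
      diag_rows[[i]] <- rec
      next
    }
    win <- (W - rev_len - (L - O) + 1L):(W - rev_len + O)
    win_chars <- cons_chars[win]
    if (!all(win_chars %in% BASES)) {
      rec$reason <- "no concrete consensus in window"
      diag_rows[[i]] <- rec
      next
    }
    cand <- revcomp_iupac(paste(win_chars, collapse = ""))
    insert_cols <- win[win <= W - rev_len]
    conservation <- mean(cons$conservation[insert_cols])
    tm_cand <- melting_temperature(cand, tm)
    dtm <- tm_cand - ref_tm
    overlap_n <- compute_primer_overlap(cand, pair$reverse,
                                        constraints$overlap_max_mismatch)
    pattern <- encode_iupac(revcomp_iupac(cand))
    host_bl <- blocked_fraction_encoded(host_codes, pattern, constraints$k_block)
    off_bl <- blocked_fraction_encoded(nt_codes, pattern, constraints$k_block)
    rec$sequence <- cand
    rec$overlap <- overlap_n
    rec$tm <- tm_cand
    rec$delta_tm <- dtm
    rec$conservation <- conservation
    rec$host_blocked <- host_bl$fraction
    rec$off_target_blocked <- off_bl$fraction
    rec$reason <- if (conservation < constraints$min_conservation) {
      "host conservation below threshold"
    } else if (abs(dtm) > constraints$tm_tolerance) {
      "Tm outside tolerance"
    } else if (overlap_n < constraints$overlap_range[1] ||
               overlap_n > constraints$overlap_range[2]) {
      "realized overlap outside range"
    } else if (off_bl$fraction > constraints$off_target_ceiling) {
      "off-target fraction above ceiling"
    } else ""
    rec$kept <- rec$reason == ""
    diag_rows[[i]] <- rec
    if (rec$kept) cand_rows[[length(cand_rows) + 1L]] <- rec
  }
  diagnostics <- do.call(rbind, diag_rows)
  out <- if (length(cand_rows)) do.call(rbind, cand_rows) else diagnostics[0, ]
  if (nrow(out)) {
    out$score <- out$host_blocked - constraints$lambda * out$off_target_blocked
    out <- out[order(-out$score, abs(out$delta_tm), -out$overlap), , drop = FALSE]
    out <- out[, c("sequence", "length", "overlap", "tm", "delta_tm",
                   "host_blocked", "off_target_blocked", "conservation", "score")]
  } else {
    out <- data.frame(sequence = character(), length = integer(),
                      overlap = integer(), tm = numeric(), delta_tm = numeric(),
                      host_blocked = numeric(), off_target_blocked = numeric(),
                      conservation = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("blocker_candidates", "data.frame")
  attr(out, "diagnostics") <- diagnostics
  attr(out, "constraints") <- constraints
  attr(out, "reference_tm") <- ref_tm
  out
}

#' Independently re-validate emitted candidates against the constraints
#'
#' Recomputes length, overlap (from the sequence), Tm and bound checks with
#' fresh calls, independent of the bookkeeping done during enumeration.
#'
#' @param candidates a `blocker_candidates` data frame.
#' @param pair the amplification [primer_pair].
#' @param constraints the [design_constraints] used.
#' @param tm the [tm_model] used.
#' @return `TRUE` if every candidate satisfies every constraint, otherwise a
#'   character vector of violations.
#' @export
validate_candidates <- function(candidates, pair, constraints,
                                tm = tm_model()) {
  ref_tm <- attr(candidates, "reference_tm")
  bad <- character()
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, ]
    L <- nchar(row$sequence)
    if (L < constraints$length_range[1] || L > constraints$length_range[2]) {
      bad <- c(bad, sprintf("candidate %d: length %d out of range", i, L))
    }
    ov <- compute_primer_overlap(row$sequence, pair$reverse,
                                 constraints$overlap_max_mismatch)
    if (ov < constraints$overlap_range[1] || ov > constraints$overlap_range[2]) {
      bad <- c(bad, sprintf("candidate %d: overlap %d out of range", i, ov))
    }
    tm_i <- melting_temperature(row$sequence, tm)
    if (abs(tm_i - ref_tm) > constraints$tm_tolerance + 1e-9) {
      bad <- c(bad, sprintf("candidate %d: |dTm| = %.2f out of tolerance",
                            i, abs(tm_i - ref_tm)))
    }
    if (row$conservation < constraints$min_conservation ||
        row$host_blocked < 0 || row$host_blocked > 1 ||
        row$off_target_blocked < 0 || row$off_target_blocked > 1 ||
        row$off_target_blocked > constraints$off_target_ceiling + 1e-12) {
      bad <- c(bad, sprintf("candidate %d: conservation/fraction bound violated", i))
    }
  }
  if (length(bad)) bad else TRUE
}
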