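# Mismatch-tolerant in-silico PCR: degenerate primer-site search on both
# strands and amplicon extraction under length bounds.

#' Positionwise mismatch count between a primer and a target window
#'
#' Applies the set-subset rule of [iupac_match()] position by position.
#'
#' @param primer a [primer] or IUPAC string.
#' @param window target window of the same length.
#' @return A list with `count` and `positions` (1-based, primer-relative).
#' @examples
#' count_mismatches("TCTTGATYRA", "TCTTGACTAA") # one mismatch, position 7
#' @export
count_mismatches <- function(primer, window) {
  p <- encode_iupac(primer_sequence(primer))
  t <- encode_iupac(toupper(window), allow_gap = TRUE)
  if (length(p) != length(t)) {
    stop("window length (", length(t), ") differs from primer length (",
         length(p), ")")
  }
  ok <- bitwAnd(p, t) == t & t > 0L
  positions <- which(!ok)
  list(count = length(positions), positions = positions)
}

# Sliding mismatch-count scan of an encoded primer over an encoded target.
# Returns starts (1-based) and mismatch counts of windows with count <= max_mm.
scan_encoded <- function(tcodes, pcodes, max_mm) {
  n <- length(tcodes)
  m <- length(pcodes)
  if (n < m) return(list(start = integer(), mismatches = integer()))
  nw <- n - m + 1L
  mm <- integer(nw)
  for (j in seq_len(m)) {
    tj <- tcodes[j:(j + nw - 1L)]
    mm <- mm + as.integer(!(bitwAnd(pcodes[j], tj) == tj & tj > 0L))
  }
  keep <- which(mm <= max_mm)
  list(start = keep, mismatches = mm[keep])
}

empty_sites <- function() {
  data.frame(ref_id = character(), start = integer(), end = integer(),
             strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Find primer binding sites on a reference sequence
#'
#' All windows with at most `max_mismatch` mismatches under the IUPAC
#' set-subset rule, on the sense strand and (optionally) the reverse
#' complement. Coordinates are 1-based closed intervals on the sense strand
#' regardless of the matching strand.
#'
#' @param ref a sequence string, or a one-row [refdb].
#' @param primer a [primer] or IUPAC string.
#' @param max_mismatch tolerated mismatches per site.
#' @param search_revcomp also search the reverse complement orientation.
#' @param ref_id id used in the output when `ref` is a bare string.
#' @return A data frame (`ref_id`, `start`, `end`, `strand`, `mismatches`,
#'   `mismatch_positions` list column of 1-based primer-relative indices),
#'   sorted by (`mismatches`, `start`).
#' @export
find_primer_sites <- function(ref, primer, max_mismatch = 1L,
                              search_revcomp = TRUE, ref_id = "seq") {
  stopifnot(max_mismatch >= 0L)
  if (inherits(ref, "refdb") || is.data.frame(ref)) {
    stopifnot(nrow(ref) == 1L)
    ref_id <- ref$id[1]
    ref <- ref$sequence[1]
  }
  pseq <- primer_sequence(primer)
  m <- nchar(pseq)
  tcodes <- encode_iupac(toupper(ref), allow_gap = TRUE)
  hits_plus <- scan_encoded(tcodes, encode_iupac(pseq), max_mismatch)
  out <- if (length(hits_plus$start)) {
    data.frame(ref_id = ref_id, start = hits_plus$start,
               end = hits_plus$start + m - 1L, strand = "+",
               mismatches = hits_plus$mismatches, stringsAsFactors = FALSE)
  } else empty_sites()
  if (isTRUE(search_revcomp)) {
    prc <- revcomp_iupac(pseq)
    hits_minus <- scan_encoded(tcodes, encode_iupac(prc), max_mismatch)
    if (length(hits_minus$start)) {
      out <- rbind(out, data.frame(
        ref_id = ref_id, start = hits_minus$start,
        end = hits_minus$start + m - 1L, strand = "-",
        mismatches = hits_minus$mismatches, stringsAsFactors = FALSE
      ))
    }
  }
  if (nrow(out)) {
    out <- out[order(out$mismatches, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    refstr <- toupper(ref)
    out$mismatch_positions <- lapply(seq_len(nrow(out)), function(i) {
      win <- substr(refstr, out$start[i], out$end[i])
      if (out$strand[i] == "+") {
        count_mismatches(pseq, win)$positions
      } else {
        # primer-relative positions on the original primer
        rev_pos <- count_mismatches(revcomp_iupac(pseq), win)$positions
        sort(m - rev_pos + 1L)
      }
    })
  } else {
    out$mismatch_positions <- list()
  }
  out
}

# Best (mismatches, then leftmost) forward site with a compatible downstream
# reverse site; returns NULL or a list describing the amplicon on strand `s`.
pair_sites <- function(fhits, rhits, m_f, m_r, min_len, max_len) {
  if (!length(fhits$start) || !length(rhits$start)) return(NULL)
  ford <- order(fhits$mismatches, fhits$start)
  rord <- order(rhits$mismatches, rhits$start)
  for (i in ford) {
    f_start <- fhits$start[i]
    f_end <- f_start + m_f - 1L
    for (j in rord) {
      r_start <- rhits$start[j]
      r_end <- r_start + m_r - 1L
      len <- r_end - f_start + 1L
      if (r_start > f_end && len >= min_len && len <= max_len) {
        return(list(start = f_start, end = r_end,
                    fwd_mm = fhits$mismatches[i], rev_mm = rhits$mismatches[j]))
      }
    }
  }
  NULL
}

#' Extract in-silico amplicons from a reference database
#'
#' For each reference the best forward site (fewest mismatches, then
#' leftmost) is paired with the best compatible reverse-primer site
#' downstream such that the amplicon length (both primer-binding sites
#' included) lies within `[min_len, max_len]`; at most one amplicon per
#' reference. Both orientations of the reference are tried; coordinates are
#' reported on the sense strand and `sequence` is the amplicon in
#' amplification orientation (reverse-complemented for `-` strand records).
#'
#' @param db a [refdb].
#' @param pair a [primer_pair].
#' @param max_mismatch tolerated mismatches per primer site.
#' @param min_len,max_len amplicon length bounds (nt).
#' @param quiet suppress the per-call log summary.
#' @return An `amplicon_set` data frame (`ref_id`, `lineage`, `start`, `end`,
#'   `strand`, `length`, `fwd_mm`, `rev_mm`, `sequence`) with a `skipped`
#'   attribute listing references without a valid primer pair.
#' @export
extract_amplicons <- function(db, pair, max_mismatch = 1L,
                              min_len = 200L, max_len = 600L, quiet = FALSE) {
  stopifnot(inherits(pair, "primer_pair"), min_len <= max_len)
  fseq <- pair$forward$sequence
  rseq <- pair$reverse$sequence
  m_f <- nchar(fseq)
  m_r <- nchar(rseq)
  fcodes <- encode_iupac(fseq)
  # reverse-primer site as it appears on the template strand being scanned
  rc_codes <- encode_iupac(revcomp_iupac(rseq))
  rows <- vector("list", nrow(db))
  skipped <- character()
  for (k in seq_len(nrow(db))) {
    seqk <- db$sequence[k]
    n <- nchar(seqk)
    found <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqk else revcomp_iupac(seqk)
      tcodes <- encode_iupac(s, allow_gap = TRUE)
      hit <- pair_sites(scan_encoded(tcodes, fcodes, max_mismatch),
                        scan_encoded(tcodes, rc_codes, max_mismatch),
                        m_f, m_r, min_len, max_len)
      if (!is.null(hit)) {
        amp_seq <- substr(s, hit$start, hit$end)
        if (strand == "+") {
          found <- data.frame(ref_id = db$id[k], lineage = db$lineage[k],
                              start = hit$start, end = hit$end, strand = "+",
                              length = hit$end - hit$start + 1L,
                              fwd_mm = hit$fwd_mm, rev_mm = hit$rev_mm,
                              sequence = amp_seq, stringsAsFactors = FALSE)
        } else {
          found <- data.frame(ref_id = db$id[k], lineage = db$lineage[k],
                              start = n - hit$end + 1L, end = n - hit$start + 1L,
                              strand = "-",
                              length = hit$end - hit$start + 1L,
                              fwd_mm = hit$fwd_mm, rev_mm = hit$rev_mm,
                              sequence = amp_seq, stringsAsFactors = FALSE)
        }
        break
      }
    }
    if (is.null(found)) skipped <- c(skipped, db$id[k]) else rows[[k]] <- found
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), lineage = character(),
                      start = integer(), end = integer(), strand = character(),
                      length = integer(), fwd_mm = integer(), rev_mm = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("amplicon_set", "data.frame")
  attr(out, "skipped") <- skipped
  if (!quiet) {
    message(sprintf("extract_amplicons: %d/%d references yielded an amplicon (%d skipped)",
                    nrow(out), nrow(db), length(skipped)))
  }
  out
}

#' Write amplicons as FASTA plus a TSV sidecar
#'
#' FASTA ids are `ref_id/start-end`; the sidecar lists `ref_id`, `lineage`,
#' `start`, `end`, `strand`, `fwd_mm`, `rev_mm`, `length`.
#'
#' @param amplicons an `amplicon_set` from [extract_amplicons()].
#' @param fasta_path,tsv_path output files.
#' @return `fasta_path`, invisibly.
#' @export
write_amplicons <- function(amplicons, fasta_path, tsv_path) {
  set <- Biostrings::BStringSet(amplicons$sequence)
  names(set) <- sprintf("%s/%d-%d %s", amplicons$ref_id, amplicons$start,
                        amplicons$end, amplicons$lineage)
  Biostrings::writeXStringSet(set, fasta_path, width = 70L)
  utils::write.table(
    amplicons[, c("ref_id", "lineage", "start", "end", "strand",
                  "fwd_mm", "rev_mm", "length")],
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(fasta_path)
}
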