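# IUPAC nucleotide machinery: bit-set encoding, degenerate matching,
# reverse complement and expansion of degenerate oligos.

# One bit per concrete base; a degenerate symbol is the union of its bases.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

BASES <- c("A", "C", "G", "T")

#' Bases covered by an IUPAC symbol
#'
#' @param sym single IUPAC nucleotide symbol.
#' @return Character vector of concrete bases (subset of A, C, G, T).
#' @examples
#' iupac_bases("Y")
#' @export
iupac_bases <- function(sym) {
  sym <- toupper(sym)
  bits <- IUPAC_BITS[sym]
  if (is.na(bits)) stop("not an IUPAC nucleotide symbol: '", sym, "'")
  BASES[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

# Encode a nucleotide string as a vector of IUPAC bit codes.
# Gaps ("-") encode to 0 when allowed; 0 never matches any primer symbol.
encode_iupac <- function(x, allow_gap = FALSE) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- unname(IUPAC_BITS[chars])
  if (allow_gap) codes[chars == "-"] <- 0L
  if (anyNA(codes)) {
    bad <- chars[is.na(codes)][1]
    stop("non-IUPAC symbol '", bad, "' in sequence")
  }
  codes
}

#' Degenerate primer-to-target symbol match
#'
#' A target symbol matches a primer symbol when the target's base set is a
#' subset of the primer's base set. This is deliberately asymmetric and
#' conservative: an `N` in a (typically low-quality) reference position does
#' not count as a match to anything but a primer `N`, whereas a primer `N`
#' matches any target.
#'
#' @param primer_symbol,target_symbol IUPAC symbols; vectorized, recycled to
#'   common length.
#' @return Logical vector.
#' @examples
#' iupac_match("Y", "T") # TRUE:  {T} is inside {C,T}
#' iupac_match("T", "Y") # FALSE: {C,T} is not inside {T}
#' @export
iupac_match <- function(primer_symbol, target_symbol) {
  p <- unname(IUPAC_BITS[toupper(primer_symbol)])
  t <- unname(IUPAC_BITS[toupper(target_symbol)])
  if (anyNA(p) || anyNA(t)) stop("non-IUPAC symbol in iupac_match()")
  bitwAnd(p, t) == t
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate symbols are complemented as sets (Y <-> R, S <-> S, ...);
#' gap characters are preserved.
#'
#' @param x a single nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp_iupac <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Expand a degenerate oligo into its concrete sequences
#'
#' @param primer a [primer] object or an IUPAC string.
#' @param cap maximum number of expansions allowed (product of per-position
#'   degeneracies); guards against combinatorial blow-up of highly degenerate
#'   oligos.
#' @return Character vector of all concrete ACGT sequences, in lexicographic
#'   order.
#' @examples
#' expand_degenerate("ACTTTCGTTCTTGATYRA") # 4 sequences (Y x R)
#' @export
expand_degenerate <- function(primer, cap = 64) {
  seq <- primer_sequence(primer)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  sets <- lapply(chars, iupac_bases)
  n <- prod(lengths(sets))
  if (n > cap) {
    stop("degeneracy ", n, " exceeds cap ", cap,
         "; raise the cap or use a consensus sequence")
  }
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

# Accept either a primer object or a bare string wherever an oligo is expected.
primer_sequence <- function(x) {
  if (inherits(x, "primer")) x$sequence else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a primer object or a single sequence string")
}
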