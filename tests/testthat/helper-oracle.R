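# Independent oracles used to cross-check the matching engine. These work on
# character sets (no bit encoding) and implement their own complement table,
# so they share nothing with the package internals they verify.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# ok[primer_symbol, target_symbol]: is target's set inside primer's set?
ORACLE_OK <- local({
  syms <- names(ORACLE_SETS)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (p in syms) for (t in syms) {
    m[p, t] <- all(ORACLE_SETS[[t]] %in% ORACLE_SETS[[p]])
  }
  m
})

oracle_count_mm <- function(primer, window) {
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  tc <- strsplit(window, "", fixed = TRUE)[[1]]
  gap <- tc == "-"
  sum(gap) + sum(!ORACLE_OK[cbind(pc[!gap], tc[!gap])])
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y",
                 W = "W", S = "S", Y = "R", K = "M", V = "B", H = "D",
                 D = "H", B = "V", N = "N", "-" = "-")

oracle_revcomp <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(x, "", fixed = TRUE)[[1]]])),
        collapse = "")
}

# mismatch count of every window start, one orientation
oracle_mm_vector <- function(seq, primer) {
  m <- nchar(primer)
  n <- nchar(seq)
  if (n < m) return(integer())
  vapply(seq_len(n - m + 1L), function(s) {
    oracle_count_mm(primer, substr(seq, s, s + m - 1L))
  }, integer(1))
}

oracle_blocked <- function(amplicon, blocker, k) {
  mm <- oracle_mm_vector(amplicon, oracle_revcomp(blocker))
  length(mm) > 0L && any(mm <= k)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac_primer <- function(n, n_degenerate = 2L) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  idx <- sample.int(n, min(n_degenerate, n))
  chars[idx] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), length(idx),
                       replace = TRUE)
  paste(chars, collapse = "")
}

fixture_pair <- function() snail_primer_set()$pair_18SV4
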