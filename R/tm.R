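# Oligo melting temperature: Wallace rule and nearest-neighbor
# thermodynamics (SantaLucia 1998 unified parameters). Degenerate oligos are
# averaged over their concrete expansions.

# Unified NN stacking parameters: dH in kcal/mol, dS in cal/(mol K),
# keyed by the 5'->3' dinucleotide on one strand.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# Duplex initiation with a terminal G.C / A.T pair.
NN_INIT <- list(GC = c(dH = 0.1, dS = -2.8), AT = c(dH = 2.3, dS = 4.1))
R_GAS <- 1.987 # cal/(mol K)

#' Melting-temperature model
#'
#' @param method `"nearest_neighbor"` (unified 1998 parameters, the default)
#'   or `"wallace"` (2 degrees per A/T, 4 per G/C; length-naive but
#'   transparent).
#' @param Na_mM monovalent cation concentration (mM); enters the entropic
#'   salt correction `0.368 (n-1) ln[Na+]`.
#' @param primer_uM total oligo strand concentration (uM); the duplex factor
#'   is `CT/4` (non-self-complementary, equal strands).
#' @param expand_cap maximum degenerate expansions averaged over.
#' @return A `tm_model` object.
#' @export
tm_model <- function(method = c("nearest_neighbor", "wallace"),
                     Na_mM = 50, primer_uM = 0.25, expand_cap = 64) {
  method <- match.arg(method)
  stopifnot(Na_mM > 0, primer_uM > 0, expand_cap >= 1)
  structure(list(method = method, Na_mM = Na_mM, primer_uM = primer_uM,
                 expand_cap = expand_cap),
            class = "tm_model")
}

wallace_tm <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

nn_tm <- function(seq, Na_mM, primer_uM) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in chars[c(1, n)]) {
    init <- if (term %in% c("G", "C")) NN_INIT$GC else NN_INIT$AT
    dH <- dH + init["dH"]
    dS <- dS + init["dS"]
  }
  dS <- dS + 0.368 * (n - 1) * log(Na_mM / 1000)
  ct <- primer_uM * 1e-6
  unname(1000 * dH / (dS + R_GAS * log(ct / 4)) - 273.15)
}

#' Melting temperature of an oligo
#'
#' Wallace rule: `Tm = 2 (A+T) + 4 (G+C)`. Nearest-neighbor: unified
#' stacking and initiation parameters with an entropic salt correction and
#' duplex concentration `CT/4`. A degenerate oligo gets the arithmetic mean
#' over all of its concrete expansions (capped by the model).
#'
#' @param sequence a [primer] or IUPAC string, length >= 8.
#' @param model a [tm_model].
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("TCTTGACTAATGAAAACATTCTTGACAA", tm_model("wallace")) # 72
#' @export
melting_temperature <- function(sequence, model = tm_model()) {
  stopifnot(inherits(model, "tm_model"))
  seq <- primer_sequence(sequence)
  if (nchar(seq) < 8L) stop("sequence shorter than 8 nt")
  expansions <- expand_degenerate(seq, cap = model$expand_cap)
  vals <- vapply(expansions, function(s) {
    switch(model$method,
           wallace = wallace_tm(s),
           nearest_neighbor = nn_tm(s, model$Na_mM, model$primer_uM))
  }, numeric(1))
  mean(vals)
}
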