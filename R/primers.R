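# Primer and primer-pair containers, the bundled published oligos, and
# wet-lab ordering metadata for blocking oligos.

#' Construct a primer
#'
#' @param name short identifier (e.g. `"18SV4-F"`).
#' @param sequence IUPAC string, written 5' to 3'.
#' @param role one of `"forward"`, `"reverse"`, `"blocking"`.
#' @param modification_3prime 3'-end modification; blocking oligos are
#'   normally synthesized with a C3 spacer (`"spacer_C3"`) so the polymerase
#'   cannot elongate them.
#' @return A `primer` object.
#' @export
primer <- function(name, sequence,
                   role = c("forward", "reverse", "blocking"),
                   modification_3prime = c("none", "spacer_C3")) {
  role <- match.arg(role)
  modification_3prime <- match.arg(modification_3prime)
  sequence <- toupper(chartr("u", "t", chartr("U", "T", sequence)))
  encode_iupac(sequence) # validates the alphabet
  if (nchar(sequence) < 8L) stop("primer '", name, "' is shorter than 8 nt")
  structure(
    list(name = name, sequence = sequence, role = role,
         modification_3prime = modification_3prime),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  mod <- if (x$modification_3prime == "spacer_C3") " [3' C3 spacer]" else ""
  cat(sprintf("<primer> %s (%s, %d nt)%s\n  5'-%s-3'\n",
              x$name, x$role, nchar(x$sequence), mod, x$sequence))
  invisible(x)
}

#' Construct a primer pair
#'
#' @param forward,reverse [primer] objects with consistent roles.
#' @param marker_name amplified marker, e.g. `"18SV4"`.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward, reverse, marker_name) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (forward$role != "forward" || reverse$role != "reverse") {
    stop("primer roles are inconsistent with their position in the pair")
  }
  structure(list(forward = forward, reverse = reverse, marker_name = marker_name),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F %s\n  R %s\n",
              x$marker_name, x$forward$sequence, x$reverse$sequence))
  invisible(x)
}

#' Published snail-metabarcoding oligo set
#'
#' The universal eukaryotic 18S V4 pair, the 28-nt blocking oligo designed
#' against *Biomphalaria* snails (5' decamer overlapping the reverse primer,
#' 3' C3 spacer), and the bacterial 16S V3V4 pair (341F/805R).
#'
#' @return A list with elements `pair_18SV4` ([primer_pair]), `blocker_18SV4`
#'   ([primer]) and `pair_16SV3V4` ([primer_pair]).
#' @examples
#' ps <- snail_primer_set()
#' nchar(ps$blocker_18SV4$sequence) # 28
#' @export
snail_primer_set <- function() {
  list(
    pair_18SV4 = primer_pair(
      primer("18SV4-F", "CCAGCASCYGCGGTAATTCC", "forward"),
      primer("18SV4-R", "ACTTTCGTTCTTGATYRA", "reverse"),
      marker_name = "18SV4"
    ),
    blocker_18SV4 = primer("18SV4BP", "TCTTGACTAATGAAAACATTCTTGACAA",
                           role = "blocking", modification_3prime = "spacer_C3"),
    pair_16SV3V4 = primer_pair(
      primer("341F", "CCTACGGGNGGCWGCAG", "forward"),
      primer("805R", "GACTACHVGGGTATCTAATCC", "reverse"),
      marker_name = "16SV3V4"
    )
  )
}

#' Synthesis and protocol metadata for a blocking oligo
#'
#' Emits the ordering annotation (3' C3 spacer) together with the wet-lab
#' defaults used with this kind of blocker: a 1.5:1 blocking-to-target primer
#' ratio and a 1.2 uM final concentration in the PCR mix. These fields are
#' inert metadata; nothing is computed from them.
#'
#' @param candidate a [primer], a candidate row from [enumerate_candidates()],
#'   or a bare sequence string.
#' @return A `synthesis_note` list.
#' @export
annotate_synthesis <- function(candidate) {
  seq <- if (is.data.frame(candidate)) candidate$sequence[1] else primer_sequence(candidate)
  structure(
    list(
      sequence = seq,
      order_string = paste0("5'-", seq, "-/3SpC3/-3'"),
      spacer_C3 = TRUE,
      blocking_to_target_ratio = "1.5:1",
      final_concentration_uM = 1.2
    ),
    class = "synthesis_note"
  )
}

#' @export
print.synthesis_note <- function(x, ...) {
  cat("<synthesis_note>\n",
      "  order:          ", x$order_string, "\n",
      "  ratio (BP:primer): ", x$blocking_to_target_ratio, "\n",
      "  final conc:     ", x$final_concentration_uM, " uM\n", sep = "")
  invisible(x)
}
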