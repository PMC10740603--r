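Package: hostblockr
Title: Blocking-Primer Design and In Silico Evaluation for Host rRNA
    Suppression in Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and audit blocking primers that suppress host
    rRNA amplification in eukaryotic metabarcoding. Implements
    mismatch-tolerant, IUPAC-aware in-silico PCR against taxonomically
    annotated reference databases (Silva-style FASTA), per-column Shannon
    entropy profiling of the 3'-terminal amplicon region, constrained
    enumeration of candidate blocking oligos (length, primer overlap,
    melting temperature, host conservation), and in-silico specificity
    scoring of a blocker against host and non-target amplicon sets. A
    seeded simulator of Silva-like reference databases makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
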