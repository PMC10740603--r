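---
title: "Designing host-blocking primers for eukaryotic metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing host-blocking primers for eukaryotic metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Universal eukaryotic 18S rRNA primers amplify whatever eukaryote dominates
the template. When the template is animal tissue -- here, planorbid snails
such as *Biomphalaria* -- the host typically contributes the overwhelming
majority of amplicons and the microeukaryote community is barely sampled.
A *blocking primer* counters this: an oligo complementary to the host
amplicon that overlaps the universal reverse-primer binding site, carries a
3' C3 spacer so the polymerase cannot elongate it, and therefore suppresses
host amplicon production while leaving non-target templates untouched.
`hostblockr` designs such blockers from a taxonomically annotated reference
database (Silva-style FASTA) and audits their predicted specificity in
silico.

## The procedure

`design_blocker()` chains five stages, each independently usable:

1. **Partitioning.** Records whose lineage contains the host clade (e.g.
   `Heterobranchia`) form the host set; records in excluded clades (e.g.
   `Metazoa`) are set aside; the rest are the non-targets against which
   specificity is screened. The host clade takes precedence over exclusion
   because the host is normally nested inside an excluded clade (a snail is
   a metazoan). Clade matching is exact whole-rank and case-insensitive,
   never substring-based, so `Metazoa` cannot accidentally match a rank
   like `Metazoan-like`.

2. **In-silico PCR.** Primer sites are located by sliding the IUPAC primer
   over both strands and counting mismatches under a *set-subset* rule: a
   target symbol matches a primer symbol only when the target's base set is
   contained in the primer's. The asymmetry is deliberate and conservative
   -- a primer `Y` matches a target `T`, but an `N` in a low-quality
   reference matches nothing except a primer `N`. The default tolerance is
   one mismatch per primer, because host clades can differ from universal
   primers at a single diagnostic position (snails do, four bases from the
   reverse primer's 3' end); the tolerance is applied per primer, not
   summed over the pair, and both knobs are exposed. Each reference yields
   at most one amplicon: the best forward site (fewest mismatches, then
   leftmost) paired with the best compatible reverse site that keeps the
   amplicon, both primer-binding sites included, within the configured
   length window (200-600 nt by default for 18S V4).

3. **Terminal-region entropy.** The last `W = 40` nt of each amplicon --
   the reverse-primer site plus the 22 nt upstream of it -- are stacked
   right-anchored at the 3' terminus, and per-column Shannon entropies (in
   bits; the logarithm base is configurable) are computed separately for
   host and non-target rows. Because the region is anchored by the primer
   site itself, positional right-justified stacking stands in for a
   multiple sequence alignment; a pre-aligned FASTA of the region can be
   supplied instead when indels matter. Gaps arising from short rows are
   excluded from the frequencies, and an all-gap column reports a missing
   entropy rather than zero. The design signal is a stretch of columns
   with host entropy near 0 and non-target entropy well above it --
   conserved in the host, variable among microeukaryotes.

4. **Candidate enumeration.** Candidates are windows of the *host
   consensus* (majority base per column; ties go to the lexicographically
   smallest base and are flagged), not per-sequence oligos: one oligo is
   ordered for a whole clade. For every length in 24-32 nt and every
   overlap of 8-12 nt with the reverse-primer site, the consensus window is
   reverse-complemented into an oligo written 5' to 3' on the strand
   competing with the reverse primer. A candidate must pass: mean host
   conservation at least 0.90 over its columns upstream of the primer
   site; a melting temperature within 3 degrees C of the reference; a
   realized overlap inside the configured range; and an off-target blocked
   fraction at or below 1%. Survivors are ranked by
   `host_blocked - lambda * off_target_blocked` with `lambda = 10`: a
   blocker that silences non-targets is worse than one that misses some
   hosts, which is why off-target weight dominates. Ties break by smaller
   `|dTm|`, then larger overlap, making the ranking deterministic.

5. **Specificity.** An amplicon is called blocked when the full-length
   blocker anneals anywhere on it with at most `k_block` mismatches
   (default 0, a strict call; raising `k_block` reproduces looser calls,
   and blocked sets grow monotonically with it). The report gives
   blocked fractions for host and non-target sets and a per-clade
   breakdown of blocked non-targets at a chosen lineage depth.

## Melting temperature

Two models are provided. The Wallace rule, `Tm = 2(A+T) + 4(G+C)`, is kept
for transparency and closed-form tests; it ignores length and stacking
effects and overshoots badly for long AT-rich oligos (the bundled 28-nt
blocker: 72 C by Wallace versus 54 C by nearest-neighbor). The default is
nearest-neighbor thermodynamics with the unified 1998 stacking and
initiation parameters, an entropic salt correction
`0.368 (n-1) ln[Na+]` at 50 mM monovalent cations, and duplex factor
`CT/4` at 0.25 uM total strands. Degenerate oligos are averaged over their
concrete expansions (capped at 64 by default).

The Tm constraint is referenced to the **mean of the forward and reverse
primer Tms** rather than the reverse primer alone. The aim of the
constraint is an oligo that competes at the annealing temperature chosen
for the primer *set*; concretely, the bundled published blocker sits 1.6 C
from the 18S V4 pair mean but 8.4 C above the reverse primer alone, so a
reverse-only reference with a tight tolerance would reject the very design
it is meant to reproduce. The reference is configurable
(`tm_reference = "reverse"` restores the single-primer comparison).

## What the simulator emulates

`simulate_refdb()` generates Silva-like databases for testing every stage
without downloads. A uniform-ACGT ancestor carries one fixed concrete
expansion of each primer site at fixed offsets; host records substitute at
0.005/site outside the primer sites (and outside the terminal 40 nt when
terminal conservation is on), non-targets at 0.15/site outside the primer
sites, and decoys are unrelated random sequences without sites.
Substitutions are i.i.d. uniform over the three alternative bases
(Jukes-Cantor-like); there are no indels by default, since the anchored,
ungapped design procedure would only exercise its gap-padding path through
them. Two deliberate planted features mirror the biology the method
exploits:

* every host record carries one fixed transition at the 4th position from
  the reverse primer's 3' end -- the host clade's diagnostic mismatch
  against the universal primer, which both necessitates the one-mismatch
  PCR tolerance and, because the consensus blocker carries the host base
  there, makes the blocker intrinsically host-specific at `k_block = 0`;
* the 22-nt design region upstream of the reverse-primer site is a fixed
  AT-rich sequence (the reverse complement of the bundled blocker's 3'
  18-mer plus pad), planted like the primer sites themselves. A design
  region drawn uniformly at random would, in a substantial fraction of
  simulations, admit *no* oligo whose Tm is compatible with the AT-rich
  18S V4 primer set -- a database that does not emulate a system in which
  a valid blocker exists, as the real one does. Fixing the region keeps
  the planted truth exact for the test oracles.

What passing simulated tests does **not** show: robustness to indels and
alignment error in real references, to chimeric or partial Silva records,
to rate heterogeneity along the gene, or to hosts whose terminal region is
genuinely polymorphic. The entropy profile is the diagnostic to inspect on
real data before trusting a design.

## Numerical and interface choices

* Coordinates are 1-based closed intervals on the sense strand, matching
  the host R/Bioconductor ecosystem; mismatch positions are 1-based and
  primer-relative.
* All tie-breaks (consensus bases, candidate ranking, site pairing) are
  deterministic and documented; identical inputs and configuration give
  byte-identical outputs for every `cmd_*()` command.
* Degenerate-expansion order is lexicographic; the simulator plants the
  first expansion.
* Read-partition summaries use the sample (n-1) standard deviation --
  these tables typically hold a handful of samples.
* The command layer rejects unknown configuration keys and echoes the
  fully resolved configuration next to its outputs.

Problem sizes used by the bundled tests: databases of 100 host + 100
non-target records (1800-nt ancestors) for end-to-end recovery over 20
seeds, 500 random sequences for oracle-equivalence checks of the matching
engine, and miniature 19-record databases for command reproducibility.

## Known limitations

* Block calls are binary annealing predictions; partial elongation arrest,
  clamp chemistry and annealing kinetics are out of scope, as are hairpin
  and dimer screens of candidates.
* The headline published fractions (about 75% of host amplicons blocked,
  under 1% of non-targets) were computed on a specific Silva release with
  an unstated block-call criterion; they are inputs for context, not
  quantities this package can reproduce without that database snapshot.
  The wet-lab blocking:target ratio (1.5:1) and final concentration
  (1.2 uM) are carried only as inert synthesis metadata.
* No multi-amplicon-per-reference mode; references are taken as shipped
  (no re-clustering, no flank trimming).
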