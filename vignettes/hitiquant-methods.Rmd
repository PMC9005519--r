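---
title: "Quantifying homology-independent targeted integration: models and methods"
author: "hitiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying homology-independent targeted integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitiquant)
```

## The problem

Homology-independent targeted integration (HITI) inserts a promoterless
donor cassette at a Cas9 cut site through non-homologous end joining
(NHEJ). The donor is flanked by *inverted* copies of the genomic target
site (protospacer + PAM placed in reverse complement), so that Cas9
releases the cassette from the vector, and so that the two possible
ligation outcomes differ sharply: forward integration destroys both
half-sites and is stable, while inverted integration regenerates two
intact sites and is cut again. The cassette itself carries STOP codons in
all three reading frames (to silence the endogenous gene regardless of
junction INDELs), a translation start (kozak or a short IRES), the
therapeutic CDS, and a polyA signal.

`hitiquant` implements the sequence-level computations such an experiment
needs, end to end, against synthetic data generated by its own simulator:
donor construction and re-cleavage prediction, read simulation for three
assay designs, an internal CIGAR-emitting local aligner, windowed INDEL
quantification, dual-amplicon estimation of the integrated-allele
fraction, junction precision classification, split-read integration-site
detection, and Hardy-Weinberg genotype prediction.

## Coordinates and the cut model

All coordinates are 0-based, half-open. For a guide placed on the plus
strand, the blunt SpCas9 cut falls `cut_offset` (default 3) nt on the
5' side of the PAM, i.e. between protospacer positions 16 and 17;
`cut_pos` names the first base 3' of the cut on the top strand, so the
edited allele is `ref[0, cut_pos) + insert + ref[cut_pos, end)`. On the
minus strand the same arithmetic is mirrored through the reverse
complement. Cuts are modeled blunt with no end resection: the "precise"
ligation model is exact concatenation, and junction INDELs are introduced
only by the simulator, where they are part of the declared ground truth.

Guide placement (`place_guide()`) demands a unique exact
protospacer+PAM match over both strands; `N` in a reference never
matches. Re-cleavage (`is_recleavable()`) likewise uses exact protospacer
matching plus an IUPAC PAM pattern: the inverted-site logic of the donor
design is exact-site logic, and mismatch-tolerant off-target scoring is
deliberately out of scope.

## Donor anatomy and the re-cleavage asymmetry

`build_donor()` assembles
`inverted site | STOPx3 | START | CDS | polyA | inverted site`
and enforces: both flanks equal to `revcomp(protospacer + PAM)`; a STOP
codon in each frame with at least six total; a CDS beginning ATG; and a
2,700-nt cassette cap, the practical AAV payload bound for this design.
The default STOP cassette is `TAATTAATTAATAATTAATTAA` (six TAA codons
covering the three frames in 22 nt); the kozak element defaults to the
`GCCACC` consensus, and the IRES element is a fixed 50-nt placeholder --
at the sequence-analysis level only the element's length and presence
matter, and both strings are configurable.

`predict_integration()` cuts the locus and both donor flanks at their
blunt positions and ligates the released core either forward or
inverted. The flank cut position is orientation-aware: an inverted flank
presents the guide on the donor's minus strand and is cut
`pam_len + cut_offset` into the flank; a direct-orientation flank (a
design error the validator flags) is cut `20 - cut_offset` in. With
inverted flanks the forward allele carries
`P[0:17] | revcomp(P[0:17])` at the 5' junction -- no site on either
strand -- while the inverted allele regenerates `P + PAM` at both
junctions. These are theorems of the construction, and the test suite
verifies them over hundreds of random guides.

## The simulator: what it emulates and what it does not

`simulate_alleles()` draws an outcome per allele from a six-class
mixture: unmodified, NHEJ INDEL, precise HITI, imprecise HITI (junction
INDELs), inverted HITI, and vector-fragment capture (a random 50-500-nt
piece of the mock AAV genome, whose 145-nt ITR placeholders mirror the
canonical ITR length). NHEJ INDEL lengths follow a truncated geometric
distribution over 1-50 nt with a 3:1 deletion:insertion ratio -- no
empirical length distribution is assumed; this default was chosen once
for realistic small-deletion dominance and is fully configurable,
including a degenerate "fixed" model used to plant known junction
species. Every allele stores its base form and event list, and
`rebuild_allele()` re-derives the sequence exactly; this truth-label
consistency is asserted in tests.

Three read generators emulate the assay designs the package targets:

* `simulate_amplicon_reads()` -- paired-end 150-nt reads from amplicons
  cut out by primer coordinates, with a forward primer shared between the
  wild-type and hybrid products. Where several reverse primers could
  prime, the shortest product wins, which reproduces the allele
  specificity of the real assay (the hybrid reverse primer sits in the
  payload and cannot prime on wild-type alleles; the genomic reverse
  primer yields an unamplifiably long product on integrated alleles).
* `simulate_junction_reads()` -- single-end reads generated at 600 nt and
  truncated to 350 nt, emulating the read-trimming step of the junction
  assay.
* `simulate_capture_reads()` -- reads drawn from a mock genome with
  start-position mass proportional to an enrichment factor inside the
  regions of interest (default 50x, a free parameter documented as
  such), plus fully-enriched episomal vector molecules. Chimeric
  host/donor reads arise naturally at integration sites.

The error model is substitution-only (uniform per-base rate, default 0)
so that every INDEL call is attributable to a simulated editing event;
an INDEL-free error model also means the suite's recovery tests measure
the estimator, not error-correction heuristics. Qualities are constant
Q30 and unused downstream. The simulator does not model PCR bias or
chimeras, duplicates, quality decay, or reference variation -- so a
passing recovery test demonstrates correctness of the quantification
logic under clean sampling noise, not robustness to every real-data
artifact.

All randomness flows through explicit `seed` arguments; identical
configuration yields byte-identical FASTQ output, which the suite checks.

## The internal aligner

`align_local()` is an affine-gap Smith-Waterman (Gotoh) aligner written
in C++ that reports a CIGAR over `M/I/D/S`, with unaligned query ends
emitted as soft clips and both strands tried (plus strand wins ties). A
gap of length $k$ costs $O + kE$. Two presets are provided:

* `preset_default()` (match 2, mismatch 4, gap open 6, extend 1) for
  amplicon reads that legitimately carry editing INDELs;
* `preset_strict()` (match 1, mismatch 50, gap open 60, extend 10,
  min score 20) -- a transcription of a BWA-MEM-style near-exact-match
  regime (`-B 50 -O 60 -E 10`-class parameters) into local-alignment
  scores, for donor-detection alignments: extension across any divergence is
  unprofitable, so chimeric reads split cleanly into a matched segment
  and soft clips.

Numerical conventions: among equal-scoring alignments the smallest
reference *end* coordinate wins (for equal-length candidates this
coincides with the smallest start), and gap runs are extended in
preference to reopened during traceback, which left-shifts INDELs -- the
variant-calling convention. A full-length exact substring match is
detected by string search before the DP runs; this is exact, because
under zero clip penalty no alignment can out-score a full-length exact
match, and the first occurrence has the smallest end. Scores are checked
against an independently written brute-force DP oracle over random short
sequence pairs in the test suite. Per-base quality scores are ignored by
design, and only the single best local hit is reported -- the downstream
procedures consume the partial-vs-full classification and the event
list, not multi-hit structure.

## Windowed INDEL quantification

A read is *modified* if any CIGAR I/D event overlaps the evaluation
window `[cut - flank, cut + flank)`, with `flank = 17` nt by default --
the window is read as 17 nt upstream *and* 17 nt downstream of the cut
(a 34-nt interval), following the phrasing "upstream and downstream of
the cleavage site"; the alternative reading (17 nt total) is rejected.
Deletions occupy `[pos, pos + len)`; insertions are zero-width at their
ligation point and count when they touch the window boundary.
Substitutions never count as modified: the quantification is
INDEL-defined. Reads whose alignment does not span the full window are
excluded from the denominator, so frequencies are over informative reads
-- a documented design choice of this package (frequencies must be over
reads that could have shown the event), as is the matching choice in
`classify_junctions()` (exposed as `denominator = "window"` / `"all"`).

`dual_amplicon_hiti()` assigns each pooled read to the wild-type or
hybrid reference by best alignment score (ties are excluded as
ambiguous), counts hybrid-assigned reads as HITI, and sub-classifies
wild-type-assigned reads through the window rule. The estimator tracks
the true integrated fraction within binomial read-sampling noise across
fractions from 1% to 20% (tested at n = 10,000 reads).

`classify_junctions()` groups junction-read events into (type, length)
species and drops species below the tissue threshold: 0.1% for retina,
0.5% for liver, both *inclusive* (a species at exactly the threshold is
kept, per the "frequency >= than" rule). The filter is idempotent.

## Split-read integration detection

`find_insert_reads()` aligns capture reads to the donor insert with the
strict preset. Full-length alignments (total clip at most 5 nt) are
insert-only evidence (episomal or concatemeric vector); partial
alignments are split into the aligned insert portion and the clipped
flank portion, kept only if strictly longer than 22 nt and 30 nt
respectively ("longer than" is implemented as strict inequality). When
both ends are clipped the larger clip is taken as the flank -- the source
procedure leaves this case open; the alternative (keeping both clips)
would double-count reads. `realign_flanks()` then assigns each flank to
the best-scoring reference among the vector genome and the host
chromosomes; ties are excluded as ambiguous. On seeded simulations the
tally recovers the true integration chromosome and assigns zero evidence
to decoy chromosomes (bounded below 0.1% of reads in the tests).

On-target counting (`ontarget_insert_frequency()`) keeps reads whose
insert alignment is partial *and* covers the insert's first 10 nt (the
5' anchor, strand-aware), realigns them to the target gene, and counts
those overlapping the cleavage region. The package reports both the raw count and a
frequency whose denominator is all reads overlapping the cleavage
region -- the denominator is a documented choice of this package.

## Hardy-Weinberg genotype prediction

`hw_genotypes()` computes the multi-allelic table
$f(i,i) = p_i^2$, $f(i,j) = 2 p_i p_j$. `heterozygote_adjust()` encodes
the halving assumption for heterozygous mutants: allele frequencies
measured in homozygous wild-type tissue keep their edited-class values,
while the wild-type frequency is halved and the other half is assigned
to the mutant allele (86% wild-type becomes 43% + 43%). Because the
wild-type plus mutant mass equals the original wild-type mass, the
edited classes are unchanged up to renormalization; keeping their mutual
proportions fixed is the package's documented assumption for the general
case.

## Problem sizes and reproducibility

The analysis scripts under `analysis/` run the whole pipeline at desk
scale: 2,000-allele populations, 8,000 amplicon reads, 2,000-3,000
junction reads, and 1,500 capture reads over a 3-kb-per-chromosome mock
genome -- sizes chosen so each stage completes in seconds while leaving
every frequency estimate comfortably inside its sampling tolerance. The
acceptance script scales the dual-amplicon recovery to 50,000 reads. For
that script's 5%-recovery computation the allele pool is built with an
exactly 5% integrated composition (rather than a multinomial draw), so
the quantity it reports is the estimator's value when the true fraction
*is* the nominal one; the test suite separately exercises the multinomial
generator and compares against the realized fraction.

## Known limitations

* Exact-match site logic: guides with near-cognate off-target sites in a
  real genome need an external off-target candidate list; the package
  only evaluates given loci.
* The aligner is a full-matrix DP intended for amplicon-scale references
  (up to a few kb); it is not a seeded genome aligner.
* Inverted-HITI alleles are invisible to the dual-amplicon assay design
  (their reads classify as wild-type-like or are excluded), mirroring
  the real assay's blind spot; the junction and capture assays are the
  instruments that see them.
* The simulator's clean error model understates real-data artifact rates;
  conclusions about robustness to PCR chimeras or sequencing INDELs are
  out of scope.
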