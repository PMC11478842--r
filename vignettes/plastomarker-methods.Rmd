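---
title: "Methods and design notes for plastomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plastomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, estimators and design decisions behind
`plastomarker`, the assumptions they make, and what the package's tests do
and do not establish.

## Coordinates and containers

All internal coordinates are 1-based closed intervals on the linearized
circular genome — the R/Bioconductor convention shared by GenBank, VCF and
IRanges. A feature that wraps the linearization origin is split into two
parts and flagged (`wraps = TRUE`); the origin-split is never counted as an
intron. The canonical linearization places the LSC first
(`canonicalize_plastome()`), matching the conventional plastome
presentation. Alignments are stored as character matrices (rows =
accessions), which keeps every column-wise operation a vectorized base-R
expression; a `column_map` ties alignment columns to ungapped reference
coordinates.

## Quadripartite partition detection

The inverted-repeat pair is found by seeding exact k-mer matches (default
k = 25) between the sequence and its reverse complement and extending every
seeded anti-diagonal to its maximal identity block, working on the circle so
origin-spanning repeats are caught. Exact identity is the default
(`max_mismatch_frac = 0`): assembled plastomes emit two identical IR copies,
and the maximal *exact* block is then a well-defined, reproducible boundary.
A consequence worth knowing: if the base just outside a junction happens to
complement-match its anti-diagonal partner, the maximal block — and hence
the reported boundary — extends past the "annotated" one. This is a
property of the definition, not a bug; the simulator makes its planted
boundaries exactly maximal so that recovery can be tested to the base.
When two candidate pairs tie in length, the pair maximizing the shorter
single-copy region wins (a tie-break that favours the canonical
quadripartite reading over degenerate nestings). Genomes without an IR of
at least `min_ir_len` (default 1000 bp) raise a condition of class
`noIRFound`, which callers such as `junction_report()` treat as "IR-lacking,
skip with a note".

Junction reports locate, for each of the four region boundaries, the
overlapping or nearest feature and the bases of that feature on either side
of the junction; a same-named feature shorter than the longest copy of that
gene in the record is flagged as a pseudogene fragment (the classic
junction-duplicated fragments at the boundaries of the IR).

## Variation statistics

SNPs are called per query accession against the designated reference row:
every column where both rows carry A/C/G/T and differ yields one record, so
multi-nucleotide stretches count one SNP per position. Transitions are
purine–purine or pyrimidine–pyrimidine changes; everything else is a
transversion. Indel events are maximal one-sided gap runs; columns gapped
in both rows are ignored entirely and do not split an event.

Nucleotide diversity π is the average over all row pairs of
differences / usable sites, a site being usable for a pair when both rows
carry a base (pairwise deletion). Pairwise deletion rather than complete
deletion was chosen because spacer alignments are gap-rich and complete
deletion would discard most of their signal. No Jukes–Cantor correction is
applied to π or to p-distances: at plastome-scale divergences the raw
proportion is what the field's sliding-window tools report. Windows tile
the alignment columns; the default window of 100 columns steps by its own
width (non-overlapping), because only a window size — not a step — is
conventionally stated, and non-overlapping tiling makes window counts and
totals unambiguous. Both parameters are configurable.

Hotspot ranking sorts loci by π (descending), breaking ties by mutation
count and then name. The per-locus "mutation count" is the number of
distinct polymorphic columns plus distinct indel events, since the two are
conventionally pooled in hotspot tables; indel diversity is the mean over
row pairs of pairwise indel events per aligned locus column. Both
conventions are stated here precisely because published tables rarely
define them.

## Repeat cataloguing

**Microsatellites.** A reported SSR is a maximal perfect tandem run of an
aperiodic 1–6 bp unit meeting the copy thresholds 7/4/3/3/3/3 (mono- to
hexanucleotide). "Maximal" means not extendable by one position on either
side; "aperiodic" means the unit is not itself a repetition of a shorter
unit, so a poly-A run is never re-reported as an AA dinucleotide repeat.
Runs are truncated to whole copies from the run start, Ns break runs, and
the reported motif is the lexicographically minimal rotation of the unit
(TA runs report as "AT"). Compound/interrupted SSRs are not merged into
single calls: no interruption distance is part of the stated thresholds, so
each perfect run is reported separately. The finder is exactly equivalent
to a brute-force scan over every (start, period) pair; that equivalence is
a standing property test.

**Dispersed repeats.** The four orientations are reductions to one
alignment geometry: comparing the sequence against itself (forward, F),
its complement (C), its reverse (R) or its reverse complement (palindromic,
P) turns each repeat pair into a run on one (anti-)diagonal. A reported
pair is a per-diagonal *maximal window*: at most `max_mismatch` (default 3)
mismatches, at least `min_len` (default 30) columns, exact matches at both
ends, and not extendable in either direction within the budget. Pairs whose
both occurrences nest inside a longer reported pair of the same kind are
suppressed, and results are capped (default 500) by descending length.
Detection seeds exact k-mers shared between the sequence and its transform:
seed 7 makes the scan *provably* equivalent to the brute-force all-pairs
scan for the default thresholds (a 30 bp window with ≤3 mismatches always
contains an exact 7-mer), and is the default up to 20 kb. Full plastomes
use seed 14 for speed; a missed repeat would need ≥30 bp with no 14 bp
exact stretch, which near-identical organellar repeats do not exhibit. All
oracle-equivalence tests run in the exact regime.

**Tandem arrays.** A bespoke period scan (this is deliberately *not* a
Tandem Repeats Finder re-implementation, and TRF's alignment scores are not
emulated): for each period the sequence is compared with itself shifted by
that period; exact-agreement runs long enough to belong to a real array
seed candidates, which grow across neighbouring runs while total
disagreements stay within `max_mismatch_frac` (default 0.2) of the covered
window plus one period. Arrays shorter than 22 bp, with fewer than 2
copies, or whose consensus unit self-agrees at a shift in the SSR range
(≤ 6) are dropped; overlapping calls at different periods keep the longest
span. Because growth is greedy within the budget, a call may absorb
flanking near-agreement and so exceed the planted array by a fringe — the
invariant each call must satisfy is the budget itself, not perfect
identity.

Attribution assigns each call its LSC/SSC/IR region and CDS/intron/IGS
class by span midpoint, flagging junction-straddling calls; dispersed
repeats are attributed per occurrence.

## Codon usage and Ka/Ks

The plastid/bacterial genetic code (table 11) is used throughout. RSCU is
the observed codon count divided by its family's count under uniform
synonymous usage; stop codons form their own family, and third-position
base composition is reported alongside (plastome CDSs shift toward A/T
there). Amino acids are grouped by a fixed hydropathy/charge convention:
acidic {D, E}, basic {K, R, H}, hydrophobic {A, V, L, I, P, F, M, W},
hydrophilic {S, T, C, N, Q, Y}, neutral {G}.

Ka/Ks follows Nei–Gojobori (1986): per-codon synonymous site fractions
averaged over both sequences; observed synonymous/nonsynonymous differences
averaged — unweighted — over all minimal mutational pathways per codon,
excluding pathways through stop codons (all pathways are used only when
every one is blocked); changes *to* stop codons count as nonsynonymous in
the site calculation, and stop codons themselves are excluded. The
Jukes–Cantor correction −3/4·log(1 − 4p/3) is applied to both proportions
and is undefined at p ≥ 3/4 (flagged). Selection classes follow the ratio:
positive above 1, neutral at 1, purifying below; Ks = 0 with Ka > 0 is
classed positive by logged convention, 0/0 is undefined. The gene-set mean
ratio is the unweighted mean over genes with a defined ratio — a stated
convention, since summary tables rarely define theirs. Site-model tests
(FUBAR/MEME/BUSTED-style) are deliberately out of scope; the counting
method is the implemented analogue.

## Diagnostic markers and in-silico PCR

A diagnostic SNP column requires (i) the same base in *every* target
accession — intraspecific fixation, the robustness argument for markers
that must survive within-species variation — (ii) that base in *no*
background accession, and (iii) no gap or N anywhere in the column. Flank
conservation (invariant columns within ±25) is attached and thresholded at
0.8 by default; both numbers are configurable, as "conserved flanks" has no
canonical value.

Primer design is exhaustive and deterministic: ordered pairs of diagnostic
SNPs whose spacing fits the product range (default 300–2500 bp) anchor a
forward and a reverse primer, each built from target-genome sequence ending
3′ exactly on the diagnostic allele, with every non-anchor position
required to be invariant across all accessions — so the anchor is the
*only* discriminating base. Candidates are filtered by length (18–27),
GC (35–65%), and nearest-neighbor Tm (52–62 °C; SantaLucia 1998 unified
parameters with the entropic salt correction at 50 mM monovalent salt,
500 nM primer), and ranked by Tm balance plus flank conservation. The
control pair is drawn from maximal runs of fully invariant columns near a
target product size (default 400 bp) and must amplify exactly once from the
reference genome — a guard against placing both primers inside the IR,
which would amplify from both copies.

In-silico PCR binds a primer wherever the full-length alignment has at most
2 internal mismatches and — the allele-specific rule — zero mismatches in
the 3′-terminal 3 bases. Allele specificity is therefore modelled purely by
3′ exclusion, with no thermodynamic mismatch penalties: that is the
qualitative mechanism of allele-specific PCR assays, and it is what the
package's end-to-end specificity property tests (all target accessions
amplify, no background accession does, the control amplifies everywhere).
Both template orientations are scanned and circular templates are handled
by a wrap appendix.

## The simulator: what it emulates, and what it does not

The generator states a world patterned on a small *Plantago*-like plastome
family: a 150 kb quadripartite genome (LSC 83 kb, IR 25 kb, SSC 17 kb) at
38% GC; six accessions of five species (two conspecific target accessions;
a divergent reference) on a fixed tree with plastome-scale branch lengths;
IR mutation rate one tenth of the single-copy regions (concerted
evolution); a Ts:Tv kernel at 1.2; indels at 0.15 events per substitution
with geometric lengths of mean 8 (matching the observed indel:SNP ratio of
roughly one to seven); ten SSR loci with one-unit slippage; twelve planted
diagnostic columns, two of them spaced for a ~1.8 kb amplicon inside an
rpoC2 / rpoC2–rpoC1 marker region; and a 9 kb IR expansion in the
*P. maritima*-like accession that captures the SSC tail gene cluster
(ndh genes, rps15, ycf1), duplicating them into the IR.

Implementation choices that define the stated world precisely:

* Evolution happens on the true alignment — substitutions and deletions in
  an ancestor coordinate frame, insertions as new columns inherited by all
  descendants — so variation-stage tests isolate the statistics from
  aligner behaviour. Inserted material does not evolve further.
* The genome is generated on a reduced frame (LSC + IRb + SSC) and IRa is
  appended as the exact reverse complement of the realized IRb, so IR
  mutations are concerted by construction. The IR expansion and SSR
  slippage are applied per accession on the realized sequences rather than
  evolved along internal branches; the captured SSC tail evolves at the SSC
  rate until capture.
* Planted IR boundaries are made exactly maximal (the bases just outside
  each junction are resampled so they cannot complement-extend the repeat)
  and junction-adjacent positions are masked from mutation, so partition
  recovery can be asserted exactly rather than approximately.
* Diagnostic columns and their ±30 bp flanks are mutation-masked; target
  rows are forced to the diagnostic allele and background rows to the
  ancestral base. When the target species has two or more accessions,
  substitutions shared by the whole target clade (stem-branch mutations)
  would satisfy the diagnostic predicate by accident; one target accession
  is reverted to the reference allele at such columns so the planted set is
  exactly the diagnostic truth. With a single target accession every
  private substitution is genuinely diagnostic and no scrubbing occurs.
* Determinism: `simulate_plastome_family()` seeds once from the
  configuration; identical configurations are byte-identical, and the truth
  report regenerates bit-for-bit.

What a green test does **not** establish: the simulator produces no
alignment error (real pipelines realign and misalign), no rate variation
within a region beyond the three-region multipliers, no codon-aware
selection inside the family simulator (a separate CDS-pair generator with a
planted dN/dS ratio backs the Ka/Ks recovery tests), no recombination, no
RNA editing, and no base-compositional drift. Estimator behaviour under
those real-data features is outside the tested envelope.

Calibration is checked against an exact expectation, not a hand-waved one:
the per-pair probability of a site difference is computed by composing the
per-branch kernel matrices along the two MRCA-to-tip halves of each pair's
path, weighting regions by their (doubled, for the IR) unmasked site
counts, and adding the planted diagnostic terms; across 20 seeds the mean
observed π must sit within three standard errors of that value. The
calibration world switches off indels and slippage — it calibrates the
substitution estimator, and indel columns would merely dilute π by a
seed-dependent amount — and uses one accession per species so the
diagnostic scrubbing never perturbs the process.

## Numerical and degenerate-input conventions

GC fractions exclude Ns from the denominator and are NA on empty ranges
(flagged). π is NA for windows without a usable pair. Zero-length or
featureless genomes annotate as all-IGS; a featureless junction report is
empty. Overlapping features resolve by precedence CDS > tRNA/rRNA >
pseudogene with a warning. VCF output is minimal v4.2, sorted on write,
with REF always the reference-row base. Ties in hotspot ranking and primer
ranking are broken deterministically (mutation count then name; score then
input order), so every pipeline output is reproducible byte-for-byte.
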