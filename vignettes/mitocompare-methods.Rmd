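---
title: "Methods and design of mitocompare"
author: "mitocompare maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

## Scope and data model

`mitocompare` analyses annotated circular fungal mitochondrial genomes.
Fungal mitogenomes carry a conserved gene complement — 14 oxidative-
phosphorylation protein-coding genes (PCGs), the ribosomal protein gene
*rps3*, two rRNAs (*rnl*, *rns*) and a tRNA set — but vary enormously in
size, mostly through mobile group I/II introns and the homing-endonuclease
ORFs (LAGLIDADG, GIY-YIG) they encode. The package quantifies that
variation: composition and strand skews, region partitioning, codon usage,
repeats and microsatellites, substitution rates and selection, intron
position classes, and gene arrangement.

The central container is the `annotated_genome`: an ordered list of
top-level features (PCG / tRNA / rRNA / ORF) with nested introns and
intronic ORFs. Coordinates are 1-based and inclusive throughout, matching
the convention of printed annotation tables; no top-level feature may wrap
the origin (a restriction that holds for the genomes this package was built
around, and is enforced at parse time). Validation distinguishes hard
errors (out-of-bounds coordinates, overlapping top-level features,
overlapping introns) from warnings that printed annotation tables are known
to contain: intronic ORFs spilling a few bp over their host intron boundary
and PCGs whose exonic length is not a codon multiple. Splicing a
frame-violating PCG still fails loudly.

A genome without sequence ("table-only") is first-class: everything derived
from coordinates alone (gaps, partition, gene order, intron statistics)
works, and sequence-dependent stages are skipped with explicit markers.

## Composition and region partitioning

Strand skews are computed on the forward strand as deposited:
AT-skew = (A − T)/(A + T), GC-skew = (G − C)/(G + C). A zero denominator
yields an explicit `NA`, never a silent 0; `N` bases count toward length
but are excluded from percentages and skews.

`region_partition()` assigns every base to exactly one of six exclusive
categories: `pcg_exon`, `intron` (intronic ORFs folded in — they are part
of the intron's bases, and a separate drill-down via
`intronic_orf_summary()` lists them without affecting the partition),
`trna`, `rrna_exon`, `free_orf`, `intergenic`. The categories always sum
to the genome length. Between two genomes, `contribution_rates()`
decomposes the total size difference as
(size difference of region) / (size difference of genome) × 100 per
category; the percents sum to 100 whenever the totals differ, and the
comparison of equal-sized genomes is reported as undefined rather than a
division by zero.

## Codon usage and RSCU

Codon counting and RSCU run under any numbered NCBI genetic code; the
default is code 4 (mold mitochondrial), where `TGA` encodes tryptophan and
only `TAA`/`TAG` are stops. The synonymous family structure is derived
programmatically from the code table — under code 4, tryptophan is a
two-fold family — never hard-coded. RSCU(c) is the family size times the
codon's share of its family; unused families are `NA`, and within any used
family the RSCU values sum to the family size by construction. Codons
containing `N` are excluded from counts and tallied separately. The
genome-level table pools all protein-coding features (typical PCGs plus
free-standing ORFs) by default, with a flag restricting to the typical
PCGs.

## Repeats and SSRs

`find_repeats()` reports maximal repeat pairs in four orientations —
forward (sequence vs itself), reverse, complement, and palindromic
(reverse complement) — with a Hamming mismatch budget, following the
REPuter parameterization (minimum length 30 bp, at most 3 mismatches, hit
cap 5000). A hit is *maximal* when it cannot be extended on either side
without exceeding the budget or leaving the sequence. The core is an exact
per-diagonal scan in C++: every diagonal of the comparison is swept once
and maximal windows are enumerated between blocking mismatches. An exact
scan was chosen over seed-and-extend because on AT-rich mitogenome-scale
sequences the short exact seeds that a pigeonhole argument allows
(⌊30/4⌋ = 7-mers) occur on essentially every diagonal, so seeding prunes
nothing while complicating the completeness argument. The scan is
quadratic; at the tens-of-kilobases scale of fungal mitogenomes it runs in
seconds. `min_length` values below 8 are rejected as degenerate
parameterizations. Circular analysis is off by default (linear REPuter
semantics); `circular = TRUE` appends a wrap pad of `min_length - 1` bp
and maps hits back onto the circle.

Maximality has one consequence worth stating for planted-truth testing: a
planted imperfect copy with m < 3 mismatches sits inside a *larger*
maximal window that absorbs up to 3 − m mismatching flank bases, so the
planted window is recovered by containment, not coordinate equality. A
copy planted with the full mismatch budget and extension-blocking flanks
is the unique maximal window and is recovered exactly; the generator and
tests use both regimes.

`find_ssrs()` is MISA-style: maximal perfect tandem runs of 1–6 bp units
with per-unit copy thresholds (defaults 10/6/5/5/5/5 — MISA's canonical
thresholds, adopted because the run parameters themselves are tool
defaults rather than published choices; they are configurable). Only
complete copies count, so span = unit × copies. Runs whose motif is itself
periodic are suppressed (an `AT` run is not additionally reported as
`ATAT`); motif classes are the lexicographic minimum over rotations of
both strands, e.g. `AAT/ATT`. Two runs separated by at most 100 bp — the
compound-SSR interruption distance — share a compound group.

## Substitution rates and selection

`align_codons()` aligns the two translated proteins globally
(BLOSUM62, affine gaps with opening 10 ≫ extension 0.5, via Biostrings)
and back-maps the alignment onto codons, dropping gap columns. K2P runs on
all nucleotide columns of that codon alignment (all three codon
positions): with transition fraction P and transversion fraction Q,
d = −½ ln((1 − 2P − Q)·√(1 − 2Q)); a non-positive log argument (saturation)
yields `NA` with a diagnostic rather than an error.

Ka/Ks follows Nei–Gojobori (1986), authored here rather than delegated:

* **Sites.** Per codon position, the denominator of the synonymous
  fraction is the number of single-nucleotide changes that do not create a
  stop — stop-creating changes are excluded from the mutational
  opportunity — and each position contributes one site, so S + N = 3 per
  codon. Site counts are averaged over the two sequences.
* **Differences.** For codons differing at several positions, all minimal
  pathways are enumerated and weighted equally; pathways through stop
  codons are discarded. If every pathway crosses a stop, the codon pair is
  excluded from the counts and reported in an `unresolved` tally.
* **Correction.** Jukes–Cantor, d = −¾ ln(1 − 4p/3), applied to pS and pN;
  omega = Ka/Ks is `NA` when Ks is 0 or a correction saturates.

The per-code lookup tables (sites per codon; pathway-averaged differences
for all 64 × 64 pairs) are computed once per genetic code and cached. The
test suite checks every sense-codon pair against an independent recursive
pathway enumerator. Selection labels derive from omega against 1 with a
1e-9 neutrality tolerance. Exact numeric parity with any particular
desktop tool's Ka/Ks variant is not a goal; NG86 is the documented
estimator.

## Intron position classes

Introns inserted at the same position of a reference CDS form one position
class (Pcl) and are treated as homologous. The insertion-site convention —
stated explicitly because both flanks are defensible — is the **reference
coordinate of the exonic nucleotide immediately 5′ of the intron** in the
spliced CDS, which reproduces names of the familiar `P731` form and maps
an intron after species-CDS position 212 of a self-referenced gene to site
212. Prefixes encode the intron's own group: `P` for group I (including
derived forms), `S` for group II, `U` for unknown; the prefix stays tied
to the group label even where published matrices occasionally rename a
class by one species' reclassified copy. Mapping uses the protein-guided
alignment above; species positions inserted relative to the reference map
to the nearest aligned reference position 5′-ward and are flagged as not
exactly mapped, and a reference below 50% amino-acid identity is rejected
as unsuitable. Homology is exact site equality after mapping.

Across species, a Pcl present in strictly more than one fifth of the
species is *common*, otherwise *rare* — at 22 species the boundary is
4.4, so 5 carriers are common and 4 are not.

## Gene arrangement

The arrangement uses 17 markers: the 15 core PCGs (including *rps3*, which
is promoted to a slot even when annotated as an ORF inside an *rnl*
intron, as is common in this family) plus the two rRNAs. Orders are
canonicalized to start at *rnl* on the forward strand (reflecting and
sign-flipping first if *rnl* is reversed); canonicalization is idempotent
and invariant under rotation and reflection. The single rearrangement
metric is the signed circular breakpoint distance restricted to shared
markers, with an adjacency (u, v) identified with (−v, −u); event-level
inference (inversions, translocations) is out of scope. Comparisons with
fewer than three shared markers are undefined.

## The synthetic-data generator

`generate_genome()` emits a circular genome realizing a declared plan plus
a truth manifest, so that every pipeline stage can be tested end to end
with no downloads. Its defaults emulate the intron-rich study system the
package was modelled on: 112,465 bp, the conserved 17-marker arrangement,
26 tRNAs, 52 introns over 13 host genes (11 in *cox1*), GC 26.98%, AT skew
+0.0615, GC skew +0.1164. Composition targets are met in expectation:
non-coding fill is drawn per base from probabilities derived from
(GC%, AT-skew, GC-skew), while PCG exons are drawn codon-wise from the
composition-weighted sense-codon distribution of code 4 (start `ATG`,
terminal `TAA`), which guarantees stop-freeness at the cost of a slight
(<0.3 percentage point genome-wide) composition bias from excluding
stops. Planted repeats get extension-blocking flank bases in all four
orientation geometries; planted SSR runs get flanks that break the motif
period on both sides, making their coordinates exactly recoverable.
Infeasible plans (features exceeding the target length) fail before any
sequence is drawn. A fixed seed reproduces the output byte for byte, and
changing the seed changes sequences but not planned annotation counts.

`evolve_cds_pair()` evolves a derived CDS from an ancestor under a uniform
proposal process: synonymous changes always accepted, nonsynonymous
changes accepted with relative probability omega, stop-creating changes
rejected. `target_dS` is interpreted as expected synonymous events per
NG86 synonymous site of the ancestor; the process stops when accepted
synonymous events reach S × target_dS, so the NG86 Ks of the pair recovers
the target through the Jukes–Cantor correction (measured: mean Ks ≈ 0.202
at a 0.2 target over 50 pairs of 500 codons). There are no indels in this
version — alignment behaviour is tested separately with hand-built
indel cases — and no rate heterogeneity among sites.

`generate_clade()` builds n species (default 22) sharing the marker
template; each species' *cox1* derives from one reference CDS by
synonymous-only evolution (so the reference mapping is exact by
construction) and carries the introns its Pcl plan assigns. The default
plan mirrors a family-scale *cox1* intron survey: 31 sites, 119 introns
over 22 species, 12 common and 19 rare classes, with the most widespread
site (731) in 12 species and singleton group II sites such as 50.

What the generator deliberately does **not** emulate: phylogenetically
correlated intron presence (carriers are drawn independently per site),
realistic homing-endonuclease sequence content inside introns, indels,
tRNA cloverleaf structure, and compositional heterogeneity along the
genome. Tests passing on generator output therefore demonstrate
correctness of the bookkeeping and estimators under the declared model,
not robustness to every pathology of real annotations.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
detector-closure genomes of roughly 14 kb (full quadratic repeat scan in a
few seconds), brute-force repeat oracles on sequences up to 2 kb,
rate-recovery simulations of 50 replicates × 500 codons per omega value,
and clades of 22–23 compact (~10 kb) genomes. The default full-scale
(112 kb) configuration is exercised for generation, composition,
validation and splicing, where it costs seconds. Report writers print
floats at fixed 4-decimal precision with deterministic row ordering so
repeated runs are byte-identical and diffable.

## Known limitations

* GenBank parsing is a pragmatic flat-file reader aimed at this package's
  writer and at straightforward records (gene/CDS/tRNA/rRNA/intron with
  `join`/`complement` locations); qualifier-heavy or multi-record files
  are out of scope.
* Features wrapping the circular origin are rejected rather than modelled.
* The repeat scan is exact but quadratic; megabase inputs would need a
  filtered algorithm.
* NG86 is the only Ka/Ks estimator; model-based estimators (e.g. ML codon
  models) and site-level positive-selection scans are out of scope.
* Pcl homology is exact-site by default; the matrix builder offers a small
  merge tolerance for noisy annotations, but systematic annotation error
  is better corrected upstream.
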