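---
title: "Methods: characterizing annotated mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing annotated mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

`mitochar` characterizes circular, annotated mitochondrial genomes of the
vertebrate architecture. This vignette records the models and procedures
implemented, the conventions chosen where several coexist in the field,
the tunable parameters, and what the bundled simulator does and does not
emulate.

## Coordinates and containers

All coordinates are 1-based inclusive positions on the heavy (H) strand of
the circle. Light-strand (L) features are stored canonically with
`start < end` plus a strand flag; orientation is applied only when a
sequence is extracted, so a single coordinate convention holds everywhere.
`start > end` is reserved for features spanning the origin; such features
concatenate the circle's tail and head before orientation. The five-column
feature-table dialect (`gene, type, from, to, anticodon`, tab-separated)
encodes the L strand by reversed coordinate order, which means it cannot
express an origin-spanning feature; the writer refuses rather than
silently misencode. In the default architecture the origin sits at the
start of tRNA-Phe, immediately after the control region, so the issue does
not arise there.

## Gene organization accounting

For features in circle order, the gap printed for a row is the signed gap
*following* that feature, `start(next) − end(this) − 1` computed modularly
(the last row gaps back to the first); negative values are overlaps. This
is the alignment between coordinates and the intergenic column used in
published organization tables. Two consequences worth stating explicitly:

- The conservation law `Σ length + Σ gap = genome length` holds exactly on
  every circular annotation, and is enforced by property tests over
  randomly generated layouts (including origin-spanning features).
- All overlap/intergenic summaries are *coordinate-derived*. Published
  prose sometimes disagrees with published coordinates (e.g. attributing
  the longest overlap to a different gene pair than the coordinates
  imply, or counting intergenic locations differently); this package
  always reports what the coordinates imply and nothing else.

Stop codons are classified purely from CDS length mod 3 plus the terminal
bases: a complete terminal `TAA/TAG/AGA/AGG`, or an incomplete terminal
`T` / `TA` which mitochondrial polyadenylation completes to `TAA`,
rendered `T(AA)` / `TA(A)`. Translation uses the vertebrate mitochondrial
code (NCBI table 2); permitted start codons default to `{ATG, GTG}` — the
set observed in the reference architecture — and are configurable because
other vertebrates also initiate with `ATA`/`ATT`. A non-permitted first
codon warns but is still reported; an internal in-frame stop is an error.

## Composition and skew

`AT-skew = (A−T)/(A+T)` and `GC-skew = (G−C)/(G+C)`; a zero denominator is
reported as undefined (`NA`) rather than infinite. Percentages are
reported to 1 decimal and skews to 2 decimals (the conventions of
published composition tables) by `format_composition()`, while unrounded
values are retained in the objects; tests that compare against published
rounded values allow ±0.01 for double rounding. Ambiguity codes are
excluded from numerators and denominators and counted separately, since
finalized genomes contain none.

Pooled PCG composition orients every gene to its coding strand first (so
the L-strand ND6 contributes its reverse complement), then concatenates in
annotation order. Codon positions are assigned **per gene** from each
gene's own reading frame: a gene ending in an incomplete stop contributes
only the positions its partial terminal codon actually has. Under the
reference architecture (four genes with length ≡ 1 mod 3) this yields
position sizes 3797/3793/3793 of the 11,383 bp total. Annotation suites
that instead chop the concatenated PCG sequence into global triplets
report 3795/3794/3794 for the same input; `regional_summaries()` offers
`position_assignment = "concatenated"` to reproduce that convention, and
the tests assert both numbers via their respective routes. The per-gene
assignment is the default because position-specific composition is a
property of reading frames, not of concatenation order.

## Consensus correction of ambiguous sites

Multi-assembler mitogenome workflows leave occasional IUPAC codes in the
best assembly. Rather than whole-genome alignment — overkill when
alternates are fragmented contigs — each ambiguous site is located in the
alternates by its exact flanking context: the `flank` bases on each side
(default 20, minimum 8) are searched in every alternate fragment, in both
orientations, circularly for circular alternates. Mitogenomes essentially
never repeat 40-mers, so a 20-bp flank pair places a site uniquely.

Voting policy, chosen conservatively where the multi-assembler practice is
silent on conflicts:

- an alternate whose matches all show the same base casts one vote (several
  agreeing matches are redundant coverage from overlapping fragments, not
  placement ambiguity);
- matches showing *different* bases are genuine placement ambiguity and
  the alternate abstains;
- a vote outside the IUPAC expansion of the primary's code is discarded
  and logged (an alternate cannot overrule the primary's evidence class);
- unanimity resolves; otherwise a strict majority; otherwise the site
  stays unresolved and the primary's code is kept.

Output length always equals input length and only originally ambiguous
positions can change — both are property-tested.

## Codon usage and Ka/Ks

RSCU is `x/(X/n)` per codon within its synonymous family; family sums
equal family sizes by construction (property-tested on random counts).
Stop codons and incomplete terminal codons are excluded from counting;
codons are reported in the RNA alphabet (`CUA`), the convention of RSCU
bar charts, with the DNA spelling alongside. Under the vertebrate
mitochondrial code no single-codon family exists (Met and Trp are
two-fold).

Pairwise Ka/Ks follows Nei & Gojobori (1986), implemented explicitly
because "calculated with tool X" is not a formula:

- *Potential sites*: at each codon position, the fraction of the three
  possible changes that are synonymous, computed among changes that do not
  create a stop (nonsense mutations ignored — the classic convention;
  conventions differ between tools, so this is worth pinning down). The
  nonsynonymous fraction is the complement, so each codon contributes
  exactly 3 sites. Site totals are averaged over the two sequences.
- *Observed differences*: codons differing at k positions are apportioned
  by averaging over all k! substitution orderings, discarding orderings
  that pass through a stop codon; in the (rare) case that every ordering
  does, all orderings are used as a documented fallback. Both per-codon
  tables are precomputed per genetic code and verified against an
  independent recursive path enumerator over all two-difference sense
  codon pairs.
- *Correction*: Jukes–Cantor, `d = −(3/4)·ln(1 − (4/3)p)`, undefined at
  `p ≥ 3/4` and then reported as saturated rather than clamped.
- *Aggregation*: gene-level Ka/Ks is `mean(Ka)/mean(Ks)` over taxon pairs
  with defined values. The ratio of means is robust to near-zero per-pair
  Ks, which makes mean-of-ratios explode; the per-pair table is returned
  so users preferring the other convention can compute it. Identical taxa
  give 0/0, reported as undefined.

Codon pairs containing gaps or ambiguity codes are deleted pairwise;
non-terminal stop codons in an alignment are skipped with a warning.

## Phylogeny preparation

The 13-PCG supermatrix requires every gene alignment to cover the same
taxon set (no silent gap-filling) with lengths divisible by 3; the
partition scheme is three stride-3 blocks per gene in supermatrix
coordinates, emitted in RAxML syntax (`DNA, ND1_pos1 = 1-969\3`) alongside
relaxed PHYLIP and NEXUS writers. Model-based inference itself
(PartitionFinder, MrBayes, RAxML) is out of scope: those runs need large
taxon downloads and hours of CPU; the package prepares their inputs and
provides a self-contained verification tree instead.

That verification tree is neighbor joining on p-distances. p-distance uses
pairwise deletion (a column is dropped only for the pair it is missing
in), matching the near-complete-sequence verification use case, and is
cross-checked against an independent distance implementation in the
tests. NJ is the Saitou–Nei agglomeration via `ape::nj()` after strict
input validation; negative branch lengths, which NJ produces on
non-additive input, are clamped to zero with a message (standard
practice). The property that NJ reconstructs the generating tree exactly
from any additive matrix is tested on random trees of up to 12 taxa.

## The simulator: what it emulates, and what it does not

`generate_mitogenome()` realizes genomes on the published 39-feature
architecture of a crocodile newt mitogenome (16,265 bp), carried in
`mitogenome_template()` with its real coordinates, strands, anticodons and
start/stop codons. Using real coordinates means the overlap/spacer
geometry of simulated genomes — 41 bp of overlap in 10 pairs, 146 bp of
intergenic spacer, the 108 bp tRNA-Thr–tRNA-Pro gap — is exact, so
organization tests can assert published totals literally.

Sequence realization: non-coding regions are i.i.d. draws from per-region
base frequencies whose defaults are the published compositions of the same
genome (control region, rRNA, tRNA, PCG, intergenic classes). PCGs are
built codon-wise from sense codons only, with the template's start codon,
stop (complete or incomplete) and no internal stops. Because excluding the
four stop codons biases a naive product-of-base-frequencies draw away from
the composition target, codon probabilities use iteratively
proportionally fitted (IPF) base weights whose sense-codon marginal equals
the target — this keeps realized A+T within binomial sampling noise of the
target (±1% at 16 kb, property-tested). Bases shared by two overlapping
PCGs (ATP8/ATP6, ND4L/ND4, ND5/ND6 — the last on opposite strands) are
jointly rejection-sampled under both genes' frame constraints before the
remaining codons are drawn; with ≤15 bp overlaps this converges
immediately. All randomness flows from one explicit seed, embedded in the
FASTA header of every emitted record.

`mutate_set()` diverges the PCGs by proposal/acceptance: point proposals
at `branch_length` per site (Poisson count), transition:transversion bias
`tstv` (default 4, typical of mitochondria), stop-creating proposals
rejected, synonymous proposals accepted, nonsynonymous accepted with
probability equal to the gene's dN/dS target. This per-site
acceptance/rejection scheme is not a full codon-model rate matrix, but it
is exact in the property that matters for testing: the *ordering* of
per-gene dN/dS is controlled, and `kaks_rank_recovery()` (13 genes × 500
codons × 12 taxa, star topology, defaults graded 0.05–0.65) measures how
well the estimation path recovers it. Divergence along an arbitrary
user-supplied tree is also supported.

What the simulator does **not** emulate: indels (alignments are gap-free
by construction), tRNA secondary structure, heteroplasmy, rate variation
among sites within a gene, compositional strand asymmetry arising from
replication mechanics (regional targets are matched, but not their
mechanistic origin), and realistic control-region repeats. Tests passing
on simulated data therefore validate the *accounting and estimation*
machinery, not robustness to alignment error or model misspecification in
real data.

`make_assembly_variants()` emulates the multi-assembler correction
scenario: injected two-base ambiguity codes always compatible with the
truth, alternates derived from the truth either whole or as overlapping
(randomly reverse-complemented) fragments whose overlap width guarantees
every site full flank context in some fragment.

## Parameters that matter

| parameter | where | default | rationale |
|---|---|---|---|
| `flank` | `resolve_ambiguities` | 20 bp | unique placement in a 16 kb circle; minimum 8 |
| `starts` | `mito_code` | ATG, GTG | the observed set; extend for ATA/ATT taxa |
| `position_assignment` | `regional_summaries` | per_gene | frame-true position sizes; `concatenated` mirrors suite output |
| `dnds`, `branch_length`, `tstv` | `mutate_set` | 0.2, 0.05/site, 4 | purifying range and divergence typical of congeneric mitogenomes |
| `at_content`, `base_freq` | `genome_spec` | published regional values | compositionally realistic genomes |
| `seed` | everywhere | explicit argument | full determinism; embedded in output headers |

## Problem sizes in the test suite

The suite runs in about a minute on one CPU: conservation on 200 random
layouts; the pathway oracle over all ~800 two-difference sense codon
pairs; 100 additive NJ recoveries (≤12 taxa); 24 injected ambiguities
across three variant sets; 20 rank-recovery replicates at 13 × 500 codons
× 12 taxa. These sizes were chosen as the smallest at which the stochastic
checks are stable, and are asserted at exactly these sizes by
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## Known limitations

- The feature-table dialect cannot express origin-spanning features
  (in-memory objects can).
- Ka/Ks is counting-based; no maximum-likelihood codon models, no
  site/branch models, no codon adaptation index.
- p-distance/NJ are verification tools, not publication-grade inference.
- The consensus stage reconciles substitutions only; indel disagreements
  between assemblies are out of scope.
- RSCU and Ka/Ks assume in-frame, stop-free CDS input and fail loudly
  otherwise rather than guessing a frame.
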