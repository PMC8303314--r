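---
title: "Mitotyping the honey bee tRNAleu-cox2 region: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitotyping the honey bee tRNAleu-cox2 region: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemito)
library(dplyr)
```

## The marker and the classification model

The intergenic region between the mitochondrial tRNA^leu^ gene and the cox2
gene is the standard maternal-lineage marker in *Apis mellifera*. Its
informative structure is architectural rather than purely sequence-based:

* a **P element** occurring in four forms — `P0` (complete), `P` (a 13 bp
  deletion in the middle), `P1` (a 15 bp deletion at the 3' end), `P2`
  (an 18 bp deletion at the 5' end) — or absent altogether;
* one to five tandem copies of a ~196 bp **Q element**;
* flanking fragments of the tRNA^leu^ gene and of cox2.

The P form diagnoses the evolutionary lineage: `P0`/`P1` mark the African A
lineage, `P` the Western European M lineage, `P2` the Y lineage, and absence
of P the Eastern European C lineage. Within lineage A, the placement of DraI
restriction sites (`TTTAAA`) refines the call: sub-lineage AI carries sites
at the 3' end of tRNA^leu^ and the 5' end of the first Q copy, AII at
tRNA^leu^ only, Z additionally in the middle of the first Q copy, and AIII is
defined by the `P1` form itself. `beemito` encodes these rules directly
(`assign_lineage()`, `assign_sublineage()`), so a call is always explainable
in terms of located elements and sites.

Named haplotypes refine architecture further: within a family (A1, A4, A30,
A65, C1–C3, M7), letter-suffixed variants are defined by specific
substitutions and 1 bp indels at numbered columns of a master alignment.
The shipped catalog (`load_reference_catalog()`) encodes 24 observed
haplotypes (16 lineage A — 13 AI, 3 AIII —, 6 C, 2 M; 15 of them novel)
plus the two unobserved family bases A4 and M7 and a synthetic outgroup row.

## The synthetic master alignment

The original survey's alignment is not deposited, so the catalog defines its
own: a fixed 804-column alignment over a synthetic element grammar
(40 bp tRNA^leu^, 68 bp `P0`, 196 bp Q, 300 bp cox2, plus four reserved
insertion columns at 100/139/298/337). The published variant-defining columns
(84, 86, 99, 100, 139, 148, 252, 286, 298, 336, 337, 646, 739, 795) are
re-anchored as 1-based columns of this alignment; the cox2 fragment is sized
at 300 bp precisely so that all cited columns exist and every variant's edits
can be embedded in generated sequences. Element template sequences are fixed
synthetic strings, constructed so that no `TTTAAA` occurs anywhere except
where a sub-lineage template plants one — every DraI site in a simulated
amplicon is therefore a deliberate diagnostic.

Two classes of sequence differences are *synthetic by construction* and
documented as such: founder substitutions that distinguish family bases the
source only distinguishes by name (C1/C2/C3 and the A1e marker, at reserved
columns 560–620), and the outgroup's divergence (15 substitutions). The
source also names "A30d" twice for two different edits; the catalog follows
the apparent intent and assigns the position-336 deletion to A30d and the
position-86 substitution to A30e.

## The simulator and what passing tests mean

`build_amplicon()` is the generative counterpart of the classifier: it
assembles any architecture (`p_form`, 0–5 Q copies, DraI template, variant
edits) from the grammar. `generate_population()` draws colonies per site
either with exact counts or multinomially from configured frequencies, under
a mandatory seed; truth labels come with every record.

The default study population (`study_population_counts()`) reproduces the
surveyed 512 colonies across 15 sites in 3 regions exactly at the level of
every published total: per-site N and haplotype richness Na, one private
haplotype per site, lineage counts 333/173/6, sub-lineages 280 AI / 53 AIII,
the six length-pattern counts (3 `P0`, 173 `Q`, 55 `P0Q`, 222 `P0QQ`,
6 `PQQ`, 53 `P1QQ`), the headline haplotype counts (A4p 117, A4t 96, A30 51,
C1 94, C2j 60, A65 3) and the reported site-exclusivity of rare variants.
The *within-site* split beyond those constraints is a reconstruction — the
colony-level table is not public — so per-site Ne and uh of the synthetic
population are not expected to match the printed ones; the printed N/Ne/uh
values ship separately (`reference_site_diversity()`) for arithmetic checks.

`add_noise()` adds substitution noise (rate at most 2%) for robustness tests
but never touches DraI motifs or 8 bp element-boundary windows. This is a
stated simulator limitation: real sequencing error does not respect
diagnostic motifs, and indel error, chimeras and mutation-rate realism are
out of scope. Consequently, a 100% noise-free recovery and a 99% recovery
under 1% noise demonstrate the classifier's logic and tolerance windows, not
the error profile of real Sanger data.

## Detection and numerical choices

Detection is alignment-based so real amplicons of different absolute lengths
can be typed by the same code path:

* anchors (tRNA^leu^, cox2) by semi-global alignment at >= 80% identity;
  if both fail the classifier reports an unrecognized amplicon rather than
  imputing — the handling of partial sequences is deliberately conservative;
* Q repeats by iterative semi-global alignment of the Q template at >= 90%
  identity per copy, masking each hit; the looser anchor threshold and the
  tighter repeat threshold separate anchor drift from repeat counting;
* the P form from the gap placement in a global alignment to the `P0`
  template, with +/- 2 bp tolerance on the 13/15/18 bp deletions; two
  simultaneous large gaps raise an "ambiguous P form" error, never a guess;
* orientation auto-detected by comparing anchor scores against the
  reverse complement.

Sub-lineage windows are: the last 10 bp of the tRNA^leu^ span plus 6 bp of
slack, the first 15 bp of the first Q copy, and that copy's central third.
A `P0` amplicon with no Q element (the A65 architecture) is called AI when
the tRNA^leu^ site is present — consistent with the phylogenetic placement
of that haplotype — and "indeterminate" (an `NA` with a note, not an error)
without it.

Haplotype calling compares a sequence only with catalog members sharing its
length pattern; an exact match wins, otherwise the minimum-edit-count member
(mismatches plus indel runs; ties broken by catalog order, which is stable
and documented). New variants are coined as the family base plus the
alphabetically first unused letter; letters are never skipped. A pattern
with no catalog member yields a provisional `X<n>` name flagged for curation.

## Diversity, differentiation, ordination

Per-site summaries use the single-locus haplotype-frequency definitions:
`Na` distinct haplotypes, `Ne = 1/sum(p^2)`, unbiased diversity
`uh = (N/(N-1))(1 - sum(p^2))`, and `Np` as *site*-private haplotypes (the
source is ambiguous between site- and region-private; site-private is
implemented). Values are kept raw and only rounded to 3 decimals in reports.

PhiPT is an AMOVA on colony-level categorical labels with the binary metric
(0 same label, 1 otherwise): with that metric all squared-distance sums
reduce to label counts, so the permutation test (default 999 permutations,
seed mandatory) costs microseconds per replicate. Negative estimates are
reported as 0 by convention with raw values retained. No multiple-testing
correction is applied across pairwise site comparisons, matching the
reporting style of the field; users combining many pairs should correct
downstream.

PCoA is the Gower double-centering of `-0.5 D^2` followed by symmetric
eigendecomposition; axis percentages are computed over positive eigenvalues
only and negative eigenvalues are reported, not silently dropped. The
published ordination itself (70.2% / 15.5% axes) is not reproducible because
the colony-level data behind the PhiPT matrix are not public; the package
verifies the method instead on planted Euclidean geometry (recovery to
Procrustes error < 1e-8).

## Character coding, tree and network

For phylogeny and network inference the alignment is recoded
(`encode_characters()`): polymorphic columns of P, the first Q, cox2 — and of
the second Q — as single-step characters with gaps as a fifth state; large
architectural deletions (P mid-deletion, P1 3' deletion, P absence, Q
absence, second-Q presence) collapsed to one binary indicator each, with the
columns they remove scored missing for the affected taxa; the two diagnostic
DraI sites as dedicated binary characters. The deletion indicators and DraI
characters are upweighted (default 10, the conventional maximum weight of
network software; configurable) — the magnitude is not stated in the source.
Retaining the second Q's polymorphic columns (as missing for taxa without a
second copy) departs from reading "single mutational steps" as
presence/absence only; it is required for variants defined solely within the
second Q (A30d, and the 337-insertion A4 variants) to remain distinct taxa,
as they are in the published tree and network.

One documented metric caveat: `step_distance()` skips characters missing in
either taxon, so taxa lacking a whole element (A65, the outgroup) have
deflated distances and the triangle inequality can fail through them; it
holds over all other catalog taxa and is tested with that scope.

The tree is neighbor joining on the step distances (the source names only a
general phylogeny package; NJ matches the distance semantics of the coding,
and parsimony is a reasonable alternative), rooted on the synthetic outgroup,
with character-bootstrap support (default 1000 replicates, seed mandatory).
The median-joining network iterates the epsilon-relaxed minimum spanning
network, adds per-character-majority medians of connected triples when they
shorten the triple's connection, and prunes medians of degree below three to
a fixpoint; `epsilon = 0` (the most parsimonious network) is the default.
Median vectors of triples whose states all differ keep the first taxon's
state — a documented tie-break that cannot occur with binary characters.

## Problem sizes used in the shipped checks

The test-suite simulations are sized for completeness rather than scale, a
deliberate choice of the package: the full 5 x 6 architecture sweep with all
sub-lineage templates; the 512-colony study population typed end to end;
1000 colonies at 1% noise for robustness; 200 replicates x 999 permutations
for the size of the PhiPT test; 100 random 8-taxon topologies for NJ
recovery; and 8-taxon binary instances for the network's spanning-tree
containment, against brute-force oracles throughout.

## Known limitations

* The element grammar is an emulation: real amplicons have other lengths
  (e.g. the real A65 amplicon is 422 bp; the synthetic one is 408 bp), and
  real P0/Q template sequences are not printed in the source. Classification
  of real data relies on the alignment thresholds, which have only been
  exercised against the grammar and its noise model.
* Lineages Y, O and S are recognised only through the P2-form rule; no
  reference panel ships for them, and their haplotypes land in the
  provisional `X` namespace.
* GenAlEx-style spreadsheet layouts, chromatogram handling and publication
  graphics are out of scope; exports are plain TSV/Newick and the plots are
  diagnostic ggplots.
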