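---
title: "Tracing whole-genome duplications from a focal gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing whole-genome duplications from a focal gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

## The problem

Paleopolyploidy — ancient whole-genome duplication (WGD) followed by
diploidization — has shaped every major plant lineage: the core-eudicot
γ triplication, the salicoid duplication of poplar and willow, the
Solanaceae *T* triplication, the grass ρ and pre-commelinid τ events,
and many more. A small, conserved transcription-factor family whose loci sit
in well-preserved syntenic neighbourhoods can act as a tracer for these
events: each WGD leaves (i) duplicate loci embedded in sister syntenic
blocks, (ii) a cloud of duplicate *flanking* gene pairs whose synonymous
divergence records the event's age, and (iii) a duplication node in the
family's gene tree whose descendant clades span the affected species.

`wgdtrace` implements that three-pronged inference as a reusable pipeline:

1. **Synteny** — chain homolog anchor pairs into collinear blocks, pull out
   the "syntelog" pairs that flank the focal loci, and summarise
   cross-genome relationships as a weighted locus network.
2. **Ks engine** — estimate per-pair synonymous (Ks) and nonsynonymous (Ka)
   distances from protein-guided codon alignments with the Nei–Gojobori
   (1986) method and Jukes–Cantor correction, then filter unreliable pairs.
3. **Dating** — summarise the retained Ks sample (95% t-interval of the
   mean, Gaussian-kernel density peaks) and match peaks against a packaged
   table of literature Ks ranges per WGD event; convert between Ks,
   substitution rate and absolute time via T = Ks/(2r).
4. **Gene trees** — detect duplication nodes with the three-support
   criterion (BS-1/BS-2/BS-3), run taxon-exclusion series, and assign
   subfamily nomenclature.
5. **Simulator** — generate fully ground-truthed datasets (planted WGDs,
   fractionated gene orders, codon sequences with known synonymous path
   distances) so that every stage, and the pipeline end to end, is testable
   without external genomes.

## The Ks model

For two in-frame coding sequences, proteins are aligned globally
(Needleman–Wunsch, BLOSUM62, affine gaps, via `Biostrings`) and
back-translated to codon columns. Nei–Gojobori counting then proceeds
per codon:

* **Sites.** Each of the three positions contributes a synonymous-site
  fraction equal to the proportion of its three single-nucleotide changes
  that preserve the amino acid, with changes to stop codons excluded from
  the denominator. S is averaged over the two sequences; N = 3L − S.
* **Differences.** A codon pair differing at *k* positions is scored by
  averaging the synonymous/nonsynonymous step counts over all *k!*
  substitution orders; orders passing through a stop codon are excluded.
  Columns with a gap, an ambiguous base, or (very rarely) no stop-free
  pathway are skipped whole — the behaviour of cleandata-style codon
  filtering.
* **Correction.** pS = Sd/S and pN = Nd/N are mapped through the
  Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p), undefined (saturated)
  at p ≥ 3/4.

Two exclusion rules follow standard practice for WGD dating: pairs with
Ks > 2.0 are treated as saturated and dropped, and pairs whose mean
third-position GC content exceeds 0.75 are dropped *within the grass
species set* (rice, sorghum by default), where extreme GC3 biases Ks.
Every rejection is logged with its reason.

The NG86 counting core is validated against a brute-force
neighbour/pathway enumeration oracle (exact equality of S, N, Sd, Nd on
randomized short alignments) in the test suite.

## Synteny chaining

Anchor pairs (significant homolog pairs; E-value filtering is assumed
upstream) are chained per chromosome pair by iterated dynamic programming:
the maximal-scoring chain with strictly increasing ranks in genome A and
strictly increasing (same orientation) or strictly decreasing (inverted)
ranks in genome B is extracted, removed, and chaining repeats. The score is
Σ similarity − gap_penalty·(rank gaps), with defaults in the MCScan
family's range: `max_gap_ranks = 25`, `min_anchors = 5`, unit gap penalty.
Gaps are measured in gene-rank units rather than base pairs, which is
robust to intergenic-length variation. The DP is checked against exhaustive
best-chain enumeration on randomized instances.

Focal-locus networks use edge weight ln(1 + block score); the absolute
scale of the block score is arbitrary (only its log enters downstream), so
it is fixed by the chaining definition above for determinism, and parallel
blocks keep the maximum-weight edge.

## Support-based duplication detection

On a rooted gene tree, every internal node whose two child clades share at
least one species is a candidate duplication. Three supports are read:
BS-1 for the node itself, BS-2 and BS-3 for its child clades; a leaf child
counts as 100 (a leaf is not an estimated clade). A call is *supported*
when min(BS-1, BS-2, BS-3) ≥ 90 (bootstrap; 0.95 for posteriors), *shared*
when the child clades share ≥ 2 species, and *species-specific* when they
share exactly one. Two conventions had to be fixed where practice is
visual: the shared/specific rule is formalized as the species-set
intersection size, and when the duplication node is adjacent to the root
after outgroup rooting — where its own bipartition is the outgroup's
trivially-present pendant split — BS-1 is taken as certain and the call is
flagged `at_root`.

Taxon-exclusion series re-run the tree, rooting and calls after pruning
chosen species. The motivating phenomenon: a lineage that diverged just
before a WGD contributes a single gene that attaches inconsistently inside
one subgenome clade, depressing BS-2/BS-3 below threshold; excluding it
restores full support. The test suite reproduces this effect from
simulation with a deliberately short internal edge.

Nomenclature follows the anchored-subfamily scheme: each gene takes the
subfamily of the smallest clade containing it and an anchor gene; within a
species and subfamily, letters follow the tree's tip order (subfamily 1:
A, C, E…; subfamily 2: B, D, F…), and a species with a single family member
keeps the bare family name. Whether the published letters encode tree order
or discovery order is not documented anywhere we know of; tip order is this
package's fixed convention.

## Dating choices

* **Interval.** "95% CI of the mean" is implemented as the Student-t
  interval on the sample mean; with n = 1 it degenerates to zero width with
  a warning.
* **Peaks.** Gaussian KDE with Silverman's rule-of-thumb bandwidth (the
  default of `stats::density`), evaluated on a regular grid over
  [0, max + 3h]; peaks are local maxima with density ≥ 25% of the global
  maximum. The floor suppresses noise shoulders and is configurable.
* **Matching.** A peak is assigned to a reference event when its mode falls
  in the event's literature Ks range or the sample CI overlaps it;
  ambiguous peaks list all candidates ranked by distance to the range
  midpoint. The packaged reference table ships both the literature ranges
  and, where the literature prints only a point value, the measured
  syntenic-block intervals as fallback ranges; rows carry citation tags and
  users can append their own.
* **Time.** T = Ks/(2r) per lineage, and r = Ks/(2T) for calibration; the
  two are exact inverses. No mixture deconvolution, relaxed clocks or
  cross-species rate smoothing are attempted.

## What the simulator emulates

`sim_config()` defaults encode the package's reference study conditions:
a two-species ingroup plus outgroup, two WGDs planted on the ancestral
branch at true pairwise synonymous distances 1.0 and 0.3, per-duplicate
retention 0.8, 200 families of 300 codons, omega = 0.2. Positions along
the ancestral branch are chosen so that a duplicate pair's true distance is
twice the synonymous depth from the WGD to the tips; the outgroup diverges
before the older WGD.

Sequences deliberately do **not** evolve under a full codon model.
Ancestral codons are drawn from a restricted set (prefixes GC, GG, CC, TC,
AC, GT) in which the third position is always 4-fold degenerate, every
single-nucleotide prefix change is nonsynonymous, and no codon has
synonymous first/second-position neighbours. Third positions then follow
an exact Jukes–Cantor process at the branch's synonymous rate and prefixes
mutate at omega times that rate. This guarantees the analytic link the
validation needs: a pair at true synonymous path distance d has
third-position difference probability exactly (3/4)(1 − e^(−4d/3)), so the
NG86 + JC estimate recovers d up to binomial noise, with no hidden bias
from degeneracy-class churn.

Consequently, passing the recovery tests demonstrates correctness of the
estimators under the model's assumptions — it does not demonstrate
robustness to features of real data the simulator omits: indels, codon
usage and GC3 bias, rate variation among sites and lineages, gene
conversion, tandem duplication, small-scale rearrangement, or
allopolyploid subgenome divergence. WGDs duplicate the entire gene order;
fractionation is i.i.d. per duplicate.

Real-data census quantities reported for the motivating family (per-genome
syntenic-block CI ranges, syntelog counts, network degrees) require the
underlying genomes and are shipped only as the reference table fixture,
never recomputed.

## Numerical and degenerate-input conventions

* Deterministic tie-breaks throughout: `Biostrings::pairwiseAlignment` for
  protein alignment; taxa sorted lexicographically before NJ; the
  same-orientation chain preferred on score ties; fixed seeds give
  byte-identical simulator output and pipeline reports.
* NG86 columns whose every substitution pathway crosses a stop are skipped
  (and counted in the rejection bookkeeping) rather than scored.
* Distances for tree building use the combined NG86 substitution
  proportion (Sd+Nd)/(3L) with JC correction, clamped at 8 when saturated,
  so NJ always receives finite input.
* Negative NJ branch lengths are clamped to zero.
* The bootstrap resampling unit is the codon column, and supports attach to
  bipartitions (via `ape::boot.phylo`), so rooting does not shuffle them.

## Problem sizes

The shipped tests and the acceptance script run the reference simulation at
200 families × 300 codons with 100 bootstrap replicates per family tree,
the oracle comparisons at 1000 (NG86) and 500 (chaining) randomized
instances, and the coverage study at 1000 samples of n = 30. These sizes
were chosen as the smallest at which the stochastic criteria are stable;
the bootstrap replicate count is a parameter (`replicates`) and 1000 is the
literature-scale setting.

## Limitations

* The support-based criterion is not a full gene-tree/species-tree
  reconciliation; duplication/loss scenarios that mimic high-support
  overlapping clades (e.g. unrecognised paralogy through missing data) will
  be called as duplications.
* KDE peak positions are biased toward zero near the origin boundary for
  very dispersed samples; the matching step therefore also considers CI
  overlap.
* The Ks clock shares all the usual caveats — rate variation between
  lineages and between paralog pairs dominates the uncertainty of absolute
  dates, which is why times are reported per-lineage with explicitly chosen
  rates.
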