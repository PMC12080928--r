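---
title: "Methods: threshold-based genus delineation and environmental forcing"
author: "taxoforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based genus delineation and environmental forcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoforce)
```

This vignette is the package's account of its models and the choices behind
them: what each stage assumes, which knobs matter, what the simulators do
and do not emulate, and where the design was genuinely open.

## 1. Pairwise genomic indices

Three relatedness indices are computed from pairwise search results, never
by shelling out to a search tool: production runs consume externally
produced BLAST-tabular files, tests and toys use the built-in exact aligner
(`exact_aligner()`, a Needleman–Wunsch global alignment via Biostrings).

**AAI** is the unweighted mean percent identity over reciprocal-best-hit
(RBH) ortholog pairs. A pair (p, q) qualifies iff q is p's best filtered hit
in one direction and p is q's best in the other; "best" means maximal
bitscore, with ties broken by lower E-value and then lexicographic subject
id so that results are identical across search backends. The default RBH
filters (identity ≥ 30%, query coverage ≥ 70%, E ≤ 1e-3) follow the common
AAI-calculator convention; they are explicit arguments because AAI values
are only comparable under identical filters. Whether one-way or two-way best
hits should be used was an open choice; two-way is the default because it is
the stricter and more widely reproduced convention, and the filters are
plain configuration for anyone needing the other.

**POCP** is `100·(C1+C2)/(T1+T2)` with the classical conserved-protein
filters (E ≤ 1e-5, identity ≥ 50%, alignable region ≥ 50% of the query).
The 12-column tabular layout does not carry query lengths, so the coverage
filter applies only when per-protein lengths are supplied — a documented
compromise rather than a silent guess.

**ANI** follows the fragment-based recipe: each assembly is cut into
consecutive non-overlapping 1,020-bp fragments (trailing remainder
discarded), fragments are searched in both directions, reciprocal best
fragment pairs passing the published identity/coverage filters (≥ 35% over
≥ 35%) are kept, and the index is their mean identity. On simulated genome
pairs with per-site substitution rate *s* ≤ 0.1 the recovered value is
100·(1 − s) within ±1 (validated in the tests).

Species verdicts use the standard boundaries — same species at ANI ≥ 96,
different below 95, ambiguous in between — and, when a dDDH value is
supplied (always consumed from external GGDC output, never computed), the
70% rule must agree or the verdict is ambiguous.

## 2. Threshold-stable genus delineation

The delineation model is single-linkage clustering with an inclusive edge
rule: at threshold *t* the genome graph has an edge wherever similarity ≥ t,
and the partition is its connected components. Single linkage is the one
linkage whose cut partitions are exactly characterised by threshold
intervals, which is what makes "a genus boundary is a range of thresholds"
well-defined.

Off-diagonal values are rounded to 2 decimals — the precision at which AAI
tables are published — before enumeration, so float noise cannot split a
stable run into spurious intervals. The partition is evaluated at every
distinct observed value; maximal runs with identical partitions become
*stable intervals*. Two conventions coexist in how such intervals are
written, and the package stores both: `lower`/`upper` are the observed
values bounding the run (the display convention used in published interval
lists), while `t_open` is the largest observed value below the run, so that
the exact semantics are "any threshold in `(t_open, upper]` yields this
partition". On a separable planted matrix the rank-1 interval's
`(t_open, upper]` equals the planted gap `(max inter, min intra]` exactly.

Candidate intervals are ranked against a reference partition (in practice, a
phylogenomic grouping) by: adjusted Rand index, descending; violated
forbidden-merge constraints, ascending; singleton count, ascending (a
threshold that shatters the panel into single-member genera is taxonomically
useless even when its ARI ties); and interval width, descending (a wider
stable range is a more robust boundary). Whether width or congruence alone
should break ties was an open question; width is used last, where it can
only separate otherwise-identical candidates. When a reference is supplied
as a tree, the package deliberately refuses to cut it automatically — the
group count is the user's taxonomic claim, not the algorithm's.

The exported dendrogram is the single-linkage merge tree at heights
100 − similarity; `ape::as.phylo()` renders leaf depths at half the merge
height (two genomes at similarity 80 sit on branches of length 10), and
cutting the underlying `hclust` tree at height 100 − t reproduces
`cluster_at_threshold(S, t)` because both use the inclusive rule.

## 3. Constrained correspondence analysis and the forcing partition

The gene presence/absence matrix is used exactly as emitted by the
pangenome pipeline — binarised (any non-empty cell, including paralog
lists, is presence), with no Hellinger or other pre-transformation — because
the question is about presence and absence, not abundance. Paralog-split
columns are not merged; that choice is surfaced rather than hidden because
upstream pipelines differ.

The fit is classical CCA: with `P = Y / y₊₊`, row masses *r* and column
masses *c*, the chi-square residual matrix is
`Q = (P − r cᵀ) / √(r cᵀ)` and total inertia is `ΣQ²` (equal to the
chi-square statistic of Y over its grand total). Habitat indicators are
weighted-centred with the row masses, Q's rows are projected onto their span
under row-mass weighting (a QR-based weighted least squares), and the fitted
matrix is decomposed by SVD. Squared singular values are the constrained
eigenvalues, capped at h − 1 axes for h habitats (rank-deficient designs
reduce the cap). The environmental fraction is constrained over total
inertia; its complement is reported as the phylogenetic fraction, following
the interpretation that residual gene-content structure in a
habitat-constrained ordination is lineage-associated. Implementation
correctness is pinned by two independent routes in the tests: a
generalized-eigenproblem oracle (agreement to 1e-8) and `vegan::cca`
(agreement to 1e-10 on eigenvalues).

Because a fraction estimated on 16 genomes is optimistic, the package
provides a label-permutation null (`env_fraction_null()`): the observed
fraction should clear the null's 95th percentile before being read as
environmental forcing, and on data with no planted habitat effect it should
sit inside the null's central range. This is the instrument that separates
environmental from phylogenetic accessory signal — not the score cutoff
below.

**Score scaling.** The original analyses in this field are run through
vegan, whose reported scores carry particular normalisation constants, and
the downstream 0.15 rule only makes sense on that scale. The package
therefore emits vegan-compatible scores: in the default symmetric scaling,
CDS scores are `V λ^{1/4} / √c` and site (linear-combination) scores
`U λ^{1/4} / √r`, verified against `vegan::scores(..., scaling = 3)` to
1e-8. Which scaling a published 0.15 cutoff referred to is genuinely
ambiguous, so the scaling is a config knob stamped into every output, and
both the habitat-indicator/axis correlations and the CDS scores are emitted
so either interpretation of a reported *r* can be checked. Axis signs are
made reproducible by forcing the largest-magnitude habitat centroid positive
on each axis.

## 4. Habitat-specific gene calling

Two complementary callers:

* **Axis-score calls** select CDS with sign-matching score of magnitude
  above the cutoff (default 0.15) on the axis most correlated with the
  habitat's indicator. CDS within the band on *every* axis are reported as
  "core-like" — in real data these are the housekeeping functions, and no
  special-casing of such genes is done: their neutrality emerges from the
  scores. The cutoff separates accessory from core-like columns; it does
  *not* separate environmentally from phylogenetically forced accessory
  columns (clade-driven columns also score well outside ±0.15 on constrained
  axes — the permutation null above is the right tool for that distinction).
  Raising the cutoff never enlarges a call set.
* **Exclusivity calls**: strict mode requires presence in all genomes of the
  habitat and absence outside (sets are then pairwise disjoint across
  habitats); any-mode relaxes to "present in at least one member", which is
  the appropriate rule when within-habitat host diversity prevents
  universally shared genes. Any-mode sets always contain their strict
  counterparts.

KEGG module completeness follows the at-most-one-missing-component rule: a
component block is satisfied by any of its interchangeable orthologs, and a
module is present when ≤ 1 block is unsatisfied — except single-component
modules, which require their component (otherwise a module with no evidence
at all would be called present). The summary table marks a function with a
filled symbol when supported by axis or strict-exclusive calls and an open
triangle when only any-mode supports it.

## 5. What the simulators emulate — and what they do not

`simulate_similarity_matrix()` draws within-genus values from one percent
range and between-genus values from another (uniform by default, optionally
truncated normal), rounded to 2 decimals, and records the planted partition
and the realised gap. It emulates the block-plus-gap structure of a real
family-level AAI table; it does not emulate hierarchical sub-structure
within genera, asymmetric measurement error, or missing pairs.

`simulate_pangenome()` generates three planted column categories over a
16-genome, 6-habitat default panel (six sponge, two coral, two flatworm,
one eelgrass, four seawater, one sediment — the shape of a real marine
isolate panel): core columns present everywhere; clade columns present
exactly in their clade then flipped at the noise rate; habitat columns
Bernoulli(penetrance) inside and Bernoulli(background) outside their
habitat. Default sizes (1,200 core, 350 per clade over 5 random clades, 120
per habitat; penetrance 0.9, background 0.05, flip 0.01) were chosen once to
mirror the scale and accessory/core balance of a family-level pangenome;
under these defaults the fitted environmental fraction lands near 40%,
i.e. in the range such panels report. The default clade structure is a
*random* seeded grouping of genomes: lineage in real data is simply another
grouping, neither aligned with nor engineered against habitat, and this
exchangeability is what makes the permutation null well-calibrated. The
generator does not emulate gene-length effects, linkage between columns,
horizontal transfer between specific clades, or geography-habitat
confounding — so a passing recovery test says the estimators work under
independent-column noise, not that real confounders are handled.

For index validation, `simulate_proteome_pair()` and
`simulate_genome_pair()` apply independent per-site substitutions at the
rate implied by the target identity and emit exact hit tables, so the
expected AAI/ANI is known to binomial accuracy.

## 6. Numerical choices and degenerate inputs

* Similarity diagonals are treated as 100 and ignored; off-diagonal values
  must lie in [0, 100] and be symmetric to 1e-8.
* Constrained eigenvalues below `max(λ)·1e-12` (and 1e-12 absolutely) are
  discarded as numerical zeros; rank-deficient designs therefore lose axes
  instead of emitting noise.
* Zero-mass rows and columns of the presence/absence matrix are dropped
  with a warning, never imputed; a single-habitat design yields zero
  constrained axes and an environmental fraction of 0 with a warning, not
  an error.
* G+C content excludes ambiguity codes from numerator and denominator, so
  it is invariant under gap runs, reordering and reverse-complementation;
  a sequence with no unambiguous base is an error.
* All tabular outputs use tab separators and a `.` decimal point regardless
  of locale; every stochastic function takes an explicit integer seed.

## 7. Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
200 random matrices of up to 8 genomes for the threshold scan (oracle
agreement at over 1,000 thresholds), 50 random matrices for the CCA
eigen-oracle, a 38-genome / 17-genus matrix and 16-genome pangenomes with
roughly 450–3,700 columns for the end-to-end recovery checks, and a
99-permutation null for the forcing test. These sizes were picked as the
smallest that exercise every code path at family-panel shape; the package
itself has no size limits beyond memory, and the full-scale pangenome
(16 × ~19,000 columns) fits comfortably.

## 8. Known limitations

* The threshold method assumes the similarity matrix is complete; missing
  pairs are not handled.
* The phylogenetic fraction is defined by complement, so any unmodelled
  structured variation (geography, host species within a habitat) is
  attributed to phylogeny; with three habitats represented by a single
  genome in the default panel, habitat and strain identity are partially
  confounded, exactly as in real panels of this shape.
* dDDH is consumed, never computed; 16S analyses and tree building beyond
  the single-linkage merge tree are out of scope.
* The built-in aligner is exact but quadratic; it is meant for fragments
  and toy proteomes, not for aligning full assemblies.
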