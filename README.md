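# taxoforce

Genome-based prokaryotic taxonomy and pangenome ecology for
family-level strain panels.

Modern bacterial taxonomy leans on whole-genome relatedness indices rather
than 16S rRNA identity: ANI and dDDH delineate species, AAI and POCP
delineate genera. But genus boundaries are fuzzy — published AAI cutoffs
range from 60% to 80% — so a defensible genus revision needs a *data-driven*
threshold. Separately, once genera are settled, the gene content of related
strains from different habitats can be decomposed into what lineage explains
and what environment explains. `taxoforce` implements both analyses for
users doing taxogenomic revisions of bacterial families and habitat-adaptation
studies of their pangenomes.

## What it computes

**Pairwise indices.** From reciprocal-best-hit protein searches (BLAST
tabular layout), AAI is the unweighted mean identity over ortholog pairs and
POCP is

    POCP = 100 · (C1 + C2) / (T1 + T2)

with `Ci` the proteins of genome *i* having a qualifying hit (E ≤ 1e-5,
identity ≥ 50%, alignable region ≥ 50%) in the other genome and `Ti` the
proteome size. `orthoani()` computes a fragment-based ANI: both assemblies
are cut into 1,020-bp fragments, reciprocal best fragment pairs are
averaged. `species_call()` applies the 95–96% ANI / 70% dDDH species rules.

**Threshold delineation.** `delineate_genera(S, reference)` treats genomes
as vertices of a graph with edges wherever similarity ≥ t (single linkage),
enumerates *every* threshold-stable partition of the matrix — maximal runs
of observed values over which the partition is invariant — and ranks the
candidate intervals against a reference grouping (typically a phylogenomic
clustering) by adjusted Rand index, forbidden-merge violations, singleton
count and interval width. The rank-1 interval is the proposed genus
boundary.

**Environmental vs phylogenetic forcing.** `cca_fit(Y, design)` runs a
canonical correspondence analysis of the binary gene presence/absence matrix
constrained by habitat categories: chi-square residuals are projected onto
weighted-centred habitat indicators and decomposed by SVD. With *h* habitats
you get at most *h − 1* constrained axes; constrained inertia over total
inertia is the environmentally forced share of gene-content variation, its
complement the phylogenetically forced share. Habitat-specific CDS are then
called either by ordination score (|score| > 0.15 on the habitat's axis) or
by strict/relaxed habitat exclusivity (`call_exclusive_cds()`), and
KEGG-module completeness uses the at-most-one-missing-component rule
(`module_completeness()`).

**Simulators.** `simulate_similarity_matrix()` plants genus blocks separated
by a known identity gap; `simulate_pangenome()` plants core, clade-driven
and habitat-driven gene columns with configurable penetrance, background and
noise. Both record their ground truth, so every stage of the pipeline is
testable end to end without downloads.

## Worked example

```r
library(taxoforce)

# a 6-genome panel: three planted genera, AAI gap between 70 and 85
sim <- simulate_similarity_matrix(c(2, 2, 2), intra_range = c(85, 95),
                                  inter_range = c(60, 70), seed = 1)
fit <- delineate_genera(sim$S, sim$truth$partition)
fit
#> Genus delineation by threshold-stable single-linkage clustering
#>   6 genomes, AAI matrix, 5 stable intervals
#>   optimal interval [87.66-87.66]: 3 groups, ARI 1.000 (exact match to reference)

# pangenome of 16 genomes in 6 habitats, planted habitat genes
pg <- simulate_pangenome(seed = 2, n_core = 100, n_phylo_per_clade = 40,
                         n_habitat_genes_per_habitat = 30)
cca <- cca_fit(pg$pa, pg$design)
cca
#> Constrained correspondence analysis of pangenome presence/absence
#>   16 genomes, 474 CDS clusters, 6 habitat categories
#>   total inertia 1.7136; constrained 0.8290 over 5 axes
#>   environmental forcing 48.4%, phylogenetic forcing 51.6%
```

The delineation fit says: across all thresholds there are 5 distinct stable
partitions, and the one holding on `(69.45, 87.66]` (the planted gap)
exactly reproduces the reference genera. The CCA fit says: of the total
chi-square variation in gene content, 48% lies in the space spanned by the
habitat indicators (5 axes for 6 habitats) — the environmentally forced
share — and 52% is residual, lineage-associated variation. (Exact numbers
depend on the seed; the ones above are what the calls shown print.)

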