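---
title: "Methods: filtering, classifying and comparing bacterial methylomes"
author: "panMethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, classifying and comparing bacterial methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

panMethylome operates on *per-site* modified-base calls: each bedMethyl
row describes one genomic position, one modification code, the valid
coverage at that position (reads calling the modification, reads
calling the canonical base, and reads calling a different
modification), and the fraction of valid reads supporting the
modification on a 0–100 scale. The package deliberately does not touch
raw signal, BAM pileups or per-read calls — those belong to the
basecaller and pileup caller upstream — and it does not compute the
pangenome, which is Roary's job. Everything downstream of those tools
is in scope: filtering, genomic-context classification, population
integration and visualization.

Two assumptions are inherited from the input format. First, calls are
per-position and strand-resolved but *biologically* unstranded for our
purposes: whether a 6mA site sits on the template or coding strand of
a gene does not change whether the gene is methylated, so containment
tests are strand-agnostic. Second, a pileup caller scores every
assessable base, so the raw tables are dominated by rows with a
methylation rate of zero; these are data, not noise, and are removed
only by the rate filter, never silently.

## Filtering

A record survives iff

* `valid_coverage >= min_coverage`, and
* `percent_modified >= min_rate`,

both **inclusive**. The thresholds are *minimums*, so a site sitting
exactly on either boundary is retained; the synthetic fixtures plant
sites at exactly 90.0 % to pin this choice. The default `min_rate` is
90 %: at typical bacterial coverage this keeps near-homogeneously
methylated positions (a motif fully methylated across the population
of cells) while discarding partial or spurious calls. Population
studies can relax it; single-genome studies can tighten it.

`min_coverage` has no universal default — it depends on sequencing
depth — so the package offers an automatic mode: the median of the
`valid_coverage` column is computed per input file, and the threshold
is the **median of those per-file medians**. The two-level median is
robust both to a single deeply- or shallowly-sequenced genome and to
within-genome coverage outliers (plasmids at different copy numbers,
for instance). Medians of even-length vectors are the arithmetic mean
of the central pair, and a fractional threshold is used exactly as is
in the `>=` comparison; rounding it would silently shift the boundary
by up to one read and is avoided. Files with zero records contribute
no median and are logged.

Structural validation (column count per line, numeric parse per
column, both separator dialects) always errors with the offending line
and column. Arithmetic validation — coverage equal to the sum of its
component counts, percent equal to `100 * n_mod / valid_coverage`
within 0.1 — warns by default and errors under `strict = TRUE`,
because real pileup files occasionally carry rounding slack that
should not abort a run.

## Coordinates

bedMethyl is BED-derived: 0-based, half-open, with the site position in
the start column. In memory the package uses `GRanges`, which is
1-based inclusive, because that is the convention of every
Bioconductor tool the package composes with; the bedMethyl reader and
writer shift by one so that round-trips are exact, and **every exported
CSV reports 0-based positions** (each file says so in a leading comment
line). GFF3's 1-based inclusive CDS coordinates map onto `GRanges`
unchanged.

## Classification

A site at 0-based position *p* is **coding** for a CDS spanning
`[start, end)` iff `start <= p < end`; a site at a CDS's start is
inside, a site at its (exclusive) end is not. The site is coding if it
is inside *any* CDS, regardless of strand. Overlapping CDS all count as
host genes: the site appears once per host in the coding output and
extended annotation, but exactly once in the count statistics, so the
coding/non-coding partition of sites is preserved
(`coding + non-coding = filtered`).

Only features of type CDS enter the classification. rRNA, tRNA and
pseudogenes are deliberately ignored — "coding" here means
protein-coding — so sites inside them classify as non-coding, which is
the conservative reading for promoter/regulatory interpretation.

For non-coding sites the flanking genes are reported in
*reference-coordinate* order: upstream is the nearest CDS ending at or
before the site, downstream the nearest CDS starting after it. Gene
strand does not enter this definition (an unstranded site has no
orientation of its own); both neighbour identifiers and their facing
boundary coordinates are emitted, so users can re-orient by gene strand
or compute distances themselves. At contig ends, and on contigs absent
from the annotation entirely, neighbours are empty — such sites are
kept and logged, never dropped.

The implementation uses sorted-interval overlap search
(`GenomicRanges::findOverlaps`), which is output-identical to the
exhaustive site-by-feature scan; the test suite asserts that
equivalence against an independent brute-force oracle on randomized
inputs.

GenBank compound locations (`join(...)`) collapse to their outermost
span. Bacterial CDS joins are rare (essentially programmed frameshifts
and annotation artifacts), and the outermost span is the simplest rule
that never *misses* a hosted site; it can at most attribute a site in
the joined-out gap to the gene.

## Pangenome integration

Roary's `gene_presence_absence.csv` maps each pangenome gene to the
locus tags carrying it per genome. Genome columns are auto-detected
after Roary's standard metadata columns, and genome identifiers are
taken from those headers; input files are matched to them by file stem,
and any mismatch is a hard error listing both sets — silent positional
alignment could corrupt every downstream matrix.

For each modification type the package builds a gene × genome matrix:

* `NA` — the gene has no locus tag in that genome (*absent*; serialized
  as an empty CSV cell, deliberately distinct from `0`),
* `0` / `1` — present without / with at least one filtered site of that
  type (binary mode), or
* the merged, sorted 0-based position list (positions mode).

When a gene has several locus tags in one genome (paralogs), evidence
is the **union** over copies: Roary cells legitimately hold multiple
tags, and "is this gene methylated in this genome" is most naturally
answered over all its copies. Locus tags present in the Roary table but
missing from a genome's extended annotation are logged and contribute
no evidence. Binarizing a positions-mode matrix reproduces the binary
matrix exactly; the tests assert this mode consistency.

Gene prevalence ("methylated in at least 95 % of strains") divides the
methylated-genome count by the number of **analyzed genomes** by
default. The alternative — only genomes carrying the gene — inflates
prevalence for accessory genes with tiny denominators; it remains
available as `denominator = "carrier"` for questions explicitly about
carriers. The threshold comparison is again inclusive (19 of 20 genomes
passes at 0.95).

## Clustering and heatmaps

Core genes are those present (non-absent) in at least
`presenceThreshold` (default 0.95) of genomes. Distances between binary
profiles are normalized Hamming distances — the fraction of positions
where two vectors differ — which for presence/absence data is the
natural metric: symmetric, in [0, 1], zero iff identical.

Absent (`NA`) cells have no defined Hamming contribution, yet core-gene
matrices may contain up to 5 % of them. For the *distance computation
only* they are imputed as 0, "no methylation evidence" — the
conservative choice, and confined by construction to a small minority
of cells. Rendering keeps the third state: absent cells stay grey in
the heatmap.

Clustering is agglomerative with **unweighted average linkage
(UPGMA)**: the distance between clusters is the mean over all
cross-cluster pairs of original distances. The implementation is
authored in the package with an explicit deterministic tie-break —
among equally minimal pairs, the pair with the lowest indices merges
first — because Hamming distances on binary data are multiples of 1/n
and tie constantly; library implementations resolve such ties by
internal order and are not reproducible across versions. Two
consequences are documented rather than hidden: (i) given the same
input order the tree is a pure function of the data; (ii) under row or
column permutation, tie resolution may legitimately change the tree,
so permutation invariance holds exactly on tie-free distance matrices
only. A small numeric tolerance (1e-10) in the minimum search absorbs
float noise from the incremental distance updates so that genuine ties
are recognized as ties, and merge heights are clamped to be
non-decreasing against last-digit float drift. The tests verify the
implementation against a naive UPGMA oracle that recomputes every
cluster distance from the original matrix, and against
`stats::hclust(method = "average")` on tie-free distances.

Leaf order is the dendrogram's natural left-to-right traversal; no
optimal-leaf-ordering pass is applied, again for determinism. Heatmaps
never re-cluster: they draw the matrix in the `ClusteredPanMatrix`
order and write that order to a sidecar CSV. Full resolution labels
every gene and grows linearly with the gene count
(`cellInches` per row); compact resolution is fixed-size without gene
labels. Genome labels are always drawn.

# The synthetic-data generator

`generateFixture()` emulates the *data products* of a bacterial
population methylome study: per-genome bedMethyl pileups over a
chromosome and a plasmid, CDS annotations in GFF3, and a Roary-layout
presence/absence table with core / accessory / unique structure —
plus a manifest recording, by construction, every quantity the
pipeline should recover (the automatic threshold, per-genome filtered
counts, coding/non-coding splits per type, per-gene position lists,
matrix cells, prevalence sets).

The defaults describe a desk-scale study: 5 genomes; a 600 kb
chromosome and an 80 kb plasmid; ~490 genes per genome (300 core, a
random subset of 150 accessory, 40 unique, with a couple of core genes
duplicated as paralogs in the first genome); per genome, 1,940 true
methylation sites in realistic type proportions (6mA most abundant,
4mC rare) and 48,000 decoy rows, for ~50,000 rows per genome. Half the
true sites are planted inside CDS: bacterial intergenic space is small
but densely methylated, so an even coding/non-coding split of
high-confidence sites is a realistic stylization. True sites draw
coverage strictly above any attainable automatic threshold and rates in
[90, 100] (a few pinned at exactly 90.0); decoys either fail on rate —
most at exactly zero, as real pileups report — with coverages
straddling the automatic threshold, or pass on rate with coverage far
below it. The generator asserts that the realized median-of-medians
separates these bands and errors before writing anything if the
specification is infeasible (e.g. genes that do not fit the contigs).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence content and motifs (no DNA is
generated, so no motif enrichment around sites), partial methylation
gradients (rates are bimodal by construction), coverage autocorrelation
along the genome, strand-paired sites at palindromic motifs,
annotation errors, or Roary misclustering. Tests against fixtures
establish that the bookkeeping — filtering, interval logic, matrix
assembly, clustering — is exact; they cannot validate the biological
thresholds themselves.

# Problem sizes in the test suite

The suite exercises the pipeline at two scales, chosen to keep a full
run in a few minutes on one CPU while still crossing every code path at
population scale: unit tests use 2–3 genome fixtures with ~2,000
pileup rows per genome, and the end-to-end acceptance checks use the
default 5-genome, ~50,000-rows-per-genome fixture, 100 randomized
classification fixtures of 500 sites × 50 CDS against the brute-force
oracle, and UPGMA oracle comparisons up to 12 × 12.

# Known limitations

* Pangenome comparison covers protein-coding genes only; intergenic
  methylation is classified per genome but not integrated across
  genomes.
* The coding/non-coding dichotomy ignores gene-bearing non-CDS features
  (rRNA, tRNA); sites there are "non-coding" by definition here.
* Prevalence and core-gene thresholds compare fractions on small
  denominators; with few genomes the 95 % default is effectively
  "all genomes".
* The absent-as-unmethylated imputation biases distances toward
  similarity for genes with many absences; the core-gene restriction
  bounds, but does not eliminate, this effect.
* No statistical testing of cluster support or methylation-phenotype
  association is attempted; the package is descriptive.
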