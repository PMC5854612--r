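---
title: "Evaluating module detection: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating module detection: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modeval)
```

# The evaluation problem

A module detection method turns a genes × samples expression matrix into a
set of gene modules. Judging its output against biological ground truth
faces three structural complications: the truth (genes co-regulated in a
known regulatory network) is **overlapping** (a gene answers to several
regulators), **non-exhaustive** (most regulatory networks are incomplete,
and many detectors leave genes unassigned), and of **uneven difficulty**
(small disjoint module structures are much easier to hit by chance than
large overlapping ones). `modeval` addresses each in turn: gold standards
derived from networks under three module definitions, comparison scores
defined at the gene-pair level that tolerate overlap and partial coverage,
and normalization of every score against a structure-preserving
permutation null.

# Gold standards from regulatory networks

Three module definitions, in increasing structural looseness:

* **Minimal co-regulation** (`minimal_coregulation()`): one module per
  regulator — its full target set. Modules overlap wherever genes have
  several regulators.
* **Strict co-regulation** (`strict_coregulation()`): genes grouped by
  their exact incoming-regulator set; a partition of the regulated genes.
* **Interconnected subgraphs** (`interconnected_modules()`): Markov
  clustering (MCL) of the network, capturing densely connected gene
  groups that need not share a direct regulator. The inflation exponent
  sets granularity; 2 (coarse) to 50 (fine) are useful settings.

All known-module sets then pass through `filter_modules()`: modules are
intersected with the expression universe, near-duplicate pairs (Jaccard
> 0.8) are merged, and modules under 5 genes are dropped — tiny modules
make pair-level scores noisy and are rarely what a practitioner wants
detected.

**MCL numerical choices.** The adjacency matrix is symmetrized with
`max(A, t(A))` (the definition concerns interconnectedness, not edge
direction), unit self-loops are added, and columns are normalized.
Iterations alternate expansion (matrix square) and inflation (elementwise
power). Each column is rescaled by its maximum before exponentiation so
that inflation exponents up to ~50 cannot underflow double precision;
entries below 1e−8 are then pruned and columns renormalized. Convergence
is a maximum absolute change below 1e−6, with an error (reporting the
residual) after 200 iterations. Clusters are read from attractor rows
(positive diagonal); identical attractor rows are deduplicated while
genuinely overlapping clusters are kept. Within a fixed input the
procedure is fully deterministic.

# Comparison scores

## Gene-pair scores (overlap-aware precision and recall)

For gene g, let M(g) be the known modules containing g and M′(g) the
observed ones; E(g, M′) is the set of genes sharing at least one observed
module with g (including g itself). Precision averages, over genes covered
by an observed module and over their observed co-members g′, the ratio

min(|M′(g) ∩ M′(g′)|, |M(g) ∩ M(g′)|) · Φ(g, g′) / |M′(g) ∩ M′(g′)|,

where Φ(g, g′) is the mean over observed modules containing both genes of
the best Jaccard match among known modules containing both. Recall is the
same construction with the roles of the two sets swapped — an exact
symmetry the test suite asserts. The pair of scores reaches (1, 1) exactly
when the two overlapping module sets are equal, and any single-gene
corruption lowers both.

The printed form of the outer average, 1/|G|, does not define what happens
for genes that no observed module covers (their E(g, M′) would be empty and
the inner term 0/0). We follow the BCubed convention: precision averages
over genes covered by at least one observed module, recall over genes
covered by at least one known module. The subset variants
(`cice_scores_subset()`) restrict the outer average to a gene subset — for
example genes in exactly one known module versus genes in several — while
keeping the inner neighbourhoods global, so subset and global scores are
directly comparable and the all-genes subset reproduces the global score
exactly.

The implementation is a dense-matrix formulation (co-membership counts via
`tcrossprod` of incidence matrices, Φ accumulated per observed module with
known modules visited in decreasing-Jaccard order). The test suite holds it
to within 1e−12 of an independent literal triple-loop evaluation of the
defining formula on hundreds of random instances.

## Module-level scores

`match_scores()` computes *recovery* (mean over known modules of the best
Jaccard with any observed module) and *relevance* (the converse). These
are coarser than the pair scores but robust and interpretable.

## Permutation normalization

Raw scores are incomparable across module definitions and datasets because
chance performance depends on module structure. `normalized_scores()`
divides each raw score by its mean over permuted versions of the known
modules, where a permutation draws one random bijection of the gene
universe and relabels every gene occurrence — module count, sizes and all
pairwise intersections are preserved exactly. The normalized score reads
as fold improvement over random modules of identical structure; the four
normalized scores combine by harmonic mean (with a hard zero rule) into
the composite used for tuning. The default is 500 permutations; the test
suite and examples use 25–100, which costs about a 2–6% relative standard
error on the null means at typical fixture sizes — adequate for the
qualitative checks made there. The permutation universe should be all
genes of the dataset when available; it defaults to the known-module gene
union.

`sticky_rewire()` provides a degree-sequence-preserving network null
(per-node in/out stickiness proportional to degree over √|E|, edge
probability the capped product) for sensitivity analyses at the network
level rather than the module level.

# Enrichment-based scores

`fisher_enrichment()` returns the exact hypergeometric upper-tail p-value;
the odds ratio uses the Haldane +0.5 correction on all cells only when
some cell is zero, and only for the odds ratio — p-values are never
corrected. `holm_sidak()` implements the Šídák step-down adjustment.
`aucodds()` integrates the fraction of items whose odds ratio meets a
cutoff over log10 cutoff ∈ [0, 3]; odds ratios are clamped into [1, 1000],
which keeps the statistic in [0, 1] and makes it insensitive to the wild
numerical ORs of tiny tables.

`regulator_coverage_score()` evaluates observed modules against weighted
per-context regulons when no hard gold standard exists (the human
situation): per weight cutoff and (regulator, context), every module is
tested and Holm–Šídák corrected across modules (the minimal family
containing the compared tests); per regulator the minimal corrected p
across contexts is kept with its matched odds ratio, because the relevant
cellular context of an observed module is unknown; regulators score their
best significant odds ratio (corrected p < 0.1) or floor at 1; `aucodds`
over regulators is averaged over weight cutoffs. The weight-cutoff grid
defaults to the deciles (0%–90%) of the positive weight distribution — a
neutral, data-adaptive choice where no canonical grid exists.

For annotation-based parameter estimation, `faucodds()` scores coverage of
the functional space and per-module coherence symmetrically and combines
them by harmonic mean (correction families: across modules within a gene
set for the coverage dimension, across gene sets within a module for the
coherence dimension); `filter_redundant_genesets()` first removes sets
with Jaccard > 0.7 against a larger retained set, largest first. `bhi()`
is the fraction of intra-module gene pairs sharing an annotation, averaged
per module then across modules (the pooled-pair alternative weights large
modules quadratically, which we avoid).

# Internal quality measures

`correlation_distance()` uses 1 − |r|: co-regulation shows up as strong
positive *or* negative correlation. (The signed variant (1 − r)/2 is
available; both keep the distance in [0, 1] with an exactly zero
diagonal.) Genes with zero variance have no defined correlation and are
reported by name as errors — filter first with `filter_low_variance()`,
whose threshold (sample standard deviation ≥ 0.5, n−1 denominator) is the
conventional pre-filter for log-scale microbial compendia (1 for human
data).

Cluster validity indices need a hard partition: `complete_assignment()`
first attaches every unassigned gene to its best-mean-correlation module
(ties to the earliest module; assigned genes never move), and
`disambiguate_modules()` keeps each multi-module gene only in its
best-correlated module. Silhouette is the standard mean width;
Davies–Bouldin uses a centroid-free medoid formulation (scatter = mean
distance to the cluster medoid, separation = medoid–medoid distance)
because only a distance matrix exists in correlation space. The
Kim–Ramakrishna index is implemented as the raw sum of its two terms —
under-partition (mean within-cluster distance to the medoid) and
over-partition (cluster count over minimal medoid separation) — without
the original's cross-candidate normalization, which requires scoring a
whole candidate range and therefore cannot be computed for a single
clustering; for comparing clusterings of the same data the raw sum
preserves the intended ordering (lower is better).

The three co-expression metrics (`coexpression_metrics()`) mirror the
three bicluster archetypes: mean pairwise correlation (global
co-expression), mean of each gene's top 5% z-scores (extreme expression —
`ceil(0.05·n)` samples per gene, computed per gene rather than pooled so a
few globally extreme samples cannot dominate), and the RMSD of
gene-standardized values around per-sample module means (pattern
tightness). `permuted_metric_test()` compares real against permuted
modules by median difference and a two-sided rank-sum test (exact for ≤ 10
values per side, normal approximation otherwise).

# Tuning harness

`grid_search()` enumerates a `param_grid()` (cartesian product in
declaration order, first parameter slowest), scores each detector output
with the normalized composite, and takes the first maximizer — a
deterministic tie-break so reruns agree. A failing detector run scores 0
with a warning rather than aborting a long search. `transfer_test()`
re-scores a target dataset at the source's best parameters; it refuses
synthetic→real transfers when realness tags are present, since parameters
tuned on synthetic data are systematically different from those tuned on
real data. `aggregate_scores()` weights each (dataset, definition) row by
1/(n_organisms · n_datasets_in_organism · n_definitions), so organisms and
definitions each carry equal total influence regardless of how many
datasets an organism contributes. `perturb_dataset()` supports robustness
curves by subsampling samples and adding Gaussian noise.

# The synthetic generator

`generate_gold_standard()` plants `n_regulators` regulons of
`targets_per_regulator` genes; a fraction `overlap_fraction` of each
regulon is borrowed from other regulons' own genes, creating multi-module
genes with controlled frequency. `simulate_expression()` uses a linear
module-activity model: each module gets an i.i.d. standard-normal activity
per sample; a `local_fraction` of modules is zeroed outside a random
active-sample subset (local co-expression, the structure biclustering
methods target); a gene is the sum of its modules' activities plus
Gaussian measurement noise of standard deviation `noise_sd` (in activity
units). Background genes carry independent unit-variance baseline noise
plus the same measurement noise, so they are non-degenerate even in
noise-free simulations and exercise the universe-restriction path of the
scoring code. All draws derive from the configuration seed; output is
bit-reproducible.

Default configuration: 10 regulons × 20 genes, 20% borrowed genes,
background at half the module-gene count, 200 samples, a quarter of
modules local with 30% active samples, noise at half the signal scale — a
mid-sized benchmark with every structural feature present at once.

**What the generator does and does not emulate.** It realizes the
statistical structures the scores must distinguish — overlap, partial
coverage, local co-expression, graded noise — with a linear additive
model. It does not emulate regulatory kinetics (no ODE/thermodynamic
simulation), network-topology realism (no scale-free degree structure),
correlated measurement error, or batch effects. Passing the synthetic
benchmark therefore demonstrates the *scoring machinery* is correct and
discriminating; it does not by itself certify detector rankings on real
compendia.

# Problem sizes and tolerances in the test suite

The suite favours exact small fixtures with independent oracles: literal
triple-loop formula evaluation (to 1e−12) on random instances of ≤ 12
genes and ≤ 5 modules; exhaustive hypergeometric enumeration for all 2×2
tables with universe ≤ 30; step-integration oracle for `aucodds`.
Stochastic checks use deliberately modest sizes chosen for tight-but-fast
statistics: 100-permutation null calibration on a 60-gene fixture,
20-seed monotone-degradation curves on 5×20-gene planted modules, and a
5-dataset (20 ordered pairs) training-versus-transfer comparison. These
sizes are the package's own trade-off between statistical resolution and
a test suite that runs in well under a minute.

# Known limitations

* The pair-score implementation is dense in the gene dimension; it is
  comfortable to a few thousand genes per module-set comparison but not
  designed for genome-wide pair matrices at single-cell scale.
* Only Pearson correlation backs the distance and co-expression measures;
  alternative similarity measures are out of scope.
* The interconnected module definition ships with MCL only; other graph
  clusterers can be applied externally and imported as GMT.
* `aucodds` depends on the [1, 1000] clamp; odds ratios beyond it are
  indistinguishable by design.
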