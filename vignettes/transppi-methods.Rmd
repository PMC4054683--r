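---
title: "Trans-acting eSNPs on a protein interaction network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-acting eSNPs on a protein interaction network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transppi)
```

# The scientific problem

Expression SNPs (eSNPs) that act in *trans* — modulating transcripts far
away on the genome or on other chromosomes — are statistically hard to
detect and mechanistically hard to interpret. `transppi` implements a
complete analysis for two interpretable classes of candidate trans
eSNPs: variants inside **exons** of a source gene, and variants anywhere
in the span of a **transcription factor** (TF) gene, introns included.
Each candidate eSNP defines a *source* gene (the gene harbouring it) and
a *target* gene (the trans-associated transcript). Source–target pairs
are projected onto a protein–protein interaction (PPI) network and
characterised by topology (geodesic distance, node degree, cluster
co-membership), co-expression, cis-effect enrichment, and functional
annotation — each quantity assessed against explicit permutation or
exact nulls.

Because the cohort-scale data such analyses consume cannot ship with a
package, `transppi` includes a first-class synthetic-data generator that
plants the very effects the analysis is designed to detect, so every
stage of the pipeline can be verified end to end.

# Association model

Association between a SNP and a transcript is a simple linear
regression of expression on additive dosage $g \in \{0, 1, 2\}$:

$$y_i = \alpha + \beta g_i + \varepsilon_i,$$

with a two-sided $t$-test on $\hat\beta$ ($n - 2$ degrees of freedom).
Samples with a missing dosage are dropped pairwise. Dosage coding is
additive and no covariates are included; the dominant use case is small
fully-sequenced cohorts ($n \approx 50$) where the direct association
to the sequenced variant is the object of interest.

A pair enters the trans scan result when its p-value passes the scan
threshold (default $10^{-6}$) *and* the target is in trans with respect
to the SNP: on a different chromosome, or on the same chromosome with
at least 1 Mb between the SNP position and the nearest boundary of the
target gene span. The SNP's own source gene is never a target.
Genotype QC uses the standard strict filters (MAF $> 0.05$, per-SNP
missingness $< 0.1$ applied first, then per-sample missingness
$< 0.1$, with per-SNP statistics recomputed on the retained samples).

All genomic coordinates in the package are 1-based and intervals are
closed; a SNP whose position equals an exon boundary is exonic.

# Network topology

The PPI network is an undirected simple graph with hop-count distances.
Distances are computed by per-node breadth-first search
(`igraph::distances`); the test suite proves the implementation
equivalent to a Floyd–Warshall oracle on dozens of random graphs. When
the network is disconnected, node pairs in different components receive
**twice the maximum finite distance observed within any component**.
This convention (rather than dropping such pairs) keeps cumulative
averages defined. The maximum is global across components — the
per-component-pair alternative was considered and rejected for
simplicity and testability.

`shortest_path()` returns one canonical geodesic: the path is
reconstructed backwards from the target, always stepping to the
lexicographically smallest neighbour one breadth-first layer closer to
the source. This makes path-level annotation analyses reproducible
across platforms and igraph versions.

Clustering uses the Louvain modularity heuristic
(`igraph::cluster_louvain`) under a fixed seed, with cluster ids
renumbered by decreasing size. Modularity is the standard
Newman–Girvan quantity; two disjoint 4-cliques score exactly 0.5, which
the suite asserts.

# Threshold trend profiles

The scan threshold is arbitrary, so trends are quantified across a
family of thresholds: on-network pairs are sorted by ascending
association p-value and every prefix of that list defines one
threshold (the $-\log_{10} p$ of the last pair included). For each
prefix the package reports the cumulative mean of pair distance, source
degree and target degree, and summarises each curve by its Spearman
correlation $r$ with the threshold.

Significance is assessed against permuted profiles: each permutation
draws the same number of source–target node pairs (uniformly over
network nodes, or by *edge switching* — resampling sources and targets
from their observed multisets, which preserves both marginals while
destroying the pairing), assigns them the real p-value ordering and
records the same $r$. The empirical p-value is the fraction of
permutations strictly beyond the observed statistic; it may be zero,
and the $(r+1)/(n+1)$ variant is deliberately not applied. The signal
direction is property-specific — for distance the alternative is a more
*negative* $r$, for degrees more *positive* — and the raw
"permuted $r$ > real $r$" count is reported alongside.

A property of this statistic worth knowing: cumulative averages of
random draws are strongly autocorrelated, so the permutation
distribution of $r$ is heavy-tailed — with profiles of 15–20 pairs,
roughly 5–10% of *random* profiles exceed $|r| = 0.85$. Empirical
significance therefore requires a nearly perfectly monotone observed
curve. This is not a defect of the implementation but a genuine
property of the statistic; it is the reason the planted fixture's
distance trend (typically $r \approx -0.9$) hovers around empirical
$p \approx 0.02$–$0.15$, and the weaker degree trend, though almost
always positive, rarely reaches $p < 0.05$ at this profile length.

# The statistics battery

* **Cis-effect enrichment.** For each unique exon source, the most
  associated eSNP is tested against the source's own expression; the
  count of nominal ($p < 0.05$) cis effects among $n$ unique sources is
  compared with Binomial($n$, 0.05) using the **strict** upper tail
  $P(X > k)$. The strict convention is asserted by an enumeration
  oracle; with the alternative $P(X \ge k)$ convention the test suite's
  frozen reference values would differ by an order of magnitude.
* **Fisher tests** (cis-effect background, cluster co-occurrence,
  binding-database membership, exon-position bins) are one-sided in the
  enrichment direction by default, two-sided on request, and validated
  against full hypergeometric enumeration for small tables.
* **Gene-set enrichment** is the upper-tail hypergeometric test with
  Benjamini–Hochberg FDR across categories; categories below the
  minimum overlap (2 for unit/path annotation) are excluded before
  testing. A TF *unit* is the TF source plus all its trans targets.
* **Co-expression.** Spearman $|r|$ of source–target pairs is compared
  with the background distribution of gene-pair correlations by
  two-sided Wilcoxon rank-sum test.
* **Path annotation content.** For shortest paths between exon sources
  and targets, two statistics per category: total occurrences of
  category genes along the paths (counted with repetition across
  paths) and the number of paths containing at least one category
  gene; compared against length-matched permuted path sets drawn
  without replacement from a permuted-path pool, with ties counting
  toward the empirical p ("equal or greater"). Endpoints are included
  in path content by default; an endpoints-excluded variant is
  available.
* **Positional bias.** Exonic eSNPs versus background exonic SNPs:
  a Fisher test of middle versus first/last exon bins (single-exon
  genes excluded; exon order strand-aware) and a rank-sum test on the
  strand-aware fractional position within the concatenated exonic
  sequence.

A subtlety found while testing the TF target-multiplicity statistic
(count of sources with two or more distinct targets): under the
edge-switching null the source multiset is preserved by construction,
so this statistic has essentially no power against that null — permuted
sets can even exceed the real count, because spreading the same slots
over the source multiset manufactures multi-target sources. The
statistic, its permutation p and the per-source count vector are all
reported, but detecting modular regulation against an edge-switching
null requires a statistic sensitive to more than the source margin.

# The synthetic-data generator

The generator defines the package's standard study conditions
(`run_config()` defaults): 50 samples, 200 genes over 4 chromosomes,
3 SNPs per gene with allele frequencies uniform on (0.10, 0.49), 2%
missing calls, a 4-block planted-partition interaction network
($p_{in} = 0.3$, $p_{out} = 0.01$) and Gaussian expression noise
($\sigma = 1$) on an already-normalised scale. There is no linkage
disequilibrium, no population structure and no count-level model —
the analysis consumes normalised expression, so the generator produces
it directly.

**Degree correction.** Real PPI networks have heavy-tailed degree
distributions; a plain planted-partition graph does not, leaving no
hubs to plant targets on. Node propensities are therefore lognormal
with mean 1 (sdlog 0.75 in the standard fixture), multiplying edge
probabilities while preserving expected edge counts and leaving
Louvain block recovery essentially perfect (ARI $\approx 0.99$).

**Planted effects.** Effects propagate mechanistically: the source
gene's expression is $\beta_{cis} \cdot$ dosage plus noise, and each
target is $\beta_{trans} \cdot$ (source expression) plus noise, so a
trans association is only as detectable as its cis cascade. Three
tiers are planted:

* **exon** pairs (12): full-strength effects
  ($\beta_{cis} = \beta_{trans} = 1.5$) whose single target is a
  direct network neighbour, sampled degree-weighted among the three
  highest-degree available neighbours, and preferentially in a
  different planted block (coding variation crosses functional
  clusters);
* **tf** units (4 × 3 targets): full-strength effects on targets drawn
  from the TF's own planted block (modular regulation); TF causal SNPs
  prefer intronic positions, as TF-span eSNPs predominantly are;
* **background** pairs (40, two per source): weak effects
  ($0.55 \times \beta_{trans}$) on uniformly random on-network trans
  targets. These play the role of the weak and spurious associations
  that enter as the threshold loosens and thereby generate the
  dilution trends the threshold scan measures.

Causal SNPs are restricted to common variants (MAF $\ge 0.3$, taking
the most common qualifying SNP in the gene). This is a power-analysis
choice made up front: the induced dosage-to-target slope is
$1.5 \times 1.5 = 2.25$ with residual standard deviation
$\sqrt{1.5^2 + 1} \approx 1.80$, so even at MAF $= 0.5$ the
noncentrality of the association $t$-statistic at $n = 50$ is
$2.25\sqrt{50 \times 0.5}/1.80 \approx 6.2$ against a critical value
of $t_{0.05/10^6, 48} \approx 5.6$ — per-pair power $\approx 0.72$ at
the genome-wide threshold, falling quickly for rarer variants. Planted
recovery at $p < 10^{-6}$ is therefore expected around 50–70% and
**cannot** reach higher in expectation under these effect sizes and
sample size; readers comparing recovery figures should calibrate
against this ceiling, not against 100%.

**What the generator does not emulate:** linkage disequilibrium and
tagging, population stratification, read-count noise and normalisation
artefacts, hub-biased false discovery, or annotation databases with
realistic term overlap (gene sets are cluster-aligned plus random).
Passing tests therefore demonstrate correctness of the statistical
machinery on data satisfying the model's assumptions, not robustness
to the pathologies of real cohorts.

# Numerical and design choices

* Missing dosages use `NA` as the dedicated sentinel; tests drop them
  pairwise, and the generator's expression model substitutes the SNP
  mean (the generative model is fully observed).
* Ties in the best-eSNP reduction break by lexicographic SNP id; scan
  output is sorted by (p, eSNP id, target id) and is invariant to input
  order.
* Degenerate trend profiles (zero variance in a cumulative mean) report
  $r = 0$ with an explicit flag rather than `NA`.
* Sub-seeds for independent random streams are derived from the master
  seed, an operation tag and a replicate index by a fixed integer hash,
  keeping every stage reproducible and collision-free below $2^{31}$.
* Edgeless graphs get the degenerate singleton partition with
  modularity reported as 0 and a warning.
* Calibration tests use sizes where the discrete exact tests are
  effectively continuous (e.g. 150 pairs against a fresh 3,000-pair
  null per replicate), since one-sided exact p-values on small tables
  are conservative by construction and would fail any uniformity check
  for reasons unrelated to correctness.
* Simulation scales in the test suite (e.g. 200-replicate calibration
  batches, 99–1,000 permutations, graphs up to 200 nodes) are chosen so
  the whole suite completes in a few minutes on one core while keeping
  every Monte-Carlo tolerance at 3 standard deviations or better.

# Known limitations

* Per-pair detection power is bounded (see above); recovery-style
  figures saturate near 70% under the standard conditions.
* Empirical trend significance at 15–20-pair profiles requires
  near-perfect monotonicity; the degree trend usually shows the right
  sign but not $p < 0.05$ at this scale.
* The edge-switching null cannot detect source-margin statistics (the
  TF multiplicity subtlety above).
* No covariate adjustment or population-structure correction is
  implemented, matching the intended small fully-sequenced cohort
  setting.
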