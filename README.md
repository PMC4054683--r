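# transppi

Trans-acting genetic variants (eSNPs) are SNPs associated with the
expression of transcripts far away on the genome — on another
chromosome, or at least 1 Mb from the gene they perturb. They are hard
to detect (the multiple-testing burden is enormous) and hard to
interpret (the mechanism connecting variant and distal transcript is
usually unknown). `transppi` implements an analysis strategy for two
interpretable classes of trans eSNPs — variants inside **exons** and
variants in the span of **transcription factor (TF) genes** — for
researchers working with small, fully sequenced cohorts with matched
expression profiles.

Each candidate eSNP defines a **source** gene (harbouring the variant)
and a **target** gene (the trans-associated transcript, linear
regression of expression on additive dosage, `p ≤ 10⁻⁶`). Source–target
pairs are projected onto a protein–protein interaction (PPI) network
and interrogated with:

* **topology** — hop-count geodesic distances (disconnected components
  get twice the maximum finite within-component distance), node
  degrees, canonical shortest paths, Louvain modularity clusters;
* **threshold trend profiles** — pairs sorted by association p-value;
  for every prefix, cumulative means of distance and degree; each curve
  summarised by Spearman *r* against the `−log₁₀ p` threshold and
  tested against permuted source–target pair profiles (empirical
  p-value = fraction of permutations strictly beyond the observed *r*);
* **a battery of exact statistics** — strict-tail binomial enrichment
  of nominal cis effects `P(X > k), X ~ Bin(n_sources, 0.05)`,
  one-sided Fisher tests against background tables, hypergeometric
  gene-set enrichment with Benjamini–Hochberg FDR for TF *units*
  (a TF source plus its targets) and for shortest-path gene content,
  Wilcoxon co-expression and effect-size comparisons, cluster
  co-occurrence, binding-database membership, exon-positional bias.

Because the real cohorts and databases cannot ship with a package, a
first-class synthetic generator (`simulate_study()`) plants the
complete causal structure — cis effects that propagate to proximal,
hub-biased trans targets; modular TF regulatory units; weak background
pairs that dilute loose thresholds; a community-structured,
heavy-tailed PPI network — so the entire pipeline is verifiable end to
end with no downloads.

## Worked example

```r
library(transppi)

cfg   <- run_config(seed = 1)      # 50 samples, 200 genes, 4-block PPI
study <- simulate_study(cfg)       # genotypes, expression, network, sets
run   <- run_pipeline(study)       # QC -> scans -> topology -> statistics

run$trend
#> # A tibble: 3 × 6
#>   property           spearman_r direction empirical_p empirical_p_greater n_perm
#> 1 mean_distance          -0.949 less            0.022               0.978   1000
#> 2 mean_source_degree      0.597 greater         0.188               0.188   1000
#> 3 mean_target_degree      0.309 greater         0.31                0.31    1000

run$cis
#> $k_nominal 13   $n_sources 13   $p 0
run$tf_cooccurrence$fisher_p
#> [1] 9.54e-05
run$summary[, c("n_exon_pairs", "n_tf_pairs", "exon_recovery")]
#>   n_exon_pairs n_tf_pairs exon_recovery
#> 1           16          7           0.5
```

Reading this output: the cumulative **distance** of exonic source–target
pairs rises as the association threshold loosens (Spearman r = −0.95
against `−log₁₀ p`; only 2.2% of 1,000 permuted pair profiles are as
monotone), i.e. the strongest associations connect proteins that
physically interact — while weaker ones scatter across the network. All
13 recovered exon sources show a nominal **cis** effect of the eSNP on
its own gene (binomial p ≈ 0), the planted mechanism. All 7 recovered
**TF** pairs fall in the same network cluster as their source
(Fisher p ≈ 1e-4 against uniform pairs), the modular mode of trans
regulation. Recovery of planted exon pairs is 50% — close to the
analytic per-pair power ceiling of ~0.7 at these effect sizes and
n = 50 (see the methods vignette), not a defect.

`autoplot(run$profile)` draws the three cumulative-mean curves against
the threshold; `tidy()`/`glance()` methods cover partitions and trend
profiles.

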