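# methtempo

Temporal DNA methylation dynamics across tissues and their association
with gene expression.

`methtempo` is an R package for RRBS (reduced-representation bisulfite
sequencing) time-course studies that ask two questions:

1. **Are temporal methylation changes tissue-general?** When CpG
   methylation shifts across a season in a target tissue (e.g. liver), is
   the same shift visible in an accessible surrogate tissue (red blood
   cells)? If so, repeated blood sampling can monitor epigenetic dynamics
   in tissues one cannot biopsy.
2. **Do methylation changes predict expression changes?** Within defined
   genomic regions — TSS, promoter, gene body, 10 kb flanks — do sites
   that gain methylation sit in genes that lose expression (and vice
   versa)?

It is aimed at molecular ecologists and epigenomics analysts working with
per-CpG count tables (Bismark coverage format) and pooled RNA counts from
cross-sectional designs: different individuals sampled at each time point.

## The statistical core

* **Per-site differential methylation.** For a pairwise time contrast with
  pooled group counts (m₁,c₁), (m₂,c₂), the binomial likelihood-ratio
  statistic 2[ℓ(p̂₁)+ℓ(p̂₂)−ℓ(p̂₀)] ~ χ²₁; a site is a DMS when the pooled
  difference |Δ| ≥ 15 percentage points and BH q ≤ 0.01. An omnibus time
  test fits per-site binomial-logit regressions by IRLS (time + temperature
  vs temperature only, χ²₂, q ≤ 0.01).
* **Cross-tissue concordance.** Methylation proportions are z-scored per
  site within tissue, changes are differences of time-point means of z,
  and concordance is Pearson r over sites called DMS in ≥ 1 tissue
  (df = n − 2).
* **Expression.** A deliberately simple negative-binomial
  likelihood-ratio time test on pooled counts (median-of-ratios size
  factors, moment dispersion from residual variance, χ²₂), with
  log₂((n̄_b+0.5)/(n̄_a+0.5)) fold changes.
* **Integration.** Omnibus-significant sites × time-responsive genes,
  trimmed at 5 pp / 0.5 log₂ units, assigned to quadrants Q1 (hypo-meth,
  up-regulated) … Q4; enrichment of the concordant quadrants Q1∪Q3 in the
  TSS region versus the 10 kb downstream control region by a two-sided
  exact hypergeometric test.
* **Synthetic cohort.** A seeded generator reproduces the study design
  (18 females, 3 time points, 2 tissues, 2 temperature environments,
  2 RNA pools × 3 females per time point) with beta-binomial methylation
  counts, known tissue-general/specific temporal effects and optional
  TSS-coupled expression, plus full ground truth for recovery tests.

The methods vignette (`vignettes/temporal-methylation.Rmd`) documents the
models, numerical choices and known limitations in detail.

## Worked example

Simulate a small cohort with tissue-general and tissue-specific effects
and TSS-coupled expression, then run the full pipeline:

```r
library(methtempo)
cfg <- pipeline_config(
  seed = 11,
  simulate = sim_config(seed = 11, n_genes = 50, chrom_length = 1.6e6,
                        n_sites = 1200, fraction_temporal = 0.4,
                        coupling_k = 0.05, fraction_temporal_genes = 0.8))
res <- run_pipeline(cfg)

res$qc$RBC
#> Sample QC over methylation proportions
#>   samples: 18; mean range 0.4195-0.5650; variance range 0.07233-0.08622
#>   location homogeneity (Kruskal-Wallis) p = 2.51e-88
#>   scale homogeneity (Fligner-Killeen)  p = 5.89e-08

table(res$classification$d12$klass)
#>        general liver_specific   rbc_specific
#>            190            129            139

res$concordance$d12$all_dms
#> Cross-tissue concordance (d12, all_dms): r = 0.592, df = 456, p = 1.45e-44

res$enrichment[["liver->liver:d12"]]
#> Quadrant enrichment (Fisher exact, two.sided)
#>          Q1+Q3 Q2+Q4
#> tss         13     1
#> down10kb    35    30
#>   odds ratio = 11.143, p = 0.006508
```

Reading the output: samples differ significantly in mean and variance of
methylation (hence the z-scoring); 190 shared sites change in both tissues
(tissue-general) against 268 in one tissue only; the changes correlate
across tissues at r = 0.59 over the 458 sites called in at least one
tissue (df = 456); and associations in the TSS region fall in the
concordant quadrants far more often than in the downstream control region
(13:1 vs 35:30, p ≈ 0.007) — the simulated negative TSS
methylation-expression coupling is recovered.

With `out_dir` set, every stage writes a provenance-headed TSV
(QC, DMS tables, classification, concordance, DE genes, candidate-gene
correlations, quadrant associations, enrichment, regions BED); identical
config and seed reproduce the files byte for byte. File-based inputs
(per-sample `.cov` files, metadata TSV, GFF3, count TSVs) follow the same
path; `write_fixture_bundle()` emits a complete bundle in those formats.
A thin command-line wrapper is installed at
`inst/scripts/methtempo-pipeline.R`.

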