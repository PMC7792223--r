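---
title: "Temporal methylation dynamics across tissues: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal methylation dynamics across tissues: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtempo)
```

## The scientific setting

Seasonal traits such as avian timing of breeding are accompanied by changes
in DNA methylation. Two questions drive this package's design. First, are
temporal methylation changes *tissue-general* — visible both in an easily
sampled surrogate tissue (red blood cells, RBC) and in a target tissue
(liver) — or tissue-specific? If blood tracks liver, repeated blood
sampling can stand in for inaccessible tissues. Second, do methylation
changes in defined genomic regions (TSS, promoter, gene body, 10 kb
flanks) relate to gene-expression changes in the predicted negative
direction?

The cohort emulated throughout is cross-sectional: 18 females, 6 sacrificed
at each of three time points across a breeding season, kept in two
temperature environments, with RRBS methylation per female and tissue and
pooled RNA counts (2 pools x 3 females per time point).

## Data model and filtering

RRBS yields, per CpG site and sample, a coverage count and a methylated
count; the methylation proportion is their ratio. Sites are retained only
when covered at least 10x in *every* sample of a tissue, and sites that are
exactly 0 or exactly 1 in all samples are removed (they cannot change over
time). Cells missing from a sample's coverage file are represented as
coverage 0 and are therefore removed by the 10x rule; there is no
imputation. CpG sites are strand-resolved and never merged across strands.
Cross-tissue analyses use the intersection of the two tissues' surviving
sites.

## Differential methylation

Two test families are implemented, both authored in this package.

**Pairwise contrasts** (time 1 vs 2, written d12; time 2 vs 3, d23) pool
reads within each group: with group totals $(m_1, c_1)$ and $(m_2, c_2)$,
the statistic is
$2[\ell(m_1,c_1,\hat p_1) + \ell(m_2,c_2,\hat p_2) - \ell(m_1{+}m_2,
c_1{+}c_2,\hat p_0)]$ on one degree of freedom, where $\ell$ is the
binomial log-likelihood and the $\hat p$ are pooled proportions. The
methylation difference is reported in percentage points,
later-minus-earlier, so hypermethylation at the later time is positive. A
site is a DMS when $|\Delta| \ge 15$ pp *and* BH-adjusted $q \le 0.01$.
The plain likelihood carries no overdispersion correction, matching the
standard RRBS logistic-regression test; a per-site Pearson scale
correction is available (`overdispersion = "scale"`) but off by default.
Pairwise tests use no covariate; whether the original analysis included
temperature in its pairwise runs is not documented, so the omnibus test is
the covariate-adjusted path.

**The omnibus time test** fits, per site, a binomial-logit regression by
iteratively reweighted least squares: full model = intercept + two
time-point indicators + temperature indicator; null model drops the time
indicators. The likelihood-ratio statistic has 2 degrees of freedom;
significance is $q \le 0.01$. Numerics: at most 50 IRLS iterations,
relative deviance tolerance $10^{-8}$, step halving whenever a step would
increase the deviance, and the linear predictor clamped to $\pm 30$, which
bounds the step under complete separation. Non-converged sites keep the
deviance at the last iterate and are flagged. When both temperature groups
carry identical data the fit reduces exactly to the closed-form pooled
three-group test, which the test suite verifies.

A shared site significant in both tissues for a contrast is classed
*tissue-general*; in exactly one, *tissue-specific*; in neither, omitted.

## Standardization and cross-tissue concordance

Samples differ in mean and variance of methylation (checked by
Kruskal-Wallis and Fligner-Killeen tests in the QC stage; the QC variance
is the population variance, divide-by-n, so tests can be exact), so
proportions are z-scored before differencing. The published description of
the standardization scope is ambiguous (grand tissue mean vs per-site mean
vs per-sample mean); the default here standardizes **each site across the
tissue's samples** (sample SD, n−1), because the figures this reproduces
plot a per-site normalized change, and per-site scaling is what makes
changes comparable across sites with different baselines. `standardize =
"sample"` and `"grand"` are available for sensitivity analysis. Zero-SD
sites are dropped with a warning.

The per-site change is the difference of time-point means of z-scores
(unweighted by coverage — z-scores are already scale-free). Concordance
between tissues is the Pearson correlation of these changes over the sites
called DMS in at least one tissue (optionally restricted to promoter or
TSS membership), with $df = n - 2$ and a two-sided t p-value.

## Region annotation

Regions are built strand-aware from gene models: TSS region 300 bp
upstream to 50 bp downstream of the transcription start (a 350 bp span);
promoter 2000 bp upstream to 200 bp downstream; gene body the full
transcript span (exons and introns); 10 kb flanks adjacent to the gene
body, not to the promoter. On the minus strand, upstream means larger
coordinates. Coordinates are 1-based inclusive internally; BED exports are
0-based half-open. Intervals are truncated at coordinate 1. One TSS per
gene is used (the annotated gene-record start); isoform resolution is out
of scope.

Assignment is inclusive-endpoint containment. Because the categories
overlap by construction, a site keeps *all* its memberships by default
(multi-assignment, matching how the region tallies it reproduces count
sites more than once); `priority_assignment = TRUE` keeps only the
highest-priority category (TSS > promoter > gene body > upstream >
downstream) for workflows that need unique labels.

## Differential expression (a simplified stand-in)

The expression stage deliberately does not replicate a full
shrinkage-based DE engine; it is a small, deterministic negative-binomial
likelihood-ratio test adequate for pooled counts at this scale, and the
integration stage equally accepts an externally produced DE table.
Normalization is median-of-ratios against the geometric-mean reference,
factors centered to geometric mean 1. Per gene, dispersion is estimated by
moments from the *residual* variance about the time-point means of
normalized counts (so a genuine time effect does not inflate the
estimate), floored at $10^{-8}$; means are fitted per group by Newton
iteration on the log scale with size factors as offsets; the full
(time-factor) and null (intercept) models are compared on 2 degrees of
freedom. As dispersion reaches the floor the statistic coincides with the
Poisson likelihood ratio. With only two pools per time point the
chi-square reference is approximate and the raw test is anticonservative;
this is a known limitation, acceptable because downstream integration
treats test and control regions symmetrically. Log2 fold changes use a 0.5
pseudo-count: $\log_2((\bar n_b + 0.5)/(\bar n_a + 0.5))$. Genes are
forwarded when the time-effect adjusted p is below 0.05 and, where a
selection-line p-value exists, its adjusted value is above 0.05.

## Integration of methylation and expression

**Candidate genes (per-female path).** The cohort is cross-sectional, so a
per-female change is constructed from all pairwise differences between
time points: each later-time female receives the mean of her value minus
every earlier-time value, and vice versa; every entry is oriented
later-minus-earlier, and the grand mean equals the difference of
time-point means exactly. Methylation and expression pairwise-change
vectors are correlated per (site, gene), per contrast; p-values are
BH-adjusted within contrast, with zero-variance (undefined) pairs flagged
and excluded from adjustment.

**Genome-wide path.** Sites with an omnibus time effect ($q \le 0.01$) are
paired with time-responsive genes through their region memberships. Here
the methylation change is on the *raw percentage scale* (difference of
time-point means of per-female percentages) — z-scores are used only for
cross-tissue concordance; the two scales are never mixed. Pairs with
$|\Delta\text{meth}| < 5$ pp or $|\log_2\text{FC}| < 0.5$ are trimmed,
and the rest are assigned quadrants: Q1 hypo-methylation/up-regulation,
Q2 hyper/up, Q3 hyper/down, Q4 hypo/down; Q1 and Q3 are concordant with
the expected negative relationship. A site contributes once per region
category it belongs to, and the site-gene-region tuples are the counting
unit of the enrichment table.

**Enrichment.** The 2x2 table is region (TSS vs 10 kb downstream control)
by quadrant class (Q1+Q3 vs Q2+Q4). The downstream flank is the control
because no methylation-expression relationship is expected there, whereas
the upstream flank overlaps promoters. The p-value is the exact
hypergeometric enumeration; sidedness is two-sided by default (the
original analysis does not state it, and two-sided is consistent with its
use of a two-sided hypergeometric test elsewhere), with one-sided options
exposed. The odds ratio is the sample odds ratio, with a 0.5 continuity
correction only when a cell is zero (flagged).

## The synthetic cohort

`sim_config()` fixes the study design: 18 females (6 per time point),
alternating warm/cold temperature assignment within time point, families
of two females, two tissues, 2 RNA pools x 3 females per time point.
Defaults that the design itself does not dictate were chosen once as
realistic for RRBS time courses and are not tuned per analysis:

* baseline methylation logit-normal with mean 0, SD 1.5 (a broad,
  U-shaped proportion distribution typical of CpG methylation);
* 10% of sites temporal, effect 25 pp per contrast, feasibility-clamped to
  [0.02, 0.98]; half the temporal effects tissue-general;
* per-sample mean shifts SD 0.1 and family effects SD 0.1 on the logit
  scale (a few percentage points at mid-range — the magnitude that makes
  the QC stage flag samples, as real cohorts do);
* coverage negative binomial with mean 30 and size 20 (moderate
  overdispersion while keeping most sites fully covered at 10x);
* methylated counts beta-binomial with intra-site correlation rho = 0.02,
  emulating biological replicate overdispersion;
* temperature is generated but given zero true effect, so the omnibus
  covariate is exercised without confounding (a nonzero effect is a
  config option);
* expression baseline log-normal (log mean log 200, SD 1), NB dispersion
  0.05; uncoupled time effects on 30% of genes with SD 1 log2 unit; TSS
  coupling, when enabled, sets a gene's per-contrast log2 shift to
  $-k \times \Delta\text{meth(pp)}$ + Normal(0, 0.3) noise from the
  temporal TSS sites it contains;
* candidate-gene expression is emitted per female (continuous,
  log-normal), separate from pooled counts, to exercise the
  pairwise-change path.

The generator guarantees at least one CpG site in every gene's TSS,
promoter, gene-body and flank intervals, so every region category is
populated at any problem size. All randomness derives from the single
config seed (fixed offsets per stage), making every output byte-identical
under a repeated seed.

What the generator does **not** emulate: read-level artifacts (bisulfite
conversion error, mapping bias), linked sites along a fragment,
chromosome-scale methylation domains, isoform structure, and
selection-line stratification. Passing recovery tests therefore shows the
statistical machinery is correct under the stated noise model, not that
the pipeline is robust to every artifact of real RRBS data.

## Calibration and recovery behaviour

The test suite runs the following study-condition checks (sizes chosen to
keep each run to seconds or a few minutes while leaving Monte-Carlo error
well inside the asserted margins):

* with no temporal effects (4,000 sites), the pairwise DMS rate at
  $q \le 0.01$ stays below 3%;
* with independent methylation and expression changes, the enrichment
  test rejects at $p \le 0.05$ in 2-8% of 500 association-level
  replicates (slightly conservative, as exact tests on tables of ~60 per
  region are);
* with all temporal effects tissue-general (20,000 sites, 25 pp), the
  cross-tissue concordance on called DMS reaches $r \ge 0.9$ and caller
  sensitivity exceeds 0.8; with all effects tissue-specific, $|r| \le
  0.2$;
* with TSS coupling $k = 0.05$ (160 genes, 2,000 sites, ~30+ associations
  per region), the enrichment test is significant in well over 80 of 100
  replicates.

One documented boundary case: the *empirical FDR* of the plain binomial
pairwise caller under the overdispersed generator is about 0.057-0.067
rather than below 0.05. The caller deliberately carries no overdispersion
correction, while the generator deliberately produces beta-binomial counts
plus sample and family effects; the rho = 0.02 component alone consumes
the whole 5% budget, and any realistic sample-level variation pushes the
rate past it. The corresponding assertion is left failing rather than
weakening either side; enabling `overdispersion = "scale"` restores
conservativeness at some cost in sensitivity.

## Running the pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(
  seed = 11,
  simulate = sim_config(seed = 11, n_genes = 50, chrom_length = 1.6e6,
                        n_sites = 1200, fraction_temporal = 0.4,
                        coupling_k = 0.05, fraction_temporal_genes = 0.8),
  out_dir = "run1")
res <- run_pipeline(cfg)
res$concordance$d12$all_dms
res$enrichment[["liver->liver:d12"]]
```

Every stage writes a TSV with a provenance header (package version, seed,
config checksum); re-running the same configuration reproduces the files
byte for byte. File-based inputs (Bismark-style coverage files, metadata
TSV, GFF3, count tables) follow the same path as simulated ones, and
`write_fixture_bundle()` emits a complete on-disk bundle in exactly those
formats.
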