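# EpiMutSig

Downstream analysis of somatic mutation calls from targeted cancer gene
panels, centred on two questions that drive cutaneous-melanoma cohort
studies:

1. **Are epigenetic regulators disproportionately mutated?**  A panel's
   genes are annotated against a registry of epigenetic regulators
   (DNA methylation/demethylation, histone modification, chromatin
   remodeling, miRNA processing), and the epigenetic share of the most
   recurrently mutated genes is compared with the panel-wide share.
2. **Do those mutations carry the ultraviolet damage signature?**  Every
   mutation event is classified by UV signature — single C>T, tandem
   CC>TT, C>T within a dinucleotide substitution (the UVB classes), and
   single G>T (the UVA class) — and per-gene UVB counts are compared
   between epigenetic and non-epigenetic genes.

The package is aimed at molecular-pathology and cancer-genomics groups
who already have per-sample mutation calls (MAF-like tables or VCF) from
a tumor-only targeted panel and want a reproducible, tested version of
the downstream arithmetic: tumor-only QC and germline filtering,
consequence calling against transcript models, merging of adjacent SNVs
into dinucleotide events, cohort tallies and rankings, and the
comparative statistics.

## The statistics at the core

With `x1` of `n1` top-ranked genes and `x2` of `n2` panel genes encoding
epigenetic regulators, the enrichment test is the pooled two-proportion
z test without continuity correction,

    z = (p̂1 − p̂2) / sqrt( p̂(1−p̂)(1/n1 + 1/n2) ),   p̂ = (x1+x2)/(n1+n2)

with a two-sided normal p-value; z² equals the Pearson chi-square on the
corresponding 2×2 table (no Yates correction), which the test suite
verifies to 1e-9.  Per-gene UVB counts in epigenetic versus
non-epigenetic genes are compared with an unpaired pooled-variance
Student t test (Welch available by flag).  Proportions are reported with
Clopper–Pearson exact binomial intervals obtained from the beta-quantile
inversion of the binomial tails.  All of these are implemented in the
package from the formulas and cross-checked in the tests against the
corresponding base-R implementations and against exact enumeration or
bisection oracles.

A seeded synthetic-cohort generator (`simulateCohort()`) emulates the
study conditions — 38 samples, a 275-gene panel with a 41-gene
epigenetic subset, negative-binomial mutation counts per sample (mean
20, SD ≈ 21.5), a UVB-dominated substitution mixture, and an epigenetic
rate multiplier of 1.6 — and emits ground-truth labels so every pipeline
stage is testable without external data.

## Worked example

```r
library(EpiMutSig)

sim <- simulateCohort(SimConfig(seed = 1))
report <- analyzeCohort(sim$variants, sim$models, sim$registry,
                        sim$panel, nSamples = 38)

report$summary
#> CohortSummary: 729 non-silent events in 235 of 275 genes across 38 samples
#>   mean 19.2 / median 17.5 / sd 19.8 mutations per sample
#>   epigenetic events: 162 (22.2%)

report$zTest
#> two-proportion z: statistic = 2.384, two-sided p = 0.01713
#>   estimate 0.1509, 95% CI [0.002788, 0.299]

report$tTest
#> Student two-sample t: statistic = 1.694 (df = 233), two-sided p = 0.09159
#>   estimate 0.6521, 95% CI [-0.1063, 1.411]
```

The summary says the simulated cohort carries 729 non-silent events, of
which 22.2% hit epigenetic regulators (the generator's 1.6× epigenetic
rate multiplier at work).  The z test compares the epigenetic share of
the 40 most recurrently mutated genes (here 12 of 40) with the panel
share (41 of 275): z = 2.38, p = 0.017, a significant enrichment.  The
t test compares mean per-gene UVB-signature counts in epigenetic
(2.8) versus non-epigenetic (2.2) mutated genes; in this single
38-sample replicate the excess has the expected sign but p = 0.09 —
at this cohort size the per-gene comparison is underpowered, which is
why the test suite checks the sign across 50 replicates rather than
any single p-value.

`writeReportBundle(report, "report/")` writes `summary.json`, the
per-event and removed-variant tables, and a plain-text report;
`cmdSimulate()`/`cmdAnalyze()` drive the same pipeline from a YAML
config (a thin CLI wrapper ships in `inst/scripts/epimutsig.R`).

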