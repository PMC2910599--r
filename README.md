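# lineamp

Integrative copy-number/expression discovery of **lineage-specific
amplicon driver genes**, for cancer genomicists comparing two
histological cohorts (e.g. lung squamous cell carcinoma versus
adenocarcinoma) profiled by tiling-path array CGH with matched
expression data.

A recurrent amplicon that appears in only one lineage is presumed to be
selected for a driver gene inside it. `lineamp` implements the full
computational strategy for finding that gene:

1. **aCGH processing** — replicate QC (drop clones with replicate
   SD > 0.075 or SNR < 3), exact penalised least-squares segmentation
   (objective `SSE + λσ̂²k`, λ = 6.75, ≤ 100 breakpoints/chromosome),
   three-state calling, and high-level amplification detection
   (log2 > 0.6 for tumors / 0.8 for CIS over ≥ 2 consecutive clones).
2. **Cohort disparity** — nearest-neighbour state imputation within
   10 Mb, aggregation of clones into ≥ 90%-concordant regions, an exact
   3×2 Fisher test (gain/neutral/loss × cohort) per region, BH
   correction over the regions with α = 0.01, 1-Mb directional merging,
   and >20% / >10% frequency filters.
3. **Dosage–expression integration** — 10-kb windowed, per-sample
   Z-transformed copy-number signal correlated with log10 expression
   (one-tailed Spearman, ρ > 0.75), plus a guarded one-tailed
   Mann–Whitney comparison of gain/amplified versus copy-number-neutral
   samples (BH α = 0.05, median and mean must be higher).
4. **Candidate cascade** — conjunction of disparity-region membership,
   cohort-restricted expression (BH ≤ 0.01), both integration methods,
   and >2-fold elevation over normal tissue; near-misses are reported
   with the single failed criterion named.
5. **SAM signature** — two-class unpaired SAM
   (`d = Δmean/(s + s0)`, permutation q-values, q ≤ 0.05) between the
   top/bottom-10 expressers of a chosen gene, with optional
   hypergeometric gene-set enrichment over GMT files.
6. **Synthetic cohorts** — a seeded generator that plants a driver
   amplicon with dosage-coupled expression, a panel of decoy genes each
   violating exactly one cascade criterion, a high-noise CIS-like
   cohort and an expression-only normal cohort, so the whole pipeline
   is testable without any external data.

## Worked example

```r
library(lineamp)

cfg <- simulationConfig(seed = 5)        # default study conditions
res <- runDriverAnalysis(cfg)            # simulate + full pipeline

res$regions[, c("start", "end", "direction", "higherCohort",
                "freqA", "freqB", "padj")]
#>      start      end direction higherCohort freqA freqB         padj
#> 1  1920000  8020000      loss           AC  0.40   0.0 9.379239e-07
#> 2 12000000 15540000      gain         SqCC  0.04   0.4 6.676252e-05
#> 3 24960000 27060000      gain         SqCC  0.04   0.8 7.195972e-15
#> 4 30960000 33060000      gain         SqCC  0.04   1.0 4.205713e-25

subset(res$cascade, candidate | nearMiss,
       c(gene, candidate, failedCriterion, rho, fold))
#>              gene candidate         failedCriterion       rho      fold
#> 1          driver      TRUE                    <NA> 0.8873518  5.499470
#> 2   decoy_outside     FALSE        disparity_region 0.8703061  5.645217
#> 3     decoy_group     FALSE            dosage_group 0.7670408 13.959395
#> 4    decoy_not_de     FALSE differential_expression 0.7527937  3.263084
#> 5 decoy_uncoupled     FALSE      dosage_correlation 0.2620495  5.101786
```

Reading the output: the four reported regions are exactly the planted
truth — the AC-biased distal loss (40% vs 0%) and three SqCC-biased
gains, including the 3.5-Mb driver region gained in 40% of the SqCC
cohort against a 4% AC background, each with its exact-Fisher adjusted
p. In the cascade report the planted driver is the only gene passing
all five criteria (dosage correlation ρ = 0.89, 5.5-fold elevation over
normals), while the near-misses each fail exactly the criterion they
were built to violate (under the default noise a decoy can slip below a
second threshold as well; at zero noise the one-criterion property is
exact).

`runPipeline(cfg, "out/")` writes the same results to disk (per-sample
SEG, amplification BED, region TSV/BED, statistics TSVs, a JSON audit
with every contingency table, and the resolved YAML config), and
`inst/scripts/lineamp.R` wraps `simulate` / `run-all` for shell use.
Probe tables, expression matrices, cohort labels and GMT gene sets are
read from plain TSV (see `readProbeTable()`, `readExpressionPanel()`,
`readGmt()`).

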