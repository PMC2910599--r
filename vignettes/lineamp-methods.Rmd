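---
title: "Discovering lineage-specific amplicon drivers with lineamp"
author: "lineamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lineage-specific amplicon drivers with lineamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineamp)
```

## The scientific problem

Recurrent DNA amplicons in epithelial tumors are thought to persist
because they carry a driver gene whose overexpression is selected for.
When two histological subtypes arise from different cell lineages — for
example squamous cell carcinoma (SqCC) and adenocarcinoma (AC) of the
lung — an amplicon may be selected in one lineage only, and the gene
driving it is then a candidate *lineage-specific oncogene*. `lineamp`
implements, as a reusable and fully tested pipeline, the integrative
copy-number/expression strategy used to find such drivers: array-CGH
profiles of the two tumor cohorts are segmented and reduced to
gain/neutral/loss states; regions whose state distribution differs
between the cohorts are found with exact tests; expression inside those
regions is screened for lineage-restricted, dosage-driven,
tumor-specific activation; and a permutation signature module
characterises the downstream transcriptional program of the winning
gene.

Because the original patient cohorts are not redistributable, the
package ships a synthetic-cohort generator with planted ground truth.
Every statistical claim made by the test suite is made against either
an independent brute-force oracle or that planted truth.

## Per-sample aCGH processing

**Replicate QC.** Each array element (tiling BAC clone) carries
replicate spot log2 ratios, a replicate standard deviation and a
signal-to-noise ratio. Clones with replicate SD above 0.075 or SNR below
3 are flagged missing (position retained); the combined log2 ratio of a
retained clone is the arithmetic mean of its replicates. The SD/SNR
thresholds are exposed in `qcFilter()`.

**Segmentation.** Profiles are fitted with an exact dynamic-programming
least-squares segmentation minimising

$$\mathrm{SSE} + \lambda\,\hat\sigma^2\, k,$$

where $k$ is the number of breakpoints (capped at 100 per chromosome),
$\lambda = 6.75$ by default, and $\hat\sigma^2$ is a robust per-clone
noise variance estimated from the median absolute successive difference
($\hat\sigma = \mathrm{MAD}(\Delta x)/\sqrt 2$). Scaling the penalty by
the noise variance makes $\lambda$ a dimensionless smoothing knob: the
same value behaves sensibly on quiet and noisy profiles, and on
noise-free input the fit degenerates gracefully to the exact piecewise
signal. The optimisation is exact (penalised optimal partitioning, with
a capped DP fallback) and is verified against exhaustive breakpoint
search in the tests. Segment means above +0.2 / below −0.2 log2 call
gain / loss states; the mapping from smoothed values to states is not
standardised anywhere, so both thresholds are configuration.

**High-level amplification.** An amplicon is a maximal run of at least
two consecutive non-missing clones with combined log2 ratio above a
threshold: 0.6 for tumors, 0.8 for carcinoma-in-situ (CIS) lesions,
whose variable tumor-cell content dilutes ratios unpredictably. Runs
never bridge missing clones — a deliberate conservative choice that
avoids inventing data. The caller operates on raw combined ratios by
default; a flag switches it to segment means, since the literature does
not say which the original algorithm used. `amplificationScore()`
summarises per-case amplicons into a per-clone incidence across a
group.

## Two-cohort disparity analysis

States missing after QC are imputed from the nearest originally
observed clone of the same sample within 10 Mb (ties: agreement keeps
the state, disagreement yields neutral; donors are never themselves
imputed, which makes the operation idempotent). Clones are aggregated
into regions per cohort — a boundary is placed wherever fewer than 90%
of a cohort's samples agree across an adjacent clone pair — and the two
cohort partitions are intersected, so that no region mixes clones that
either cohort considers heterogeneous. Each sample is then reduced to
one representative state per region (majority over member clones, ties
neutral: the least-assumptive reduction from per-clone scores to one
table per region; the full table is retained for audit), and the
resulting 3×2 state-by-cohort table is tested with an exact Fisher test
implemented by direct enumeration of the conditional distribution.
Benjamini–Hochberg correction is applied over the number of distinct
regions; regions at adjusted p ≤ 0.01 survive, adjacent survivors
within 1 Mb agreeing in direction merge, and finally a region must be
altered — in its own direction — in more than 20% of one cohort with a
between-cohort difference above 10%. The direction of a region is the
state with the largest absolute frequency difference, which is also
what the merge rule compares. The frequency filters are interpreted
direction-specifically; a flag is not exposed for the combined
interpretation because the merge rule is already directional.

Under a null simulation with no cohort differences the fraction of
regions passing the BH step is far below the nominal 0.01 (exact Fisher
p-values on discrete tables are conservative); the acceptance suite
verifies this over 200 seeded replicates.

## Copy-number/expression integration

Two complementary methods link dosage to expression within the cohort
of interest:

1. **Windowed Z-score correlation.** A 10-kb moving average of the
   combined log2 ratios (clones weighted by bp overlap; windows tile
   each chromosome from position 0) is standardised per sample across
   the whole profile, averaged over the windows spanning each gene, and
   correlated with log10 expression using Spearman's rank correlation
   with a one-tailed test for positive association. Note that the
   per-sample Z-transform is monotone *within* a sample but not across
   samples, so cross-sample ranks can differ from those of raw windowed
   means; we follow the stated recipe literally.
2. **Gain-versus-neutral test.** Samples are classified by the majority
   segmentation state over the gene; expression in gain/amplified
   samples is compared with copy-number-neutral samples by a one-tailed
   Mann–Whitney test (loss samples excluded, their count reported), and
   the association counts only if the BH-adjusted p ≤ 0.05 *and* the
   gain group's median and mean are both higher.

Mann–Whitney tests use the exact null distribution whenever the data
are tie-free and small (the implementation delegates to
`stats::wilcox.test`, exact below 50 per group, which subsumes the
exact-when-n≤20 regime the design calls for); otherwise the normal
approximation with tie and continuity correction. Tumor-versus-normal
elevation is quantified as the ratio of group medians on the linear
scale (inputs are exponentiated according to their declared scale) —
medians because the estimator behind published "fold" values is rarely
stated and medians are robust to the long tails of expression data.

## The candidate cascade

`runCascade()` audits five criteria per gene: membership in a disparity
region; one-tailed differential expression between the cohorts at BH
p ≤ 0.01; Spearman dosage correlation ρ > 0.75 at BH p < 0.01; the
guarded gain-versus-neutral test at BH p ≤ 0.05; and tumor-versus-normal
elevation at fold > 2 with BH p ≤ 0.01. The elevation criterion uses a
fold-plus-alpha rule rather than any single observed p-value, so that
an observed statistic is never enshrined as a threshold. A candidate
must pass all five; genes failing exactly one are reported as
near-misses with the failed criterion named, reproducing the reasoning
that excludes passenger genes which fail a single hypothesis. The two
integration methods are required jointly (sequential AND), matching the
narrative in which the second method winnows the survivors of the
first. Early-lesion corroboration — the fraction of a CIS-like cohort
amplified over each candidate at threshold 0.8 — is reported but never
gates candidacy.

## SAM signature module

`samTwoClass()` implements the unpaired two-class significance analysis
of microarrays: $d_i = (\bar x_{i1} - \bar x_{i2})/(s_i + s_0)$ with
the pooled standard error $s_i$, the fudge factor $s_0$ chosen on a
percentile grid by minimising the coefficient of variation of the
spread of $d$ across $s$-quantile bins (a fixed-$s_0$ mode exists so
oracle tests can pin the statistic down), and q-values estimated from
label permutations: the FDR at threshold $|d_{(k)}|$ is $\hat\pi_0$
times the median permutation count of statistics exceeding the
threshold over the observed count, $\hat\pi_0$ being the fraction of
observed statistics inside the permutation interquartile range; a
gene's q is the minimum FDR over all thresholds that call it. When the
number of distinct group assignments is small the permutation set is
enumerated exhaustively, making the q-values deterministic; otherwise
1,000 seeded random permutations are used (both counts are
configuration). Extreme-expresser groups (default 10 per tail, the
conventional design) are selected on the probe with the highest mean
intensity, ties at the boundary broken by stable sample order. The
optional gene-set enrichment step is a one-sided hypergeometric test
over user-supplied GMT sets — an open replacement for proprietary
pathway databases with the same statistical contract.

## The synthetic study conditions

The generator simulates one chromosome arm (emulating a 40-Mb arm at
80-kb tiling density, 500 clones of 100 kb) for an AC-like and a
SqCC-like cohort of 50 samples each, a 20-sample CIS-like cohort with
doubled probe noise, and a 30-sample expression-only normal cohort.
All statistics in this design are per-arm, so one arm suffices;
multi-chromosome inputs are supported by the analysis functions
regardless. Planted regions follow the alteration architecture the
pipeline is meant to resolve: a distal 6-Mb loss in 39% of AC; the
3.5-Mb focal driver gain in 40% of SqCC (30% of carriers at
amplification level) against a 5% AC background; a region gained at
45%/40% in both cohorts (removed by the frequency-difference filter); an
80% and a 100% SqCC gain; a universal low-level gain on the distal end
of the arm shared by all tumors, which gives every profile a realistic
variance floor for the per-sample Z-transform; and the driver region
gained in 35% of the CIS-like cohort at amplification level.

Carrier status uses exact counts (`round(fraction × n)` carriers chosen
by seeded sampling) so that noise-free frequencies are exact; each
carried region's shift is scaled per sample by a uniform factor in
1 ± 0.2, the scalar heterogeneity/cellularity attenuation that is the
only intra-tumor heterogeneity modelled. Noise is Gaussian on log2
ratios with a per-replicate SD of 0.05 (three replicate spots); 5% of
clones per sample receive inflated replicate SD or sub-threshold SNR to
exercise QC. The platform literature gives no noise magnitudes, so
these are free parameters of the simulation, documented here, not
derived values. Expression (log10 scale) for coupled genes is
`cohort baseline + slope × measured mean log2 over the gene interval +
N(0, 0.1)`: coupling to the *measured* dosage reflects that transcript
abundance tracks the DNA content actually present in the profiled
tissue, and gives dosage-correlation behaviour comparable to published
values (driver ρ ≈ 0.86 noise-free, ≈ 0.80 under default noise).

The decoy panel plants one gene per cascade criterion, each violating
exactly that criterion at zero noise: `decoy_outside` sits in the
45%/40% region killed by the frequency filters; `decoy_not_de` carries
a high constant AC baseline (its dosage coupling keeps ρ high while the
cohort contrast vanishes); `decoy_uncoupled` follows a non-monotone
dosage→expression level map — gain-level samples express more than
amplification-level samples — which is the only way to keep the
gain-versus-neutral contrast while destroying rank correlation once
noise is zero; `decoy_group` lies in the 100% region, so its neutral
comparison group is empty and the group test is not testable (its
two-level monotone expression map keeps ρ high); and
`decoy_not_elevated` is expressed in normals near tumor baseline
(fold ≈ 1.2). Null genes are flat everywhere and fail several criteria.
These compositions were derived by closed-form rank arithmetic when the
panel was designed; the noise-free invariant "each decoy fails exactly
its intended criterion" is asserted over 20 seeds in the acceptance
suite. Under default noise, borderline decoys may additionally drop
below the ρ = 0.75 bar — the single-criterion property is a property of
the noise-free construction, not of every noisy replicate.

## Numerical and degenerate-input choices

* Exact p-values throughout are defined with a relative tie tolerance
  of 10⁻⁷ when comparing table probabilities (Fisher) — distinct
  probabilities at the table sizes involved differ by far more.
* Constant expression probes get p = 1 and a flag; constant profiles
  make the Z-transform undefined and are flagged rather than zeroed.
* Segmentation tie-breaks prefer fewer breakpoints; the noise-variance
  floor (10⁻¹²) keeps the penalty defined on noise-free input.
* All writers emit six significant digits and write atomically
  (temp-file + rename), making repeated runs byte-identical — asserted
  end-to-end in the acceptance suite.
* Fold changes with non-positive linear medians are undefined and
  flagged, never coerced.

## Problem sizes used in validation

The shipped validation uses the study conditions above: oracle
equivalence on exhaustive small inputs (all 3×2 tables to total 12,
all label permutations to n = 10, all rank permutations to n = 7,
all breakpoint placements to n = 12); 200 null replicates of the
500-region two-cohort simulation; 100 replicates of the 40%-versus-5%
planted-gain recovery at n = 50 + 50; 20 noise-free replicates of the
full cascade; and byte-level determinism of the full pipeline on a
reduced cohort. These sizes are the package's validation design.

## Limitations

The generator emulates piecewise-constant single-arm profiles with
Gaussian noise and scalar heterogeneity; it does not model spatial
array artifacts, probe-specific response, subclonal mixtures beyond the
scalar, correlated noise, or normalisation residue — so passing tests
demonstrate correctness of the statistics and plumbing on data
honouring the segmentation model, not robustness to every failure mode
of real arrays. The disparity machinery supports exactly two tumor
cohorts per comparison; survival analysis, pathway knowledge bases and
wet-lab corroboration are out of scope.
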