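---
title: "Methods: co-expression module QTL mapping and integrative regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression module QTL mapping and integrative regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlnet)
```

## The problem

Meningiomas are graded I–III by WHO histology; grade tracks malignancy.
Expression arrays and SNP arrays on the same tumors let one ask a
systems-level question: is there a co-expression module whose summary
expression (i) correlates with grade and (ii) is itself under detectable
genetic influence? This package implements that analysis end to end —
network construction, module-QTL (mQTL) mapping, hub calling, and an
integrative regression that decomposes per-gene grade association into
connectivity and mQTL components — and pairs it with a synthetic-cohort
generator so every stage can be validated against planted truth.

## Quality control

SNPs are kept iff MAF ≥ 0.05, call rate ≥ 0.95 and Hardy–Weinberg
equilibrium p ≥ 0.01 (Pearson 1-df chi-square, no continuity correction; a
conditional exact test is available but off by default since the upstream
genotyping tool's method is a chi-square-style screen). All thresholds are
inclusive, matching their "minimum … of" phrasing, and all three statistics
are computed on the original matrix so the rules are order-independent.
MAF and call rate use non-missing calls only; genotypes are stored as
alternate-allele counts and MAF folds to `min(p, 1-p)`, so allele labelling
cannot affect downstream results.

Expression probes arrive log2-scaled. The variance filter keeps a probe iff
at least 10% of samples deviate from the probe median by ≥ log2(1.8) ≈
0.848; the multiplicative ("fold change according to the median") reading
on the log scale was chosen because the data are already log2, and it makes
the filter invariant under adding a constant to a probe. Probes annotated
to chromosome Y are dropped (the genotyping platform carries no Y SNPs);
unannotated probes are kept. Missing values are imputed by k-nearest
neighbours (k = 10): each missing cell takes the mean, at that sample, of
the k probes nearest to the target probe by Euclidean distance on the
samples observed in both (rescaled by the shared-sample count so probes
with different missingness are comparable); ties break by probe order, so
imputation is deterministic.

## Network, modules and module statistics

Adjacency is `a_ij = |cor(x_i, x_j)|^beta` with β = 6 and Pearson
correlation (the standard convention for the adjacency); kIN, kME and GS
use Spearman correlation throughout, with average ranks for ties. Scale-free
topology is assessed by binning whole-network connectivity into 10
equal-width bins spanning [min k, max k] ("bins of equal size" read as
equal width, the standard fit index; equal-count binning is available via
`binning = "count"`), taking each non-empty bin's mean connectivity and
empirical probability, and regressing log10 p(k) on log10 k. The fit report
satisfies `r_squared == pearson_cor^2` by construction.

Module detection is deliberately explicit, since tutorial-style pipelines
leave it to a packaged call: average-linkage hierarchical clustering of
1 − TOM, a static cut at height 0.995, clusters below 30 probes relabelled
"unassigned", then iterative merging of the module pair with the highest
eigengene correlation while it exceeds 0.75. All knobs are arguments and
`pipeline_config()` fields. The permissive 0.995 cut occasionally absorbs a
background probe that correlates with a module factor by chance; the
planted-recovery tests therefore score membership by Jaccard overlap rather
than exact equality.

The module eigengene is the first right-singular direction over samples of
the probe-standardized module matrix, rescaled to unit variance and
sign-anchored so it correlates non-negatively with the mean standardized
module expression. The anchor fixes an otherwise arbitrary SVD sign;
a consequence worth stating is that negating *every* probe flips the anchor
and hence the eigengene — the summary is defined up to that sign, and all
downstream tests are two-sided in it. PC2 is produced the same way for the
improvement and PC1+PC2 association models.

Per-probe module statistics: kIN = Σ over other module probes of
|Spearman ρ| (self excluded), kME = Spearman ρ with the eigengene, GS =
Spearman ρ with a trait, plus the expression sd. On planted data kME⁶ and
kIN agree to Spearman ≥ 0.98 — the qualitative property that justifies kME
as a centrality proxy. Note a limitation of the homogeneous-noise
generator: with `x = u f + e` and constant residual sd, probe sd *rises*
with the loading and hence with kIN, so the empirical observation that
lowly connected genes are the more variable ones only reproduces under
heterogeneous residual noise (noisy probes are simultaneously less
connected and more variable); the test suite checks the trend in that
regime.

## Hubs

The module graph connects probes whose β-powered adjacency reaches
`edge_threshold` (default 0.1; this is dataset-specific and must be chosen
with the hub cutoffs in mind). Degree and betweenness are unweighted, with
betweenness on raw counts (unordered pairs once, endpoints excluded),
because the canonical hub cutoffs — degree ≥ 250 AND betweenness ≥ 2,500,
both inclusive — are stated on raw values. On desk-scale modules those
cutoffs are unreachable (a 123-node graph caps degree at 122), so the
analysis driver also reports hubs at the 90th-percentile cutoffs of the
realized distributions; the canonical thresholds stay the package default.

## Association scans

SNPs enter as outcomes, not predictors: the allele count is modelled as
y_i ~ Binomial(2, π_i) with logit(π_i) linear in the module summaries, and
the added covariates are tested by likelihood ratio (df = number added).
This is the binomial-logistic analogue of the left-hand-side score test
tradition for genotype-as-outcome scans; a GLM score test is available via
`method = "score"` and agrees with the LRT to Spearman ≥ 0.99 on null
simulations. Monomorphic or nearly missing genotypes are skipped with a
recorded reason. Complete separation triggers a ridge-penalized IRLS refit
(λ = 1e-4) whose record is flagged; p-values from that path are conservative
screening values, not calibrated tail probabilities.

Three mQTL scans are run: the eigengene alone; the PC2 improvement over an
eigengene base model (1-df LRT); and the elementwise sum PC1+PC2 as a
single regressor. Tiers formalize the "order of 10⁻⁵ or less" language as
suggestive p < 1e-4 and significant p ≤ 1e-6 (both configurable). Within a
gene only the minimum-p SNP is kept, ties broken lexicographically. The
stage scan uses the binary indicator (grade I vs II/III) as the single
covariate. Genomic control transforms each p to its 1-df chi-square
quantile and divides the median by 0.4549364 (the χ²₁ median); the
operation accepts any p-vector, so λ can be reported per scan.

## Integrative regression

Observations here are module probes, not samples. GSmQTL_gj is the Spearman
correlation of probe g with mQTL genotype j (pairwise-complete over missing
calls). The response — GS for WHO grade — is rank-inverse-normal
transformed, z_i = Φ⁻¹((r_i − 0.5)/n); only responses are transformed,
predictors enter raw. AIC is fixed to the RSS form n·ln(RSS/n) + 2(p+1) so
model comparisons are implementation-independent. Stepwise selection starts
from the *full* model (the direction of the original analysis is unstated;
full-start with bidirectional moves was chosen and is recorded here), takes
the single add/remove move with the largest AIC decrease, and breaks ties
by preferring removal, then lexicographic name — the search is fully
deterministic. Two consequences of AIC's fixed penalty are documented in
the tests rather than wished away: each pure-noise candidate is admitted
with probability P(χ²₁ > 2) ≈ 0.157, so "exactly the true predictor" is
recovered only about half the time with four noise candidates, while the
true predictor itself is essentially always kept.

Significant selected columns (t-test p < 0.01) are split by coefficient
sign and summed row-wise into GSmQTLRisk (positive) and GSmQTLProtective
(negative). Flipping a SNP's allele coding flips its GSmQTL column and
migrates it between the two sums; the stepwise fit is invariant under the
flip, but the three-regressor final model is not exactly so (the sums
change), which is why the suite tests the migration and the stepwise
invariance. The final model regresses the transformed GS on kME, Protective
and Risk; the report carries R², adjusted R², the model-level
VIF = 1/(1 − R²) (the convention that reproduces the printed 0.51 → 2.04
pair, alongside per-predictor VIFs for multicollinearity diagnosis),
Shapiro–Wilk residual normality, and Spearman(fitted, observed GS).
Median dichotomization labels each probe (K±, R±, P±) by strict comparison
to the median — values equal to the median go to the lower group
(configurable only by re-coding, documented here) — and reports per-group
GS summaries.

## Enrichment and replication

One hypergeometric engine serves all gene-set collections (GO, pathway,
miRNA-target, TFBS-target — all just GMT sets here): upper-tail
p = P(X ≥ x) over the user-supplied universe, BH-FDR across terms, and a
coverage filter x / |query ∩ universe| with defaults 0.001 / 10% (3% for
the mQTL-gene variant). Coverage is read as "fraction of the query covered
by the term"; the alternative reading is exposed by transposing query and
term. PPI enrichment replaces a database's analytic null with an explicit
permutation: B random same-size node subsets of the PPI universe,
expected = null mean, p = (1 + #{null ≥ obs})/(B + 1), so p ≥ 1/(B+1)
always and the whole null is seedable.

The replication stage uses a location-scale batch adjustment (per probe and
batch: center, scale, restore pooled moments). It removes additive and
multiplicative batch effects exactly but, unlike empirical-Bayes
correction, does not shrink across probes — adequate for the planted
location/scale batches the generator emits, and stated as such. Stage DE is
a per-probe Welch t-test with BH-FDR at 0.05 (a moderated-t would differ
mainly at very small group sizes); the kME connectivity shift of DE probes
is a two-sided Wilcoxon rank-sum plus a 10,000-permutation background of
the mean-kME difference.

## The synthetic generator

`simulate_cohort()` emits the study conditions: 59 samples allocated
39/15/5 to WHO grades I/II/III (largest-remainder allocation so a template
that divides n exactly gives exact counts, then a seeded shuffle of sample
order), SNPs with MAF ~ Uniform(0.05, 0.5) and Binomial(2, m) genotypes
(Hardy–Weinberg by construction) masked missing at 2% by default, and a
latent factor f_s = γ·grade_s + Σ_j δ_j g_js + N(0,1) (γ = δ = 0.8) that
drives a planted module x_gs = u_g f_s + N(0, σ_e), u_g ~ Uniform(0.5, 1),
σ_e = 1, over independent-noise background probes. Grade enters linearly
(1,2,3); GS uses Spearman, so the coding's spacing is immaterial. mQTL
effects act on the shared factor, not on individual genes, matching the
premise that SNPs associate with the module summary. Genotypes, phenotypes
and expression consume separate RNG streams derived from the master seed,
so resizing one matrix never perturbs another. The replication generator
reuses the probe universe, shifts planted DE probes by 2σ between stages,
and applies per-batch location/scale offsets.

What the generator does *not* emulate — linkage disequilibrium between
SNPs, copy-number events, probe cross-hybridization, heteroskedastic
probe noise (see the kIN/sd note above), and realistic module count (it
plants one module, not sixteen) — bounds what passing tests show: they
validate the machinery and its calibration, not performance on real arrays.

## Problem sizes and numerical choices

Validation runs use cohorts of 59–300 samples, 10–800 SNPs and up to 1,200
probes, with 2,000-replicate null calibrations, 200-replicate power
measurements, and a 100k-draw λ check; these sizes give stable estimates
while keeping the full suite inside a few minutes. Degenerate inputs are
first-class: monomorphic SNPs skip with a reason, constant traits report NA
correlations, rank-deficient designs error naming the aliased columns,
zero-variance probes are rejected before correlation, and empty
risk/protective sums warn and degrade the dichotomization gracefully. The
run manifest contains the config, seed, package version and per-file
checksums — and deliberately no timestamps, so that two runs under one
master seed are byte-identical; wall-clock context goes to the console log
instead.

## Known limitations

The genotype-as-outcome LRT treats the module summary as fixed, ignoring
its estimation error; at 59 samples the mQTL scans are underpowered and the
integrative stage may legitimately find no significant GSmQTL columns (the
drivers then fall back to the top-ranked SNPs and say so). The
location-scale batch adjustment and Welch DE are transparent stand-ins for
empirical-Bayes tools, adequate at the generator's batch structure. Hub
cutoffs 250/2,500 are only meaningful relative to the (unstated) edge
definition of the original visual network and require a dataset-scale
module to be attainable.
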