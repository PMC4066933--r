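# mqtlnet

Integrative module-QTL analysis for tumor expression/genotype cohorts, with
meningioma as the motivating setting. The package reimplements, as tested and
reusable R functions plus a numbered analysis workflow, a systems-genetics
pipeline that:

1. quality-controls SNPs (MAF ≥ 5%, call rate ≥ 95%, Hardy–Weinberg
   equilibrium p ≥ 0.01) and expression probes (k-nearest-neighbour
   imputation, chromosome-Y exclusion, a ≥ 1.8-fold-change-from-median filter
   in ≥ 10% of samples);
2. builds a weighted gene co-expression network with soft-threshold adjacency
   a_ij = |cor(x_i, x_j)|^β (β = 6), checks approximate scale-free topology by
   regressing log10 p(k) on log10 k over 10 equal-width connectivity bins,
   computes topological overlap TOM_ij = (Σ_u a_iu a_uj + a_ij) /
   (min(k_i,k_j) + 1 − a_ij), detects modules by average-linkage clustering of
   1 − TOM with eigengene merging, and profiles the grade-linked module by
   kIN (Σ_j≠i |Spearman ρ_ij|), kME (Spearman ρ with the module eigengene) and
   GS (Spearman ρ with WHO grade);
3. calls hub genes from degree and raw betweenness centrality of the
   thresholded module graph (canonical cutoffs degree ≥ 250 and betweenness
   ≥ 2,500);
4. maps module QTLs (mQTLs) by logistic regression with the SNP allele count
   as the *dependent* variable, y_i ~ Binomial(2, π_i),
   logit(π_i) = α + b·ME, with likelihood-ratio tests for the PC2-improvement
   and PC1+PC2 models, tiers (suggestive p < 10⁻⁴, significant p ≤ 10⁻⁶),
   per-gene deduplication, the binary-stage scan, and the genomic-control
   inflation factor λ = median(χ²)/0.4549;
5. decomposes module gene significance by stepwise-AIC regression of the
   rank-inverse-normal GS on the per-probe mQTL correlations (GSmQTL),
   aggregates significant columns by coefficient sign into GSmQTLRisk and
   GSmQTLProtective, fits GS ~ kME + Protective + Risk (reporting the
   model-level VIF = 1/(1−R²)), and dichotomizes probes at the medians into
   the eight (K±, R±, P±) groups;
6. provides hypergeometric gene-set enrichment with BH-FDR and coverage
   filters, a permutation test of PPI interaction-count enrichment, a
   location-scale batch adjustment, Welch-t stage differential expression,
   and the kME connectivity-shift test against a 10,000-permutation
   background.

Every stage can be exercised on synthetic cohorts with planted ground truth:
`sim_params()` / `simulate_cohort()` generate Hardy–Weinberg genotypes, the
39/15/5 WHO grade I/II/III template at n = 59, and a planted co-expression
module whose latent factor responds to grade and to designated mQTL SNPs;
`simulate_replication()` adds a batch-affected replication cohort with
planted differential expression.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (59 samples, 800 SNPs, 1,200 probes, a planted 120-probe module with
3 mQTLs) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/03_network.R
Rscript analysis/04_association.R
Rscript analysis/05_integration.R
Rscript analysis/06_enrichment_replication.R
```

Representative output (verbatim from a run of the scripts above):

```
SNP QC: 684 of 800 kept (20 maf, 92 call-rate, 8 hwe failures)
scale-free fit: R2 = 0.802, cor = -0.895, slope = -1.068
modules detected: 1 (sizes 123; 1047 probes unassigned)
target module: M1 (rho = 0.454 with WHO grade, p = 0.0003)
kME^6 vs kIN Spearman correlation: 0.993
ME scan: 1 SNPs at the suggestive tier or better; planted recovered: 1 of 3
stage scan: 684 SNPs tested, genomic-control lambda = 0.970
final model: adj R2 = 0.107, VIF = 1.14, Spearman(fitted, GS) = 0.328
replication DE: 63 probes flagged at FDR < 0.05; 100% of planted DE probes recovered
```

Reading the numbers: the detected module M1 recovers the planted 120-probe
module (123 members), its eigengene correlates with WHO grade, and kME⁶
tracks intramodular connectivity almost perfectly — the property that makes
kME a usable centrality proxy. At n = 59 only the strongest planted mQTL
reaches the suggestive tier (power at this cohort size is limited, as the
acceptance measurements at n = 200 show), so the integrative model explains
a modest share of GS variance here; λ ≈ 0.97 indicates no inflation in the
stage scan. The replication step recovers all planted DE probes after batch
adjustment.

A single call `run_pipeline(geno, expr, pheno, pipeline_config(seed = 1),
out_dir)` executes QC → network → module selection → centrality →
association → integration in memory and writes a deterministic JSON
manifest (config, seed, per-file checksums), so two runs with one master
seed are byte-identical.

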