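#!/usr/bin/env Rscript
# Simulate the study cohorts: a discovery cohort of 59 meningioma-like
# samples (39/15/5 across WHO grades I/II/III) with genotypes, expression
# and a planted grade-linked co-expression module driven by mQTL SNPs, plus
# a batch-affected replication expression cohort with planted differential
# expression. All layers are written in the package's on-disk formats so
# the downstream steps run from files, as they would on real data.

library(mqtlnet)

seed <- 20260L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

params <- sim_params(seed = seed, n_samples = 59, n_snps = 800,
                     n_probes = 1200, module_size = 120, n_mqtl = 3,
                     mqtl_effect = 0.8, factor_grade_effect = 0.8,
                     genotype_missing_rate = 0.02, n_y_probes = 30,
                     n_batches = 2, batch_location = c(0, 4),
                     batch_scale = c(1, 1.3), de_effect = 2, n_de = 60,
                     rep_n_samples = 100)
co <- simulate_cohort(params)
rep_ <- simulate_replication(params, co$truth)

write_genotypes(co$geno, file.path(data_dir, "genotypes.tsv"))
write_expression(co$expr, file.path(data_dir, "expression.tsv"))
write_phenotypes(co$pheno, file.path(data_dir, "phenotypes.tsv"))
write.table(co$expr$probe_meta, file.path(data_dir, "probe_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_expression(rep_$expr, file.path(data_dir, "replication_expression.tsv"))
write_phenotypes(rep_$pheno, file.path(data_dir, "replication_phenotypes.tsv"))
write.table(data.frame(sample_id = names(rep_$batch),
                       batch = unname(rep_$batch)),
            file.path(data_dir, "replication_batches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- data.frame(
  kind = c(rep("module_probe", length(co$truth$module_probes)),
           rep("mqtl_snp", length(co$truth$mqtl_ids)),
           rep("replication_de_probe", length(rep_$de_probes))),
  id = c(co$truth$module_probes, co$truth$mqtl_ids, rep_$de_probes))
write.table(truth, file.path(data_dir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d samples x %d SNPs x %d probes (module %d, %d mQTLs)\n",
            params$n_samples, params$n_snps, params$n_probes,
            params$module_size, params$n_mqtl))
cat(sprintf("replication: %d samples, %d batches, %d DE probes\n",
            params$rep_n_samples, params$n_batches, length(rep_$de_probes)))
cat("written to", data_dir, "\n")
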