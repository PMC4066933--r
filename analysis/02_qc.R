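#!/usr/bin/env Rscript
# Quality control of the simulated cohort: align the three data layers on
# shared samples, filter SNPs on MAF >= 5% / call rate >= 95% / HWE
# p >= 0.01, impute missing expression by k-nearest neighbours, drop
# chromosome-Y probes, and keep probes with a >= 1.8-fold change from their
# median in >= 10% of samples.

library(mqtlnet)

data_dir <- "results/data"
qc_dir <- "results/qc"
dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)

geno <- read_genotypes(file.path(data_dir, "genotypes.tsv"), "tsv_dosage")
expr <- read_expression(file.path(data_dir, "expression.tsv"),
                        file.path(data_dir, "probe_annotation.tsv"))
pheno <- read_phenotypes(file.path(data_dir, "phenotypes.tsv"))
al <- align_cohort(geno, expr, pheno)
cat(sprintf("aligned cohort: %d samples\n", nrow(al$geno$calls)))

th <- qc_thresholds()
fs <- filter_snps(al$geno, th)
cat(sprintf("SNP QC: %d of %d kept (%d maf, %d call-rate, %d hwe failures)\n",
            sum(fs$report$kept), nrow(fs$report),
            sum(grepl("maf", fs$report$fail_reason)),
            sum(grepl("call_rate", fs$report$fail_reason)),
            sum(grepl("hwe", fs$report$fail_reason))))
write.table(fs$report, file.path(qc_dir, "snp_qc_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_genotypes(fs$geno, file.path(qc_dir, "genotypes_qc.tsv"))

ex <- knn_impute(al$expr, th$knn_k)
n0 <- nrow(ex$values)
ex <- drop_chromosome(ex, "Y")
cat(sprintf("chromosome-Y exclusion: %d probes dropped\n",
            n0 - nrow(ex$values)))
n1 <- nrow(ex$values)
ex <- variance_filter(ex, th)
cat(sprintf("variance filter: %d of %d probes kept\n", nrow(ex$values), n1))
write_expression(ex, file.path(qc_dir, "expression_qc.tsv"))
write.table(ex$probe_meta, file.path(qc_dir, "probe_annotation_qc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_phenotypes(al$pheno, file.path(qc_dir, "phenotypes_aligned.tsv"))
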