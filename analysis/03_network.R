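#!/usr/bin/env Rscript
# Co-expression network over the QC'd probes: soft-threshold adjacency
# (power 6), scale-free topology fit over 10 connectivity bins, topological
# overlap, module detection, eigengenes, module-trait correlations, and the
# per-probe profile (kIN, kME, GS, sd) of the grade-linked target module,
# followed by degree/betweenness hub calling on the module graph.

library(mqtlnet)

qc_dir <- "results/qc"
net_dir <- "results/network"
dir.create(net_dir, showWarnings = FALSE, recursive = TRUE)

ex <- read_expression(file.path(qc_dir, "expression_qc.tsv"))
pheno <- read_phenotypes(file.path(qc_dir, "phenotypes_aligned.tsv"))

net <- adjacency(ex, beta = 6)
k <- connectivity(net)
sft <- scale_free_fit(k, n_bins = 10)
cat(sprintf("scale-free fit: R2 = %.3f, cor = %.3f, slope = %.3f\n",
            sft$r_squared, sft$pearson_cor, sft$slope))
write.table(data.frame(r_squared = sft$r_squared,
                       pearson_cor = sft$pearson_cor, slope = sft$slope),
            file.path(net_dir, "scale_free_fit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sft$bins, file.path(net_dir, "scale_free_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tom <- tom_similarity(net)
assignment <- detect_modules(tom, ex)
mods <- setdiff(unique(assignment), "unassigned")
cat(sprintf("modules detected: %d (sizes %s; %d probes unassigned)\n",
            length(mods),
            paste(vapply(mods, function(m) sum(assignment == m), 1L),
                  collapse = ", "),
            sum(assignment == "unassigned")))
write.table(data.frame(probe_id = names(assignment),
                       module = unname(assignment)),
            file.path(net_dir, "modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

egs <- lapply(mods, function(m)
  module_eigengene(ex, names(assignment)[assignment == m]))
names(egs) <- mods
mt <- module_trait_correlations(lapply(egs, `[[`, "me"), pheno)
write.table(mt, file.path(net_dir, "module_trait.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

trait <- setNames(pheno$who_grade, pheno$sample_id)
sel <- select_target_module(mt, assignment, ex, trait, trait = "who_grade")
cat(sprintf("target module: %s (rho = %.3f with WHO grade, p = %.2g)\n",
            sel$module, sel$rho, sel$p))
write.table(sel$summary, file.path(net_dir, "module_selection.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

members <- names(assignment)[assignment == sel$module]
eg <- egs[[sel$module]]
write.table(data.frame(sample_id = names(eg$me), ME = unname(eg$me),
                       PC2 = unname(eg$pc2)),
            file.path(net_dir, "target_eigengene.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
profile <- module_profile(ex, members, eg$me,
                          pheno[, "who_grade", drop = FALSE])
write.table(profile, file.path(net_dir, "target_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("kME^6 vs kIN Spearman correlation: %.3f\n",
            cor(profile$kME^6, profile$kIN, method = "spearman")))

# module graph and hub calling; the edge threshold (and hence the hub
# cutoffs' reach) is dataset-specific -- at this module size the canonical
# 250/2500 cutoffs are unattainable, so scaled cutoffs are also reported
graph <- build_graph(net, members, edge_threshold = 0.1)
ctab <- centrality_table(graph)
scaled_deg <- stats::quantile(ctab$degree, 0.9)
scaled_btw <- stats::quantile(ctab$betweenness, 0.9)
ctab$hub_scaled <- ctab$degree >= scaled_deg & ctab$betweenness >= scaled_btw
cat(sprintf("module graph: %d nodes, %d edges; %d hubs at 250/2500, %d at the 90th-percentile cutoffs (%.0f/%.0f)\n",
            igraph::vcount(graph), igraph::ecount(graph), sum(ctab$hub),
            sum(ctab$hub_scaled), scaled_deg, scaled_btw))
write.table(ctab, file.path(net_dir, "centrality.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_graph_edges(graph, file.path(net_dir, "module_edges.tsv"), sif = TRUE)
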