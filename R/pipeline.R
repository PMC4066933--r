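# End-to-end orchestration: QC -> network -> module selection -> centrality
# -> association scans -> integrative regression, with a deterministic
# manifest so a run is fully reproducible from its master seed.

#' Pipeline configuration
#'
#' Defaults are the workflow's canonical thresholds: soft power 6, MAF 0.05,
#' call rate 0.95, HWE p 0.01, 1.8-fold / 10% expression filter, hub
#' cutoffs 250 / 2500, significance tiers 1e-4 / 1e-6, enrichment FDR 0.001
#' with 10% coverage (3% for the mQTL variant), replication FDR 0.05, and
#' 10000 permutations.
#'
#' @param ... overrides of any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    beta = 6,
    maf_min = 0.05, call_rate_min = 0.95, hwe_p_min = 0.01,
    fold_change = 1.8, sample_fraction = 0.10, knn_k = 10,
    drop_chrom = "Y",
    min_module_size = 30, cut_height = 0.995, merge_threshold = 0.75,
    edge_threshold = 0.1, hub_degree_min = 250, hub_betweenness_min = 2500,
    suggestive_max = 1e-4, significant_max = 1e-6,
    enrich_fdr = 0.001, enrich_coverage = 0.10, mqtl_coverage = 0.03,
    replication_fdr = 0.05, n_permutations = 10000,
    target_trait = "who_grade", sig_p_threshold = 0.01,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' Select the module most correlated with a trait
#'
#' Returns the module whose eigengene maximizes the absolute Spearman
#' correlation with the trait; ties go to the larger module. Also reports
#' the per-module mean absolute gene significance.
#'
#' @param mt table from [module_trait_correlations()].
#' @param assignment probe -> module labels (for sizes and mean |GS|).
#' @param expr [expression_matrix()] (for mean |GS|; optional).
#' @param trait_values named trait vector (optional, with expr).
#' @param trait trait name in `mt`.
#' @return list: `module`, `rho`, `p`, `summary` (per-module data.frame).
#' @export
select_target_module <- function(mt, assignment, expr = NULL,
                                 trait_values = NULL, trait = "who_grade") {
  tt <- mt[mt$trait == trait & !is.na(mt$rho), , drop = FALSE]
  if (nrow(tt) == 0) stop("no module-trait correlations for trait ", trait)
  sizes <- vapply(tt$module, function(m) sum(assignment == m), numeric(1))
  if (all(tt$p > 0.5, na.rm = TRUE))
    warning("no module correlates with the trait (all p > 0.5)")
  ord <- order(-abs(tt$rho), -sizes)
  best <- tt[ord[1], ]
  summary <- data.frame(module = tt$module, rho = tt$rho, p = tt$p,
                        size = sizes, stringsAsFactors = FALSE)
  if (!is.null(expr) && !is.null(trait_values)) {
    summary$mean_abs_gs <- vapply(tt$module, function(m) {
      probes <- names(assignment)[assignment == m]
      gs <- suppressWarnings(
        cor(t(expr$values[probes, , drop = FALSE]),
            trait_values[colnames(expr$values)], method = "spearman"))
      mean(abs(gs), na.rm = TRUE)
    }, numeric(1))
  }
  list(module = best$module, rho = best$rho, p = best$p, summary = summary)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full integrative pipeline on an aligned cohort
#'
#' Stages: cohort alignment; SNP QC (MAF / call rate / HWE) and expression
#' QC (imputation, variance filter, chromosome exclusion); soft-threshold
#' network, scale-free fit, TOM, module detection and eigengenes; target
#' module selection by trait correlation; hub calling; mQTL scans (ME, PC2
#' improvement, PC1+PC2) and the stage scan with genomic-control lambda;
#' GSmQTL stepwise regression, risk/protective aggregation, final model and
#' dichotomization. All tabular outputs are written as TSV under `out_dir`
#' together with a deterministic JSON manifest (config, seed, versions,
#' per-file checksums). Console messages log per-stage record counts;
#' timestamps appear only in the log so that same-seed runs are
#' byte-identical.
#'
#' @param geno [genotype_matrix()].
#' @param expr [expression_matrix()].
#' @param pheno [phenotype_table()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @param quiet suppress log messages.
#' @return list with the stage outputs and `manifest`.
#' @export
run_pipeline <- function(geno, expr, pheno, config = pipeline_config(),
                         out_dir, quiet = FALSE) {
  cfg <- config
  log <- function(...) if (!quiet)
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  al <- align_cohort(geno, expr, pheno)
  log("aligned cohort: %d samples", nrow(al$geno$calls))

  th <- qc_thresholds(cfg$maf_min, cfg$call_rate_min, cfg$hwe_p_min,
                      cfg$fold_change, cfg$sample_fraction, cfg$knn_k)
  fs <- filter_snps(al$geno, th)
  log("SNP QC: %d of %d kept", ncol(fs$geno$calls), ncol(al$geno$calls))
  ex <- knn_impute(al$expr, th$knn_k)
  ex <- drop_chromosome(ex, cfg$drop_chrom)
  ex <- variance_filter(ex, th)
  log("expression QC: %d of %d probes kept", nrow(ex$values),
      nrow(al$expr$values))
  if (nrow(ex$values) < 3) stop("stage qc: too few probes survive")

  net <- adjacency(ex, beta = cfg$beta)
  k <- connectivity(net)
  sft <- tryCatch(scale_free_fit(k), error = function(e) NULL)
  tom <- tom_similarity(net)
  assignment <- detect_modules(tom, ex, cfg$min_module_size,
                               cfg$cut_height, cfg$merge_threshold)
  mods <- setdiff(unique(assignment), "unassigned")
  log("network: %d modules detected", length(mods))
  if (length(mods) == 0) stop("stage coexpr: no modules detected")

  egs <- lapply(mods, function(m)
    module_eigengene(ex, names(assignment)[assignment == m]))
  names(egs) <- mods
  mt <- module_trait_correlations(lapply(egs, `[[`, "me"), al$pheno)
  trait_vec <- setNames(al$pheno[[cfg$target_trait]], al$pheno$sample_id)
  sel <- select_target_module(mt, assignment, ex, trait_vec,
                              trait = cfg$target_trait)
  target <- sel$module
  log("target module: %s (rho=%.3f, p=%.2g)", target, sel$rho, sel$p)
  members <- names(assignment)[assignment == target]
  eg <- egs[[target]]
  profile <- module_profile(ex, members, eg$me,
                            al$pheno[, cfg$target_trait, drop = FALSE])

  graph <- build_graph(net, members, cfg$edge_threshold)
  ctab <- centrality_table(graph, cfg$hub_degree_min,
                           cfg$hub_betweenness_min)
  log("centrality: %d hubs of %d nodes", sum(ctab$hub), nrow(ctab))

  scan <- mqtl_scan(fs$geno, eg$me, eg$pc2)
  scan$tier <- classify_tier(scan$p, cfg$suggestive_max, cfg$significant_max)
  stage <- setNames(al$pheno$stage_binary, al$pheno$sample_id)
  sscan <- stage_scan(fs$geno, stage)
  sscan$tier <- classify_tier(sscan$p, cfg$suggestive_max,
                              cfg$significant_max)
  lam <- genomic_lambda(sscan$p[!is.na(sscan$p)])
  log("association: %d mQTL records, stage lambda %.3f",
      nrow(scan), lam$lambda)

  me_scan <- scan[scan$model == "ME", ]
  mqtl_ids <- me_scan$snp_id[me_scan$tier %in% c("significant",
                                                 "suggestive")]
  integ <- NULL
  if (length(mqtl_ids) >= 1) {
    gsm <- gsmqtl_matrix(ex$values[members, , drop = FALSE], fs$geno,
                         mqtl_ids)
    gs <- setNames(profile[[paste0("GS_", cfg$target_trait)]],
                   profile$probe_id)
    step <- stepwise_aic(rank_inverse_normal(gs), as.data.frame(gsm))
    agg <- aggregate_risk_protective(step, gsm, cfg$sig_p_threshold)
    fin <- final_model(gs, setNames(profile$kME, profile$probe_id),
                       agg$protective, agg$risk)
    groups <- dichotomize_groups(profile$kME, agg$risk, agg$protective, gs)
    integ <- list(gsmqtl = gsm, stepwise = step, aggregation = agg,
                  final = fin, groups = groups)
    log("integration: adj R2 %.3f over %d probes",
        fin$adj_r_squared, length(gs))
  } else log("integration skipped: no mQTL at the suggestive tier")

  # outputs
  files <- character(0)
  files["modules"] <- .write_tsv(
    data.frame(probe_id = names(assignment), module = unname(assignment)),
    file.path(out_dir, "modules.tsv"))
  files["eigengene"] <- .write_tsv(
    data.frame(sample_id = names(eg$me), ME = unname(eg$me),
               PC2 = unname(eg$pc2)),
    file.path(out_dir, "eigengene.tsv"))
  files["profile"] <- .write_tsv(profile, file.path(out_dir, "profile.tsv"))
  files["centrality"] <- .write_tsv(ctab,
                                    file.path(out_dir, "centrality.tsv"))
  files["mqtl"] <- .write_tsv(scan, file.path(out_dir, "mqtl_scans.tsv"))
  files["stage"] <- .write_tsv(sscan, file.path(out_dir, "stage_scan.tsv"))
  files["module_trait"] <- .write_tsv(mt,
                                      file.path(out_dir, "module_trait.tsv"))
  if (!is.null(sft))
    files["scale_free"] <- .write_tsv(
      data.frame(r_squared = sft$r_squared, pearson_cor = sft$pearson_cor,
                 slope = sft$slope),
      file.path(out_dir, "scale_free.tsv"))
  if (!is.null(integ)) {
    files["groups"] <- .write_tsv(integ$groups,
                                  file.path(out_dir, "groups.tsv"))
    fincf <- data.frame(term = rownames(integ$final$coefficients),
                        integ$final$coefficients)
    files["final_model"] <- .write_tsv(fincf,
                                       file.path(out_dir, "final_model.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mqtlnet")),
    seed = cfg$seed,
    config = unclass(cfg),
    counts = list(samples = nrow(al$geno$calls),
                  snps_kept = ncol(fs$geno$calls),
                  probes_kept = nrow(ex$values),
                  modules = length(mods),
                  target_module = target,
                  hubs = sum(ctab$hub),
                  mqtl_suggestive = length(mqtl_ids)),
    lambda = lam$lambda,
    checksums = {
      sums <- tools::md5sum(unname(files))
      as.list(setNames(unname(sums), basename(names(sums))))
    })
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log("manifest written to %s", manifest_path)

  list(aligned = al, snp_qc = fs, expr_qc = ex, network = net,
       scale_free = sft, assignment = assignment, eigengenes = egs,
       module_trait = mt, target_module = target, profile = profile,
       centrality = ctab, mqtl = scan, stage = sscan, lambda = lam,
       integration = integ, manifest = manifest, out_dir = out_dir)
}
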