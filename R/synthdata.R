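# Synthetic cohorts with a planted co-expression module, grade-linked latent
# factor and mQTL effects, so downstream stages can be validated against
# known ground truth.

#' Simulation parameters for a synthetic tumor cohort
#'
#' Defaults mirror the discovery-cohort template: 59 samples split 39/15/5
#' across WHO grades I/II/III, biallelic SNPs in Hardy-Weinberg proportions
#' with MAF drawn uniformly, and one planted co-expression module driven by a
#' latent factor that responds linearly to grade and to a set of mQTL SNPs.
#'
#' @param n_samples number of samples.
#' @param grade_proportions three non-negative weights for grades I/II/III;
#'   normalized to 1. Samples are allocated by largest remainder so a
#'   template that divides n exactly gives exact counts.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range range of minor-allele frequencies, subset of (0, 0.5].
#' @param genotype_missing_rate fraction of genotype calls masked missing.
#' @param n_probes total expression probes.
#' @param module_size number of probes in the planted module.
#' @param factor_grade_effect gamma: latent-factor shift per grade unit.
#' @param n_mqtl number of SNPs with a direct effect on the latent factor.
#' @param mqtl_effect delta: per-allele latent-factor shift of each mQTL SNP.
#' @param loading_range range of module-probe loadings u_g on the factor.
#' @param residual_sd sigma_e: residual sd of module probes (log2 units).
#' @param background_sd sd of background (non-module) probes.
#' @param n_y_probes background probes annotated to chromosome Y.
#' @param n_batches replication cohort: number of batches.
#' @param batch_location per-batch additive offsets (recycled).
#' @param batch_scale per-batch multiplicative sd factors (recycled).
#' @param de_effect planted between-stage shift (in units of residual sd) for
#'   replication differentially expressed probes.
#' @param n_de number of planted DE probes in the replication cohort.
#' @param rep_n_samples replication cohort size.
#' @param seed master seed; per-matrix streams are derived from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 59,
                       grade_proportions = c(39, 15, 5),
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       genotype_missing_rate = 0.01,
                       n_probes = 1000,
                       module_size = 100,
                       factor_grade_effect = 0.8,
                       n_mqtl = 3,
                       mqtl_effect = 0.8,
                       loading_range = c(0.5, 1),
                       residual_sd = 1,
                       background_sd = 1,
                       n_y_probes = 0,
                       n_batches = 2,
                       batch_location = c(0, 5),
                       batch_scale = c(1, 1.2),
                       de_effect = 2,
                       n_de = 50,
                       rep_n_samples = 100,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$module_size <= p$n_probes,
            p$residual_sd > 0, p$background_sd > 0,
            all(p$grade_proportions >= 0), sum(p$grade_proportions) > 0,
            p$maf_range[1] > 0, p$maf_range[2] <= 0.5,
            p$n_mqtl <= p$n_snps, p$n_batches >= 1)
  p$grade_proportions <- p$grade_proportions / sum(p$grade_proportions)
  class(p) <- "sim_params"
  p
}

# largest-remainder allocation of n samples to the grade template
.allocate_grades <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a genotype/expression/phenotype cohort with planted structure
#'
#' Genotypes: SNP j gets MAF m_j ~ Uniform(maf_range) and calls
#' Binomial(2, m_j) (Hardy-Weinberg), then missingness is masked at the
#' stated rate. Grades follow the template proportions. A latent factor
#' f_s = gamma * grade_s + sum_j delta_j g_js + N(0,1) drives the module:
#' probe g has x_gs = u_g f_s + N(0, sigma_e); background probes are
#' independent noise. The factor uses the unmasked genotypes. Deterministic
#' under the seed; genotype, phenotype and expression use separate RNG
#' streams derived from the master seed, so e.g. changing `n_probes` does
#' not perturb the genotypes.
#'
#' @param params a [sim_params()].
#' @return list with `geno`, `expr`, `pheno`, and `truth` (module probe ids,
#'   latent factor, mQTL ids and effects, loadings).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- p$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  snp_ids <- sprintf("snp%04d", seq_len(p$n_snps))
  probe_ids <- sprintf("probe%04d", seq_len(p$n_probes))

  # genotype stream
  set.seed(p$seed + 1L)
  maf <- runif(p$n_snps, p$maf_range[1], p$maf_range[2])
  calls <- vapply(maf, function(m) rbinom(n, 2, m), numeric(n))
  dimnames(calls) <- list(sample_ids, snp_ids)
  mqtl_ids <- if (p$n_mqtl > 0) sample(snp_ids, p$n_mqtl) else character(0)
  full_calls <- calls
  if (p$genotype_missing_rate > 0) {
    mask <- runif(length(calls)) < p$genotype_missing_rate
    calls[mask] <- NA_real_
  }

  # phenotype stream
  set.seed(p$seed + 2L)
  counts <- .allocate_grades(n, p$grade_proportions)
  if (p$factor_grade_effect != 0 && any(counts == 0 & p$grade_proportions > 0))
    stop("empty grade class under a non-zero grade effect")
  grades <- sample(rep(1:3, times = counts))
  pheno <- phenotype_table(data.frame(sample_id = sample_ids,
                                      who_grade = grades))

  # expression stream
  set.seed(p$seed + 3L)
  f <- p$factor_grade_effect * grades + rnorm(n)
  if (p$n_mqtl > 0)
    f <- f + full_calls[, mqtl_ids, drop = FALSE] %*%
      rep(p$mqtl_effect, p$n_mqtl)
  f <- as.numeric(f)
  module_probes <- probe_ids[seq_len(p$module_size)]
  u <- runif(p$module_size, p$loading_range[1], p$loading_range[2])
  xmod <- outer(u, f) + matrix(rnorm(p$module_size * n, sd = p$residual_sd),
                               p$module_size, n)
  nbg <- p$n_probes - p$module_size
  xbg <- matrix(rnorm(nbg * n, sd = p$background_sd), nbg, n)
  values <- rbind(xmod, xbg)
  dimnames(values) <- list(probe_ids, sample_ids)

  chrom <- rep(NA_character_, p$n_probes)
  if (p$n_y_probes > 0) {
    ybg <- seq(p$n_probes - p$n_y_probes + 1, p$n_probes)
    chrom[ybg] <- "Y"
  }
  meta <- data.frame(probe_id = probe_ids,
                     gene = paste0("GENE", seq_len(p$n_probes)),
                     chrom = chrom, stringsAsFactors = FALSE)

  list(geno = genotype_matrix(calls),
       expr = expression_matrix(values, meta),
       pheno = pheno,
       truth = list(module_probes = module_probes,
                    factor = setNames(f, sample_ids),
                    mqtl_ids = mqtl_ids,
                    mqtl_effect = p$mqtl_effect,
                    loadings = setNames(u, module_probes)))
}

#' Simulate a replication expression cohort with batches and planted DE
#'
#' Uses the same probe universe as the discovery cohort. Stage-1 samples get
#' a `de_effect * residual_sd` shift at the planted DE probes; each batch is
#' then offset/scaled by the stated location and scale.
#'
#' @param params a [sim_params()].
#' @param truth the `truth` component of [simulate_cohort()].
#' @return list with `expr`, `batch` (labels), `pheno`, `de_probes`.
#' @export
simulate_replication <- function(params, truth) {
  p <- params
  stopifnot(p$n_batches >= 1)
  set.seed(p$seed + 4L)
  n <- p$rep_n_samples
  sample_ids <- sprintf("R%03d", seq_len(n))
  probe_ids <- sprintf("probe%04d", seq_len(p$n_probes))
  stage <- rbinom(n, 1, 0.5)
  # guarantee both groups
  if (all(stage == 0)) stage[1] <- 1
  if (all(stage == 1)) stage[1] <- 0
  who <- ifelse(stage == 0, 1, sample(2:3, n, replace = TRUE))
  batch <- rep_len(seq_len(p$n_batches), n)

  de_probes <- sample(probe_ids, min(p$n_de, p$n_probes))
  values <- matrix(rnorm(p$n_probes * n, sd = p$residual_sd),
                   p$n_probes, n, dimnames = list(probe_ids, sample_ids))
  shift <- p$de_effect * p$residual_sd
  values[de_probes, stage == 1] <- values[de_probes, stage == 1] + shift

  loc <- rep_len(p$batch_location, p$n_batches)
  scl <- rep_len(p$batch_scale, p$n_batches)
  for (b in seq_len(p$n_batches)) {
    cols <- which(batch == b)
    values[, cols] <- values[, cols] * scl[b] + loc[b]
  }

  pheno <- phenotype_table(data.frame(sample_id = sample_ids,
                                      who_grade = who))
  list(expr = expression_matrix(values),
       batch = setNames(batch, sample_ids),
       pheno = pheno,
       de_probes = de_probes)
}
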