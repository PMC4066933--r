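# Association scans with SNP allele counts as the model outcome: mQTL scans
# against module summaries, SNP-stage association, significance tiers,
# per-gene deduplication and the genomic-control inflation factor.

.CHISQ1_MEDIAN <- 0.4549364

# binomial-logistic fit of allele counts on covariates; returns deviance,
# coefficients, se, convergence flag
.fit_allele_glm <- function(g, X) {
  y <- cbind(alt = g, ref = 2 - g)
  df <- as.data.frame(X)
  fit <- suppressWarnings(
    if (ncol(df) == 0) glm(y ~ 1, family = binomial())
    else glm(y ~ ., data = df, family = binomial()))
  fitted_eta <- fit$linear.predictors
  sep <- !fit$converged || any(abs(fitted_eta) > 15)
  list(fit = fit, deviance = fit$deviance, separation = sep)
}

# ridge-penalized logistic refit for (quasi-)separated genotypes
.ridge_logistic <- function(g, X, lambda = 1e-4, maxit = 100) {
  X1 <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X1) - 1)), ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- 2 * mu * (1 - mu)
    z <- eta + (g - 2 * mu) / pmax(w, 1e-10)
    bn <- solve(crossprod(X1 * sqrt(w)) + pen, crossprod(X1 * w, z))
    if (max(abs(bn - b)) < 1e-8) { b <- bn; break }
    b <- bn
  }
  eta <- as.numeric(X1 %*% b)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  dev <- -2 * sum(g * log(mu) + (2 - g) * log(1 - mu) -
                    (g * log(pmax(g / 2, 1e-12)) +
                       (2 - g) * log(pmax(1 - g / 2, 1e-12))))
  list(coef = as.numeric(b), deviance = dev)
}

#' Logistic association test with the SNP as the dependent phenotype
#'
#' Models the allele count as y_i ~ Binomial(2, pi_i) with
#' logit(pi_i) = intercept + b * covariates, and tests the added covariates
#' by a likelihood-ratio test against the model containing only
#' `base_covariates` (df = number added). Missing genotypes are dropped
#' pairwise. Monomorphic genotypes are skipped; separation triggers a
#' ridge-penalized refit and sets the `flagged` field. A GLM score test of
#' the added covariates is available via `method = "score"`.
#'
#' @param genotype numeric 0/1/2 vector (NA = missing).
#' @param covariates data.frame or named matrix of covariates to test.
#' @param base_covariates optional data.frame of covariates present in both
#'   models (NULL = intercept-only base).
#' @param method "lrt" (default) or "score".
#' @param snp_id label carried into the record.
#' @return one-row data.frame: snp_id, effect, se, p, n, tier, flagged,
#'   skip_reason.
#' @export
genotype_outcome_test <- function(genotype, covariates,
                                  base_covariates = NULL,
                                  method = c("lrt", "score"),
                                  snp_id = NA_character_) {
  method <- match.arg(method)
  covariates <- as.data.frame(covariates)
  skip <- function(reason) data.frame(
    snp_id = snp_id, effect = NA_real_, se = NA_real_, p = NA_real_,
    n = sum(!is.na(genotype)), tier = "none", flagged = FALSE,
    skip_reason = reason, stringsAsFactors = FALSE)

  keep <- !is.na(genotype) & complete.cases(covariates)
  if (!is.null(base_covariates)) {
    base_covariates <- as.data.frame(base_covariates)
    keep <- keep & complete.cases(base_covariates)
  }
  g <- genotype[keep]
  if (length(g) < 10) return(skip("fewer than 10 non-missing genotypes"))
  if (length(unique(g)) < 2) return(skip("monomorphic"))
  Xadd <- covariates[keep, , drop = FALSE]
  Xbase <- if (is.null(base_covariates))
    Xadd[, 0, drop = FALSE] else base_covariates[keep, , drop = FALSE]
  Xfull <- cbind(Xbase, Xadd)
  df_test <- ncol(Xadd)

  if (method == "score") {
    p <- .score_test(g, as.matrix(Xbase), as.matrix(Xadd))
    return(data.frame(snp_id = snp_id, effect = NA_real_, se = NA_real_,
                      p = p, n = length(g), tier = classify_tier(p),
                      flagged = FALSE, skip_reason = NA_character_,
                      stringsAsFactors = FALSE))
  }

  full <- .fit_allele_glm(g, Xfull)
  base <- .fit_allele_glm(g, Xbase)
  flagged <- FALSE
  if (full$separation) {
    rf <- .ridge_logistic(g, Xfull)
    rb <- .ridge_logistic(g, Xbase)
    lr <- max(rb$deviance - rf$deviance, 0)
    eff <- rf$coef[ncol(as.matrix(Xbase)) + 2]  # first added covariate
    se <- NA_real_
    flagged <- TRUE
  } else {
    lr <- max(base$deviance - full$deviance, 0)
    cf <- summary(full$fit)$coefficients
    last <- nrow(cf) - df_test + 1
    eff <- cf[last, 1]
    se <- cf[last, 2]
  }
  p <- pchisq(lr, df = df_test, lower.tail = FALSE)
  data.frame(snp_id = snp_id, effect = eff, se = se, p = p, n = length(g),
             tier = classify_tier(p), flagged = flagged,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

# GLM score test: fit the null binomial model, test added covariates
.score_test <- function(g, Xbase, Xadd) {
  n <- length(g)
  X0 <- cbind(1, Xbase)
  fit0 <- .fit_allele_glm(g, as.data.frame(Xbase))
  mu <- fit0$fit$fitted.values          # P(alt) per trial
  w <- 2 * mu * (1 - mu)
  r <- g - 2 * mu
  Xa <- as.matrix(Xadd)
  U <- crossprod(Xa, r)
  # information with null-model nuisance projection
  I_aa <- crossprod(Xa * w, Xa)
  I_a0 <- crossprod(Xa * w, X0)
  I_00 <- crossprod(X0 * w, X0)
  V <- I_aa - I_a0 %*% solve(I_00, t(I_a0))
  stat <- as.numeric(t(U) %*% solve(V, U))
  pchisq(stat, df = ncol(Xa), lower.tail = FALSE)
}

#' Significance tier of a p-value
#'
#' "significant" iff p <= 1e-6; "suggestive" iff 1e-6 < p < 1e-4 (the
#' "order of 1e-5 or less" selection rule); otherwise "none".
#'
#' @param p p-value(s) in (0, 1].
#' @param suggestive_max,significant_max tier cutoffs.
#' @return character vector.
#' @export
classify_tier <- function(p, suggestive_max = 1e-4, significant_max = 1e-6) {
  ifelse(is.na(p), "none",
         ifelse(p <= significant_max, "significant",
                ifelse(p < suggestive_max, "suggestive", "none")))
}

#' mQTL scan of every SNP against module summaries
#'
#' Three scans: (A) regressor = module eigengene; (B) improvement test of
#' PC2 over a base model containing the eigengene (1-df LRT); (C) regressor
#' = the elementwise sum PC1 + PC2. Each record is tiered.
#'
#' @param geno a [genotype_matrix()] aligned to the summaries.
#' @param me,pc2 module eigengene and second component, named by sample.
#' @param scans subset of c("ME", "ME_plus_PC2_improvement", "PC1plusPC2").
#' @return data.frame of association records with a `model` column.
#' @export
mqtl_scan <- function(geno, me, pc2,
                      scans = c("ME", "ME_plus_PC2_improvement",
                                "PC1plusPC2")) {
  ids <- rownames(geno$calls)
  stopifnot(all(ids %in% names(me)))
  me <- me[ids]
  pc2 <- pc2[ids]
  out <- list()
  for (sc in scans) {
    recs <- lapply(colnames(geno$calls), function(s) {
      g <- geno$calls[, s]
      r <- switch(sc,
        ME = genotype_outcome_test(g, data.frame(ME = me), snp_id = s),
        ME_plus_PC2_improvement = genotype_outcome_test(
          g, data.frame(PC2 = pc2),
          base_covariates = data.frame(ME = me), snp_id = s),
        PC1plusPC2 = genotype_outcome_test(
          g, data.frame(PC1plusPC2 = me + pc2), snp_id = s))
      r$model <- sc
      r
    })
    out[[sc]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep the most significant SNP per gene
#'
#' Unmapped SNPs pass through untouched; within a gene the minimum-p record
#' wins, ties broken by lexicographic snp_id.
#'
#' @param table association table with `snp_id` and `p`.
#' @param snp_gene named character vector snp_id -> gene (may be partial).
#' @return deduplicated table with a `gene` column.
#' @export
dedup_by_gene <- function(table, snp_gene) {
  table$gene <- unname(snp_gene[table$snp_id])
  mapped <- !is.na(table$gene)
  keep <- rep(TRUE, nrow(table))
  for (g in unique(table$gene[mapped])) {
    idx <- which(mapped & table$gene == g)
    if (length(idx) > 1) {
      ord <- idx[order(table$p[idx], table$snp_id[idx])]
      keep[setdiff(idx, ord[1])] <- FALSE
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP association with binary tumor stage
#'
#' Runs [genotype_outcome_test()] for every SNP with the stage indicator
#' (0 = WHO grade I, 1 = grades II/III) as the single covariate.
#'
#' @param geno a [genotype_matrix()].
#' @param stage_binary named 0/1 vector over the genotype samples.
#' @return association table.
#' @export
stage_scan <- function(geno, stage_binary) {
  ids <- rownames(geno$calls)
  stopifnot(all(ids %in% names(stage_binary)))
  st <- stage_binary[ids]
  if (length(unique(st[!is.na(st)])) < 2)
    stop("both stage classes must be present")
  recs <- lapply(colnames(geno$calls), function(s)
    genotype_outcome_test(geno$calls[, s], data.frame(stage = st),
                          snp_id = s))
  res <- do.call(rbind, recs)
  res$model <- "stage"
  res
}

#' Genomic-control inflation factor lambda
#'
#' Each p-value is mapped to its 1-df chi-square quantile; lambda is the
#' median of those over the null median 0.4549364. Order-invariant.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return list: `lambda`, `n_tests`.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  q <- qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda = median(q) / .CHISQ1_MEDIAN, n_tests = length(p))
}

#' Gene overlaps between tiered association tables
#'
#' For every pair of tables, reports genes whose symbol appears in both
#' tables' selected (tiered) records, either directly or through a
#' user-supplied proxy map (e.g. linkage-disequilibrium proxies); proxy hits
#' carry provenance "proxy". Genes present in at least two tables are
#' flagged as duplicate findings.
#'
#' @param tables named list of association tables with `snp_id`, `p`,
#'   `tier`, optional `gene`.
#' @param snp_gene named vector snp_id -> gene for unannotated tables.
#' @param proxy_map optional named list gene -> character vector of proxy
#'   gene symbols.
#' @param tiers tiers counted as selected.
#' @return list with `pairs` (data.frame table1, table2, gene, provenance)
#'   and `duplicate_findings` (genes in >= 2 tables).
#' @export
replicate_overlap <- function(tables, snp_gene = NULL, proxy_map = NULL,
                              tiers = c("significant", "suggestive")) {
  genes_of <- function(tb) {
    sel <- tb[tb$tier %in% tiers, , drop = FALSE]
    g <- if ("gene" %in% names(sel) && any(!is.na(sel$gene))) sel$gene
    else unname(snp_gene[sel$snp_id])
    direct <- unique(g[!is.na(g)])
    proxies <- character(0)
    if (!is.null(proxy_map))
      proxies <- setdiff(unique(unlist(proxy_map[direct])), direct)
    list(direct = direct, proxy = proxies)
  }
  sets <- lapply(tables, genes_of)
  nm <- names(tables)
  rows <- list()
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in seq(i + 1, length(nm))) {
      a <- sets[[i]]; b <- sets[[j]]
      both <- intersect(a$direct, b$direct)
      via_proxy <- setdiff(union(intersect(a$direct, b$proxy),
                                 intersect(b$direct, a$proxy)), both)
      if (length(both))
        rows[[length(rows) + 1]] <- data.frame(
          table1 = nm[i], table2 = nm[j], gene = both,
          provenance = "direct", stringsAsFactors = FALSE)
      if (length(via_proxy))
        rows[[length(rows) + 1]] <- data.frame(
          table1 = nm[i], table2 = nm[j], gene = via_proxy,
          provenance = "proxy", stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(table1 = character(0), table2 = character(0),
               gene = character(0), provenance = character(0))
  counts <- table(unlist(lapply(sets, function(s) s$direct)))
  list(pairs = pairs,
       duplicate_findings = names(counts)[counts >= 2])
}
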