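# Integrative regression machinery: GSmQTL construction, rank
# inverse-normal transform, OLS reports with AIC/VIF/normality, stepwise-AIC
# selection, risk/protective aggregation and median dichotomization.
# Observations in all these regressions are module probes, not samples.

#' Spearman correlations of module probes with mQTL genotypes (GSmQTL)
#'
#' Column j, row g = Spearman correlation of probe g's expression with SNP
#' j's allele counts; missing genotypes dropped pairwise.
#'
#' @param expr_module expression values of the module probes (matrix probes
#'   x samples) or an [expression_matrix()].
#' @param geno a [genotype_matrix()] aligned to the same samples.
#' @param mqtl_ids SNP ids (must be polymorphic).
#' @return matrix probes x mQTLs of correlations.
#' @export
gsmqtl_matrix <- function(expr_module, geno, mqtl_ids) {
  x <- if (inherits(expr_module, "expression_matrix")) expr_module$values
  else expr_module
  stopifnot(all(mqtl_ids %in% colnames(geno$calls)))
  g <- geno$calls[colnames(x), mqtl_ids, drop = FALSE]
  mono <- apply(g, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  if (any(mono)) stop("monomorphic mQTL SNP: ", mqtl_ids[mono][1])
  out <- suppressWarnings(cor(t(x), g, method = "spearman",
                              use = "pairwise.complete.obs"))
  dimnames(out) <- list(rownames(x), mqtl_ids)
  out
}

#' Rank inverse-normal transform
#'
#' z_i = qnorm((r_i - 0.5) / n) with r_i the average rank of x_i. Invariant
#' under strictly increasing transforms of the input; mean zero when there
#' are no ties.
#'
#' @param x numeric vector, n >= 2, not all equal.
#' @return transformed vector.
#' @export
rank_inverse_normal <- function(x) {
  stopifnot(length(x) >= 2)
  if (length(unique(x[!is.na(x)])) < 2) stop("constant input")
  r <- rank(x, ties.method = "average", na.last = "keep")
  qnorm((r - 0.5) / sum(!is.na(x)))
}

.aic_rss <- function(rss, n, n_coef) n * log(rss / n) + 2 * (n_coef + 1)

#' Ordinary least squares with AIC, VIF and residual-normality report
#'
#' AIC is the RSS form n log(RSS/n) + 2 (p + 1), p = number of coefficients
#' including the intercept (constant terms omitted consistently, so only
#' differences matter). The model-level VIF is 1/(1 - R^2); per-predictor
#' VIFs come from regressing each predictor on the others. Residual
#' normality is a Shapiro-Wilk test.
#'
#' @param response numeric vector.
#' @param predictors data.frame or matrix of predictors (may have zero
#'   columns for the intercept-only model).
#' @return list of class `regression_report`: coefficients (data.frame with
#'   estimate, se, t, p), `r_squared`, `adj_r_squared`, `aic`, `model_vif`,
#'   `vifs`, `shapiro_w`, `shapiro_p`, `fitted`, `residuals`, `n`.
#' @export
fit_linear <- function(response, predictors) {
  X <- as.data.frame(predictors)
  n <- length(response)
  stopifnot(n > ncol(X) + 1)
  fit <- if (ncol(X) == 0) lm(response ~ 1)
  else lm(response ~ ., data = X)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design; aliased: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  names(cf) <- c("estimate", "se", "t", "p")
  rss <- sum(resid(fit)^2)
  r2 <- sm$r.squared
  vifs <- if (ncol(X) >= 2) {
    vapply(seq_len(ncol(X)), function(j) {
      r2j <- summary(lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared
      1 / (1 - r2j)
    }, numeric(1))
  } else setNames(numeric(0), character(0))
  if (length(vifs)) names(vifs) <- names(X)
  sh <- if (n >= 3 && n <= 5000 && sd(resid(fit)) > 0)
    shapiro.test(resid(fit)) else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    coefficients = cf,
    r_squared = r2,
    adj_r_squared = sm$adj.r.squared,
    aic = .aic_rss(rss, n, length(coef(fit))),
    model_vif = 1 / (1 - r2),
    vifs = vifs,
    shapiro_w = unname(sh$statistic), shapiro_p = sh$p.value,
    fitted = fitted(fit), residuals = resid(fit),
    predictors = names(X), n = n), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("regression_report: n=%d, R2=%.3f (adj %.3f), AIC=%.2f, VIF=%.2f\n",
              x$n, x$r_squared, x$adj_r_squared, x$aic, x$model_vif))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stepwise model selection by AIC (bidirectional, deterministic)
#'
#' Starts from the full model. At each step every single-predictor addition
#' and removal is scored with the RSS-form AIC of [fit_linear()]; the move
#' with the largest AIC decrease is applied; the search stops when no move
#' decreases the AIC. Ties prefer removal, then lexicographic predictor
#' name.
#'
#' @param response numeric vector.
#' @param predictors data.frame of candidate predictors.
#' @return `regression_report` of the selected model (with `selected`, the
#'   chosen predictor names).
#' @export
stepwise_aic <- function(response, predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) >= 2) {
    # duplicate/aliased columns are an error up front
    qr_rank <- qr(cbind(1, as.matrix(X)))$rank
    if (qr_rank < ncol(X) + 1) stop("aliased predictor columns")
  }
  current <- sort(names(X))
  aic_of <- function(vars) fit_linear(response, X[, vars, drop = FALSE])$aic
  cur_aic <- aic_of(current)
  repeat {
    moves <- data.frame(var = character(0), action = character(0),
                        aic = numeric(0), stringsAsFactors = FALSE)
    for (v in sort(current))
      moves <- rbind(moves, data.frame(var = v, action = "remove",
                                       aic = aic_of(setdiff(current, v))))
    for (v in sort(setdiff(names(X), current)))
      moves <- rbind(moves, data.frame(var = v, action = "add",
                                       aic = aic_of(sort(c(current, v)))))
    if (nrow(moves) == 0) break
    # deterministic order: best AIC, removal before addition, then name
    moves <- moves[order(moves$aic,
                         match(moves$action, c("remove", "add")),
                         moves$var), , drop = FALSE]
    if (moves$aic[1] >= cur_aic - 1e-10) break
    v <- moves$var[1]
    current <- if (moves$action[1] == "remove") setdiff(current, v)
    else sort(c(current, v))
    cur_aic <- moves$aic[1]
  }
  rep_ <- fit_linear(response, X[, current, drop = FALSE])
  rep_$selected <- current
  rep_
}

#' Aggregate significant GSmQTL columns into risk and protective sums
#'
#' From a stepwise report over GSmQTL columns, collects predictors with
#' t-test p below the threshold and splits them by coefficient sign:
#' positive coefficients sum (row-wise) into GSmQTLRisk, negative into
#' GSmQTLProtective.
#'
#' @param report a `regression_report` from [stepwise_aic()].
#' @param gsmqtl matrix of GSmQTL columns (probes x SNPs).
#' @param p_threshold t-test p cutoff (default 0.01).
#' @return list with `risk`, `protective` (numeric per probe),
#'   `risk_vars`, `protective_vars`.
#' @export
aggregate_risk_protective <- function(report, gsmqtl, p_threshold = 0.01) {
  cf <- report$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  vars <- rownames(cf)[cf$p < p_threshold]
  # lm mangles non-syntactic names; map back to gsmqtl columns
  match_col <- function(v) {
    hit <- colnames(gsmqtl)[make.names(colnames(gsmqtl)) == v |
                              colnames(gsmqtl) == v]
    if (length(hit) != 1) stop("cannot map predictor ", v)
    hit
  }
  pos <- vapply(vars[cf[vars, "estimate"] > 0], match_col, character(1))
  neg <- vapply(vars[cf[vars, "estimate"] < 0], match_col, character(1))
  if (length(pos) + length(neg) == 0)
    warning("no significant variables; risk and protective sums are zero")
  zero <- rep(0, nrow(gsmqtl))
  risk <- if (length(pos)) rowSums(gsmqtl[, pos, drop = FALSE]) else
    setNames(zero, rownames(gsmqtl))
  prot <- if (length(neg)) rowSums(gsmqtl[, neg, drop = FALSE]) else
    setNames(zero, rownames(gsmqtl))
  list(risk = risk, protective = prot,
       risk_vars = unname(pos), protective_vars = unname(neg))
}

#' Final integrative model: GS ~ kME + Protective + Risk
#'
#' OLS of the rank-inverse-normal transformed gene significance on the
#' three regressors; the report carries fitted values and the Spearman
#' correlation between fitted and observed GS.
#'
#' @param gs gene-significance vector (per module probe).
#' @param kme kME vector.
#' @param protective,risk aggregated GSmQTL sums.
#' @return `regression_report` with extra fields `fitted_gs_spearman` and
#'   `fitted`.
#' @export
final_model <- function(gs, kme, protective, risk) {
  X <- data.frame(kME = kme)
  if (sd(protective) > 0) X$GSmQTLProtective <- protective
  if (sd(risk) > 0) X$GSmQTLRisk <- risk
  rep_ <- fit_linear(rank_inverse_normal(gs), X)
  rep_$fitted_gs_spearman <- suppressWarnings(
    cor(rep_$fitted, gs, method = "spearman"))
  rep_
}

#' Median dichotomization into the eight (K, R, P) groups
#'
#' Each probe is labelled K+/K- (kME above / not above its median), R+/R-
#' (risk sum) and P+/P- (protective sum); values equal to the median go to
#' the lower group. Returns per-group size and GS summary.
#'
#' @param kme,risk,protective,gs aligned per-probe vectors.
#' @return data.frame: group, n, mean_gs, median_gs, sd_gs.
#' @export
dichotomize_groups <- function(kme, risk, protective, gs) {
  half <- function(v, tag) {
    if (sd(v) == 0) warning(tag, " split degenerate: constant vector")
    ifelse(v > median(v), paste0(tag, "+"), paste0(tag, "-"))
  }
  grp <- paste0(half(kme, "K"), half(risk, "R"), half(protective, "P"))
  levels <- as.vector(outer(outer(c("K+", "K-"), c("R+", "R-"), paste0),
                            c("P+", "P-"), paste0))
  out <- do.call(rbind, lapply(levels, function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               mean_gs = if (any(sel)) mean(gs[sel]) else NA_real_,
               median_gs = if (any(sel)) median(gs[sel]) else NA_real_,
               sd_gs = if (sum(sel) > 1) sd(gs[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
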