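# Genotype and expression quality control: MAF / call-rate / HWE filters on
# SNPs, fold-change variance filter and chromosome exclusion on probes, and
# k-nearest-neighbour imputation of missing expression values.

#' Default QC thresholds
#'
#' MAF >= 0.05, call rate >= 0.95, HWE p >= 0.01 for SNPs; probes must show a
#' >= 1.8-fold change from their median in >= 10% of samples. All thresholds
#' inclusive.
#'
#' @param maf_min minimum minor-allele frequency.
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value.
#' @param fold_change minimum fold change from the probe median (linear
#'   scale; applied as |log2 deviation| >= log2(fold_change)).
#' @param sample_fraction minimum fraction of samples showing the change.
#' @param knn_k neighbours used by [knn_impute()].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.95,
                          hwe_p_min = 0.01, fold_change = 1.8,
                          sample_fraction = 0.10, knn_k = 10) {
  stopifnot(maf_min > 0, maf_min <= 0.5, call_rate_min > 0,
            call_rate_min <= 1, hwe_p_min > 0, hwe_p_min <= 1,
            fold_change > 1, sample_fraction > 0, sample_fraction <= 1,
            knn_k >= 1)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, fold_change = fold_change,
                 sample_fraction = sample_fraction, knn_k = knn_k),
            class = "qc_thresholds")
}

#' Minor allele frequency of a genotype vector
#'
#' Computed on non-missing calls and folded to the minor allele:
#' min(p-hat, 1 - p-hat) with p-hat = sum(calls) / (2 n).
#'
#' @param calls numeric vector of 0/1/2 allele counts, NA = missing.
#' @return frequency in [0, 0.5].
#' @export
minor_allele_frequency <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0) stop("all calls missing")
  p <- sum(obs) / (2 * length(obs))
  min(p, 1 - p)
}

#' Call rate (fraction of non-missing calls)
#' @param calls numeric vector, NA = missing.
#' @return fraction in [0, 1].
#' @export
call_rate <- function(calls) {
  stopifnot(length(calls) >= 1)
  mean(!is.na(calls))
}

#' Pearson 1-df chi-square test of Hardy-Weinberg equilibrium
#'
#' Expected counts n(1-p)^2, 2np(1-p), np^2 with p the sample allele
#' frequency; no continuity correction. An exact test (conditional on the
#' allele counts, standard mid-less heterozygote enumeration) is available
#' via `method = "exact"`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @param method "chisq" (default) or "exact".
#' @return list with `chi_square` (NA for exact) and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotype counts")
  nalt <- n_ab + 2 * n_bb
  if (nalt == 0 || nalt == 2 * n)
    stop("monomorphic genotype counts: HWE test undefined")
  p <- nalt / (2 * n)
  if (method == "chisq") {
    expd <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
    chi <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
    list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
  } else {
    # exact: enumerate heterozygote counts conditional on allele counts
    na_ <- 2 * n - nalt
    nb <- nalt
    hets <- seq(nb %% 2, min(na_, nb), by = 2)
    logpr <- vapply(hets, function(h) {
      lgamma(n + 1) - lgamma((na_ - h) / 2 + 1) - lgamma(h + 1) -
        lgamma((nb - h) / 2 + 1) + h * log(2) +
        lgamma(na_ + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    pr <- exp(logpr - max(logpr))
    pr <- pr / sum(pr)
    pobs <- pr[match(n_ab, hets)]
    list(chi_square = NA_real_,
         p = min(1, sum(pr[pr <= pobs * (1 + 1e-7)])))
  }
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' All three statistics are computed on the original matrix (the rules are
#' order-independent) and a SNP is kept iff it passes all of them
#' (inclusive thresholds). Monomorphic SNPs get HWE p = NA and fail the MAF
#' rule anyway.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `geno` (filtered) and `report` (per-SNP data.frame with
#'   maf, call_rate, hwe_p, kept flag and comma-separated failing rules).
#' @export
filter_snps <- function(geno, thresholds = qc_thresholds()) {
  th <- thresholds
  calls <- geno$calls
  stats <- apply(calls, 2, function(g) {
    obs <- g[!is.na(g)]
    maf <- if (length(obs)) minor_allele_frequency(g) else NA_real_
    cr <- call_rate(g)
    counts <- c(sum(obs == 0), sum(obs == 1), sum(obs == 2))
    hwe <- if (length(obs) && maf > 0)
      hwe_test(counts[1], counts[2], counts[3])$p else NA_real_
    c(maf = maf, call_rate = cr, hwe_p = hwe)
  })
  report <- data.frame(snp_id = colnames(calls), t(stats),
                       stringsAsFactors = FALSE)
  fail_maf <- is.na(report$maf) | report$maf < th$maf_min
  fail_cr <- report$call_rate < th$call_rate_min
  fail_hwe <- !is.na(report$hwe_p) & report$hwe_p < th$hwe_p_min
  report$kept <- !(fail_maf | fail_cr | fail_hwe)
  report$fail_reason <- apply(cbind(maf = fail_maf, call_rate = fail_cr,
                                    hwe = fail_hwe), 1,
                              function(f) paste(names(f)[f], collapse = ","))
  if (!any(report$kept)) warning("no SNPs pass the filters")
  geno$calls <- calls[, report$kept, drop = FALSE]
  geno$snp_meta <- geno$snp_meta[report$kept, , drop = FALSE]
  rownames(geno$snp_meta) <- NULL
  list(geno = geno, report = report)
}

#' Fold-change variance filter for expression probes
#'
#' Keeps a probe iff the fraction of samples whose log2 value deviates from
#' the probe median by at least log2(fold_change) is at least
#' `sample_fraction` (both inclusive). Invariant under adding a constant to
#' a probe.
#'
#' @param expr an [expression_matrix()] (log2 scale).
#' @param thresholds a [qc_thresholds()].
#' @return filtered [expression_matrix()].
#' @export
variance_filter <- function(expr, thresholds = qc_thresholds()) {
  th <- thresholds
  cut <- log2(th$fold_change)
  dev <- abs(expr$values - apply(expr$values, 1, median, na.rm = TRUE))
  frac <- rowMeans(dev >= cut, na.rm = TRUE)
  keep <- frac >= th$sample_fraction
  expr$values <- expr$values[keep, , drop = FALSE]
  expr$probe_meta <- expr$probe_meta[keep, , drop = FALSE]
  rownames(expr$probe_meta) <- NULL
  expr
}

#' Drop probes annotated to a chromosome (default Y)
#'
#' Probes without a chromosome annotation are kept.
#' @param expr an [expression_matrix()].
#' @param chromosome chromosome label, compared literally.
#' @return filtered [expression_matrix()].
#' @export
drop_chromosome <- function(expr, chromosome = "Y") {
  chrom <- expr$probe_meta$chrom
  keep <- is.na(chrom) | chrom != chromosome
  expr$values <- expr$values[keep, , drop = FALSE]
  expr$probe_meta <- expr$probe_meta[keep, , drop = FALSE]
  rownames(expr$probe_meta) <- NULL
  expr
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell (probe g, sample s) is replaced by the mean over the k
#' probes nearest to g (Euclidean distance on the samples observed in both
#' probes) of their values at sample s; only probes observed at s are
#' candidates. Ties are broken by probe order, so the result is
#' deterministic.
#'
#' @param expr an [expression_matrix()]; every probe needs >= 1 observed
#'   value.
#' @param k number of neighbours.
#' @return [expression_matrix()] without missing values.
#' @export
knn_impute <- function(expr, k = 10) {
  x <- expr$values
  if (!anyNA(x)) return(expr)
  if (any(rowSums(!is.na(x)) == 0))
    stop("probe with no observed values: ",
         rownames(x)[rowSums(!is.na(x)) == 0][1])
  miss <- which(is.na(x), arr.ind = TRUE)
  for (g in unique(miss[, 1])) {
    target <- x[g, ]
    shared <- !is.na(target)
    # squared distance over shared observed samples, per candidate probe
    d <- apply(x, 1, function(row) {
      ok <- shared & !is.na(row)
      if (!any(ok)) return(Inf)
      sum((row[ok] - target[ok])^2) * length(target) / sum(ok)
    })
    d[g] <- Inf
    ord <- order(d)  # stable: ties by probe order
    for (s in miss[miss[, 1] == g, 2]) {
      cand <- ord[!is.na(x[ord, s]) & is.finite(d[ord])]
      if (length(cand) == 0)
        stop("no neighbour with an observed value for sample ",
             colnames(x)[s])
      nb <- cand[seq_len(min(k, length(cand)))]
      x[g, s] <- mean(x[nb, s])
    }
  }
  expr$values <- x
  expr
}
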