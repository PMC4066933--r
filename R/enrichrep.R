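# Hypergeometric gene-set enrichment with coverage filters, permutation
# PPI-interaction enrichment, a location-scale batch adjustment, and the
# replication-cohort differential-expression / connectivity statistics.

#' Hypergeometric gene-set enrichment with FDR and coverage filters
#'
#' For each term: overlap x of the query with the term inside the universe;
#' upper-tail p = P(X >= x), X ~ Hypergeometric(N, K, n); BH adjustment
#' across tested terms; coverage = x / (query genes in universe). A term
#' passes iff q < fdr_threshold and coverage >= coverage_min.
#'
#' @param query character vector of gene symbols.
#' @param sets a `gene_set_collection` (or named list with `genes`).
#' @param universe background gene symbols.
#' @param fdr_threshold BH-FDR cutoff (default 0.001).
#' @param coverage_min minimum fraction of the query covered by the term
#'   (default 0.10).
#' @return data.frame: term, description, N, K, n, x, p, q, coverage, pass.
#' @export
hypergeom_enrichment <- function(query, sets, universe,
                                 fdr_threshold = 0.001,
                                 coverage_min = 0.10) {
  universe <- unique(universe)
  q_genes <- intersect(unique(query), universe)
  if (length(q_genes) == 0) stop("query has no genes in the universe")
  N <- length(universe)
  n <- length(q_genes)
  rows <- lapply(names(sets), function(tm) {
    genes <- intersect(sets[[tm]]$genes, universe)
    K <- length(genes)
    x <- length(intersect(genes, q_genes))
    p <- if (K == 0) 1 else
      phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, description = sets[[tm]]$description,
               N = N, K = K, n = n, x = x, p = p,
               coverage = x / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$pass <- out$q < fdr_threshold & out$coverage >= coverage_min
  out[order(out$p), c("term", "description", "N", "K", "n", "x", "p", "q",
                      "coverage", "pass")]
}

#' Benjamini-Hochberg FDR adjustment
#' @param p_values p-values in (0, 1].
#' @return q-values (monotone step-up adjustment).
#' @export
bh_fdr <- function(p_values) p.adjust(p_values, method = "BH")

#' Permutation test of PPI interaction-count enrichment
#'
#' Observed = edges of the PPI network with both endpoints in the gene set
#' (after intersecting the set with the PPI node universe). Null = edge
#' counts of B uniformly random node subsets of the same size; expected =
#' null mean; p = (1 + #\{null >= observed\}) / (B + 1).
#'
#' @param genes gene set.
#' @param ppi a [ppi_edge_list()].
#' @param B number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list: observed, expected, p, n_in_network, B, null quantiles.
#' @export
ppi_enrichment <- function(genes, ppi, B = 10000, seed = 1L) {
  stopifnot(B >= 100)
  nodes <- unique(c(ppi$a, ppi$b))
  in_net <- intersect(unique(genes), nodes)
  if (nrow(ppi) == 0)
    return(list(observed = 0L, expected = 0, p = 1,
                n_in_network = length(in_net), B = B,
                null_quantiles = c(`50%` = 0, `95%` = 0, `99%` = 0)))
  if (length(in_net) < 2)
    stop("fewer than 2 query genes present in the PPI network")
  count_edges <- function(set) sum(ppi$a %in% set & ppi$b %in% set)
  obs <- count_edges(in_net)
  set.seed(seed)
  null <- replicate(B, count_edges(sample(nodes, length(in_net))))
  list(observed = obs, expected = mean(null),
       p = (1 + sum(null >= obs)) / (B + 1),
       n_in_network = length(in_net), B = B,
       null_quantiles = quantile(null, c(0.5, 0.95, 0.99)))
}

#' Location-scale batch adjustment
#'
#' Per probe and batch, centers and scales the values, then restores the
#' probe's pooled mean and sd. A simple stand-in for empirical-Bayes batch
#' correction; it removes additive and multiplicative batch effects but
#' does not shrink across probes.
#'
#' @param expr an [expression_matrix()].
#' @param batch named batch labels over the samples (>= 2 per batch).
#' @return adjusted [expression_matrix()].
#' @export
batch_adjust <- function(expr, batch) {
  x <- expr$values
  batch <- batch[colnames(x)]
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  pooled_mean <- rowMeans(x)
  pooled_sd <- apply(x, 1, sd)
  out <- x
  for (b in unique(batch)) {
    cols <- which(batch == b)
    m <- rowMeans(x[, cols, drop = FALSE])
    s <- apply(x[, cols, drop = FALSE], 1, sd)
    s[s == 0] <- 1
    out[, cols] <- (x[, cols, drop = FALSE] - m) / s
  }
  out <- out * pooled_sd + pooled_mean
  expr$values <- out
  expr
}

#' Per-probe Welch t-test of differential expression between stages
#'
#' BH adjustment across probes; a probe is flagged at q < 0.05.
#' Constant probes (zero variance in both groups) get NA statistics.
#'
#' @param expr an [expression_matrix()].
#' @param stage_binary named 0/1 vector over the samples (>= 2 per group).
#' @param fdr cutoff for the DE flag.
#' @return data.frame: probe_id, t, p, q, de.
#' @export
stage_de <- function(expr, stage_binary, fdr = 0.05) {
  x <- expr$values
  st <- stage_binary[colnames(x)]
  g0 <- which(st == 0); g1 <- which(st == 1)
  if (length(g0) < 2 || length(g1) < 2)
    stop("each stage group needs >= 2 samples")
  m0 <- rowMeans(x[, g0, drop = FALSE]); m1 <- rowMeans(x[, g1, drop = FALSE])
  v0 <- apply(x[, g0, drop = FALSE], 1, stats::var)
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  n0 <- length(g0); n1 <- length(g1)
  se2 <- v0 / n0 + v1 / n1
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  tstat[degenerate] <- NA; p[degenerate] <- NA
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  data.frame(probe_id = rownames(x), t = tstat, p = p, q = q,
             de = !is.na(q) & q < fdr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Connectivity (kME) shift of differentially expressed probes
#'
#' Two-sided Wilcoxon rank-sum test of kME among DE-flagged probes versus
#' the remaining probes, plus a permutation background: B random
#' relabelings of the flag vector give the null distribution of the
#' mean-kME difference and an empirical two-sided p.
#'
#' @param kme named kME vector.
#' @param de_flags logical vector aligned to `kme`.
#' @param B permutations (default 10000).
#' @param seed RNG seed.
#' @return list: wilcoxon_stat, wilcoxon_p, observed_diff, perm_p, B,
#'   null_quantiles.
#' @export
connectivity_shift <- function(kme, de_flags, B = 10000, seed = 1L) {
  stopifnot(length(kme) == length(de_flags))
  if (!any(de_flags) || all(de_flags))
    stop("need at least one flagged and one unflagged probe")
  wt <- wilcox.test(kme[de_flags], kme[!de_flags], exact = FALSE)
  obs <- mean(kme[de_flags]) - mean(kme[!de_flags])
  set.seed(seed)
  nf <- sum(de_flags)
  null <- replicate(B, {
    idx <- sample(length(kme), nf)
    mean(kme[idx]) - mean(kme[-idx])
  })
  list(wilcoxon_stat = unname(wt$statistic), wilcoxon_p = wt$p.value,
       observed_diff = obs,
       perm_p = (1 + sum(abs(null) >= abs(obs))) / (B + 1),
       B = B, null_quantiles = quantile(null, c(0.025, 0.5, 0.975)))
}
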