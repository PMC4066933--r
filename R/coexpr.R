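# Weighted co-expression network: soft-threshold adjacency, scale-free
# topology fit, topological overlap, module detection, eigengenes and the
# per-probe module statistics kIN / kME / GS.

#' Soft-threshold adjacency matrix
#'
#' a_ij = |cor(x_i, x_j)|^beta with unit diagonal. Pearson correlation by
#' default (the usual convention for the adjacency); Spearman available.
#'
#' @param expr an [expression_matrix()] with no missing values, >= 3 samples.
#' @param beta soft-thresholding power (default 6).
#' @param cor_method "pearson" or "spearman".
#' @return list of class `coexpr_network` with `adjacency`, `beta`,
#'   `probe_ids`, `cor_method`.
#' @export
adjacency <- function(expr, beta = 6, cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  x <- expr$values
  stopifnot(ncol(x) >= 3, !anyNA(x))
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    stop("zero-variance probe: ", rownames(x)[sds == 0][1])
  a <- abs(cor(t(x), method = cor_method))^beta
  diag(a) <- 1
  structure(list(adjacency = a, beta = beta, probe_ids = rownames(x),
                 cor_method = cor_method),
            class = "coexpr_network")
}

#' Whole-network connectivity per probe
#'
#' k_i = sum over j != i of a_ij.
#' @param network a `coexpr_network` (or plain adjacency matrix).
#' @return named numeric vector.
#' @export
connectivity <- function(network) {
  a <- if (inherits(network, "coexpr_network")) network$adjacency else network
  rowSums(a) - diag(a)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Connectivity values are binned into `n_bins` equal-width intervals
#' spanning [min k, max k] (equal-count binning optional); each non-empty
#' bin contributes its mean connectivity k and empirical probability
#' p(k) = count / total. The fit regresses log10 p(k) on log10 k: under
#' approximate scale-free topology the two are strongly negatively
#' correlated.
#'
#' @param k numeric vector of connectivity values (positive).
#' @param n_bins number of bins (default 10).
#' @param binning "width" (equal-width, default) or "count" (equal-count).
#' @return list of class `scale_free_fit`: `bins` (data.frame k, p_k,
#'   count), `r_squared`, `pearson_cor`, `slope`, `n_bins`.
#' @export
scale_free_fit <- function(k, n_bins = 10, binning = c("width", "count")) {
  binning <- match.arg(binning)
  k <- k[is.finite(k)]
  if (length(unique(k)) < n_bins)
    stop("need at least n_bins distinct connectivity values")
  if (max(k) == min(k)) stop("all connectivity values identical")
  if (binning == "width") {
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    idx <- findInterval(k, br, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    idx <- ceiling(rank(k, ties.method = "first") / (length(k) / n_bins))
    idx <- pmin(pmax(idx, 1L), n_bins)
  }
  counts <- tabulate(idx, nbins = n_bins)
  nonempty <- which(counts > 0)
  if (length(nonempty) < 3) stop("fewer than 3 non-empty bins")
  kbar <- vapply(nonempty, function(b) mean(k[idx == b]), numeric(1))
  pk <- counts[nonempty] / length(k)
  if (any(kbar <= 0)) stop("non-positive bin mean connectivity")
  fit <- lm(log10(pk) ~ log10(kbar))
  r <- cor(log10(kbar), log10(pk))
  structure(list(bins = data.frame(k = kbar, p_k = pk,
                                   count = counts[nonempty]),
                 r_squared = r^2, pearson_cor = r,
                 slope = unname(coef(fit)[2]), n_bins = n_bins),
            class = "scale_free_fit")
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' TOM_ii = 1; the u-sum excludes i and j.
#'
#' @param network a `coexpr_network` or adjacency matrix.
#' @return symmetric TOM matrix in [0, 1].
#' @export
tom_similarity <- function(network) {
  a <- if (inherits(network, "coexpr_network")) network$adjacency else network
  diag(a) <- 0
  l <- a %*% a              # includes u = i and u = j terms only via zeros
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' static tree cut at `cut_height`, clusters smaller than `min_module_size`
#' relabelled "unassigned", then iterative merging of modules whose
#' eigengenes correlate above `merge_threshold`. Final labels "M1", "M2", ...
#' are ordered by decreasing module size.
#'
#' @param tom TOM matrix.
#' @param expr the [expression_matrix()] the TOM came from (needed for
#'   eigengene-based merging); may be NULL to skip merging.
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height static cut height on 1 - TOM (default 0.995).
#' @param merge_threshold eigengene correlation above which modules merge
#'   (default 0.75).
#' @return named character vector probe_id -> module label.
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           cut_height = 0.995, merge_threshold = 0.75) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  labels <- rep("unassigned", nrow(tom))
  names(labels) <- rownames(tom)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  for (i in seq_along(keep)) labels[cl == as.integer(keep[i])] <-
    paste0("tmp", i)
  # iterative eigengene merge
  if (!is.null(expr) && length(keep) >= 2) {
    repeat {
      mods <- setdiff(unique(labels), "unassigned")
      if (length(mods) < 2) break
      mes <- vapply(mods, function(m)
        module_eigengene(expr, names(labels)[labels == m])$me,
        numeric(ncol(expr$values)))
      cc <- cor(mes)
      diag(cc) <- -Inf
      mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[mx[1], mx[2]] <= merge_threshold) break
      labels[labels == mods[mx[2]]] <- mods[mx[1]]
    }
  }
  mods <- setdiff(unique(labels), "unassigned")
  ord <- mods[order(-vapply(mods, function(m) sum(labels == m), numeric(1)),
                    mods)]
  final <- labels
  for (i in seq_along(ord)) final[labels == ord[i]] <- paste0("M", i)
  final
}

#' Module eigengene (first principal component) of a probe set
#'
#' Member probes are standardized across samples; the eigengene is the first
#' right-singular direction over samples, rescaled to unit variance and
#' sign-aligned so that it correlates non-negatively with the mean
#' standardized module expression. The second component is returned the same
#' way.
#'
#' @param expr an [expression_matrix()].
#' @param member_probes probe ids of the module (>= 2).
#' @return list with `me`, `pc2` (named numeric over samples),
#'   `var_explained` (first two proportions).
#' @export
module_eigengene <- function(expr, member_probes) {
  x <- expr$values[member_probes, , drop = FALSE]
  stopifnot(nrow(x) >= 2, ncol(x) >= 3)
  xs <- t(scale(t(x)))           # standardize each probe
  if (anyNA(xs)) stop("zero-variance probe in module")
  sv <- svd(xs)
  if (sv$d[1] == 0) stop("rank-0 module")
  align <- function(v) {
    r <- sum(v * colMeans(xs))
    if (r < 0) -v else if (r == 0 && v[which.max(abs(v))] < 0) -v else v
  }
  unitvar <- function(v) {
    s <- sd(v)
    if (s == 0) v else v / s
  }
  me <- unitvar(align(sv$v[, 1]))
  pc2 <- if (length(sv$d) >= 2 && sv$d[2] > 0)
    unitvar(align(sv$v[, 2])) else rep(0, ncol(xs))
  names(me) <- names(pc2) <- colnames(x)
  list(me = me, pc2 = pc2,
       var_explained = (sv$d^2 / sum(sv$d^2))[1:2])
}

#' Spearman correlations between module eigengenes and phenotype traits
#'
#' @param eigengenes named list module -> eigengene vector (samples named).
#' @param pheno a [phenotype_table()]; every numeric column except
#'   sample_id is treated as a trait.
#' @param traits optional character vector restricting the traits used.
#' @return data.frame (module, trait, rho, p); constant traits are reported
#'   with NA rho/p.
#' @export
module_trait_correlations <- function(eigengenes, pheno, traits = NULL) {
  tcols <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                   "sample_id")
  if (!is.null(traits)) tcols <- intersect(tcols, traits)
  out <- list()
  for (m in names(eigengenes)) {
    me <- eigengenes[[m]]
    ids <- intersect(names(me), pheno$sample_id)
    if (length(ids) < 4) stop("fewer than 4 shared samples for module ", m)
    for (tr in tcols) {
      v <- pheno[[tr]][match(ids, pheno$sample_id)]
      ok <- !is.na(v)
      if (sum(ok) < 4 || length(unique(v[ok])) < 2) {
        out[[length(out) + 1]] <- data.frame(module = m, trait = tr,
                                             rho = NA_real_, p = NA_real_)
        next
      }
      ct <- suppressWarnings(cor.test(me[ids][ok], v[ok],
                                      method = "spearman", exact = FALSE))
      out[[length(out) + 1]] <- data.frame(module = m, trait = tr,
                                           rho = unname(ct$estimate),
                                           p = ct$p.value)
    }
  }
  do.call(rbind, out)
}

#' Per-probe module statistics: kIN, kME, GS and expression sd
#'
#' kIN is the sum of absolute Spearman correlations of a probe with all
#' other module probes (self excluded); kME (module membership) is the
#' Spearman correlation of the probe with the module eigengene; GS (gene
#' significance) is the Spearman correlation of the probe with each trait.
#' Average ranks are used for ties.
#'
#' @param expr an [expression_matrix()].
#' @param member_probes module probe ids.
#' @param me module eigengene (named over samples).
#' @param traits data.frame of per-sample traits (rows aligned to the
#'   expression samples) or NULL.
#' @return data.frame of class `module_profile`: probe_id, kIN, kME, sd and
#'   one `GS_<trait>` column per trait.
#' @export
module_profile <- function(expr, member_probes, me, traits = NULL) {
  x <- expr$values[member_probes, , drop = FALSE]
  sc <- cor(t(x), method = "spearman")
  kin <- rowSums(abs(sc)) - 1
  kme <- as.numeric(cor(t(x), me[colnames(x)], method = "spearman"))
  out <- data.frame(probe_id = member_probes, kIN = kin, kME = kme,
                    sd = apply(x, 1, sd), stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    for (tr in names(traits)) {
      v <- traits[[tr]]
      out[[paste0("GS_", tr)]] <- suppressWarnings(
        as.numeric(cor(t(x), v, method = "spearman",
                       use = "pairwise.complete.obs")))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("module_profile", "data.frame")
  out
}
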