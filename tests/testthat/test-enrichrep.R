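test_that("hypergeometric enrichment matches the brute-force tail on the fixed example", {
  universe <- paste0("g", 1:20)
  sets <- structure(list(T1 = list(description = "term",
                                   genes = paste0("g", 1:5))),
                    class = "gene_set_collection")
  query <- c("g1", "g2", "g3", "g6", "g7")  # overlap x = 3
  out <- hypergeom_enrichment(query, sets, universe,
                              fdr_threshold = 0.05, coverage_min = 0)
  expect_equal(out$x, 3)
  expect_equal(out$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(out$p, brute_hyper_tail(20, 5, 5, 3), tolerance = 1e-12)

  # degenerate certainty and zero overlap both give p = 1
  out2 <- hypergeom_enrichment(universe,
                               structure(list(ALL = list(description = "",
                                                         genes = universe)),
                                         class = "gene_set_collection"),
                               universe, 0.05, 0)
  expect_equal(out2$p, 1)
  sets0 <- structure(list(T0 = list(description = "",
                                    genes = paste0("g", 15:20))),
                     class = "gene_set_collection")
  out3 <- hypergeom_enrichment(paste0("g", 1:5), sets0, universe, 0.05, 0)
  expect_equal(out3$p, brute_hyper_tail(20, 6, 5, out3$x), tolerance = 1e-12)
})

test_that("enrichment agrees with exhaustive enumeration on small universes", {
  set.seed(202)
  for (i in 1:20) {
    N <- sample(8:15, 1)
    universe <- paste0("u", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    term <- sample(universe, K)
    query <- sample(universe, n)
    sets <- structure(list(T = list(description = "", genes = term)),
                      class = "gene_set_collection")
    out <- hypergeom_enrichment(query, sets, universe, 0.05, 0)
    expect_equal(out$p, brute_hyper_tail(N, K, n, out$x), tolerance = 1e-12)
  }
})

test_that("coverage and FDR filters gate the pass flag", {
  universe <- paste0("g", 1:100)
  sets <- structure(list(
    big_hit = list(description = "", genes = paste0("g", 1:10)),
    tiny = list(description = "", genes = paste0("g", c(1, 99))),
    miss = list(description = "", genes = paste0("g", 90:99))),
    class = "gene_set_collection")
  query <- paste0("g", 1:10)
  out <- hypergeom_enrichment(query, sets, universe,
                              fdr_threshold = 0.001, coverage_min = 0.10)
  expect_true(out$pass[out$term == "big_hit"])
  expect_false(out$pass[out$term == "miss"])
  # the same strong term fails when coverage demands half the query
  out2 <- hypergeom_enrichment(query, sets, universe, 0.001,
                               coverage_min = 0.5)
  expect_true(out2$pass[out2$term == "big_hit"])
  out3 <- hypergeom_enrichment(query, sets["tiny"], universe, 0.001, 0.5)
  expect_false(out3$pass[1])
  expect_error(hypergeom_enrichment("absent", sets, universe, 0.05, 0),
               "universe")
})

test_that("BH adjustment matches the step-up construction and stays monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.5, 4)), rep(0.5, 4))
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("PPI permutation enrichment detects a planted clique and matches the ER closed form", {
  set.seed(303)
  nodes <- paste0("n", 1:60)
  # sparse random background + a 6-clique
  bg <- t(combn(nodes, 2))
  keep <- runif(nrow(bg)) < 0.03
  clique <- t(combn(paste0("n", 1:6), 2))
  ppi <- ppi_edge_list(c(bg[keep, 1], clique[, 1]),
                       c(bg[keep, 2], clique[, 2]))
  res <- ppi_enrichment(paste0("n", 1:6), ppi, B = 999, seed = 5)
  expect_equal(res$p, 1 / 1000, tolerance = 1e-12)
  expect_gt(res$observed, res$expected)

  # Erdos-Renyi: expected in-set edges ~ C(m,2) * density
  dens <- 0.15
  er <- t(combn(nodes, 2))
  sel <- runif(nrow(er)) < dens
  ppi2 <- ppi_edge_list(er[sel, 1], er[sel, 2])
  true_dens <- nrow(ppi2) / choose(60, 2)
  res2 <- ppi_enrichment(sample(nodes, 10), ppi2, B = 3000, seed = 7)
  expect_equal(res2$expected, choose(10, 2) * true_dens, tolerance = 0.1)
  expect_gte(res2$p, 1 / 3001)

  empty <- ppi_edge_list(character(0), character(0))
  res3 <- ppi_enrichment(c("a", "b"), empty, B = 100, seed = 1)
  expect_equal(res3$observed, 0)
  expect_equal(res3$p, 1)
})

test_that("batch adjustment removes location/scale offsets but keeps correlation structure", {
  p <- sim_params(seed = 51, n_snps = 10, n_probes = 150, module_size = 50,
                  n_batches = 2, batch_location = c(0, 5),
                  batch_scale = c(1, 1.5), de_effect = 0,
                  rep_n_samples = 80)
  co <- simulate_cohort(p)
  r <- simulate_replication(p, co$truth)
  adj <- batch_adjust(r$expr, r$batch)
  m1 <- rowMeans(adj$values[, r$batch == 1])
  m2 <- rowMeans(adj$values[, r$batch == 2])
  expect_lt(max(abs(m1 - m2)), 0.8)
  expect_lt(abs(mean(m1 - m2)), 0.05)

  # module structure survives: kME ranks stable pre/post adjustment
  co2 <- simulate_cohort(sim_params(seed = 52, n_samples = 80, n_snps = 10,
                                    n_probes = 100, module_size = 40,
                                    residual_sd = 0.7))
  batch2 <- setNames(rep(1:2, length.out = 80),
                     colnames(co2$expr$values))
  shifted <- co2$expr
  shifted$values[, batch2 == 2] <- shifted$values[, batch2 == 2] * 1.4 + 3
  adj2 <- batch_adjust(shifted, batch2)
  eg_pre <- module_eigengene(co2$expr, co2$truth$module_probes)
  eg_post <- module_eigengene(adj2, co2$truth$module_probes)
  kme_pre <- module_profile(co2$expr, co2$truth$module_probes, eg_pre$me)$kME
  kme_post <- module_profile(adj2, co2$truth$module_probes, eg_post$me)$kME
  expect_gte(cor(kme_pre, kme_post, method = "spearman"), 0.9)

  expect_error(batch_adjust(co2$expr,
                            setNames(c(1, rep(2, 79)),
                                     colnames(co2$expr$values))),
               ">= 2 samples")
})

test_that("stage DE is calibrated under the null and powerful at a 2-sd shift", {
  set.seed(61)
  n <- 60
  x <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("p%04d", 1:1000), paste0("s", 1:n)))
  st <- setNames(rep(c(0, 1), each = n / 2), colnames(x))
  de <- stage_de(expression_matrix(x), st)
  expect_lte(mean(de$de), 0.07)
  expect_lte(mean(de$p < 0.05), 0.07)

  x2 <- matrix(rnorm(300 * 100), 300, 100,
               dimnames = list(sprintf("q%04d", 1:300), paste0("s", 1:100)))
  st2 <- setNames(rep(c(0, 1), each = 50), colnames(x2))
  x2[1:60, st2 == 1] <- x2[1:60, st2 == 1] + 2
  de2 <- stage_de(expression_matrix(x2), st2)
  expect_gte(mean(de2$de[1:60]), 0.8)

  xc <- rbind(x2, const = rep(1, 100))
  dec <- stage_de(expression_matrix(xc), st2)
  expect_true(is.na(dec$p[dec$probe_id == "const"]))
})

test_that("connectivity shift detects kME separation and the permutation p agrees", {
  set.seed(71)
  kme <- runif(200)
  names(kme) <- sprintf("p%03d", 1:200)
  flags_top <- kme >= median(kme)
  res <- connectivity_shift(kme, flags_top, B = 2000, seed = 3)
  expect_lt(res$wilcoxon_p, 1e-10)
  expect_equal(res$perm_p, 1 / 2001, tolerance = 1e-12)

  # null flags: both tests calibrated and mostly concordant at alpha 0.05
  agree <- 0
  pvals <- numeric(60)
  for (i in 1:60) {
    fl <- sample(c(rep(TRUE, 40), rep(FALSE, 160)))
    r <- connectivity_shift(kme, fl, B = 400, seed = i)
    pvals[i] <- r$wilcoxon_p
    agree <- agree + ((r$wilcoxon_p < 0.05) == (r$perm_p < 0.05))
  }
  expect_gte(agree / 60, 0.9)
  expect_gt(mean(pvals > 0.05), 0.85)
  expect_error(connectivity_shift(kme, rep(TRUE, 200), B = 100),
               "flagged")
})
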