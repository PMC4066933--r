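test_that("soft-threshold adjacency follows |cor|^beta with unit diagonal", {
  s <- seq_len(10)
  x <- rbind(p1 = s, p2 = 11 - s,                  # cor -1
             p3 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
             p4 = rnorm(10))
  colnames(x) <- paste0("s", s)
  net <- adjacency(expression_matrix(x), beta = 6)
  expect_equal(unname(diag(net$adjacency)), rep(1, 4))
  expect_equal(net$adjacency["p1", "p2"], 1)
  r <- cor(x["p1", ], x["p3", ])
  expect_equal(net$adjacency["p1", "p3"], abs(r)^6)
  expect_true(isSymmetric(net$adjacency))

  # hand value: |cor| = 0.86 -> 0.86^6 ~ 0.4046
  expect_equal(abs(-0.86)^6, 0.4046, tolerance = 1e-4)

  x0 <- rbind(x, p5 = rep(1, 10))
  expect_error(adjacency(expression_matrix(x0)), "p5")
})

test_that("connectivity sums off-diagonal adjacency", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(connectivity(a)), rep(1, 3))
})

test_that("scale-free fit recovers a planted power law and flags degenerate input", {
  # construct k values whose bin counts follow p(k) ~ k^-1.5 at bin means
  centers <- seq(5, 95, by = 10)
  counts <- round(1000 * centers^-1.5 / sum(centers^-1.5))
  k <- rep(centers, counts)
  k <- k + runif(length(k), -1e-6, 1e-6)  # make values distinct
  fit <- scale_free_fit(k, n_bins = 10)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$slope, -1.5, tolerance = 0.01)
  expect_equal(fit$r_squared, fit$pearson_cor^2, tolerance = 1e-12)
  expect_lt(fit$pearson_cor, 0)
  expect_equal(sum(fit$bins$p_k), 1, tolerance = 1e-12)

  set.seed(4)
  ku <- runif(500, 1, 100)
  fitu <- scale_free_fit(ku, 10)
  expect_lt(fitu$r_squared, 0.5)
  expect_error(scale_free_fit(rep(2, 50)), "distinct")
})

test_that("TOM matches the brute-force double loop and hits its bounds", {
  set.seed(8)
  for (i in 1:5) {
    a <- matrix(runif(25), 5)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(unname(tom_similarity(a)), brute_tom(a), tolerance = 1e-12)
  }
  # isolated pair with no shared neighbors
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 0
  a[3, 4] <- a[4, 3] <- 0.9
  expect_equal(tom_similarity(a)[1, 2], 0)
  # identical rows fully connected
  a1 <- matrix(1, 3, 3)
  expect_true(all(tom_similarity(a1) == 1))
})

test_that("module detection recovers planted blocks, merges duplicates, leaves noise unassigned", {
  set.seed(15)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, m, sd) t(sapply(seq_len(m), function(i)
    f + rnorm(n, sd = sd)))
  x <- rbind(block(f1, 40, 0.7), block(f2, 40, 0.7),
             matrix(rnorm(40 * n), 40))
  dimnames(x) <- list(sprintf("p%03d", 1:120), sprintf("s%02d", 1:n))
  e <- expression_matrix(x)
  net <- adjacency(e, beta = 6)
  tom <- tom_similarity(net)
  lab <- detect_modules(tom, e, min_module_size = 20, cut_height = 0.995,
                        merge_threshold = 0.75)
  truth1 <- sprintf("p%03d", 1:40)
  truth2 <- sprintf("p%03d", 41:80)
  mods <- setdiff(unique(lab), "unassigned")
  expect_equal(length(mods), 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  m_of <- function(truth) names(which.max(table(lab[truth])))
  expect_gte(jac(names(lab)[lab == m_of(truth1)], truth1), 0.95)
  expect_gte(jac(names(lab)[lab == m_of(truth2)], truth2), 0.95)
  # the permissive default cut can absorb an occasional noise probe that
  # correlates with a block factor by chance; the bulk stays unassigned
  expect_gte(mean(lab[sprintf("p%03d", 81:120)] == "unassigned"), 0.9)

  # two perfectly correlated halves of one block merge into one module
  xx <- rbind(block(f1, 25, 0.3), block(f1, 25, 0.3))
  dimnames(xx) <- list(sprintf("q%03d", 1:50), sprintf("s%02d", 1:n))
  ee <- expression_matrix(xx)
  labm <- detect_modules(tom_similarity(adjacency(ee, 6)), ee,
                         min_module_size = 20)
  expect_equal(length(setdiff(unique(labm), "unassigned")), 1)

  # pure noise: everything unassigned
  xn <- matrix(rnorm(80 * n), 80)
  dimnames(xn) <- list(sprintf("r%03d", 1:80), sprintf("s%02d", 1:n))
  en <- expression_matrix(xn)
  labn <- detect_modules(tom_similarity(adjacency(en, 6)), en,
                         min_module_size = 30)
  expect_true(all(labn == "unassigned"))
})

test_that("module eigengene is the standardized probe for a rank-1 module and is sign-stable", {
  n <- 20
  base <- rnorm(n)
  x <- rbind(p1 = 2 * base + 3, p2 = -base, p3 = base * 0.5)
  colnames(x) <- paste0("s", 1:n)
  e <- expression_matrix(x)
  eg <- module_eigengene(e, c("p1", "p3"))
  zs <- as.numeric(scale(base))
  expect_equal(unname(eg$me), zs, tolerance = 1e-8)
  expect_gte(cor(eg$me, colMeans(t(scale(t(x[c("p1", "p3"), ]))))), 0)

  # flipping every probe flips the mean module expression, so the
  # sign-anchored eigengene flips with it; the summary is unchanged up to
  # that sign and flipping a single probe of a larger module leaves it be
  e2 <- e; e2$values <- -e2$values
  eg2 <- module_eigengene(e2, c("p1", "p3"))
  expect_equal(unname(eg2$me), -unname(eg$me), tolerance = 1e-8)
  e3 <- e; e3$values["p3", ] <- -e3$values["p3", ]
  eg3 <- module_eigengene(e3, c("p1", "p2", "p3"))
  expect_equal(abs(cor(eg3$me, module_eigengene(e, c("p1", "p2", "p3"))$me)),
               1, tolerance = 1e-8)

  # planted factor: eigengene tracks the latent factor
  co <- small_cohort(seed = 19, n_samples = 100, n_snps = 20, n_probes = 80,
                     module_size = 30, residual_sd = 0.1)
  egf <- module_eigengene(co$expr, co$truth$module_probes)
  expect_gte(abs(cor(egf$me, co$truth$factor)), 0.99)
})

test_that("module-trait correlations handle exact, noisy and constant traits", {
  set.seed(22)
  n <- 40
  me <- rnorm(n)
  names(me) <- sprintf("S%03d", 1:n)
  ph <- phenotype_table(data.frame(
    sample_id = names(me),
    who_grade = sample(1:3, n, replace = TRUE)))
  ph$exact <- rank(me)
  ph$noise <- rnorm(n)
  ph$const <- 1
  mt <- module_trait_correlations(list(M1 = me), ph)
  expect_equal(mt$rho[mt$trait == "exact"], 1)
  expect_lt(abs(mt$rho[mt$trait == "noise"]), 0.4)
  expect_true(is.na(mt$rho[mt$trait == "const"]))
})

test_that("module profile computes kIN, kME and GS as Spearman statistics", {
  n <- 15
  s <- seq_len(n)
  x <- rbind(p1 = s, p2 = s^3, p3 = rev(s))   # perfectly rank-correlated
  colnames(x) <- paste0("s", s)
  e <- expression_matrix(x)
  me <- as.numeric(scale(s)); names(me) <- colnames(x)
  traits <- data.frame(grade = s)  # strictly increasing in the probe
  pr <- module_profile(e, c("p1", "p2", "p3"), me, traits)
  expect_equal(pr$kIN, rep(2, 3))          # |rho| = 1 with both others
  expect_equal(pr$kME, c(1, 1, -1))
  expect_equal(pr$GS_grade, c(1, 1, -1))
  expect_equal(pr$sd[1], sd(s))
})

test_that("planted loadings induce the kME^6 ~ kIN relation and the sd/kIN trend", {
  co <- small_cohort(seed = 27, n_samples = 150, n_snps = 20, n_probes = 150,
                     module_size = 100, residual_sd = 1)
  eg <- module_eigengene(co$expr, co$truth$module_probes)
  pr <- module_profile(co$expr, co$truth$module_probes, eg$me)
  expect_gte(cor(pr$kME^6, pr$kIN, method = "spearman"), 0.8)

  # variability vs connectivity: with heterogeneous residual noise (the
  # regime real arrays live in), noisy probes are both more variable and
  # less connected, so low-kIN probes have the higher sd
  set.seed(28)
  n <- 150
  f <- rnorm(n)
  sig <- runif(100, 0.5, 2)
  xh <- t(sapply(sig, function(s) f + rnorm(n, sd = s)))
  dimnames(xh) <- list(sprintf("h%03d", 1:100), sprintf("s%03d", 1:n))
  eh <- expression_matrix(xh)
  egh <- module_eigengene(eh, rownames(xh))
  prh <- module_profile(eh, rownames(xh), egh$me)
  lo <- prh$sd[prh$kIN < median(prh$kIN)]
  hi <- prh$sd[prh$kIN >= median(prh$kIN)]
  expect_gt(mean(lo), mean(hi))
})
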