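test_that("GSmQTL columns are probe-SNP Spearman correlations with pairwise NA handling", {
  set.seed(101)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  x <- rbind(exact = g,                       # probe equal to the genotype
             noise = rnorm(n))
  colnames(x) <- paste0("s", 1:n)
  geno <- genotype_matrix(matrix(g, n, 1,
                                 dimnames = list(colnames(x), "snp1")))
  gm <- gsmqtl_matrix(x, geno, "snp1")
  expect_equal(gm["exact", "snp1"], 1)
  expect_lt(abs(gm["noise", "snp1"]), 0.4)

  gmiss <- geno
  gmiss$calls[1, 1] <- NA
  gm2 <- gsmqtl_matrix(x, gmiss, "snp1")
  expect_equal(gm2["noise", "snp1"],
               suppressWarnings(cor(x["noise", -1], g[-1],
                                    method = "spearman")))

  gmono <- geno; gmono$calls[, 1] <- 1
  expect_error(gsmqtl_matrix(x, gmono, "snp1"), "monomorphic")
})

test_that("rank inverse-normal transform matches normal quantiles and is rank-invariant", {
  z <- rank_inverse_normal(c(10, 3, 7, 5))
  expect_equal(sort(z), qnorm(c(0.125, 0.375, 0.625, 0.875)),
               tolerance = 1e-12)
  expect_equal(sort(round(z, 4)), c(-1.1503, -0.3186, 0.3186, 1.1503))
  expect_equal(mean(z), 0, tolerance = 1e-12)

  x <- rexp(50)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(log(x)))
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(x^3))
  expect_error(rank_inverse_normal(rep(1, 5)), "constant")

  # heavy-tailed input becomes acceptably normal
  set.seed(5)
  ok <- mean(replicate(40, {
    shapiro.test(rank_inverse_normal(rexp(1000)))$p.value > 0.01
  }))
  expect_gte(ok, 0.95)
})

test_that("fit_linear reports OLS coefficients, the VIF identity and aliasing errors", {
  set.seed(7)
  n <- 100
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  X <- as.data.frame(scale(X))
  y <- 2 * X$x1 - 1.5 * X$x2 + rnorm(n, sd = 0.01)
  rep_ <- fit_linear(y, X)
  expect_equal(rep_$coefficients["x1", "estimate"], 2, tolerance = 0.01)
  expect_equal(rep_$coefficients["x2", "estimate"], -1.5, tolerance = 0.01)
  expect_equal(rep_$model_vif, 1 / (1 - rep_$r_squared), tolerance = 1e-12)
  expect_lte(rep_$adj_r_squared, rep_$r_squared)

  # exact linear response
  y2 <- 3 + X$x1
  r2 <- suppressWarnings(fit_linear(y2, X["x1"]))  # perfect fit warns
  expect_equal(r2$r_squared, 1)
  expect_equal(unname(r2$residuals), rep(0, n), tolerance = 1e-10)

  Xa <- data.frame(a = X$x1, b = X$x1)
  expect_error(fit_linear(y, Xa), "aliased")
})

test_that("a single-regressor fit with R2 = 0.51 yields model VIF 2.04", {
  n <- 100
  x <- as.numeric(scale(seq_len(n)))
  e <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))
  y <- sqrt(0.51) * x + sqrt(0.49) * e   # R2 exactly 0.51 by construction
  rep_ <- fit_linear(y, data.frame(kME = x))
  expect_equal(rep_$r_squared, 0.51, tolerance = 1e-12)
  expect_equal(round(rep_$model_vif, 2), 2.04)
})

test_that("stepwise AIC keeps true predictors, limits noise, never worsens AIC", {
  set.seed(11)
  kept_true <- 0; noise_in <- 0
  for (i in 1:60) {
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("x", 1:5))))
    y <- 2 * X$x1 + rnorm(n, sd = 0.5)
    sel <- stepwise_aic(y, X)
    if ("x1" %in% sel$selected) kept_true <- kept_true + 1
    noise_in <- noise_in + length(setdiff(sel$selected, "x1"))
    full_aic <- fit_linear(y, X)$aic
    null_aic <- fit_linear(y, X[, 0, drop = FALSE])$aic
    expect_lte(sel$aic, full_aic + 1e-9)
    expect_lte(sel$aic, null_aic + 1e-9)
  }
  expect_equal(kept_true, 60)
  # AIC admits each null predictor with prob P(chi2_1 > 2) ~ 0.157, so on
  # average ~0.6 of the 4 noise columns slip in; far fewer than all of them
  expect_lt(noise_in / 60, 1.2)

  # pure-noise response collapses to the intercept-only model in the
  # majority of runs (each of 3 null candidates enters with prob ~0.157)
  set.seed(12)
  empty <- mean(replicate(50, {
    X <- as.data.frame(matrix(rnorm(80 * 3), 80,
                              dimnames = list(NULL, paste0("x", 1:3))))
    length(stepwise_aic(rnorm(80), X)$selected) == 0
  }))
  expect_gt(empty, 0.5)

  X <- data.frame(a = rnorm(50))
  X$b <- X$a
  expect_error(stepwise_aic(rnorm(50), X), "aliased")
})

test_that("risk/protective aggregation splits by sign and is coding-invariant", {
  set.seed(13)
  n <- 200
  gsm <- cbind(snpA = rnorm(n), snpB = rnorm(n), snpC = rnorm(n))
  rownames(gsm) <- paste0("p", 1:n)
  y <- 1.5 * gsm[, "snpA"] - 1.2 * gsm[, "snpB"] + rnorm(n, sd = 0.3)
  step <- stepwise_aic(y, as.data.frame(gsm))
  agg <- aggregate_risk_protective(step, gsm)
  expect_equal(agg$risk_vars, "snpA")
  expect_equal(agg$protective_vars, "snpB")
  expect_equal(unname(agg$risk), unname(gsm[, "snpA"]))
  expect_equal(unname(agg$protective), unname(gsm[, "snpB"]))

  # flipping a genotype coding flips the GSmQTL column sign: the stepwise
  # fit itself is coding-invariant and the column migrates to the other sum
  gsm2 <- gsm; gsm2[, "snpA"] <- -gsm2[, "snpA"]
  colnames(gsm2) <- c("snpA", "snpB", "snpC")
  step2 <- stepwise_aic(y, as.data.frame(gsm2))
  agg2 <- aggregate_risk_protective(step2, gsm2)
  expect_true("snpA" %in% agg2$protective_vars)
  expect_setequal(step2$selected, step$selected)
  expect_equal(step2$r_squared, step$r_squared, tolerance = 1e-12)
  expect_equal(step2$aic, step$aic, tolerance = 1e-9)

  stepn <- stepwise_aic(rnorm(n), as.data.frame(gsm))
  expect_warning(aggregate_risk_protective(stepn, gsm,
                                           p_threshold = 1e-12),
                 "no significant")
})

test_that("final model recovers planted coefficients and satisfies the VIF identity", {
  set.seed(17)
  ok <- 0; total <- 0
  for (i in 1:40) {
    n <- 150
    kme <- rnorm(n); prot <- rnorm(n); risk <- rnorm(n)
    lat <- 0.8 * kme + 0.5 * risk - 0.4 * prot + rnorm(n, sd = 0.5)
    gs <- exp(lat / 2)                # monotone distortion of the latent GS
    f <- final_model(gs, kme, prot, risk)
    cf <- f$coefficients
    est <- cf[c("kME", "GSmQTLProtective", "GSmQTLRisk"), "estimate"]
    se <- cf[c("kME", "GSmQTLProtective", "GSmQTLRisk"), "se"]
    # the rank inverse-normal response is a monotone map of lat; its best
    # linear predictor scales the generating coefficients by the normal-
    # scores slope on lat, computed here directly from the latent truth
    z <- qnorm((rank(gs) - 0.5) / n)
    slope <- sum((z - mean(z)) * (lat - mean(lat))) /
      sum((lat - mean(lat))^2)
    truth <- c(0.8, -0.4, 0.5) * slope
    ok <- ok + sum(abs(est - truth) <= 2 * se)
    total <- total + 3
    expect_equal(f$model_vif, 1 / (1 - f$r_squared), tolerance = 1e-12)
  }
  expect_gte(ok / total, 0.9)

  # constant protective component collapses to a 2-regressor model
  n <- 80
  kme <- rnorm(n); risk <- rnorm(n)
  f2 <- final_model(0.5 * kme + 0.3 * risk + rnorm(n, sd = 0.2),
                    kme, rep(0, n), risk)
  expect_setequal(rownames(f2$coefficients),
                  c("(Intercept)", "kME", "GSmQTLRisk"))
})

test_that("median dichotomization populates the eight groups with the expected ordering", {
  set.seed(19)
  n <- 400
  kme <- rnorm(n); risk <- rnorm(n); prot <- rnorm(n)
  gs <- 0.8 * kme + 0.6 * risk - 0.5 * prot + rnorm(n, sd = 0.4)
  tab <- dichotomize_groups(kme, risk, prot, gs)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$n > 0))
  expect_equal(sum(tab$n), n)
  expect_equal(tab$group[which.max(tab$mean_gs)], "K+R+P-")
  expect_equal(tab$group[which.min(tab$mean_gs)], "K-R-P+")
  expect_warning(dichotomize_groups(kme, rep(1, n), prot, gs),
                 "degenerate")
})
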