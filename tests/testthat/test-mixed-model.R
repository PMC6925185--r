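test_that("backward selection keeps generating covariates, drops noise", {
  # strong planted effects so the signal is unambiguous
  set.seed(61)
  res <- replicate(40, {
    n <- 72
    cov <- simulate_covariates(paste0("s", 1:n))
    y <- 10 * (cov$sex == "M") + 8 * (cov$year - 2015) +
      1.2 * cov$placement_day + rnorm(n, 0, 4)
    ph <- data.frame(onset_day = round(y), cov)
    sel <- select_fixed_effects(ph)
    c(signal = all(c("sex", "year", "placement_day") %in% sel$selected),
      extra = length(setdiff(sel$selected,
                             c("sex", "year", "placement_day"))))
  })
  # generating covariates are always retained; an AIC-guarded drop keeps a
  # spurious term at the chi-square(1) > 2 rate (~16% per term), so demand
  # under one extra term on average and a majority of exact recoveries
  expect_equal(mean(res["signal", ]), 1)
  expect_lt(mean(res["extra", ]), 1)
  expect_gt(mean(res["extra", ] == 0), 0.3)
  # pure noise: near-empty model, adjusted R2 ~ 0
  set.seed(62)
  cov <- simulate_covariates(paste0("s", 1:200))
  ph <- data.frame(onset_day = rnorm(200), cov)
  sel <- select_fixed_effects(ph)
  expect_lt(sel$adj_r2, 0.1)
  # perfectly collinear candidate is reported and dropped
  ph$implant_day <- ph$placement_day - 30
  sel2 <- select_fixed_effects(ph)
  expect_true("placement_day" %in% sel2$dropped_collinear)
})

test_that("REML finds the boundary on noiseless genetic phenotypes", {
  coh <- small_cohort()
  si <- scan_inputs(coh)
  m1 <- trait_model(h2 = 1, var_p = 49)
  covs <- coh$phenotype[si$keep, c("sample", "sex", "year", "placement_day",
                                   "age_class", "mass", "implant_day")]
  p1 <- simulate_phenotype(subset_genotypes(coh$genotypes,
                                            samples = si$keep),
                           coh$kinship_true[si$keep, si$keep], m1,
                           covariates = covs, seed = 63)
  fit <- fit_null_reml(p1$onset_day, si$X, si$GRM)
  expect_gt(fit$h2, 0.85)
  expect_lt(fit$sigma2_e / (fit$sigma2_g + fit$sigma2_e), 0.12)
  # a singular GRM (MZ twins) with a noiseless genetic phenotype forces the
  # residual variance to the boundary, which is flagged
  n <- 40
  set.seed(630)
  phi <- diag(0.5, n)
  phi[1, 2] <- phi[2, 1] <- 0.5  # duplicate pair
  K2 <- make_grm(phi)
  L <- chol(K2 + diag(1e-10, n))
  a <- drop(crossprod(L, rnorm(n)))
  fitb <- fit_null_reml(a, matrix(1, n, 1), K2)
  expect_gt(fitb$h2, 0.999)
  expect_true(fitb$flags[["boundary"]])
  # identity GRM with white noise: unidentifiable, flat likelihood flagged
  n <- 80
  set.seed(64)
  fit0 <- fit_null_reml(rnorm(n), matrix(1, n, 1), diag(n))
  expect_true(any(fit0$flags))
})

test_that("REML recovers a moderate h2 over replicates", {
  # scaled-down recovery check; full n=500 x 200-replicate sweep in the
  # acceptance suite
  n <- 200
  phi <- matrix(0, n, n); diag(phi) <- 0.5
  for (f in 0:39) {
    idx <- f * 4 + 1:4
    phi[idx, idx][phi[idx, idx] == 0] <- 0.25
  }
  GRM <- 2 * phi
  L <- chol(GRM)
  X <- cbind(1, rnorm(n))
  set.seed(65)
  est <- replicate(40, {
    a <- sqrt(0.6) * drop(crossprod(L, rnorm(n)))
    y <- drop(X %*% c(1, 2)) + a + rnorm(n, 0, sqrt(0.4))
    fit_null_reml(y, X, GRM)$h2
  })
  expect_lt(abs(mean(est) - 0.6), 0.08)  # MC SE ~ 0.025 at 40 replicates
})

test_that("Gibbs heritability agrees with REML and reports diagnostics", {
  n <- 150
  phi <- matrix(0, n, n); diag(phi) <- 0.5
  for (f in 0:29) {
    idx <- f * 5 + 1:5
    phi[idx, idx][phi[idx, idx] == 0] <- 0.25
  }
  GRM <- 2 * phi
  set.seed(66)
  L <- chol(GRM)
  X <- cbind(1, rnorm(n))
  a <- sqrt(0.8 * 25) * drop(crossprod(L, rnorm(n)))
  y <- drop(X %*% c(5, 1)) + a + rnorm(n, 0, sqrt(0.2 * 25))
  reml <- fit_null_reml(y, X, GRM)
  post <- mcmc_heritability(y, X, GRM, iters = 20000, burnin = 4000,
                            thin = 10, seed = 67)
  expect_equal(post$mode_h2, reml$h2, tolerance = 0.1)
  expect_true(post$hpd95[1] <= post$mode_h2 &&
                post$mode_h2 <= post$hpd95[2])
  expect_true(all(post$hpd95 >= 0 & post$hpd95 <= 1))
  expect_true(all(post$psrf < 1.1))
  expect_true(all(post$ess > 50))
  # identical chains give a Gelman-Rubin of exactly 1
  post_id <- mcmc_heritability(y, X, GRM, chains = 2, iters = 3000,
                               burnin = 500, thin = 5, seed = 68,
                               identical_chains = TRUE)
  expect_identical(unname(post_id$psrf), rep(1, 3))
})

test_that("score scan: null p uniform, planted effect recovered, skips counted", {
  coh <- small_cohort()
  si <- scan_inputs(coh)
  # permuted phenotype: p-values uniform by Kolmogorov-Smirnov
  set.seed(69)
  fitp <- fit_null_reml(sample(si$y), si$X, si$GRM)
  scp <- assoc_scan(fitp, si$G, maf_min = 0.05)
  expect_gt(stats::ks.test(scp$p, "punif")$p.value, 0.01)
  # planted effect: beta estimate near truth across the cohort's loci
  fit <- fit_null_reml(si$y, si$X, si$GRM)
  sc <- assoc_scan(fit, si$G, maf_min = 0.05)
  ids <- coh$genotypes$variant_meta$id[coh$trait$causal_idx]
  got <- sc[match(ids, sc$id), ]
  expect_true(all(!is.na(got$beta)))
  expect_lt(mean(abs(got$beta - coh$trait$beta)), 3)
  # monomorphic variants are excluded
  d <- cbind(si$G$dosages[, 1:5], 0)
  gm <- genotype_table(d, rbind(si$G$variant_meta[1:5, ],
                                data.frame(scaffold = "zz", pos = 1,
                                           ref = "A", alt = "G",
                                           id = "mono")), si$G$sample_ids)
  scm <- assoc_scan(fit, gm, maf_min = 0)
  expect_false("mono" %in% scm$id)
})

test_that("simpleM counts independent signals (duplicate and oracle checks)", {
  G <- plain_founders(n = 150, m = 200, seed = 70)
  meff <- effective_tests(G)
  expect_gt(meff, 0.9 * 200)
  # every variant duplicated: ~m/2
  d <- G$dosages[, rep(1:100, each = 2)]
  gd <- genotype_table(d, data.frame(scaffold = "s", pos = (1:200) * 11,
                                     ref = "A", alt = "G"))
  expect_lt(effective_tests(gd), 0.55 * 200)
  # small correlated panel equals the unblocked single-matrix oracle
  Gc <- plain_founders(n = 150, m = 60, seed = 71, ld_block_size = 15,
                       ld_rho = 0.8)
  ev <- eigen(cor(Gc$dosages), symmetric = TRUE, only.values = TRUE)$values
  oracle <- which(cumsum(pmax(ev, 0)) / sum(pmax(ev, 0)) >= 0.995)[1]
  expect_equal(effective_tests(Gc, block = 100), oracle)
})

test_that("threshold arithmetic reproduces the published constants", {
  # alpha = 0.1 over 14,004 effective tests
  expect_equal(bonferroni_threshold(0.1, 14004), 7.14e-6, tolerance = 1e-3)
  # top-hit adjusted p
  expect_equal(adjust_p(3.81e-6, 14004), 0.053, tolerance = 0.01)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(adjust_p(0.5, 14004), 1)
  # consistency: p below threshold iff adjusted p below alpha
  set.seed(72)
  p <- 10^runif(500, -8, 0)
  below <- p < bonferroni_threshold(0.1, 14004)
  expect_equal(below, adjust_p(p, 14004) < 0.1)
  # expected null count at the suggestive threshold
  enc <- expected_null_count(2.13e-4, 46996)
  expect_equal(enc$rounded, 10)
  expect_equal(expected_null_count(0.5, 0)$expected, 0)
  m <- 1234
  expect_equal(expected_null_count(1 / m, m)$expected, 1)
})

test_that("genomic lambda is calibrated and scales with inflation", {
  set.seed(73)
  p <- runif(1e5)
  expect_equal(genomic_lambda(p), 1, tolerance = 0.02)
  chi <- qchisq(p, 1, lower.tail = FALSE) * 1.5
  p_inf <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_inf), 1.5, tolerance = 0.05)
  expect_equal(genomic_lambda(0.5), 1)
})
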