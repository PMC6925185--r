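test_that("quantile normalization maps ranks to standard-normal scores", {
  x <- matrix(c(1, 5, 9, 20, 50), 1)
  z <- as.numeric(quantile_normalize(x))
  expect_false(is.unsorted(z))
  expect_equal(z, -rev(z))  # symmetric about 0
  set.seed(121)
  big <- matrix(rnbinom(40 * 50, mu = 80, size = 5), 40, 50)
  zb <- quantile_normalize(big)
  expect_lt(max(abs(rowMeans(zb))), 0.02)  # ties perturb exact zero means
  expect_equal(unname(apply(zb, 1, var)), rep(1, 40), tolerance = 0.15)
  # ties: equal values via average ranks, matches the oracle
  xt <- matrix(c(3, 7, 7, 1, 9), 1)
  zt <- as.numeric(quantile_normalize(xt))
  oracle <- qnorm((rank(drop(xt)) - 0.5) / 5)
  expect_equal(zt, oracle)
  expect_equal(zt[2], zt[3])
  # constant tag flagged and zeroed
  zc <- quantile_normalize(matrix(c(4, 4, 4, 4), 1))
  expect_equal(as.numeric(zc), rep(0, 4))
  expect_equal(attr(zc, "constant_tags"), 1L)
})

test_that("per-tissue MAF filter applies thresholds and counts carriers", {
  d <- cbind(c(0, 0, 1), c(0, 1, 2), c(1, 1, 1))  # alt freqs 1/6, 1/2, 1/2
  g <- genotype_table(d, data.frame(scaffold = "s", pos = c(10, 20, 30),
                                    ref = "A", alt = "G"),
                      c("a", "b", "c"))
  out_h <- eqtl_maf_filter(g, c("a", "b", "c"), maf_min = 0.2)
  expect_false(g$variant_meta$id[1] %in% out_h$id)  # MAF 1/6 < 0.2 dropped
  expect_true(g$variant_meta$id[3] %in% out_h$id)   # MAF 0.5 kept
  out_b <- eqtl_maf_filter(g, c("a", "b", "c"), maf_min = 0.1)
  expect_true(g$variant_meta$id[1] %in% out_b$id)
  # carriers equal a brute-force dosage scan (minor allele aware)
  set.seed(122)
  dd <- matrix(sample(0:2, 30 * 20, TRUE, prob = c(1, 1, 2)), 30, 20)
  gg <- genotype_table(dd, data.frame(scaffold = "s", pos = (1:20) * 9,
                                      ref = "A", alt = "G"))
  out <- eqtl_maf_filter(gg, gg$sample_ids, maf_min = 0)
  for (r in seq_len(nrow(out))) {
    j <- match(out$id[r], gg$variant_meta$id)
    f <- mean(dd[, j]) / 2
    truth <- if (f <= 0.5) sum(dd[, j] >= 1) else sum(dd[, j] <= 1)
    expect_equal(out$carriers[r], truth)
  }
})

test_that("cis/trans classification respects the 500 kb inclusive window", {
  n <- 43
  spec <- population_spec(K = 1, fst = 0, sizes = n, m = 5,
                          maf_range = c(0.3, 0.5))
  G <- simulate_genotypes(draw_subpop_frequencies(spec, 123), spec,
                          seed = 123, scaffold_size = 5)
  v <- G$variant_meta
  set.seed(124)
  expr <- list(counts = matrix(rnbinom(3 * n, mu = 100, size = 5), 3, n,
                               dimnames = list(c("t1", "t2", "t3"),
                                               G$sample_ids)),
               tag_meta = data.frame(tag = c("t1", "t2", "t3"),
                                     scaffold = c(v$scaffold[1],
                                                  v$scaffold[1], "other"),
                                     position = c(v$pos[1] + 499000,
                                                  v$pos[1] + 501000, 5)),
               covariates = data.frame(sample = G$sample_ids,
                                       state = factor(rep(c("a", "b"),
                                                          length.out = n))))
  sc <- scan_cis_trans(v$id[1], G, expr)
  expect_equal(sc$class[sc$tag == "t1"], "cis")    # 499 kb
  expect_equal(sc$class[sc$tag == "t2"], "trans")  # 501 kb
  expect_equal(sc$class[sc$tag == "t3"], "trans")  # other scaffold
  expect_equal(sum(sc$top_trans), 1L)
})

test_that("planted cis effects are recovered and nulls FDR-controlled", {
  n <- 43
  spec <- population_spec(K = 1, fst = 0, sizes = n, m = 200,
                          maf_range = c(0.2, 0.5))
  G <- simulate_genotypes(draw_subpop_frequencies(spec, 125), spec,
                          seed = 125)
  cis <- data.frame(variant_idx = 50, tag_idx = 1, effect = 1.0)
  hits <- vapply(1:10, function(s) {
    ex <- simulate_expression(G, expression_spec(n_tags = 30,
                                                 cis_pairs = cis,
                                                 state_sd = 0.3),
                              seed = 200 + s)
    sc <- scan_cis_trans(G$variant_meta$id[50], G, ex)
    any(sc$class == "cis" & sc$tag == ex$tag_meta$tag[1] & sc$q < 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # zero effect: that pair almost never significant
  nulls <- vapply(1:10, function(s) {
    ex <- simulate_expression(G, expression_spec(n_tags = 30,
                                                 state_sd = 0.3),
                              seed = 300 + s)
    sc <- scan_cis_trans(G$variant_meta$id[50], G, ex)
    sum(sc$significant, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(nulls > 0), 0.3)
  # state-only variation is absorbed by the covariate: no calls
  ex_state <- simulate_expression(G, expression_spec(n_tags = 30,
                                                     state_sd = 1.5),
                                  seed = 126)
  sc_state <- scan_cis_trans(G$variant_meta$id[c(10, 50, 90)], G, ex_state)
  expect_equal(sum(sc_state$significant, na.rm = TRUE), 0L)
})

test_that("q-values match a brute-force BH oracle within each class", {
  n <- 40
  spec <- population_spec(K = 1, fst = 0, sizes = n, m = 20,
                          maf_range = c(0.3, 0.5))
  G <- simulate_genotypes(draw_subpop_frequencies(spec, 127), spec,
                          seed = 127)
  ex <- simulate_expression(G, expression_spec(n_tags = 15, state_sd = 0.2),
                            seed = 128)
  sc <- scan_cis_trans(G$variant_meta$id[c(3, 12)], G, ex)
  for (cls in unique(sc$class)) {
    sub <- sc[sc$class == cls, ]
    p <- sub$p
    nq <- length(p)
    oracle <- vapply(seq_len(nq), function(i) {
      min(1, min((nq / rank(p)[i]) * p[i],
                 min((nq / seq(rank(p)[i], nq)) *
                       sort(p)[seq(rank(p)[i], nq)])))
    }, numeric(1))
    expect_equal(sub$q, unname(p.adjust(p, "BH")))
    expect_equal(sort(sub$q), sort(oracle), tolerance = 1e-12)
    # monotone in p within class
    expect_false(is.unsorted(sub$q[order(sub$p)]))
  }
})

test_that("modelling a true covariate increases detection power", {
  n <- 43
  spec <- population_spec(K = 1, fst = 0, sizes = n, m = 50,
                          maf_range = c(0.3, 0.5))
  G <- simulate_genotypes(draw_subpop_frequencies(spec, 129), spec,
                          seed = 129)
  cis <- data.frame(variant_idx = 25, tag_idx = 1, effect = 0.5)
  p_with <- p_without <- numeric(12)
  for (s in 1:12) {
    ex <- simulate_expression(G, expression_spec(n_tags = 10,
                                                 cis_pairs = cis,
                                                 state_sd = 1.0),
                              seed = 400 + s)
    sc1 <- scan_cis_trans(G$variant_meta$id[25], G, ex)
    ex2 <- ex
    ex2$covariates$state <- factor(rep("one", n))  # drop the information
    sc2 <- tryCatch(scan_cis_trans(G$variant_meta$id[25], G, ex2),
                    error = function(e) NULL)
    tag <- ex$tag_meta$tag[1]
    p_with[s] <- sc1$p[sc1$tag == tag]
    p_without[s] <- if (is.null(sc2)) NA else sc2$p[sc2$tag == tag]
  }
  expect_lt(median(p_with), median(p_without, na.rm = TRUE))
})
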