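test_that("LD pruning leaves no violating pair (exhaustive oracle)", {
  G <- plain_founders(n = 120, m = 300, seed = 41, ld_block_size = 20,
                      ld_rho = 0.85)
  kept <- ld_prune(G, window = 50, step = 10, r2_max = 0.5)
  d <- G$dosages[, kept, drop = FALSE]
  # oracle: every same-scaffold pair within 50 retained-or-not positions
  vm <- G$variant_meta[kept, ]
  for (i in seq_along(kept)) {
    near <- which(vm$scaffold == vm$scaffold[i] &
                    abs(kept - kept[i]) < 50 & seq_along(kept) > i)
    if (!length(near)) next
    r2 <- suppressWarnings(cor(d[, i], d[, near, drop = FALSE]))^2
    expect_true(all(r2 <= 0.5 + 1e-12, na.rm = TRUE))
  }
  expect_lt(length(kept), 300)
  # duplicated variant: exactly one of the pair survives
  dd <- cbind(G$dosages[, 1], G$dosages[, 1], G$dosages[, 2])
  gd <- genotype_table(dd, data.frame(scaffold = "s", pos = c(10, 20, 30),
                                      ref = "A", alt = "G"))
  expect_equal(length(ld_prune(gd)), 2L)
  # independent variants all survive
  gi <- plain_founders(n = 200, m = 60, seed = 42)
  expect_equal(length(ld_prune(gi)), 60L)
})

test_that("PCA separates diverged subpopulations and is sign-deterministic", {
  G <- plain_founders(n = 120, m = 2000, seed = 43, fst = 0.3, K = 2)
  lab <- attr(G, "labels")
  pc <- pca_genotypes(G, n_components = 5)
  expect_gt(abs(cor(pc$scores[, 1], as.numeric(factor(lab)))), 0.9)
  # homogeneous population: no component separates a random split
  Gh <- plain_founders(n = 100, m = 2000, seed = 44)
  pch <- pca_genotypes(Gh, n_components = 5)
  set.seed(1)
  split <- sample(c(0, 1), 100, TRUE)
  expect_lt(max(abs(cor(pch$scores, split))), 0.3)
  # a duplicated sample gets identical scores
  dd <- rbind(G$dosages, G$dosages[1, , drop = FALSE])
  gd <- genotype_table(dd, G$variant_meta,
                       c(G$sample_ids, "dup"))
  pcd <- pca_genotypes(gd, n_components = 3)
  expect_equal(unname(pcd$scores["dup", ]), unname(pcd$scores[1, ]),
               tolerance = 1e-8)
  # over-asking components warns and truncates
  expect_warning(pca_genotypes(plain_founders(n = 10, m = 50, seed = 45),
                               n_components = 20), "truncating")
})

test_that("robust kinship hits pedigree expectations and self = 0.5", {
  G <- plain_founders(n = 40, m = 5000, seed = 46)
  rk <- robust_kinship(G)
  expect_equal(unname(diag(rk$kinship)), rep(0.5, 40))
  off <- rk$kinship[upper.tri(rk$kinship)]
  expect_lt(max(abs(off)), 0.1)  # unrelated
  # within-subpopulation unrelated pairs stay near zero despite structure;
  # cross-subpopulation pairs carry the estimator's known negative offset
  # -F/(1-F), which the ancestry-adjusted estimator removes
  Gs <- plain_founders(n = 60, m = 5000, seed = 47, fst = 0.3, K = 2)
  rks <- robust_kinship(Gs)
  lab <- attr(Gs, "labels")
  within1 <- rks$kinship[lab == "pop1", lab == "pop1"]
  expect_lt(abs(mean(within1[upper.tri(within1)])), 0.02)
  cross <- rks$kinship[lab == "pop1", lab == "pop2"]
  expect_lt(abs(mean(cross) - (-0.3 / 0.7)), 0.05)
  pcs <- pca_genotypes(Gs, n_components = 1)$scores[, 1]
  aks <- adjusted_kinship(Gs, pcs)
  expect_lt(abs(mean(aks[lab == "pop1", lab == "pop2"])), 0.05)
  # sparse overlap yields NA; small panels warn
  d <- G$dosages
  d[1, 101:5000] <- NA
  gna <- genotype_table(d, G$variant_meta, G$sample_ids)
  rkn <- robust_kinship(gna, min_shared = 200)
  expect_true(all(is.na(rkn$kinship[1, -1])))
  expect_warning(robust_kinship(subset_genotypes(G, variants = 1:500)),
                 "noisy")
})

test_that("ancestry-adjusted kinship removes structure inflation", {
  # homogeneous population: tracks the robust estimator (the two use
  # different denominators, so agreement is tight on average with a wider
  # worst pair)
  G <- plain_founders(n = 60, m = 4000, seed = 48)
  pc <- pca_genotypes(G, n_components = 1)
  ak <- adjusted_kinship(G, pc$scores[, 1])
  rk <- robust_kinship(G)
  dmat <- abs(ak - rk$kinship)
  expect_lt(mean(dmat[upper.tri(dmat)]), 0.02)
  expect_lt(max(dmat[upper.tri(dmat)]), 0.12)
  expect_equal(unname(diag(ak)), rep(0.5, 60), tolerance = 0.05)
  # sibs inside a structured cohort still read ~0.25 after adjustment
  spec <- population_spec(K = 2, fst = 0.3, sizes = 40, m = 4000)
  founders <- simulate_genotypes(draw_subpop_frequencies(spec, 49), spec,
                                 seed = 49)
  fam <- simulate_families(founders, pedigree_spec(6, 4), seed = 49)
  all_d <- rbind(founders$dosages, fam$genotypes$dosages)
  ga <- genotype_table(all_d, founders$variant_meta, rownames(all_d))
  pca_all <- pca_genotypes(ga, n_components = 1)
  aka <- adjusted_kinship(ga, pca_all$scores[, 1])
  for (f in 1:6) {
    sibs <- fam$pedigree$id[fam$pedigree$family == f]
    expect_lt(abs(mean(aka[sibs, sibs][upper.tri(diag(length(sibs)))]) -
                    0.25), 0.07)
  }
  expect_error(adjusted_kinship(G, pc$scores[1:10, 1, drop = FALSE]),
               "match")
})

test_that("GRM construction is symmetric positive semi-definite", {
  coh <- small_cohort()
  K <- make_grm(coh$kinship_true)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8))
})

test_that("Weir-Cockerham F_ST recovers divergence and its extremes", {
  # identical frequencies: ~0
  G0 <- plain_founders(n = 100, m = 2000, seed = 51)
  lab0 <- rep(c("a", "b"), 50)
  expect_lt(abs(pairwise_fst(G0, lab0)[1, 2]), 0.01)
  # alternately fixed alleles: ~1
  d <- rbind(matrix(0, 10, 50), matrix(2, 10, 50))
  gf <- genotype_table(d, data.frame(scaffold = "s", pos = (1:50) * 3,
                                     ref = "A", alt = "G"))
  expect_gt(pairwise_fst(gf, rep(c("a", "b"), each = 10))[1, 2], 0.97)
  # Balding-Nichols parameter recovery
  G3 <- plain_founders(n = 200, m = 5000, seed = 52, fst = 0.3, K = 2)
  est <- pairwise_fst(G3, attr(G3, "labels"))[1, 2]
  expect_equal(est, 0.3, tolerance = 0.03)
  expect_error(pairwise_fst(G0, rep("a", 100)), "two")
})

test_that("unrelated-subset selection is verified by an oracle scan", {
  coh <- small_cohort()
  rk <- robust_kinship(coh$genotypes)
  sel <- select_unrelated(rk$kinship)
  sub <- rk$kinship[sel, sel]
  diag(sub) <- 0
  expect_true(all(sub < 2^-4.5))
  # all-unrelated input returns everyone
  G <- plain_founders(n = 30, m = 3000, seed = 53)
  rka <- robust_kinship(G)
  expect_equal(length(select_unrelated(rka$kinship)), 30L)
  # one full-sib pair: exactly one removed
  phi <- diag(0.5, 10)
  rownames(phi) <- colnames(phi) <- paste0("s", 1:10)
  phi[1, 2] <- phi[2, 1] <- 0.25
  expect_equal(length(select_unrelated(phi)), 9L)
})

test_that("family reconstruction recovers litters and PO subtypes", {
  founders <- plain_founders(n = 30, m = 10000, seed = 54)
  fam <- simulate_families(founders, pedigree_spec(4, 4), seed = 54)
  rk <- robust_kinship(fam$genotypes)
  cl <- classify_and_build_families(rk)
  expect_equal(cl$n_families, 4L)
  # partition matches the generating pedigree exactly
  truth <- split(fam$pedigree$id, fam$pedigree$family)
  got <- split(cl$families$sample, cl$families$family)
  expect_setequal(unname(lapply(truth, sort)), unname(lapply(got, sort)))
  fs_calls <- cl$calls$subtype[cl$calls$degree == "1st"]
  expect_true(all(fs_calls == "full-sib"))
  # parent-offspring subtype via near-zero IBD0 sharing
  both <- genotype_table(rbind(founders$dosages, fam$genotypes$dosages),
                         founders$variant_meta,
                         c(founders$sample_ids, fam$genotypes$sample_ids))
  clb <- classify_and_build_families(robust_kinship(both))
  po <- clb$calls[clb$calls$id1 %in% fam$pedigree$sire &
                    clb$calls$id2 %in% fam$pedigree$id, ]
  po <- po[po$degree == "1st", ]
  expect_true(nrow(po) > 0)
  expect_true(all(po$subtype == "parent-offspring"))
  # unrelated cohort: zero families
  rk0 <- robust_kinship(plain_founders(n = 20, m = 5000, seed = 55))
  expect_equal(classify_and_build_families(rk0)$n_families, 0L)
})

test_that("family-membership fraction matches the generator within 5 points", {
  coh <- small_cohort()
  rk <- robust_kinship(coh$genotypes)
  cl <- classify_and_build_families(rk)
  frac <- nrow(cl$families) / length(coh$genotypes$sample_ids)
  expect_equal(frac, 0.8, tolerance = 0.05 / 0.8)
})
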