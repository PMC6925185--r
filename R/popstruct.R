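# Population structure: LD pruning, PCA, KING-robust and ancestry-adjusted
# kinship, Weir-Cockerham F_ST, unrelated-subset selection and first-degree
# pedigree reconstruction.

impute_mean <- function(d) {
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Greedy windowed LD pruning
#'
#' Mirrors the common --indep-pairwise scheme: within windows of
#' \code{window} consecutive variants sliding by \code{step} along each
#' scaffold, pairs with squared dosage correlation above \code{r2_max} are
#' broken by removing the lower-MAF variant (ties by later position) until
#' no within-window pair exceeds the bound.
#'
#' @param G a \code{genotype_table} (variants sorted by scaffold/position).
#' @param window window size in variants.
#' @param step window slide in variants.
#' @param r2_max largest tolerated within-window r2.
#' @return integer indices (into \code{G}'s variants) of the retained set.
#' @export
ld_prune <- function(G, window = 50, step = 10, r2_max = 0.5) {
  d <- impute_mean(G$dosages)
  mafs <- maf(G)
  vm <- G$variant_meta
  keep <- rep(TRUE, ncol(d))
  for (sc in unique(vm$scaffold)) {
    sc_idx <- which(vm$scaffold == sc)
    starts <- seq(1, max(1, length(sc_idx) - 1), by = step)
    for (s in starts) {
      win <- sc_idx[s:min(s + window - 1, length(sc_idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      repeat {
        r2 <- suppressWarnings(cor(d[, win, drop = FALSE]))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        if (all(r2 <= r2_max)) break
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        a <- win[worst[1]]; b <- win[worst[2]]
        drop_v <- if (isTRUE(mafs[a] < mafs[b])) a
                  else if (isTRUE(mafs[b] < mafs[a])) b
                  else max(a, b)  # tie: later position
        keep[drop_v] <- FALSE
        win <- win[win != drop_v]
        if (length(win) < 2) break
      }
    }
  }
  which(keep)
}

#' Principal components of the standardized dosage matrix
#'
#' Dosages are mean-imputed, centered and scaled by sqrt(2p(1-p)), then
#' decomposed; each component's sign is fixed by making its
#' largest-magnitude variant loading positive, so results are
#' deterministic.
#'
#' @param G a \code{genotype_table} (typically LD-pruned).
#' @param n_components number of components to return.
#' @param maf_min variants below this MAF are excluded first.
#' @return list(scores n x k matrix, explained_variance proportion per
#'   component, n_variants).
#' @export
pca_genotypes <- function(G, n_components = 20, maf_min = 0.01) {
  mafs <- maf(G)
  keep <- which(!is.na(mafs) & mafs > maf_min)
  d <- impute_mean(G$dosages[, keep, drop = FALSE])
  p <- colMeans(d) / 2
  sdv <- sqrt(2 * p * (1 - p))
  X <- sweep(sweep(d, 2, 2 * p), 2, sdv, "/")
  n <- nrow(X)
  k <- min(n_components, n - 1, ncol(X))
  if (k < n_components)
    warning("rank supports only ", k, " components; truncating")
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  keep_k <- seq_len(k)
  scores <- sv$u[, keep_k, drop = FALSE] %*% diag(sv$d[keep_k], k, k)
  # sign convention via loadings v = X'u/d
  for (j in keep_k) {
    v <- crossprod(X, sv$u[, j]) / sv$d[j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- G$sample_ids
  colnames(scores) <- paste0("PC", keep_k)
  list(scores = scores,
       explained_variance = (sv$d^2 / sum(sv$d^2))[keep_k],
       n_variants = length(keep))
}

#' KING-robust pairwise kinship
#'
#' Allele-sharing estimator robust to population structure:
#' phi = (N_hethet - 2 N_opposite_homozygote) / (N_het_i + N_het_j),
#' counted over jointly non-missing variants. The companion zero-sharing
#' matrix is the IBD0-scale estimate: the opposite-homozygote count divided
#' by its expectation for unrelated individuals, sum over shared variants of
#' 2 p^2 (1-p)^2 (about 0 for parent-offspring, about 0.25 for full sibs,
#' about 1 for unrelated pairs).
#'
#' @param G a \code{genotype_table}; fewer than 1,000 variants triggers a
#'   warning, and pairs sharing fewer than \code{min_shared} non-missing
#'   variants get NA.
#' @param min_shared minimum jointly non-missing variants per pair.
#' @return list(kinship, zero_sharing, n_shared) of symmetric matrices.
#' @export
robust_kinship <- function(G, min_shared = 100) {
  d <- G$dosages
  m <- ncol(d)
  if (m < 1000) warning("robust kinship on only ", m,
                        " variants; estimates will be noisy")
  M <- (!is.na(d)) * 1
  d0 <- d; d0[is.na(d0)] <- -9
  H <- (d0 == 1) * 1
  A <- (d0 == 0) * 1
  B <- (d0 == 2) * 1
  hethet <- tcrossprod(H)
  opp <- tcrossprod(A, B); opp <- opp + t(opp)
  denom <- tcrossprod(H, M) + tcrossprod(M, H)
  phi <- (hethet - 2 * opp) / denom
  p <- colMeans(d, na.rm = TRUE) / 2
  w <- 2 * p^2 * (1 - p)^2
  e0 <- tcrossprod(sweep(M, 2, w, "*"), M)
  zero <- opp / e0
  diag(zero) <- 0
  shared <- tcrossprod(M)
  low <- shared < min_shared
  phi[low] <- NA; zero[low] <- NA
  dimnames(phi) <- dimnames(zero) <- list(G$sample_ids, G$sample_ids)
  list(kinship = phi, zero_sharing = zero, n_shared = shared)
}

#' Ancestry-adjusted kinship
#'
#' Conditions kinship on sample ancestry: per variant, individual allele
#' frequencies mu are predicted by regressing half-dosages on the supplied
#' principal components, then
#' phi_ij = sum (g_i - 2 mu_i)(g_j - 2 mu_j) /
#'          (4 sum sqrt(mu_i(1-mu_i) mu_j(1-mu_j))),
#' the individual-frequency formulation of structure-conditional kinship.
#' The result feeds the genetic relatedness matrix as GRM = 2 phi.
#'
#' @param G a \code{genotype_table}.
#' @param pcs matrix of component scores (samples x k), e.g. the first
#'   column of [pca_genotypes()] scores.
#' @return symmetric adjusted kinship matrix.
#' @export
adjusted_kinship <- function(G, pcs) {
  pcs <- as.matrix(pcs)
  if (nrow(pcs) != nrow(G$dosages))
    stop("component scores do not match the sample set")
  d <- G$dosages
  Z <- cbind(1, pcs)
  dimp <- impute_mean(d)
  beta <- solve(crossprod(Z), crossprod(Z, dimp / 2))
  mu <- Z %*% beta
  mu <- pmin(pmax(mu, 0.01), 0.99)
  M <- (!is.na(d)) * 1
  R <- (d - 2 * mu)
  R[is.na(R)] <- 0
  S <- sqrt(mu * (1 - mu)) * M
  num <- tcrossprod(R)
  den <- 4 * tcrossprod(S)
  phi <- num / den
  dimnames(phi) <- list(G$sample_ids, G$sample_ids)
  phi
}

#' Genetic relatedness matrix from kinship
#'
#' GRM = 2 x kinship, symmetrized and made positive semi-definite by
#' clipping negative eigenvalues at zero.
#'
#' @param kinship symmetric kinship matrix.
#' @return positive semi-definite GRM.
#' @export
make_grm <- function(kinship) {
  K <- 2 * (kinship + t(kinship)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    K <- e$vectors %*% (v * t(e$vectors))
    dimnames(K) <- dimnames(kinship)
  }
  K
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Variance-components estimator from genotype counts, averaged across
#' variants as a ratio of sums, for every pair of labeled groups.
#'
#' @param G a \code{genotype_table}.
#' @param labels group label per sample.
#' @return symmetric matrix of pairwise F_ST (diagonal 0).
#' @export
pairwise_fst <- function(G, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least two labeled groups")
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      out[i, j] <- out[j, i] <-
        wc_fst_two(G$dosages[labels == groups[i], , drop = FALSE],
                   G$dosages[labels == groups[j], , drop = FALSE])
    }
  }
  out
}

# Weir & Cockerham (1984) theta for two populations, ratio of sums
wc_fst_two <- function(d1, d2) {
  r <- 2
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  ok <- n1 >= 2 & n2 >= 2
  n1 <- n1[ok]; n2 <- n2[ok]
  p1 <- colMeans(d1[, ok, drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(d2[, ok, drop = FALSE], na.rm = TRUE) / 2
  h1 <- colMeans(d1[, ok, drop = FALSE] == 1, na.rm = TRUE)
  h2 <- colMeans(d2[, ok, drop = FALSE] == 1, na.rm = TRUE)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  sum(a[poly]) / sum((a + b + cc)[poly])
}

#' Select a maximal unrelated subset
#'
#' Greedy: while any pair's kinship reaches the threshold, remove the
#' sample with the most remaining relatives (ties broken by id order,
#' later removed first... i.e. the later id is removed).
#'
#' @param kinship symmetric kinship matrix with sample dimnames.
#' @param threshold pairs at or above this kinship are "related"
#'   (default 2^-4.5, the conventional 3rd-degree boundary).
#' @return character vector of retained sample ids.
#' @export
select_unrelated <- function(kinship, threshold = 2^-4.5) {
  ids <- rownames(kinship)
  rel <- kinship >= threshold
  rel[is.na(rel)] <- FALSE
  diag(rel) <- FALSE
  keep <- rep(TRUE, nrow(rel))
  repeat {
    deg <- rowSums(rel[keep, keep, drop = FALSE])
    if (!any(deg > 0)) break
    cand <- which(deg == max(deg))
    drop_i <- cand[length(cand)]  # tie: later id order
    keep[which(keep)[drop_i]] <- FALSE
  }
  ids[keep]
}

#' Classify pairwise relationships and build first-degree families
#'
#' Relationship degree follows the powers-of-two kinship bins
#' (duplicate/MZ >= 2^-1.5; 1st degree in [2^-2.5, 2^-1.5); 2nd degree in
#' [2^-3.5, 2^-2.5)). Within first-degree pairs, parent-offspring and full
#' sibs are separated by the zero-sharing (IBD0-scale) fraction:
#' below \code{po_max} is parent-offspring, above \code{fs_min} full sibs,
#' otherwise ambiguous. Families are the connected components of the
#' first-degree graph.
#'
#' @param kin result of [robust_kinship()] (or a list with \code{kinship}
#'   and \code{zero_sharing} matrices).
#' @param po_max,fs_min zero-sharing cutoffs for the PO/FS split, tuned for
#'   ~1e4-variant panels.
#' @return list(calls = data.frame(id1, id2, kinship, zero_sharing, degree,
#'   subtype), families = data.frame(sample, family) for samples in
#'   first-degree components, n_families).
#' @export
classify_and_build_families <- function(kin, po_max = 0.005, fs_min = 0.1) {
  phi <- kin$kinship; zero <- kin$zero_sharing
  ids <- rownames(phi)
  n <- nrow(phi)
  pairs <- which(upper.tri(phi), arr.ind = TRUE)
  k <- phi[pairs]; z <- zero[pairs]
  degree <- rep("unrelated", nrow(pairs))
  degree[k >= 2^-3.5] <- "2nd"
  degree[k >= 2^-2.5] <- "1st"
  degree[k >= 2^-1.5] <- "dup/MZ"
  degree[is.na(k)] <- NA
  subtype <- rep(NA_character_, nrow(pairs))
  first <- which(degree == "1st")
  subtype[first] <- ifelse(z[first] < po_max, "parent-offspring",
                           ifelse(z[first] > fs_min, "full-sib", "ambiguous"))
  calls <- data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                      kinship = k, zero_sharing = z, degree = degree,
                      subtype = subtype, stringsAsFactors = FALSE)
  edges <- pairs[first, , drop = FALSE]
  comp <- uf_components(n, edges)
  in_family <- seq_len(n) %in% unique(as.vector(edges))
  families <- data.frame(sample = ids[in_family],
                         family = comp[in_family],
                         stringsAsFactors = FALSE)
  families$family <- match(families$family, unique(families$family))
  list(calls = calls, families = families,
       n_families = length(unique(families$family)))
}
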