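# Permutation null for the suggestive-variant count, Harrell-Davis quantile
# inversion for its exceedance probability, and overlapping-subset
# complementary-pairs stability selection (ComPaSS) corroboration. All
# rescans refit the null model, via the shared eigen-rotation so each round
# costs O(n m).

# precompute everything that does not depend on the phenotype
fast_scan_context <- function(X, GRM, G, maf_min = 0) {
  mafs <- maf(G)
  keep <- which(!is.na(mafs) & mafs >= maf_min & mafs > 0)
  d <- impute_mean(G$dosages[, keep, drop = FALSE])
  rot <- reml_rotation(X, GRM)
  Gt <- crossprod(rot$U, d)
  list(rot = rot, Gt = Gt, Gt2 = Gt^2, keep = keep,
       ids = G$variant_meta$id[keep])
}

# score-test p-values for one phenotype vector under a context
fast_scan_p <- function(ctx, y) {
  yt <- drop(crossprod(ctx$rot$U, y))
  opt <- optimize(reml_rll, c(0, 1), yt = yt, xi = ctx$rot$xi,
                  maximum = TRUE, tol = 1e-9)
  cand <- c(opt$maximum, 0, 1 - 1e-12)
  ll <- vapply(cand, reml_rll, numeric(1), yt = yt, xi = ctx$rot$xi)
  h2 <- cand[which.max(ll)]
  v <- h2 * ctx$rot$xi + (1 - h2)
  sigma2_p <- sum(yt^2 / v) / length(yt)
  w <- 1 / (pmax(sigma2_p, 1e-12) * v)
  U <- drop(crossprod(ctx$Gt, w * yt))
  V <- drop(crossprod(ctx$Gt2, w))
  p <- rep(NA_real_, length(V))
  ok <- V > 1e-12
  p[ok] <- pchisq(U[ok]^2 / V[ok], df = 1, lower.tail = FALSE)
  p
}

#' Permute a phenotype sheet
#'
#' Reassigns each monitored sample's onset day to another sample, leaving
#' covariates, genotypes and kinship untouched. The identity permutation is
#' excluded (redrawn) whenever more than one phenotyped sample exists.
#'
#' @param pheno phenotype sheet (or any data.frame with \code{onset_day}).
#' @param seed integer seed; fixed seed gives a reproducible permutation.
#' @return the sheet with \code{onset_day} permuted across phenotyped rows.
#' @export
permute_phenotype <- function(pheno, seed = NULL) {
  idx <- which(!is.na(pheno$onset_day))
  with_substream(seed, "permute", {
    if (length(idx) > 1) {
      repeat {
        perm <- sample(idx)
        if (!all(perm == idx)) break
      }
    } else perm <- idx
    pheno$onset_day[idx] <- pheno$onset_day[perm]
    pheno
  })
}

#' Permutation null suite for a GWAS
#'
#' For each round the phenotype is permuted across samples, the null mixed
#' model refit, and the scan repeated; the suite records the count of
#' variants below the suggestive threshold per round and the ranked
#' p-value envelope (per-rank median with a 2.5-97.5% interval).
#'
#' @param y phenotype vector (aligned with \code{G}'s samples).
#' @param X fixed-effect design.
#' @param GRM genetic relatedness matrix.
#' @param G scan \code{genotype_table}.
#' @param rounds permutation rounds (study scale 5,000).
#' @param suggestive_threshold the suggestive p threshold whose null count
#'   is tracked (cohort-specific; the study's own was 2.13e-4).
#' @param seed integer seed.
#' @param maf_min scan MAF filter.
#' @return a \code{permutation_null}: counts (per round), envelope
#'   data.frame(rank, median, lo, hi), rounds, seed, n_redraws.
#' @export
permutation_null_suite <- function(y, X, GRM, G, rounds = 5000,
                                   suggestive_threshold = 2.13e-4,
                                   seed = 1, maf_min = 0) {
  ctx <- fast_scan_context(X, GRM, G, maf_min)
  m <- ncol(ctx$Gt)
  counts <- integer(rounds)
  ranked <- matrix(NA_real_, rounds, m)
  n_redraws <- 0L
  set.seed(substream_seed(seed, "perm_suite"))
  idx <- seq_along(y)
  for (r in seq_len(rounds)) {
    repeat {
      perm <- sample(idx)
      if (length(idx) == 1 || !all(perm == idx)) break
    }
    p <- tryCatch(fast_scan_p(ctx, y[perm]), error = function(e) NULL)
    if (is.null(p)) { n_redraws <- n_redraws + 1L; next }
    p <- p[!is.na(p)]
    counts[r] <- sum(p <= suggestive_threshold)
    ranked[r, seq_along(p)] <- sort(p)
  }
  envelope <- data.frame(
    rank = seq_len(m),
    median = apply(ranked, 2, median, na.rm = TRUE),
    lo = apply(ranked, 2, quantile, probs = 0.025, na.rm = TRUE),
    hi = apply(ranked, 2, quantile, probs = 0.975, na.rm = TRUE))
  structure(list(counts = counts, envelope = envelope, rounds = rounds,
                 suggestive_threshold = suggestive_threshold, seed = seed,
                 n_redraws = n_redraws),
            class = "permutation_null")
}

#' Harrell-Davis distribution-free quantile estimator
#'
#' Weights every order statistic by increments of the regularized
#' incomplete beta function: for sample size n and quantile q, with
#' a = q(n+1) and b = (1-q)(n+1), the weight of the i-th order statistic is
#' I_{i/n}(a, b) - I_{(i-1)/n}(a, b).
#'
#' @param sample numeric sample (n >= 1).
#' @param q quantile in (0, 1).
#' @return the estimate.
#' @export
hd_quantile <- function(sample, q) {
  stopifnot(length(sample) >= 1, q > 0, q < 1)
  x <- sort(sample)
  n <- length(x)
  a <- q * (n + 1); b <- (1 - q) * (n + 1)
  w <- pbeta(seq_len(n) / n, a, b) - pbeta(seq_len(n) / n - 1 / n, a, b)
  sum(w * x)
}

#' Exceedance probability via Harrell-Davis inversion
#'
#' Finds the smallest quantile level q (on a grid of step \code{grid_step})
#' at which the Harrell-Davis estimate of the null-count distribution
#' reaches the observed count, and returns 1 - q: the probability of
#' observing at least this count under the null.
#'
#' @param null_counts per-round null counts from [permutation_null_suite()].
#' @param observed the observed count.
#' @param grid_step resolution of the quantile grid.
#' @return exceedance probability in (0, 1).
#' @export
exceedance_probability <- function(null_counts, observed,
                                   grid_step = 1e-4) {
  if (length(unique(null_counts)) < 2)
    stop("null counts are degenerate")
  qs <- seq(grid_step, 1 - grid_step, by = grid_step)
  # hd_quantile is monotone in q: binary search for the crossing
  lo <- 1L; hi <- length(qs)
  if (hd_quantile(null_counts, qs[hi]) < observed) return(grid_step)
  if (hd_quantile(null_counts, qs[lo]) >= observed) return(1 - qs[lo])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (hd_quantile(null_counts, qs[mid]) >= observed) hi <- mid else lo <- mid
  }
  1 - qs[hi]
}

#' Overlapping two-thirds ComPaSS split
#'
#' Partitions n samples into subsets A and B of size ~2n/3 each that share
#' an overlap of ~n/3 samples, with the remaining samples divided into two
#' equal complementary halves; A and B together cover every sample. An odd
#' remainder is absorbed into the overlap so the subsets stay equal-sized.
#'
#' @param sample_ids sample identifiers (n >= 6).
#' @param seed integer seed.
#' @return list(A, B, overlap) of sample-id vectors.
#' @export
compass_split <- function(sample_ids, seed = NULL) {
  n <- length(sample_ids)
  if (n < 6) stop("need at least 6 samples to split")
  overlap_n <- round(n / 3)
  half <- (n - overlap_n) %/% 2L
  overlap_n <- n - 2L * half  # absorb odd remainder into the overlap
  with_substream(seed, "compass_split", {
    ord <- sample(sample_ids)
    overlap <- ord[seq_len(overlap_n)]
    a_half <- ord[overlap_n + seq_len(half)]
    b_half <- ord[overlap_n + half + seq_len(half)]
    list(A = c(overlap, a_half), B = c(overlap, b_half), overlap = overlap)
  })
}

#' ComPaSS corroboration with overlapping subsets
#'
#' Per resample, samples are split with [compass_split()], the null mixed
#' model is refit and the candidate variants rescanned within each subset,
#' and a variant is validated when the larger of its two subset p-values is
#' at most \code{alpha}. The corroboration estimate eta-hat is the
#' validated fraction over resamples; variants with eta-hat >= eta are
#' corroborated.
#'
#' @param y phenotype vector aligned with \code{G}'s samples.
#' @param X fixed-effect design (same rows).
#' @param GRM genetic relatedness matrix.
#' @param G \code{genotype_table} of candidate variants (subset it first).
#' @param resamples number of resampling rounds (study scale 100).
#' @param alpha per-subset critical value (study value 1e-3).
#' @param eta corroboration parameter (study value 0.6).
#' @param seed integer seed.
#' @return data.frame(id, eta_hat, corroborated); attribute
#'   \code{n_redraws}.
#' @export
compass_corroborate <- function(y, X, GRM, G, resamples = 100, alpha = 1e-3,
                                eta = 0.6, seed = 1) {
  n <- length(y)
  ids <- G$variant_meta$id
  validated <- matrix(FALSE, resamples, length(ids))
  n_redraws <- 0L
  r <- 1L
  while (r <= resamples) {
    split <- compass_split(seq_len(n), seed = substream_seed(
      seed, paste0("compass_", r + n_redraws)))
    p_sub <- lapply(split[c("A", "B")], function(sub) {
      tryCatch({
        ctx <- fast_scan_context(X[sub, , drop = FALSE],
                                 GRM[sub, sub, drop = FALSE],
                                 subset_genotypes(G, samples = sub))
        p <- rep(NA_real_, length(ids))
        p[ctx$keep] <- fast_scan_p(ctx, y[sub])
        p
      }, error = function(e) NULL)
    })
    if (any(vapply(p_sub, is.null, logical(1)))) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > 10 * resamples) stop("too many failed resamples")
      next
    }
    pmax_sub <- pmax(p_sub$A, p_sub$B)
    validated[r, ] <- !is.na(pmax_sub) & pmax_sub <= alpha
    r <- r + 1L
  }
  out <- data.frame(id = ids, eta_hat = colMeans(validated),
                    stringsAsFactors = FALSE)
  out$corroborated <- out$eta_hat >= eta
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Calibrate ComPaSS on effect-size-matched background variants
#'
#' Samples \code{n_variants} variants uniformly across the distribution of
#' scan effect sizes (equal-width bins over the beta range, uniform over
#' occupied bins, uniform within a bin, without replacement), runs
#' [compass_corroborate()] on them, and reports the corroborated count
#' against the type-I expectation of 0.05 x n_variants.
#'
#' @param assoc an \code{assoc_table} with a \code{beta} column.
#' @param y,X,GRM,G as in [compass_corroborate()]; \code{G} must contain
#'   the assoc variants.
#' @param n_variants number of background variants to sample.
#' @param bins number of equal-width effect-size bins.
#' @inheritParams compass_corroborate
#' @return list(records, n_corroborated, bound, eta_median, n_sampled).
#' @export
compass_calibrate <- function(assoc, y, X, GRM, G, n_variants = 1000,
                              bins = 20, resamples = 100, alpha = 1e-3,
                              eta = 0.6, seed = 1) {
  if (nrow(assoc) < n_variants) {
    message("only ", nrow(assoc), " variants available; sampling all")
    chosen <- assoc$id
  } else {
    with_substream(seed, "calibrate_sample", {
      edges <- seq(min(assoc$beta), max(assoc$beta), length.out = bins + 1)
      bin <- findInterval(assoc$beta, edges, rightmost.closed = TRUE)
      pool <- split(seq_len(nrow(assoc)), bin)
      chosen_idx <- integer(0)
      while (length(chosen_idx) < n_variants && length(pool)) {
        b <- sample(length(pool), 1)
        take <- sample(length(pool[[b]]), 1)
        chosen_idx <- c(chosen_idx, pool[[b]][take])
        pool[[b]] <- pool[[b]][-take]
        pool <- pool[lengths(pool) > 0]
      }
      chosen <- assoc$id[chosen_idx]
    })
  }
  Gc <- subset_genotypes(G, variants = match(chosen, G$variant_meta$id))
  rec <- compass_corroborate(y, X, GRM, Gc, resamples = resamples,
                             alpha = alpha, eta = eta, seed = seed)
  list(records = rec, n_corroborated = sum(rec$corroborated),
       bound = 0.05 * nrow(rec), eta_median = median(rec$eta_hat),
       n_sampled = nrow(rec))
}
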