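# The animal model: y = Xb + a + e with a ~ N(0, sigma2_g * GRM) and
# e ~ N(0, sigma2_e * I). REML works in the eigenspace of the GRM projected
# orthogonal to X, which reduces the restricted likelihood to a
# one-dimensional profile in h2 = sigma2_g / (sigma2_g + sigma2_e) and makes
# the score-test projection a diagonal reweighting - the same machinery is
# reused by the permutation and stability-selection suites.

#' Backward stepwise fixed-effect selection
#'
#' Starts from the full ordinary-least-squares model of onset day on all
#' candidate covariates and repeatedly drops the term whose removal most
#' improves AIC, provided the nested-model comparison is non-significant
#' (p >= alpha), i.e. dropping it does not significantly reduce fit.
#' Collinear candidates are reported and the later-listed one dropped
#' before selection begins.
#'
#' @param pheno phenotype sheet with \code{onset_day} and the candidate
#'   columns; rows with missing onset are ignored.
#' @param candidates candidate covariate names (default the six standard
#'   husbandry covariates).
#' @param alpha significance level guarding a drop.
#' @return list(selected, adj_r2, formula, steps, dropped_collinear).
#' @export
select_fixed_effects <- function(pheno,
                                 candidates = c("sex", "year", "implant_day",
                                                "age_class", "placement_day",
                                                "mass"),
                                 alpha = 0.05) {
  d <- pheno[!is.na(pheno$onset_day), , drop = FALSE]
  for (v in c("sex", "year", "age_class"))
    if (v %in% candidates) d[[v]] <- factor(d[[v]])
  cur <- candidates
  # drop aliased (collinear) candidates, later-listed first
  dropped_collinear <- character(0)
  repeat {
    f <- stats::reformulate(cur, response = "onset_day")
    fit <- lm(f, data = d)
    al <- is.na(coef(fit))
    if (!any(al)) break
    # find the latest-listed candidate contributing an aliased column
    terms_al <- unique(attr(fit$terms, "term.labels")[
      attr(model.matrix(fit), "assign")[al]])
    victim <- cur[max(match(terms_al, cur), na.rm = TRUE)]
    dropped_collinear <- c(dropped_collinear, victim)
    cur <- setdiff(cur, victim)
  }
  fit <- lm(stats::reformulate(cur, response = "onset_day"), data = d)
  steps <- list()
  repeat {
    aic0 <- AIC(fit)
    best <- NULL
    for (term in cur) {
      reduced <- lm(stats::reformulate(setdiff(cur, term) %0% "1",
                                       response = "onset_day"), data = d)
      p_drop <- anova(reduced, fit)[2, "Pr(>F)"]
      aic1 <- AIC(reduced)
      if (aic1 < aic0 && (is.na(p_drop) || p_drop >= alpha)) {
        if (is.null(best) || aic1 < best$aic) {
          best <- list(term = term, aic = aic1, p = p_drop, fit = reduced)
        }
      }
    }
    if (is.null(best)) break
    steps[[length(steps) + 1]] <- data.frame(dropped = best$term,
                                             aic = best$aic, p_drop = best$p)
    cur <- setdiff(cur, best$term)
    fit <- best$fit
    if (!length(cur)) break
  }
  list(selected = cur, adj_r2 = summary(fit)$adj.r.squared,
       fit = fit, steps = if (length(steps)) do.call(rbind, steps) else NULL,
       dropped_collinear = dropped_collinear)
}

`%0%` <- function(x, fallback) if (length(x)) x else fallback

# eigen machinery shared by REML / score tests / resampling:
# U_r spans the complement of X, xi are eigenvalues of the projected GRM
reml_rotation <- function(X, GRM) {
  n <- nrow(X)
  qx <- qr(X)
  p <- qx$rank
  # explicit orthonormal basis of the complement of col(X), then the
  # projected GRM is eigendecomposed within it (no leakage from the fixed-
  # effect directions even when the GRM is singular)
  Q2 <- qr.Q(qx, complete = TRUE)[, (p + 1):n, drop = FALSE]
  es <- eigen(crossprod(Q2, GRM %*% Q2), symmetric = TRUE)
  list(U = Q2 %*% es$vectors, xi = pmax(es$values, 0), p = p, n = n)
}

# profiled restricted log-likelihood in h2 (sigma2_p profiled out)
reml_rll <- function(h2, yt, xi) {
  v <- h2 * xi + (1 - h2)
  q <- length(yt)
  -0.5 * (q * log(sum(yt^2 / v)) + sum(log(v)))
}

#' Fit the null animal model by REML
#'
#' Maximizes the restricted likelihood over h2 in [0, 1] on the
#' eigen-rotated data; variance components are non-negative by
#' construction, and boundary solutions (residual variance collapsing to
#' zero, i.e. h2 -> 1, or a fully environmental fit) are permitted and
#' flagged. A near-flat restricted likelihood (unidentifiable h2, e.g.
#' GRM close to identity) is also flagged.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (include the intercept).
#' @param GRM genetic relatedness matrix (2 x kinship), PSD.
#' @param tol boundary/flatness tolerance.
#' @return a \code{null_model_fit}: variance components, h2, fixed-effect
#'   estimates, restricted log-likelihood, flags, and the cached projection
#'   (\code{P}, \code{Py}) for score tests.
#' @export
fit_null_reml <- function(y, X, GRM, tol = 1e-8) {
  stopifnot(length(y) == nrow(X), nrow(GRM) == length(y))
  if (qr(X)$rank >= length(y)) stop("model has no residual degrees of freedom")
  rot <- reml_rotation(X, GRM)
  yt <- drop(crossprod(rot$U, y))
  opt <- optimize(reml_rll, c(0, 1), yt = yt, xi = rot$xi, maximum = TRUE,
                  tol = 1e-10)
  # compare against the boundaries explicitly
  cand_h2 <- c(opt$maximum, 0, 1 - 1e-12)
  ll <- vapply(cand_h2, reml_rll, numeric(1), yt = yt, xi = rot$xi)
  h2 <- cand_h2[which.max(ll)]
  v <- h2 * rot$xi + (1 - h2)
  sigma2_p <- sum(yt^2 / v) / (rot$n - rot$p)
  sigma2_g <- h2 * sigma2_p
  sigma2_e <- (1 - h2) * sigma2_p
  # fixed effects by GLS at the fitted variances
  V <- sigma2_g * GRM + sigma2_e * diag(rot$n)
  Vi <- solve(V + diag(tol * mean(diag(V)), rot$n))
  XtVi <- crossprod(X, Vi)
  bhat <- solve(XtVi %*% X, XtVi %*% y)
  P <- Vi - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  grid <- vapply(seq(0.01, 0.99, length.out = 25), reml_rll, numeric(1),
                 yt = yt, xi = rot$xi)
  flags <- c(boundary = h2 <= 1e-6 || h2 >= 1 - 1e-6,
             flat_likelihood = diff(range(grid)) < 1e-4)
  structure(list(beta = drop(bhat), sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = h2, loglik_restricted = max(ll), flags = flags,
                 P = P, Py = drop(P %*% y), X = X, y = y,
                 rotation = rot, yt = yt),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf(
    "null_model_fit: sigma2_g = %.3f, sigma2_e = %.3f, h2 = %.3f%s\n",
    x$sigma2_g, x$sigma2_e, x$h2,
    if (any(x$flags)) paste0(" [", paste(names(x$flags)[x$flags],
                                         collapse = ", "), "]") else ""))
  invisible(x)
}

#' Score-test genome-wide association scan
#'
#' Per variant with MAF at or above \code{maf_min}: score statistic
#' U = x' P y with variance V = x' P x under the null-model projection P;
#' p-value from U^2 / V against chi-square(1); allelic effect
#' beta = U / V in days per counted (alt) allele. Missing dosages are
#' imputed to the variant mean; variants with no genotypic variance after
#' imputation are skipped and counted.
#'
#' @param fit a [fit_null_reml()] result for the scan samples.
#' @param G \code{genotype_table} over the same samples (same order).
#' @param maf_min MAF threshold (default 0.05).
#' @return an \code{assoc_table} data.frame: id, scaffold, pos, ref, alt,
#'   counted allele, maf, beta, p; attribute \code{n_skipped}.
#' @export
assoc_scan <- function(fit, G, maf_min = 0.05) {
  if (nrow(G$dosages) != length(fit$y))
    stop("genotype table does not match the fitted samples")
  mafs <- maf(G)
  keep <- which(!is.na(mafs) & mafs >= maf_min)
  d <- impute_mean(G$dosages[, keep, drop = FALSE])
  U <- drop(crossprod(d, fit$Py))
  V <- colSums(d * (fit$P %*% d))
  ok <- V > 1e-12
  chi <- rep(NA_real_, length(keep))
  chi[ok] <- U[ok]^2 / V[ok]
  out <- data.frame(id = G$variant_meta$id[keep],
                    scaffold = G$variant_meta$scaffold[keep],
                    pos = G$variant_meta$pos[keep],
                    ref = G$variant_meta$ref[keep],
                    alt = G$variant_meta$alt[keep],
                    counted_allele = G$variant_meta$alt[keep],
                    maf = unname(mafs[keep]),
                    beta = ifelse(ok, U / V, NA_real_),
                    p = pchisq(chi, df = 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  attr(out, "n_skipped") <- sum(!ok)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Effective number of independent tests (simpleM)
#'
#' Per scaffold, composite-LD correlation matrices are computed over
#' consecutive blocks of variants; each block contributes the smallest
#' number of leading eigenvalues whose sum reaches \code{C} of the total
#' eigenvalue mass, and block contributions are summed across the genome.
#'
#' @param G \code{genotype_table} of the scan variant set.
#' @param C fraction of variance to capture (default 0.995).
#' @param block block size in variants (default 100).
#' @return integer effective test count M_eff.
#' @export
effective_tests <- function(G, C = 0.995, block = 100) {
  vm <- G$variant_meta
  d <- impute_mean(G$dosages)
  meff <- 0L
  for (sc in unique(vm$scaffold)) {
    idx <- which(vm$scaffold == sc)
    starts <- seq(1, length(idx), by = block)
    for (s in starts) {
      b <- idx[s:min(s + block - 1, length(idx))]
      db <- d[, b, drop = FALSE]
      sds <- apply(db, 2, sd)
      db <- db[, sds > 0, drop = FALSE]
      if (ncol(db) == 0) next
      if (ncol(db) == 1) { meff <- meff + 1L; next }
      ev <- eigen(cor(db), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      cum <- cumsum(ev) / sum(ev)
      meff <- meff + as.integer(which(cum >= C)[1])
    }
  }
  meff
}

#' Bonferroni threshold over effective tests
#'
#' @param alpha family-wise error target.
#' @param m_eff effective number of independent tests.
#' @return genome-wide p-value threshold alpha / m_eff.
#' @export
bonferroni_threshold <- function(alpha, m_eff) {
  stopifnot(m_eff >= 1)
  alpha / m_eff
}

#' Bonferroni-adjust p-values over effective tests
#'
#' @param p raw p-values.
#' @param m_eff effective number of independent tests.
#' @return min(1, p * m_eff), consistent with [bonferroni_threshold()]:
#'   p < alpha/m_eff iff adjusted p < alpha.
#' @export
adjust_p <- function(p, m_eff) {
  stopifnot(m_eff >= 1)
  pmin(1, p * m_eff)
}

#' Expected null count at a p-value threshold
#'
#' @param threshold per-test p threshold in (0, 1).
#' @param m number of tests.
#' @return list(expected = m * threshold, rounded).
#' @export
expected_null_count <- function(threshold, m) {
  stopifnot(threshold > 0, threshold < 1, m >= 0)
  list(expected = m * threshold, rounded = round(m * threshold))
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null median qchisq(0.5, 1) ~ 0.4549.
#'
#' @param p_values vector of association p-values.
#' @return lambda.
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  chi <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}
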