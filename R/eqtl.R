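# cis/trans eQTL scan: rank-based quantile normalization, per-tissue MAF
# filtering, additive linear models with physiological-state (and optional
# platform) covariates, and Benjamini-Hochberg FDR computed separately
# within the cis and trans classes.

#' Rank-based quantile normalization to the standard normal
#'
#' Per tag: counts are ranked (ties by average rank) and mapped to normal
#' quantiles at (rank - 0.5) / n. Constant tags map to all zeros and are
#' flagged.
#'
#' @param counts tags x samples count matrix (or a single tag vector).
#' @return matrix of the same shape; attribute \code{constant_tags} lists
#'   flagged rows.
#' @export
quantile_normalize <- function(counts) {
  vec <- is.null(dim(counts))
  if (vec) counts <- matrix(counts, nrow = 1)
  n <- ncol(counts)
  stopifnot(n >= 3)
  out <- t(apply(counts, 1, function(x) qnorm((rank(x) - 0.5) / length(x))))
  const <- apply(counts, 1, function(x) length(unique(x)) == 1)
  out[const, ] <- 0
  dimnames(out) <- dimnames(counts)
  if (vec) out <- drop(out)
  attr(out, "constant_tags") <- which(const)
  out
}

#' Per-tissue MAF filter for the eQTL scan
#'
#' MAF is computed within the tissue's samples; variants below
#' \code{maf_min} are dropped. The carrier count (samples carrying at
#' least one minor allele) is reported per retained variant.
#'
#' @param G \code{genotype_table}.
#' @param samples_in_tissue sample ids assayed in this tissue.
#' @param maf_min tissue MAF threshold (e.g. 0.2, or 0.1 for a larger
#'   tissue panel).
#' @return data.frame(id, maf, carriers) for retained variants.
#' @export
eqtl_maf_filter <- function(G, samples_in_tissue, maf_min) {
  stopifnot(length(samples_in_tissue) > 0)
  idx <- match(samples_in_tissue, G$sample_ids)
  if (anyNA(idx)) stop("unknown tissue sample id(s)")
  d <- G$dosages[idx, , drop = FALSE]
  f <- colMeans(d, na.rm = TRUE) / 2
  mafs <- pmin(f, 1 - f)
  minor_is_alt <- f <= 0.5
  carriers <- ifelse(minor_is_alt, colSums(d >= 1, na.rm = TRUE),
                     colSums(d <= 1, na.rm = TRUE))
  keep <- !is.na(mafs) & mafs >= maf_min
  data.frame(id = G$variant_meta$id[keep], maf = unname(mafs[keep]),
             carriers = unname(carriers[keep]), stringsAsFactors = FALSE)
}

#' Scan variants for cis and trans eQTL associations
#'
#' Per variant-tag pair an additive ordinary linear model,
#' normalized expression ~ dosage + covariates, is fit and the dosage term
#' tested; a pair is cis when variant and tag share a scaffold and lie
#' within \code{cis_kb} (inclusive), trans otherwise. Benjamini-Hochberg
#' q-values are computed separately within the cis and within the trans
#' class; records at q below \code{q_max} are flagged significant, and the
#' top trans tag per variant is marked regardless of q.
#'
#' @param variants variant ids (or indices) in \code{G} to test.
#' @param G \code{genotype_table}.
#' @param expr list as from [simulate_expression()]: \code{counts}
#'   (tags x samples), \code{tag_meta} (tag, scaffold, position),
#'   \code{covariates} (sample, state, optional platform).
#' @param cis_kb cis window half-width in kb (inclusive boundary).
#' @param q_max FDR significance threshold.
#' @return data.frame(variant, tag, class, distance_kb, beta, p, q,
#'   significant, top_trans) ordered by p within class.
#' @export
scan_cis_trans <- function(variants, G, expr, cis_kb = 500, q_max = 0.1) {
  samples <- intersect(G$sample_ids, colnames(expr$counts))
  if (length(samples) < 5) stop("too few samples shared with expression data")
  gidx <- if (is.numeric(variants)) variants
          else match(variants, G$variant_meta$id)
  if (anyNA(gidx)) stop("unknown variant id(s)")
  covars <- expr$covariates[match(samples, expr$covariates$sample), ,
                            drop = FALSE]
  terms <- character(0)
  if (length(unique(covars$state)) > 1) terms <- c(terms, "state")
  if ("platform" %in% names(covars) &&
      length(unique(covars$platform)) > 1) terms <- c(terms, "platform")
  Z <- if (length(terms))
    model.matrix(stats::reformulate(terms), data = covars)
  else matrix(1, nrow(covars), 1, dimnames = list(NULL, "(Intercept)"))
  if (qr(Z)$rank < ncol(Z)) {
    bad <- colnames(Z)[is.na(lm.fit(Z, rnorm(nrow(Z)))$coefficients)]
    stop("rank-deficient covariate design: ", paste(bad, collapse = ", "))
  }
  qz <- qr(Z)
  norm_expr <- quantile_normalize(expr$counts[, samples, drop = FALSE])
  RE <- t(apply(norm_expr, 1, function(e) qr.resid(qz, e)))
  dos <- G$dosages[match(samples, G$sample_ids), gidx, drop = FALSE]
  dos <- impute_mean(dos)
  n <- length(samples)
  df <- n - ncol(Z) - 1
  rows <- list()
  vm <- G$variant_meta[gidx, , drop = FALSE]
  tm <- expr$tag_meta
  for (v in seq_along(gidx)) {
    g <- qr.resid(qz, dos[, v])
    sg <- sd(g)
    if (sg == 0) next
    se_tag <- apply(RE, 1, sd)
    r <- as.numeric(RE %*% g) / ((n - 1) * se_tag * sg)
    r[se_tag == 0] <- 0
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    tstat <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tstat), df)
    beta <- r * se_tag / sg
    same_scf <- tm$scaffold == vm$scaffold[v]
    dist_kb <- ifelse(same_scf, abs(tm$position - vm$pos[v]) / 1000,
                      NA_real_)
    is_cis <- same_scf & dist_kb <= cis_kb
    rows[[v]] <- data.frame(variant = vm$id[v], tag = tm$tag,
                            class = ifelse(is_cis, "cis", "trans"),
                            distance_kb = ifelse(is_cis, dist_kb, NA_real_),
                            beta = beta, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(out)
  out$q <- NA_real_
  for (cls in c("cis", "trans")) {
    sel <- out$class == cls
    if (any(sel)) out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out$significant <- out$q < q_max
  out$top_trans <- FALSE
  for (v in unique(out$variant)) {
    tr <- which(out$variant == v & out$class == "trans")
    if (length(tr)) out$top_trans[tr[which.min(out$p[tr])]] <- TRUE
  }
  out[order(out$class, out$p), , drop = FALSE]
}
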