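# Independent-locus pruning of scan hits and phenotypic variance
# partitioning over locus / covariate combinations.

#' Prune associated variants into independent loci by LD
#'
#' Greedy by significance: keep the best remaining hit, drop all
#' same-scaffold hits in moderate-to-high LD with it (dosage r2 at or
#' above \code{r2_max}), repeat. Hits on different scaffolds are never
#' pruned against each other.
#'
#' @param hits an \code{assoc_table} (or data.frame with id, scaffold, p).
#' @param G \code{genotype_table} containing the hit variants.
#' @param r2_max LD pruning boundary (inclusive removal).
#' @return a \code{locus_set}: list(loci = retained hits ordered by p,
#'   clusters = named cluster assignment for every input hit).
#' @export
prune_hits_by_ld <- function(hits, G, r2_max = 0.5) {
  hits <- hits[order(hits$p), , drop = FALSE]
  idx <- match(hits$id, G$variant_meta$id)
  if (anyNA(idx)) stop("hit variant(s) missing from genotype table")
  d <- impute_mean(G$dosages[, idx, drop = FALSE])
  remaining <- seq_len(nrow(hits))
  cluster <- setNames(rep(NA_integer_, nrow(hits)), hits$id)
  keep <- integer(0)
  cl <- 0L
  while (length(remaining)) {
    cl <- cl + 1L
    best <- remaining[1]
    keep <- c(keep, best)
    cluster[best] <- cl
    same_scf <- remaining[hits$scaffold[remaining] == hits$scaffold[best]]
    if (length(same_scf) > 1) {
      r2 <- suppressWarnings(
        cor(d[, best], d[, same_scf, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      linked <- same_scf[drop(r2) >= r2_max]
      cluster[linked] <- cl
      remaining <- setdiff(remaining, linked)
    }
    remaining <- setdiff(remaining, best)
  }
  structure(list(loci = hits[keep, , drop = FALSE],
                 clusters = cluster),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", nrow(x$loci), "independent loci from",
      length(x$clusters), "hits\n")
  invisible(x)
}

#' Phenotypic variance explained by loci and/or fixed effects
#'
#' Ordinary least squares of onset day on the chosen design; reports
#' adjusted and plain R-squared plus the fitted-versus-observed pairs.
#' Collinear columns are dropped with a report.
#'
#' @param y phenotype vector.
#' @param X_fixed fixed-effect design matrix without intercept columns
#'   beyond the first (used in modes \code{fixed_only} and
#'   \code{combined}).
#' @param loci_dosages samples x loci dosage matrix (mean-imputed
#'   internally; used in modes \code{loci_only} and \code{combined}).
#' @param mode which design to fit.
#' @return list(adj_r2, r2, fitted, observed, dropped).
#' @export
variance_explained <- function(y, X_fixed = NULL, loci_dosages = NULL,
                               mode = c("combined", "fixed_only",
                                        "loci_only")) {
  mode <- match.arg(mode)
  parts <- list(intercept = matrix(1, length(y), 1))
  if (mode %in% c("fixed_only", "combined")) {
    if (is.null(X_fixed)) stop("mode needs X_fixed")
    parts$fixed <- as.matrix(X_fixed)
  }
  if (mode %in% c("loci_only", "combined")) {
    if (is.null(loci_dosages)) stop("mode needs loci_dosages")
    parts$loci <- impute_mean(as.matrix(loci_dosages))
  }
  X <- do.call(cbind, parts)
  if (length(y) <= ncol(X)) stop("more predictors than observations")
  qx <- qr(X)
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)),
                                 qx$pivot[seq_len(qx$rank)])]
  fit <- lm.fit(X[, qx$pivot[seq_len(qx$rank)], drop = FALSE], y)
  fitted <- drop(X[, qx$pivot[seq_len(qx$rank)], drop = FALSE] %*%
                   fit$coefficients)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p_eff <- qx$rank - 1
  adj_r2 <- 1 - (1 - r2) * (length(y) - 1) / (length(y) - p_eff - 1)
  list(adj_r2 = adj_r2, r2 = r2, fitted = fitted, observed = y,
       dropped = dropped)
}

#' Forward stepwise selection over top loci
#'
#' Greedy forward selection from the supplied locus dosages, adding at each
#' step the locus that maximizes the adjusted R-squared of the refitted
#' model; the full path is reported.
#'
#' @param y phenotype vector.
#' @param loci_dosages samples x loci dosage matrix (columns named).
#' @param k_max maximum loci to select.
#' @return data.frame path (step, locus, adj_r2), possibly empty.
#' @export
forward_select_loci <- function(y, loci_dosages, k_max = 10) {
  loci_dosages <- impute_mean(as.matrix(loci_dosages))
  if (is.null(colnames(loci_dosages)))
    colnames(loci_dosages) <- paste0("L", seq_len(ncol(loci_dosages)))
  selected <- integer(0)
  path <- data.frame(step = integer(0), locus = character(0),
                     adj_r2 = numeric(0), stringsAsFactors = FALSE)
  k_max <- min(k_max, ncol(loci_dosages))
  for (step in seq_len(k_max)) {
    cand <- setdiff(seq_len(ncol(loci_dosages)), selected)
    if (!length(cand)) break
    scores <- vapply(cand, function(j) {
      variance_explained(y, loci_dosages =
                           loci_dosages[, c(selected, j), drop = FALSE],
                         mode = "loci_only")$adj_r2
    }, numeric(1))
    j <- cand[which.max(scores)]
    selected <- c(selected, j)
    path <- rbind(path, data.frame(step = step,
                                   locus = colnames(loci_dosages)[j],
                                   adj_r2 = max(scores),
                                   stringsAsFactors = FALSE))
  }
  path
}
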