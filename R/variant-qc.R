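# Site-level QC reproducing a multi-caller reduced-representation pipeline:
# restriction to digest-fragment targets, all-caller concordance merging,
# and inclusive-boundary depth / heterozygosity / missingness filters.

#' Restrict variants to sized target fragments
#'
#' Keeps variants whose 1-based position falls inside a target fragment
#' (half-open 0-based intervals) whose length lies in
#' \code{[min_len, max_len]} - the size selection of a double-digest
#' protocol.
#'
#' @param G a \code{genotype_table}.
#' @param targets a [target_regions()] set.
#' @param min_len,max_len fragment-length bounds in bp (inclusive).
#' @return filtered \code{genotype_table}.
#' @export
restrict_to_targets <- function(G, targets, min_len = 125, max_len = 350) {
  t2 <- targets[targets$length >= min_len & targets$length <= max_len, ,
                drop = FALSE]
  vm <- G$variant_meta
  pos0 <- vm$pos - 1L  # VCF 1-based -> interval space
  keep <- logical(nrow(vm))
  for (r in seq_len(nrow(t2))) {
    keep <- keep | (vm$scaffold == t2$scaffold[r] &
                      pos0 >= t2$start[r] & pos0 < t2$end[r])
  }
  subset_genotypes(G, variants = keep)
}

#' Merge call sets by all-caller concordance
#'
#' Variants are retained only when present (same scaffold, position, ref,
#' alt) in every call set. Per-variant genotype concordance is the fraction
#' of samples, among those non-missing in all call sets, whose calls are
#' identical across callers; variants below \code{min_concordance}
#' (inclusive keep at the boundary) are removed. The consensus genotype is
#' the agreeing call, missing where callers disagree or all are missing.
#'
#' @param callsets list of >= 2 \code{genotype_table}s over the same samples.
#' @param min_concordance minimum retained concordance (default 0.95).
#' @return list(genotypes = consensus \code{genotype_table},
#'   stats = per-retained-variant data.frame, n_not_shared,
#'   n_low_concordance).
#' @export
concordance_merge <- function(callsets, min_concordance = 0.95) {
  stopifnot(length(callsets) >= 2)
  ids <- lapply(callsets, `[[`, "sample_ids")
  for (k in seq_along(callsets)[-1]) {
    if (!identical(ids[[1]], ids[[k]]))
      stop("sample sets differ between call sets: ",
           paste(union(setdiff(ids[[1]], ids[[k]]),
                       setdiff(ids[[k]], ids[[1]])), collapse = ", "))
  }
  keys <- lapply(callsets, function(cs)
    with(cs$variant_meta, paste(scaffold, pos, ref, alt)))
  shared <- Reduce(intersect, keys)
  n_not_shared <- length(unique(unlist(keys))) - length(shared)
  aligned <- lapply(seq_along(callsets), function(k) {
    idx <- match(shared, keys[[k]])
    callsets[[k]]$dosages[, idx, drop = FALSE]
  })
  vm <- callsets[[1]]$variant_meta[match(shared, keys[[1]]), , drop = FALSE]
  n <- nrow(aligned[[1]]); mm <- length(shared)
  obs <- !Reduce(`|`, lapply(aligned, is.na))      # non-missing in all
  agree <- matrix(TRUE, n, mm)
  for (k in seq_along(aligned)[-1])
    agree <- agree & (aligned[[k]] == aligned[[1]])
  agree[!obs] <- NA
  denom <- colSums(obs)
  conc <- ifelse(denom > 0, colSums(agree & obs, na.rm = TRUE) / denom,
                 NA_real_)
  keep <- !is.na(conc) & conc >= min_concordance
  n_low <- sum(!keep)
  # consensus: agreeing non-missing call; NA where any disagreement among
  # non-missing calls, or everything missing
  cons <- aligned[[1]]
  n_nonmiss <- Reduce(`+`, lapply(aligned, function(a) !is.na(a)))
  first_val <- aligned[[1]]
  for (k in seq_along(aligned)[-1]) {
    take <- is.na(first_val) & !is.na(aligned[[k]])
    first_val[take] <- aligned[[k]][take]
  }
  disagree <- matrix(FALSE, n, mm)
  for (k in seq_along(aligned))
    disagree <- disagree | (!is.na(aligned[[k]]) & aligned[[k]] != first_val)
  cons <- first_val
  cons[disagree | n_nonmiss == 0] <- NA
  ord <- order(vm$scaffold[keep], vm$pos[keep])
  cons_keep <- cons[, keep, drop = FALSE][, ord, drop = FALSE]
  vm_keep <- vm[keep, , drop = FALSE][ord, , drop = FALSE]
  G <- genotype_table(cons_keep, vm_keep, callsets[[1]]$sample_ids)
  stats <- site_stats(G)
  stats$concordance <- conc[keep][ord]
  list(genotypes = G, stats = stats,
       n_not_shared = as.integer(n_not_shared),
       n_low_concordance = as.integer(n_low))
}

#' Per-variant site statistics
#'
#' Missingness, observed/expected heterozygosity (expected = 2p(1-p) from
#' the pooled observed allele frequency), and biallelic SNP status.
#'
#' @param G a \code{genotype_table}.
#' @param depth optional per-variant mean depth to attach.
#' @return data.frame with one row per variant.
#' @export
site_stats <- function(G, depth = NULL) {
  d <- G$dosages
  n <- nrow(d)
  nm <- colSums(!is.na(d))
  missingness <- 1 - nm / n
  p <- colMeans(d, na.rm = TRUE) / 2
  het_obs <- colMeans(d == 1, na.rm = TRUE)
  het_exp <- 2 * p * (1 - p)
  bases <- c("A", "C", "G", "T")
  is_snp <- G$variant_meta$ref %in% bases & G$variant_meta$alt %in% bases
  data.frame(id = G$variant_meta$id, depth = depth %||% rep(NA_real_, ncol(d)),
             missingness = missingness, het_obs = het_obs,
             het_exp = het_exp,
             het_ratio = ifelse(het_exp > 0, het_obs / het_exp, NA_real_),
             is_biallelic_snp = is_snp, stringsAsFactors = FALSE)
}

#' Apply site-level filters
#'
#' Removal rules, boundaries inclusive as stated: mean depth >= 65x
#' (about 4x the panel mean), observed/expected heterozygosity ratio
#' >= 1.2, missingness > 0.10 (i.e. genotypes present in >= 90% of
#' samples are kept), and non-biallelic records when
#' \code{biallelic_only}.
#'
#' @param G a \code{genotype_table}.
#' @param stats a [site_stats()] data.frame aligned with \code{G} (depth
#'   column used when present).
#' @param max_depth depth removal boundary (inclusive).
#' @param max_het_ratio obs/exp heterozygosity removal boundary (inclusive).
#' @param max_missing largest retained missingness fraction.
#' @param biallelic_only drop non-SNP / non-biallelic records.
#' @return list(genotypes, report) where report counts removals per rule
#'   (a variant may violate several) and survivors.
#' @export
apply_site_filters <- function(G, stats, max_depth = 65, max_het_ratio = 1.2,
                               max_missing = 0.10, biallelic_only = TRUE) {
  stopifnot(nrow(stats) == ncol(G$dosages))
  by_depth <- !is.na(stats$depth) & stats$depth >= max_depth
  by_het <- !is.na(stats$het_ratio) & stats$het_ratio >= max_het_ratio
  by_miss <- stats$missingness > max_missing
  by_allele <- if (biallelic_only) !stats$is_biallelic_snp else
    rep(FALSE, nrow(stats))
  remove <- by_depth | by_het | by_miss | by_allele
  report <- data.frame(rule = c("depth", "het_ratio", "missingness",
                                "not_biallelic", "removed_total", "kept"),
                       count = c(sum(by_depth), sum(by_het), sum(by_miss),
                                 sum(by_allele), sum(remove), sum(!remove)))
  list(genotypes = subset_genotypes(G, variants = !remove), report = report)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; indels and non-SNP records are
#' excluded from the ratio.
#'
#' @param G a \code{genotype_table}.
#' @return list(titv, transitions, transversions); \code{titv} is NA with a
#'   message when no transversions are observed.
#' @export
titv_ratio <- function(G) {
  vm <- G$variant_meta
  bases <- c("A", "C", "G", "T")
  snp <- vm$ref %in% bases & vm$alt %in% bases & vm$ref != vm$alt
  pair <- paste0(vm$ref[snp], vm$alt[snp])
  ti <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- sum(snp) - ti
  list(titv = if (tv == 0) NA_real_ else ti / tv,
       transitions = ti, transversions = tv,
       undefined = tv == 0)
}

#' Minor allele frequency
#'
#' Computed on non-missing genotypes of the chosen sample subset;
#' by construction MAF <= 0.5. All-missing variants get NA.
#'
#' @param G a \code{genotype_table}.
#' @param subset sample ids (default all samples).
#' @return named numeric vector of per-variant MAF.
#' @export
maf <- function(G, subset = NULL) {
  d <- G$dosages
  if (!is.null(subset)) {
    idx <- match(subset, G$sample_ids)
    if (anyNA(idx)) stop("unknown sample id(s) in subset")
    d <- d[idx, , drop = FALSE]
  }
  f <- colMeans(d, na.rm = TRUE) / 2
  out <- pmin(f, 1 - f)
  out[colSums(!is.na(d)) == 0] <- NA_real_
  setNames(out, G$variant_meta$id)
}
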