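# Phenotype, telemetry and expression generators. The trait model mirrors
# the animal model fitted downstream: y = Xb + sum_j g_j beta_j + a + e with
# a ~ N(0, sigma2_g * 2*Phi).

#' Specify the generative trait model for torpor-onset day
#'
#' @param h2 narrow-sense heritability of onset day (additive genetic share
#'   of phenotypic variance, causal loci included).
#' @param var_p total phenotypic variance in days^2 (default SD 7 days,
#'   realistic for an onset spread of a few weeks).
#' @param causal_idx column indices of causal variants (may be empty).
#' @param beta allelic effects in days per alt allele, aligned with
#'   \code{causal_idx}; the study-scale default plants effects of 4-8 days.
#' @param fixed_beta named fixed-effect coefficients: \code{sex} (days added
#'   for males), \code{year} (days per year level step), \code{placement}
#'   (days per day of later hibernaculum placement).
#' @return a \code{trait_model} list.
#' @export
trait_model <- function(h2 = 0.8, var_p = 49, causal_idx = integer(0),
                        beta = numeric(0),
                        fixed_beta = c(sex = 3, year = -2, placement = 0.4)) {
  stopifnot(h2 >= 0, h2 <= 1, length(causal_idx) == length(beta))
  structure(list(h2 = h2, var_p = var_p, causal_idx = as.integer(causal_idx),
                 beta = beta, fixed_beta = fixed_beta),
            class = "trait_model")
}

#' Generate a covariate sheet for a cohort
#'
#' Sex, monitoring year, hibernaculum placement day (calendar ordinal),
#' datalogger implant day, age class (74% juveniles, as in laboratory
#' ground-squirrel cohorts) and body mass.
#'
#' @param sample_ids cohort sample ids.
#' @param seed integer seed.
#' @return data.frame, one row per sample.
#' @export
simulate_covariates <- function(sample_ids, seed = NULL) {
  n <- length(sample_ids)
  with_substream(seed, "covariates", {
    data.frame(sample = sample_ids,
               sex = sample(c("F", "M"), n, replace = TRUE),
               year = sample(2015:2017, n, replace = TRUE),
               placement_day = round(rnorm(n, 274, 5)),
               age_class = sample(c("juvenile", "adult"), n, replace = TRUE,
                                  prob = c(0.74, 0.26)),
               mass = round(rnorm(n, 220, 25)),
               implant_day = round(rnorm(n, 244, 6)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate the torpor-onset phenotype under the animal model
#'
#' y = Xb + sum_j g_j beta_j + a + e, with polygenic values
#' a ~ N(0, sigma2_poly * 2*Phi) and residuals e ~ N(0, (1 - h2) * var_p).
#' The polygenic variance is h2 * var_p minus the variance realized by the
#' planted causal loci, so the decomposition sums consistently.
#'
#' @param G \code{genotype_table} for the cohort.
#' @param kinship true kinship matrix Phi over the cohort samples.
#' @param model a [trait_model()].
#' @param covariates covariate sheet from [simulate_covariates()] (built on
#'   the fly when NULL).
#' @param seed integer seed.
#' @return phenotype sheet (sample, onset_day, sex, year, placement_day,
#'   age_class, mass, implant_day) with attributes \code{realized_h2} and
#'   \code{genetic_values}.
#' @export
simulate_phenotype <- function(G, kinship, model, covariates = NULL,
                               seed = NULL) {
  n <- length(G$sample_ids)
  stopifnot(nrow(kinship) == n)
  if (is.null(covariates)) covariates <- simulate_covariates(G$sample_ids, seed)
  with_substream(seed, "phenotype", {
    X <- model.matrix(~ sex + factor(year) + placement_day, covariates)
    if (qr(X)$rank < ncol(X)) stop("singular covariate design")
    fb <- model$fixed_beta
    b <- c(0, fb[["sex"]],
           fb[["year"]] * seq_len(length(unique(covariates$year)) - 1),
           fb[["placement"]])
    xb <- drop(X %*% b)
    causal <- numeric(n)
    if (length(model$causal_idx)) {
      gc <- G$dosages[, model$causal_idx, drop = FALSE]
      gc[is.na(gc)] <- rep(colMeans(gc, na.rm = TRUE),
                           each = nrow(gc))[is.na(gc)]
      causal <- drop(gc %*% model$beta)
    }
    var_causal <- if (length(model$causal_idx)) var(causal) else 0
    var_poly <- model$h2 * model$var_p - var_causal
    if (var_poly < 0) {
      warning("causal loci exceed h2 * var_p; polygenic variance set to 0")
      var_poly <- 0
    }
    L <- chol(2 * kinship + diag(1e-8, n))
    a <- sqrt(var_poly) * drop(crossprod(L, rnorm(n)))
    e <- rnorm(n, 0, sqrt((1 - model$h2) * model$var_p))
    y <- xb + causal + a + e
    g_tot <- causal + a
    out <- data.frame(sample = G$sample_ids,
                      onset_day = as.integer(round(y)),
                      covariates[, c("sex", "year", "placement_day",
                                     "age_class", "mass", "implant_day")],
                      stringsAsFactors = FALSE)
    attr(out, "genetic_values") <- g_tot
    # heritability is genetic over genetic-plus-residual variance (fixed
    # effects excluded, as in the fitted animal model)
    vg <- var(g_tot); vr <- var(g_tot + e)
    attr(out, "realized_h2") <- if (vr > 0) vg / vr else NA_real_
    out
  })
}

#' Simulate a body-temperature telemetry trace
#'
#' Homeothermic temperature near 37 C with Gaussian noise before onset, a
#' steep drop to torpor near 5 C at the injected onset day (beginning at
#' 12:00), then torpor punctuated by brief arousal spikes. Arousals never
#' precede the injected onset, so ground truth is unambiguous.
#'
#' @param onset_day injected first-torpor day relative to placement
#'   (day 0 = placement); \code{NA} for a trace that never enters torpor.
#' @param placement_day calendar ordinal of hibernaculum placement.
#' @param cadence_minutes datalogger cadence, one of 20, 30, 60.
#' @param noise_sd homeothermic noise SD in degrees C.
#' @param seed integer seed.
#' @param monitoring_start_day first recording day relative to placement.
#' @param n_days trace length in days from monitoring start.
#' @param sample sample id attached to the trace.
#' @return a \code{telemetry_trace}: list(sample, readings, monitoring_start,
#'   placement) with POSIXct timestamps (UTC).
#' @export
simulate_telemetry <- function(onset_day, placement_day = 274,
                               cadence_minutes = 30, noise_sd = 0.5,
                               seed = NULL, monitoring_start_day = -30,
                               n_days = 60, sample = "S1") {
  stopifnot(cadence_minutes %in% c(20, 30, 60))
  if (!is.na(onset_day) && onset_day < monitoring_start_day)
    stop("onset precedes monitoring start")
  base <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
  placement <- base + (placement_day - 1) * 86400
  start <- placement + monitoring_start_day * 86400
  with_substream(seed, paste0("telemetry_", sample), {
    tt <- seq(0, n_days * 86400 - 1, by = cadence_minutes * 60)
    ts <- start + tt
    tday <- as.numeric(difftime(ts, placement, units = "days"))
    temp <- rnorm(length(tt), 37, noise_sd)
    if (!is.na(onset_day)) {
      onset_time <- onset_day + 0.5  # torpor entry begins at noon
      after <- tday >= onset_time
      dt_h <- (tday[after] - onset_time) * 24
      torpor <- 5 + 32 * exp(-dt_h / 0.5)
      # brief arousal spikes, strictly after onset
      ar_start <- seq(onset_day + 5, max(tday) + 10, by = 10)
      for (a in ar_start) {
        sp <- tday[after] >= a & tday[after] < a + 0.5
        torpor[sp] <- 36
      }
      temp[after] <- torpor + rnorm(sum(after), 0, min(noise_sd, 0.3))
    }
    temp <- pmin(pmax(temp, -4.9), 44.9)
    structure(list(sample = sample,
                   readings = data.frame(timestamp = ts, temp_c = temp),
                   monitoring_start = start, placement = placement),
              class = "telemetry_trace")
  })
}

#' Specify synthetic expression data
#'
#' @param n_tags number of transcript tags.
#' @param cis_pairs data.frame(variant_idx, tag_idx, effect) of planted cis
#'   effects (log-scale shift per alt allele); may be empty.
#' @param n_states number of physiological-state levels.
#' @param state_sd SD of per-tag, per-state log-scale effects.
#' @param platform whether a two-level sequencing-platform covariate with a
#'   log-scale batch shift is included.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param base_mean baseline count mean.
#' @return an \code{expression_spec} list.
#' @export
expression_spec <- function(n_tags = 50, cis_pairs = NULL, n_states = 5,
                            state_sd = 0, platform = FALSE,
                            dispersion = 0.2, base_mean = 100) {
  structure(list(n_tags = as.integer(n_tags), cis_pairs = cis_pairs,
                 n_states = as.integer(n_states), state_sd = state_sd,
                 platform = platform, dispersion = dispersion,
                 base_mean = base_mean),
            class = "expression_spec")
}

#' Simulate tag-count expression with planted cis effects
#'
#' Counts are negative binomial; log-mean is shifted additively by
#' dosage x cis-effect for planted pairs, by per-state effects, and by an
#' optional platform batch effect. Tags in planted pairs are placed within
#' 100 kb of their variant; the rest are scattered across scaffolds.
#'
#' @param G cohort \code{genotype_table}.
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @return list(counts tags x samples, tag_meta, covariates, truth).
#' @export
simulate_expression <- function(G, spec, seed = NULL) {
  n <- length(G$sample_ids); m <- ncol(G$dosages)
  cis <- spec$cis_pairs
  if (!is.null(cis) && nrow(cis) && any(cis$variant_idx > m))
    stop("cis target variant outside genotype table")
  with_substream(seed, "expression", {
    vm <- G$variant_meta
    tag_meta <- data.frame(
      tag = paste0("Tag_", seq_len(spec$n_tags)),
      scaffold = sample(unique(vm$scaffold), spec$n_tags, replace = TRUE),
      position = sample.int(max(vm$pos), spec$n_tags, replace = TRUE),
      stringsAsFactors = FALSE)
    if (!is.null(cis) && nrow(cis)) {
      for (r in seq_len(nrow(cis))) {
        v <- cis$variant_idx[r]; tg <- cis$tag_idx[r]
        tag_meta$scaffold[tg] <- vm$scaffold[v]
        tag_meta$position[tg] <- vm$pos[v] + sample(1000:100000, 1)
      }
    }
    state <- factor(sample(paste0("state", seq_len(spec$n_states)), n,
                           replace = TRUE))
    platform <- if (spec$platform)
      factor(sample(c("pfA", "pfB"), n, replace = TRUE)) else NULL
    state_eff <- matrix(rnorm(spec$n_tags * spec$n_states, 0, spec$state_sd),
                        spec$n_tags, spec$n_states)
    pf_eff <- if (spec$platform) rnorm(spec$n_tags, 0, 0.3) else NULL
    logmu <- matrix(log(spec$base_mean), spec$n_tags, n)
    logmu <- logmu + state_eff[, as.integer(state), drop = FALSE]
    if (spec$platform)
      logmu <- logmu + outer(pf_eff, as.numeric(platform == "pfB"))
    if (!is.null(cis) && nrow(cis)) {
      for (r in seq_len(nrow(cis))) {
        g <- G$dosages[, cis$variant_idx[r]]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        logmu[cis$tag_idx[r], ] <- logmu[cis$tag_idx[r], ] + cis$effect[r] * g
      }
    }
    counts <- matrix(rnbinom(spec$n_tags * n, mu = exp(logmu),
                             size = 1 / spec$dispersion),
                     spec$n_tags, n,
                     dimnames = list(tag_meta$tag, G$sample_ids))
    covars <- data.frame(sample = G$sample_ids, state = state,
                         stringsAsFactors = FALSE)
    if (spec$platform) covars$platform <- platform
    list(counts = counts, tag_meta = tag_meta, covariates = covars,
         truth = cis)
  })
}

#' Assemble a full synthetic study cohort
#'
#' Default scale mirrors a laboratory hibernation-genetics study: 119
#' genotyped samples of which 72 are phenotyped, two subpopulations at
#' Balding-Nichols divergence 0.16, 19 litters covering about 80% of the
#' cohort, heritability 0.8 and a few causal loci with allelic effects of
#' 4-8 days. The variant count defaults to 5,000 for tractable simulation
#' studies; a full-scale panel (47,000) is a parameter away.
#'
#' @param n cohort size (genotyped samples).
#' @param n_pheno number of phenotyped (telemetry-monitored) samples.
#' @param m variant count.
#' @param K,fst subpopulation count and Balding-Nichols divergence.
#' @param n_families,litter_sizes,family_fraction litter structure.
#' @param ld_block_size,ld_rho LD block structure of the founder haplotypes.
#' @param h2 generating heritability.
#' @param n_causal number of planted causal variants (allelic effects drawn
#'   from +/- 4..8 days, scaled down if they would exceed h2 * var_p).
#' @param var_p phenotypic variance (days^2).
#' @param seed root seed; all stages draw named substreams from it.
#' @return list(genotypes, labels, pedigree, kinship_true, phenotype,
#'   trait, phenotyped_ids).
#' @export
simulate_cohort <- function(n = 119, n_pheno = 72, m = 5000, K = 2,
                            fst = 0.16, n_families = 19, litter_sizes = 3:7,
                            family_fraction = 0.8, ld_block_size = 10,
                            ld_rho = 0.7, h2 = 0.8, n_causal = 3,
                            var_p = 49, seed = 1) {
  n_off_target <- round(family_fraction * n)
  n_single <- n - n_off_target
  n_parents <- 2L * n_families
  pspec <- population_spec(K = K, fst = fst,
                           sizes = ceiling((n_parents + n_single) / K),
                           m = m)
  freqs <- draw_subpop_frequencies(pspec, seed)
  founders <- simulate_genotypes(freqs, pspec, ld_block_size = ld_block_size,
                                 ld_rho = ld_rho, seed = seed)
  # litters drawn to fill the family block of the cohort exactly
  fspec <- pedigree_spec(n_families, litter_sizes, family_fraction,
                         total_offspring = n_off_target)
  fam <- simulate_families(founders, fspec, seed)
  keep_off <- seq_len(min(n_off_target, length(fam$genotypes$sample_ids)))
  offspring <- subset_genotypes(fam$genotypes, samples = keep_off)
  off_labels <- attr(fam$genotypes, "labels")[keep_off]
  ped <- fam$pedigree[keep_off, , drop = FALSE]
  # unrelated singletons: founders never used as parents
  unused <- setdiff(founders$sample_ids, fam$parents)
  if (length(unused) < n - length(keep_off))
    stop("not enough unused founders for singleton block")
  single_ids <- unused[seq_len(n - length(keep_off))]
  singles <- subset_genotypes(founders, samples = single_ids)
  fl <- attr(founders, "labels")[match(single_ids, founders$sample_ids)]
  dos <- rbind(offspring$dosages, singles$dosages)
  cohort <- genotype_table(dos, founders$variant_meta, rownames(dos))
  labels <- c(off_labels, fl)
  # true kinship: litters are full sibs from unrelated parents
  nn <- length(cohort$sample_ids)
  phi <- matrix(0, nn, nn, dimnames = list(cohort$sample_ids,
                                           cohort$sample_ids))
  diag(phi) <- 0.5
  for (f in unique(ped$family)) {
    idx <- which(cohort$sample_ids %in% ped$id[ped$family == f])
    phi[idx, idx][upper.tri(phi[idx, idx]) | lower.tri(phi[idx, idx])] <- 0.25
  }
  # causal variants at moderate MAF, effects 4-8 days, scaled into h2*var_p
  trait <- with_substream(seed, "trait", {
    f_coh <- colMeans(cohort$dosages, na.rm = TRUE) / 2
    mafs <- pmin(f_coh, 1 - f_coh)
    cand <- which(mafs >= 0.2 & mafs <= 0.45)
    # spread causal loci across distinct LD blocks so effects add ~independently
    causal <- integer(0)
    if (n_causal > 0) {
      cand <- sample(cand)
      for (v in cand) {
        if (all(abs(v - causal) > 5 * ld_block_size)) causal <- c(causal, v)
        if (length(causal) == n_causal) break
      }
      causal <- sort(causal)
    }
    beta <- if (n_causal > 0)
      sample(c(-1, 1), n_causal, TRUE) * runif(n_causal, 4, 8) else numeric(0)
    if (n_causal > 0) {
      gc <- impute_mean(cohort$dosages[, causal, drop = FALSE])
      vc <- var(drop(gc %*% beta))
      if (vc > 0.8 * h2 * var_p) beta <- beta * sqrt(0.8 * h2 * var_p / vc)
    }
    trait_model(h2 = h2, var_p = var_p, causal_idx = causal, beta = beta)
  })
  pheno <- simulate_phenotype(cohort, phi, trait, seed = seed)
  phenotyped <- with_substream(seed, "monitored",
                               sort(sample(cohort$sample_ids, n_pheno)))
  pheno$onset_day[!(pheno$sample %in% phenotyped)] <- NA_integer_
  list(genotypes = cohort, labels = labels, pedigree = ped,
       kinship_true = phi, phenotype = pheno, trait = trait,
       phenotyped_ids = phenotyped)
}
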