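# Synthetic cohort: Balding-Nichols subpopulation divergence, block-copy LD
# haplotypes, litter-structured families, and multi-caller corruption. The
# generator is the ground truth against which every analysis stage is tested.

#' Specify a structured source population
#'
#' @param K number of subpopulations (>= 1).
#' @param fst per-subpopulation Balding-Nichols divergence from the shared
#'   ancestral pool, recycled to length \code{K}; \code{0 <= fst < 1}. Two
#'   subpopulations each at divergence F show pairwise Weir-Cockerham
#'   F_ST of about F.
#' @param sizes founder count per subpopulation, recycled to length \code{K}.
#' @param m number of variants.
#' @param maf_range range of the uniform ancestral allele-frequency draw.
#' @return a \code{population_spec} list.
#' @export
population_spec <- function(K = 2, fst = 0.16, sizes = 50, m = 5000,
                            maf_range = c(0.05, 0.5)) {
  stopifnot(K >= 1, m >= 1, all(fst >= 0), all(fst < 1))
  structure(list(K = as.integer(K), fst = rep_len(fst, K),
                 sizes = rep_len(as.integer(sizes), K), m = as.integer(m),
                 maf_range = maf_range),
            class = "population_spec")
}

#' Draw subpopulation allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies p are uniform on the spec's MAF range; each
#' subpopulation's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean
#' p and variance F p (1-p). F = 0 returns p exactly.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed (or NULL to use the current stream).
#' @return list with \code{ancestral} (length m) and \code{freq}
#'   (K x m matrix of subpopulation frequencies).
#' @export
draw_subpop_frequencies <- function(spec, seed = NULL) {
  if (any(spec$fst >= 1)) stop("fst must be < 1")
  with_substream(seed, "subpop_freq", {
    p <- runif(spec$m, spec$maf_range[1], spec$maf_range[2])
    freq <- matrix(NA_real_, spec$K, spec$m)
    for (k in seq_len(spec$K)) {
      f <- spec$fst[k]
      if (f == 0) {
        freq[k, ] <- p
      } else {
        freq[k, ] <- rbeta(spec$m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }
    }
    list(ancestral = p, freq = freq)
  })
}

# one haplotype under the block-copy LD model: within a block the latent
# uniform that thresholds against allele frequency persists with
# probability ld_rho per variant, inducing positive LD; blocks independent
sim_haplotype <- function(p, block_id, ld_rho) {
  m <- length(p)
  new_block <- c(TRUE, block_id[-1] != block_id[-m])
  refresh <- new_block | (runif(m) >= ld_rho)
  seg <- cumsum(refresh)
  u <- runif(max(seg))[seg]
  as.integer(u < p)
}

#' Simulate founder genotypes with block LD
#'
#' Founders carry two haplotypes each; marginally each variant is
#' Binomial(2, p) in its subpopulation, and within blocks of
#' \code{ld_block_size} consecutive variants a latent copy process with
#' persistence \code{ld_rho} induces positive r2; cross-block LD is zero.
#'
#' @param freqs result of [draw_subpop_frequencies()].
#' @param spec the [population_spec()] used to draw \code{freqs}.
#' @param ld_block_size variants per LD block (1 = fully independent).
#' @param ld_rho per-variant latent persistence probability in [0, 1).
#' @param seed integer seed.
#' @param scaffold_size variants per scaffold in the emitted metadata.
#' @return a \code{genotype_table} with attributes \code{haplotypes}
#'   (list of two n x m 0/1 matrices), \code{labels} (subpopulation per
#'   sample) and \code{block_id}.
#' @export
simulate_genotypes <- function(freqs, spec, ld_block_size = 1, ld_rho = 0,
                               seed = NULL, scaffold_size = 1000L) {
  stopifnot(ld_rho >= 0, ld_rho < 1)
  m <- spec$m
  n <- sum(spec$sizes)
  block_id <- (seq_len(m) - 1L) %/% as.integer(ld_block_size)
  with_substream(seed, "founders", {
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    labels <- rep(seq_len(spec$K), spec$sizes)
    for (i in seq_len(n)) {
      p <- freqs$freq[labels[i], ]
      h1[i, ] <- sim_haplotype(p, block_id, ld_rho)
      h2[i, ] <- sim_haplotype(p, block_id, ld_rho)
    }
    tab <- genotype_table(h1 + h2, synth_variant_meta(m, scaffold_size),
                          paste0("F", seq_len(n)))
    attr(tab, "haplotypes") <- list(h1 = h1, h2 = h2)
    attr(tab, "labels") <- paste0("pop", labels)
    attr(tab, "block_id") <- block_id
    attr(tab, "ld_rho") <- ld_rho
    tab
  })
}

synth_variant_meta <- function(m, scaffold_size = 1000L) {
  idx <- seq_len(m) - 1L
  data.frame(scaffold = paste0("scf", idx %/% scaffold_size + 1L),
             pos = (idx %% scaffold_size) * 997L + 1L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Specify litter-structured families
#'
#' @param n_families number of litters.
#' @param litter_sizes candidate litter sizes, sampled uniformly per family.
#' @param family_fraction target fraction of the assembled cohort belonging
#'   to first-degree (littermate) families.
#' @param total_offspring optional exact total litter size; drawn sizes are
#'   nudged within [1, max(litter_sizes)] until they sum to it.
#' @return a \code{pedigree_spec} list.
#' @export
pedigree_spec <- function(n_families = 19, litter_sizes = 3:7,
                          family_fraction = 0.8, total_offspring = NULL) {
  stopifnot(all(litter_sizes >= 1), n_families >= 1,
            family_fraction >= 0, family_fraction <= 1)
  if (!is.null(total_offspring) &&
      (total_offspring < n_families ||
       total_offspring > n_families * max(litter_sizes)))
    stop("total_offspring unreachable with these litter sizes")
  structure(list(n_families = as.integer(n_families),
                 litter_sizes = as.integer(litter_sizes),
                 family_fraction = family_fraction,
                 total_offspring = total_offspring),
            class = "pedigree_spec")
}

# transmit one gamete: the chosen parental haplotype persists per variant
# with probability 1 - s, s = (1 - ld_rho)/2, so unlinked (ld_rho = 0)
# variants segregate independently and tight blocks co-segregate
transmit_gamete <- function(h1, h2, block_id, ld_rho) {
  m <- length(h1)
  s <- (1 - ld_rho) / 2
  boundary <- c(TRUE, block_id[-1] != block_id[-m])
  prob <- ifelse(boundary, 0.5, s)
  switches <- runif(m) < prob
  state <- cumsum(switches) %% 2L
  ifelse(state == 0L, h1, h2)
}

#' Simulate littermate families from founder parents
#'
#' Each family draws two distinct founder parents from the same
#' subpopulation and produces a litter; each offspring receives one gamete
#' per parent with Mendelian transmission that respects the founders' LD
#' block structure (unlinked variants segregate independently).
#'
#' @param founders a \code{genotype_table} from [simulate_genotypes()]
#'   (haplotypes attribute required).
#' @param spec a [pedigree_spec()].
#' @param seed integer seed.
#' @return list with \code{genotypes} (offspring \code{genotype_table},
#'   haplotypes attached), \code{pedigree} (id, sire, dam, family) and
#'   \code{parents} (founder ids used).
#' @export
simulate_families <- function(founders, spec, seed = NULL) {
  haps <- attr(founders, "haplotypes")
  if (is.null(haps)) stop("founders must carry haplotypes (simulate_genotypes)")
  labels <- attr(founders, "labels") %||% rep("pop1", nrow(founders$dosages))
  block_id <- attr(founders, "block_id") %||% seq_len(ncol(founders$dosages)) - 1L
  ld_rho <- attr(founders, "ld_rho") %||% 0
  n_found <- length(founders$sample_ids)
  if (2L * spec$n_families > n_found)
    stop("founder pool too small for ", spec$n_families, " families")
  with_substream(seed, "families", {
    # pair parents within subpopulation, never selfing, without reuse
    avail <- split(seq_len(n_found), labels)
    fam_pop <- rep_len(names(avail), spec$n_families)
    sire <- dam <- integer(spec$n_families)
    for (f in seq_len(spec$n_families)) {
      pool <- avail[[fam_pop[f]]]
      if (length(pool) < 2) { # fall back to the largest remaining pool
        fam_pop[f] <- names(which.max(vapply(avail, length, integer(1))))
        pool <- avail[[fam_pop[f]]]
        if (length(pool) < 2) stop("founder pool exhausted")
      }
      pair <- sample(pool, 2)
      sire[f] <- pair[1]; dam[f] <- pair[2]
      avail[[fam_pop[f]]] <- setdiff(pool, pair)
    }
    sizes <- spec$litter_sizes[sample.int(length(spec$litter_sizes),
                                          spec$n_families, replace = TRUE)]
    if (!is.null(spec$total_offspring)) {
      while (sum(sizes) > spec$total_offspring) {
        cand <- which(sizes > 1)
        j <- cand[sample.int(length(cand), 1)]
        sizes[j] <- sizes[j] - 1L
      }
      while (sum(sizes) < spec$total_offspring) {
        cand <- which(sizes < max(spec$litter_sizes))
        j <- cand[sample.int(length(cand), 1)]
        sizes[j] <- sizes[j] + 1L
      }
    }
    m <- ncol(founders$dosages)
    n_off <- sum(sizes)
    oh1 <- matrix(0L, n_off, m); oh2 <- matrix(0L, n_off, m)
    ped <- data.frame(id = character(n_off), sire = character(n_off),
                      dam = character(n_off), family = integer(n_off),
                      stringsAsFactors = FALSE)
    r <- 0L
    for (f in seq_len(spec$n_families)) {
      for (k in seq_len(sizes[f])) {
        r <- r + 1L
        oh1[r, ] <- transmit_gamete(haps$h1[sire[f], ], haps$h2[sire[f], ],
                                    block_id, ld_rho)
        oh2[r, ] <- transmit_gamete(haps$h1[dam[f], ], haps$h2[dam[f], ],
                                    block_id, ld_rho)
        ped$id[r] <- sprintf("FAM%02d_%d", f, k)
        ped$sire[r] <- founders$sample_ids[sire[f]]
        ped$dam[r] <- founders$sample_ids[dam[f]]
        ped$family[r] <- f
      }
    }
    tab <- genotype_table(oh1 + oh2, founders$variant_meta, ped$id)
    attr(tab, "haplotypes") <- list(h1 = oh1, h2 = oh2)
    attr(tab, "labels") <- fam_pop[ped$family]
    attr(tab, "block_id") <- block_id
    attr(tab, "ld_rho") <- ld_rho
    list(genotypes = tab, pedigree = ped,
         parents = founders$sample_ids[unique(c(sire, dam))])
  })
}

#' Kinship expected from a pedigree
#'
#' Standard recursive pedigree kinship: founders are unrelated and
#' non-inbred, phi(i,i) = 0.5 (plus half the parental kinship), and a
#' non-founder's kinship with anyone older is the average of its parents'.
#'
#' @param ids all individual ids, founders first or any order.
#' @param sire,dam parent ids aligned with \code{ids}; NA for founders.
#' @return symmetric kinship matrix over \code{ids}.
#' @export
pedigree_kinship <- function(ids, sire, dam) {
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- match(sire, ids); di <- match(dam, ids)
  # order so parents precede children
  done <- is.na(si) & is.na(di)
  order_idx <- which(done)
  phi[cbind(order_idx, order_idx)] <- 0.5
  remaining <- setdiff(seq_len(n), order_idx)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(si[i]) || si[i] %in% order_idx) &&
        (is.na(di[i]) || di[i] %in% order_idx)
    }, logical(1))]
    if (!length(ready)) stop("pedigree has a cycle or missing parents")
    for (i in ready) {
      for (j in order_idx) {
        v <- mean(c(if (!is.na(si[i])) phi[si[i], j] else 0,
                    if (!is.na(di[i])) phi[di[i], j] else 0))
        phi[i, j] <- phi[j, i] <- v
      }
      pk <- if (!is.na(si[i]) && !is.na(di[i])) phi[si[i], di[i]] else 0
      phi[i, i] <- 0.5 + 0.5 * pk
      order_idx <- c(order_idx, i)
    }
    remaining <- setdiff(remaining, ready)
  }
  phi
}

#' Corrupt a genotype table into discordant multi-caller call sets
#'
#' Emulates independent variant callers: per caller, each genotype is
#' replaced by a different random genotype with probability
#' \code{discord_rate} and set missing with probability
#' \code{missing_rate}; per-variant mean depth is drawn from
#' \code{depth_profile}.
#'
#' @param G clean \code{genotype_table}.
#' @param n_callers number of call sets.
#' @param discord_rate,missing_rate per-genotype corruption probabilities.
#' @param depth_profile function(m) returning per-variant mean depths, a
#'   vector of length m, or a scalar. Default Gamma with mean 16x.
#' @param seed integer seed.
#' @return list with \code{callsets} (list of \code{genotype_table}) and
#'   \code{depth} (per-variant mean depth).
#' @export
corrupt_callsets <- function(G, n_callers = 3, discord_rate = 0,
                             missing_rate = 0, depth_profile = NULL,
                             seed = NULL) {
  stopifnot(discord_rate >= 0, discord_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  m <- ncol(G$dosages); n <- nrow(G$dosages)
  with_substream(seed, "callsets", {
    depth <- if (is.null(depth_profile)) {
      rgamma(m, shape = 4, rate = 0.25)
    } else if (is.function(depth_profile)) {
      depth_profile(m)
    } else rep_len(depth_profile, m)
    callsets <- vector("list", n_callers)
    for (k in seq_len(n_callers)) {
      d <- G$dosages
      if (discord_rate > 0) {
        flip <- which(runif(n * m) < discord_rate & !is.na(d))
        if (length(flip)) {
          cur <- d[flip]
          d[flip] <- vapply(cur, function(g) sample(setdiff(0:2, g), 1),
                            numeric(1))
        }
      }
      if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
      callsets[[k]] <- genotype_table(d, G$variant_meta, G$sample_ids)
    }
    list(callsets = callsets, depth = depth)
  })
}
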