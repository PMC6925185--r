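---
title: "Methods: from body-temperature telemetry to torpor-onset genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from body-temperature telemetry to torpor-onset genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`torporscan` implements the statistical chain of a hibernation-timing
mapping study: a ground squirrel cohort is monitored with intraperitoneal
body-temperature dataloggers, genotyped by reduced-representation
(double-digest) sequencing, and the first day of autumn torpor is mapped
as a quantitative trait. This vignette records the models, the tunable
parameters, the numerical decisions, and what the synthetic ground-truth
generator does and does not emulate.

## 1. The phenotype: first day of torpor

Dataloggers record body temperature every 20, 30 or 60 minutes.
`window_average()` averages the trace in non-overlapping 4-hour windows;
`call_first_torpor()` takes the earliest window whose mean falls **to or
below 25 °C** (inclusive, matching homeothermy near 34–39 °C against
torpor a few degrees above ambient); `qualify_and_center()` converts the
hit to integer days from hibernaculum placement (day 0 = placement,
earlier days negative) and disqualifies calls with fewer than 10 days of
continuous prior monitoring.

Decisions the source protocol leaves open, fixed here:

* **Window alignment.** Windows are aligned to the local midnight of the
  first recording day. A window is dated by the calendar day containing
  its start. Alignment only matters when the temperature drop straddles a
  window boundary; the generator places onsets at midday so tests are
  alignment-robust, and `window_hours` is a parameter.
* **"Continuous monitoring".** Operationalized as no recording gap longer
  than twice the median cadence before the onset window (`max_gap_factor
  = 2`); longer gaps disqualify the call with a stated reason.

## 2. Variant quality control

Call sets from several variant callers over the same samples are merged
by `concordance_merge()`: a variant is kept only if present (same
scaffold, position, ref, alt) in **all** call sets, and its genotype
concordance — the fraction of samples, among those non-missing in every
call set, with identical calls — must reach 0.95 (kept at the boundary).
The concordance denominator excludes samples missing in any call set; the
all-agree (rather than pairwise) definition is the stricter reading of a
multi-caller concordance rule and is the one implemented. The consensus
genotype is the agreeing call; disagreements become missing.

`apply_site_filters()` then removes sites with mean depth ≥ 65×
(about four times a typical 16× mean), observed/expected heterozygosity
ratio ≥ 1.2 (expected heterozygosity `2p(1-p)` from the pooled allele
frequency — per-subpopulation expectations would require known labels),
missingness > 10 % (genotypes present in ≥ 90 % of samples are kept), and
non-biallelic records. All boundaries are inclusive on the removal side,
following the quoted ≥ conventions. Note that the heterozygosity-ratio
rule is intrinsically stochastic: a clean Hardy–Weinberg site at n ≈ 100
samples has a ratio sampling SD large enough that some clean low-MAF
sites exceed 1.2. The filter report therefore accounts for every removal
by rule, and the tests verify removals against an independent per-site
oracle rather than asserting that clean data passes untouched.
Indels participate in all filters but are excluded from the Ti/Tv ratio.

## 3. Population structure and relatedness

* `ld_prune()` mirrors the common `--indep-pairwise 50 10 0.5` scheme;
  within a violating pair the lower-MAF variant is removed, ties broken
  by later position — deterministic.
* `pca_genotypes()` decomposes the mean-imputed, frequency-standardized
  dosage matrix; each component's sign is fixed by making its
  largest-magnitude loading positive, so results are reproducible.
* `robust_kinship()` is the allele-sharing (KING-robust) estimator
  `phi = (N_HetHet - 2 N_OppHom) / (N_Het_i + N_Het_j)`. Its companion
  "zero-sharing" matrix is the **IBD0-scale** estimate: the
  opposite-homozygote count divided by its expectation for unrelated
  pairs, `sum(2 p^2 q^2)` over jointly typed sites. On this scale
  parent-offspring pairs sit near 0, full sibs near 0.25 and unrelated
  pairs near 1, which is what makes the parent-offspring (< 0.005) versus
  full-sib (> 0.1) cutoffs of `classify_and_build_families()` coherent;
  the raw opposite-homozygote fraction would not separate these classes
  at realistic allele frequencies. Both cutoffs are tuned for panels of
  ~10⁴ variants and are arguments.
* Across strongly diverged subpopulations the allele-sharing estimator is
  **not** unbiased: its expectation for unrelated cross-population pairs
  is `-F/(1-F)` under a Balding–Nichols divergence `F`. This is a known
  property (and the reason one computes relatedness within divergent
  subsets separately). `adjusted_kinship()` removes it by conditioning on
  ancestry: per variant, individual allele frequencies are predicted by
  regressing half-dosages on the supplied principal components, and
  kinship is computed from the ancestry-centered residuals — the
  individual-allele-frequency formulation of structure-conditional
  kinship, one published choice among several. The GRM is `2 × kinship`,
  symmetrized and eigenvalue-clipped at zero.
* `pairwise_fst()` is the Weir–Cockerham two-population
  variance-components estimator, averaged over variants as a ratio of
  sums; monomorphic (pooled) sites are excluded.
* Relationship degrees follow the powers-of-two kinship bins
  (1st degree: `[2^-2.5, 2^-1.5)`); families are connected components of
  the first-degree graph.

## 4. The animal model

Heritability and association both rest on
`y = Xb + a + e`, `a ~ N(0, sigma²_g K)`, `e ~ N(0, sigma²_e I)`, with
`K` the GRM.

* **Fixed-effect selection** (`select_fixed_effects()`): backward
  elimination from the OLS model on {sex, year, implant day, age class,
  placement day, mass}; a term is dropped when dropping it lowers AIC and
  the nested-model p ≥ 0.05. Perfectly collinear candidates are removed
  first (later-listed loses). This AIC-guarded rule retains a spurious
  1-df term whenever its chi-square exceeds 2 (~16 % of the time), which
  is intrinsic to AIC stepwise selection, not a defect; strongly
  generating covariates are retained essentially always.
* **REML** (`fit_null_reml()`): the restricted likelihood is profiled to
  one dimension in `h²` on the eigenbasis of `K` within the orthogonal
  complement of `X`. The complement basis is constructed explicitly by QR
  before the eigendecomposition — projecting with `I - H` and
  eigendecomposing the full matrix can leak the fixed-effect directions
  into genuinely null directions of a singular `K` (e.g. duplicate
  samples) and miss boundary solutions. Variance components are
  non-negative by construction; `h²` at the 0 or 1 boundary (within 1e-6)
  and near-flat restricted likelihoods (range < 1e-4 across an interior
  grid, e.g. `K = I`) are flagged, not rejected.
* **Gibbs sampler** (`mcmc_heritability()`): conjugate updates for the
  fixed effects (flat prior), the rotated breeding values (independent
  normals in the eigenbasis of `K`, making each sweep O(n)), and both
  variances under inverse-gamma(shape = nu/2, scale = nu·V/2) priors with
  V = 1, nu = 0.002 — the conventional weakly informative choice. Three
  chains; study-scale settings are 10⁶ iterations, 10⁵ burn-in, thinning
  200, all scalable. The posterior mode of `h²` uses a Gaussian kernel
  density with Silverman bandwidth; the 95 % interval is highest
  posterior density; Gelman–Rubin statistics are floored at 1 (values
  below 1 arise only when between-chain variance is ~0 and carry no
  diagnostic meaning), and values above 1.1 trigger a warning. Near the
  `h² = 1` boundary this prior is nearly scale-invariant in the residual
  variance and piles posterior mass at the boundary, so the posterior
  mode can sit above the REML maximum for strongly heritable data — the
  same shape as the study posterior this package emulates (mode 0.99
  against a boundary REML fit). The sampler's agreement with REML is
  therefore validated in the interior of the parameter space.
* **Score-test scan** (`assoc_scan()`): per variant `U = x'Py`,
  `V = x'Px`, `p` from `U²/V ~ chi-square(1)`, `beta = U/V` in days per
  counted (alt) allele, with the allele identity stored. Missing dosages
  are mean-imputed at scan time only (never at I/O time); zero-variance
  variants are skipped and counted. The chi-square tail is exact only
  asymptotically: at n ≈ 70 the far tail (p ~ 1e-3) is conservative by
  tens of percent, approaching calibration by n ≈ 600–1000. Simulation
  studies that score tail counts are therefore sized accordingly (below).
* **Multiple testing**: `effective_tests()` implements the simpleM
  eigenvalue procedure per scaffold over consecutive blocks; the
  variance-captured constant C = 0.995 and block size 100 are the
  procedure's conventional values, both arguments. `bonferroni_threshold
  (alpha, M_eff)` and `adjust_p()` are consistent by construction;
  `genomic_lambda()` is the median implied chi-square over 0.4549.

## 5. Permutation and stability-selection corroboration

* `permutation_null_suite()` permutes the phenotype across samples
  (covariates stay put — the quoted design reassigns the phenotype alone;
  a flag flips this), refits the null model each round, rescans, and
  records per-round suggestive-threshold counts plus the ranked-p
  envelope (per-rank median and 2.5–97.5 % interval). The suggestive
  threshold defaults to the cohort-specific value `10/m` (ten expected
  null hits), the construction the published 2.13e-4 figure follows.
* `hd_quantile()` is the Harrell–Davis estimator (incomplete-beta weights
  over order statistics). `exceedance_probability()` inverts it on a
  quantile grid of step 1e-4 (binary search over the monotone map),
  returning `1 - q` at the smallest `q` whose estimate reaches the
  observed count. The grid step bounds the resolution; the estimator's
  sampling SD at 500 permutation rounds is ~0.005 at the 98th percentile
  and shrinks with rounds, so precise exceedance statements use the full
  5,000-round null.
* `compass_split()` draws overlapping two-thirds subsets: |A| = |B| =
  round(2n/3), overlap round(n/3), the remainder split into equal
  complementary halves; an odd remainder is absorbed into the overlap so
  the subsets stay equal and A ∪ B covers every sample (n = 72 gives
  48/48 with overlap 24). `compass_corroborate()` validates a variant in
  a resample iff max(p_A, p_B) ≤ alpha (1e-3), and corroborates iff the
  validated fraction reaches eta (0.6) over 100 resamples.
  `compass_calibrate()` samples background variants uniformly across the
  effect-size distribution by equal-width binning (20 bins over the beta
  range, uniform over occupied bins, without replacement) — "uniformly
  across the distribution" is not otherwise specified — and scores the
  corroborated count against the 0.05 type-I bound.

## 6. Variance partitioning and eQTLs

`prune_hits_by_ld()` greedily keeps the most significant hit and drops
same-scaffold hits with dosage r² ≥ 0.5 (composite LD on dosages,
consistent with `ld_prune()`; different scaffolds never prune each
other). `variance_explained()` reports **adjusted** R² from OLS for
fixed-only, loci-only and combined designs (the adjusted figure is what
the emulated study plots), dropping collinear columns with a report.
`forward_select_loci()` reports the greedy adjusted-R² path.

`scan_cis_trans()` fits, per variant-tag pair, normalized expression ~
dosage + physiological state (+ platform where present) by OLS and tests
the dosage term; expression is first rank-normalized per tag to standard
normal quantiles at (rank − 0.5)/n with average ranks for ties
(`quantile_normalize()`; constant tags map to zeros and are flagged). A
pair is cis iff same scaffold and distance ≤ 500 kb (inclusive).
Benjamini–Hochberg q-values are computed separately within the cis and
trans classes, the convention of the matrix-eQTL style tools; records
with q < 0.1 are flagged and the top trans tag per variant is marked
regardless of q. Per-tissue MAF filters (0.2, or 0.1 for a larger
panel) are computed within the tissue's samples, with minor-allele
carrier counts reported, not enforced.

## 7. The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that generates the
conditions the analysis assumes:

* **Structure**: Balding–Nichols subpopulation frequencies
  (Beta(p(1−F)/F, (1−p)(1−F)/F); two subpopulations at F = 0.16 by
  default, matching the within-colony divergence scale of the emulated
  cohort, with 0.3–0.5 available for the strong-divergence regime).
  Chosen over coalescent simulation for speed and parameter control.
* **LD**: haplotypes from a block-copy latent-uniform process — within
  blocks of `ld_block_size` variants the latent uniform persists with
  probability `ld_rho` per variant; blocks are independent. This gives
  controllable within-block r² and exactly zero cross-block LD.
* **Families**: 19 litters of 3–7 offspring covering 80 % of the default
  119-sample cohort (litter sizes nudged to hit the family block
  exactly); parents are founders outside the cohort, so first-degree
  structure is littermate sibships, as in the emulated colony. Gametes
  follow the block structure (switch probability (1−ld_rho)/2, so
  unlinked variants segregate independently).
* **Phenotype**: y = Xb + Σ g_j beta_j + a + e with a drawn on the true
  pedigree kinship; default h² = 0.8 (the emulated study's band is
  0.6–1.0), phenotypic SD 7 days (an onset spread of a few weeks), three
  causal loci with allelic effects drawn from ±4–8 days, rescaled only if
  they would exceed the h² budget, and placed in distinct LD blocks.
  Realized h² is recorded as genetic over genetic-plus-residual variance.
* **Telemetry**: homeothermy at 37 °C with Gaussian noise, a steep
  exponential drop to ~5 °C starting at noon of the injected onset day,
  and arousal spikes that begin ≥ 5 days after onset — cosmetic and never
  before onset, so ground truth is unambiguous.
* **Expression**: negative-binomial counts with log-scale cis effects,
  per-state effects and an optional platform batch.
* **Call sets**: per-caller genotype flips and missingness at given
  rates, gamma-distributed site depths (mean 16×).

What the generator does **not** emulate: coalescent genealogies and
recombination maps, sequencing reads and base quality, genotyping error
correlated with depth or allele balance, admixed individuals,
multigenerational pedigrees, selection, or expression count structure
beyond a single dispersion parameter. Passing tests therefore demonstrate
the statistical machinery under the stated generative assumptions, not
robustness to every artefact of real reduced-representation data.

## 8. Simulation study sizes

The package's validation studies use sizes chosen for statistical, not
historical, reasons; they are recorded here as package decisions.
Heritability recovery: 200 replicates at n = 500 (litters of four),
generating h² ∈ {0.3, 0.6, 0.9}; sampler-versus-REML agreement at n =
300, 50,000 iterations, at h² = 0.6 where the posterior is interior
(§4). Score-test size and genomic lambda: 200 replicates of a null
family-structured cohort, n = 300, m = 5,000. Permutation suite: an
unrelated cohort of n = 1,000 with m = 1,000 independent variants —
unrelated because the per-round count is Binomial only under
exchangeability, and n sized so the chi-square tail is accurate at the
suggestive threshold (§4); 500 rounds for the count mean, 5,000 for the
exceedance quantile (§5). Corroboration: planted allelic effect of two
phenotypic SD at n = 120 over 20 generator seeds, 50 resamples; null
corroboration on 200 variants of the null cohort. Structure: F_ST
recovery at n = 100 per subpopulation and m = 5,000; kinship at 10⁴
unlinked variants. Telemetry: 500 noisy traces across cadences.

## 9. Known limitations

* The score test's chi-square tail is conservative at small n (§4);
  small-cohort suggestive-threshold counts run below m·t, which is a
  property of the test statistic shared with the tools this pipeline
  emulates, and is precisely what the permutation null is for.
* The Gibbs sampler's weakly informative inverse-gamma prior attracts
  the posterior to the h² = 1 boundary for strongly heritable data; mode
  summaries there reflect the prior (§4). Parameter-expanded priors
  would mitigate this but are out of scope.
* `adjusted_kinship()` removes ancestry-aligned genetic covariance; when
  causal variance is itself aligned with ancestry (differentiated causal
  loci), heritability against the adjusted GRM is attenuated. Recovery
  studies therefore score against pedigree-true relatedness.
* VCF handling is deliberately minimal: biallelic diploid GT only,
  multiallelic records excluded with a count; no BAM/FASTQ handling, no
  indexing.
* Pedigree reconstruction stops at first-degree components; no
  multigenerational likelihoods.
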