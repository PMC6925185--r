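# torporscan

Quantitative genetics of hibernation timing. `torporscan` implements the
full inference chain of a torpor-onset mapping study in a hibernating
ground squirrel: it calls the first day of autumn torpor from
body-temperature datalogger traces, performs multi-caller variant quality
control on reduced-representation genotypes, estimates population
structure and relatedness, fits the animal model to estimate narrow-sense
heritability (by REML and by a Gibbs sampler), runs a score-test
genome-wide association scan with effective-test multiple-testing
correction, corroborates hits by phenotype permutation and
complementary-pairs stability selection, partitions phenotypic variance
over independent loci, and scans candidate loci for cis/trans expression
QTLs. A synthetic cohort generator with Balding–Nichols population
divergence, block linkage disequilibrium and litter-structured families
provides ground truth for every stage.

## The model

The phenotype is the first day of torpor, `y` (integer days; day 0 = the
day of placement into the hibernaculum, earlier days negative), called as
the first 4-hour window of the telemetry trace whose mean body temperature
falls to or below 25 °C, qualified by at least 10 days of continuous prior
monitoring.

Heritability and association both rest on the animal model

    y = X b + a + e,   a ~ N(0, sigma²_g · K),   e ~ N(0, sigma²_e · I)

where `X` holds the selected fixed effects (sex, year of monitoring,
hibernaculum placement day), `K = 2 Φ` is the genetic relatedness matrix
built from ancestry-adjusted kinship coefficients, and narrow-sense
heritability is `h² = sigma²_g / (sigma²_g + sigma²_e)`. REML maximizes
the restricted likelihood in the eigenspace of `K` projected orthogonal to
`X`; the Bayesian fit is a Gibbs sampler with conjugate updates under
inverse-gamma (V = 1, nu = 0.002) priors, three chains, with the posterior
mode and 95 % highest-posterior-density interval reported. Per-variant
association uses the score statistic `U = xᵀPy`, `V = xᵀPx` against
chi-square(1), with `P` the null-model projection, and `β = U/V` in days
per allele. The genome-wide threshold is `alpha / M_eff`, where `M_eff`
comes from the simpleM eigenvalue procedure, and the suggestive threshold
is set so that ~10 null variants are expected. Corroboration uses (i) a
permutation null of the suggestive-count with the Harrell–Davis quantile
estimator inverted to an exceedance probability, and (ii) ComPaSS-style
stability selection over overlapping two-thirds subsets (|A| = |B| =
2n/3, overlap n/3; validated iff max(p_A, p_B) ≤ 1e-3; corroborated iff
validated in ≥ 60 % of 100 resamples).

## Worked example

```r
library(torporscan)

# a study-scale synthetic cohort: 119 genotyped, 72 phenotyped,
# 19 litters, two subpopulations at F_ST 0.16, h2 = 0.8
coh <- simulate_cohort(n = 119, n_pheno = 72, m = 5000, seed = 42)
G <- coh$genotypes

# population structure and relatedness: LD prune -> PCA ->
# ancestry-adjusted kinship -> GRM
pruned <- ld_prune(G)
pc <- pca_genotypes(subset_genotypes(G, variants = pruned))
phi_hat <- adjusted_kinship(G, pc$scores[, 1])

# animal model on the phenotyped subset (PC1 as a fixed effect alongside
# sex, year and placement day)
keep <- which(!is.na(coh$phenotype$onset_day))
y <- coh$phenotype$onset_day[keep]
X <- cbind(model.matrix(~ sex + factor(year) + placement_day,
                        coh$phenotype[keep, ]),
           pc1 = pc$scores[keep, 1])
fit <- fit_null_reml(y, X, make_grm(phi_hat[keep, keep]))
fit
#> null_model_fit: sigma2_g = 15.436, sigma2_e = 15.957, h2 = 0.492

# association scan and multiple-testing correction
G72 <- subset_genotypes(G, samples = keep)
assoc <- assoc_scan(fit, G72, maf_min = 0.05)
meff <- effective_tests(G72)
c(m_eff = meff, threshold = signif(bonferroni_threshold(0.1, meff), 3))
#>     m_eff threshold
#>  3.09e+03  3.24e-05
genomic_lambda(assoc$p)
#> [1] 1.000085

# the three planted causal loci (true allelic effects 4.3-5.3 days)
assoc[assoc$id %in% G$variant_meta$id[coh$trait$causal_idx],
      c("id", "maf", "beta", "p")]
#>                      id   maf  beta        p
#> scf2:719835 scf2:719835 0.354 -3.73 0.043120
#> scf3:572279 scf3:572279 0.215 -4.32 0.000587
#> scf5:868388 scf5:868388 0.438  4.27 0.005419
```

The inflation factor of 1.000 shows the adjusted GRM plus leading
component absorbing the family and two-subpopulation structure. All three
planted loci surface with effect estimates near their generating values,
but at n = 72 none clears the genome-wide threshold — the motivation for
the permutation and stability-selection corroboration stages
(`permutation_null_suite()`, `compass_corroborate()`). The fitted h² of
0.49 sits below the generating 0.8 because the ancestry component absorbs
the causal variance that is aligned with the subpopulation axis; the
heritability acceptance studies therefore score recovery against
pedigree-true relatedness (see the methods vignette).

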