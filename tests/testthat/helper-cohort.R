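# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

# mid-sized default-style cohort used across modules
small_cohort <- function() {
  cached("small_cohort", function()
    simulate_cohort(n = 80, n_pheno = 60, m = 2000, n_families = 10,
                    litter_sizes = 3:8, seed = 101))
}

# unrelated single-population founders, unlinked variants
plain_founders <- function(n = 60, m = 1500, seed = 202, fst = 0,
                           K = 1, ld_block_size = 1, ld_rho = 0) {
  spec <- population_spec(K = K, fst = fst, sizes = ceiling(n / K), m = m)
  freqs <- draw_subpop_frequencies(spec, seed)
  simulate_genotypes(freqs, spec, ld_block_size = ld_block_size,
                     ld_rho = ld_rho, seed = seed)
}

# null-model ingredients for the phenotyped subset of a cohort
scan_inputs <- function(coh) {
  keep <- which(!is.na(coh$phenotype$onset_day))
  list(y = coh$phenotype$onset_day[keep],
       X = model.matrix(~ sex + factor(year) + placement_day,
                        coh$phenotype[keep, ]),
       GRM = make_grm(coh$kinship_true[keep, keep]),
       G = subset_genotypes(coh$genotypes, samples = keep),
       keep = keep)
}

# tiny hand-written VCF fixture
write_mini_vcf <- function(path, extra_lines = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chr1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    paste(c("chr1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
            "0|1", "./.", "0/0"), collapse = "\t"),
    extra_lines)
  writeLines(lines, path)
  path
}
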