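# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# one population, 240 cows in 6 half-sib groups, 3 chromosomes x 150 SNPs,
# features chr1 + chr2 with 60% of the genetic variance
small_cfg <- function(seed = 42L, ...) {
  sim_config(
    n_populations = 1L, n_per_population = 240L, n_sires_per_population = 6L,
    chromosomes = data.frame(label = paste0("chr", 1:3), n_snps = 150L,
                             length_bp = 5e7),
    feature_chromosomes = c("chr1", "chr2"),
    feature_variance_fractions = c(0.35, 0.25),
    n_qtl = 90L, n_herds_per_population = 4L,
    qtl_effect_scaling_per_population = 1,
    seed = seed, ...
  )
}

small_dataset <- function() cached("small_dataset", function() simulate_dataset(small_cfg()))

small_geno_imputed <- function() cached("small_geno", function() {
  mean_impute_missing(small_dataset()$geno)
})

small_grm <- function() cached("small_grm", function() vanraden_grm(small_geno_imputed()))

small_grmset <- function() cached("small_grmset", function() {
  feature_grms(small_geno_imputed(), c("chr1", "chr2"))
})

small_design <- function() cached("small_design", function() {
  build_fixed_design(small_dataset()$phenotypes)
})

small_y <- function() {
  ph <- small_dataset()$phenotypes
  stats::setNames(ph$trait, ph$animal_id)
}

small_vc <- function() cached("small_vc", function() {
  reml_fit(small_y(), small_design(), list(genomic = small_grm()))
})

# tiny hand-constructed genotype matrix for exact-arithmetic tests
toy_geno <- function(counts, chr = "chr1", pos = NULL, pop = "pop1") {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  genotype_matrix(
    counts,
    data.frame(snp_id = paste0("s", seq_len(p)), chr = rep_len(chr, p), pos = pos),
    data.frame(animal_id = paste0("a", seq_len(nrow(counts))),
               population = pop, sire_id = NA_character_, dam_id = NA_character_)
  )
}

# pedigree-only phenotype table (no genotypes) for validation-plan tests
toy_pedigree <- function(n_groups, group_size, n_singles = 0L, seed = 1L) {
  ids <- character(0); sires <- character(0); dams <- character(0)
  for (g in seq_len(n_groups)) {
    ids <- c(ids, sprintf("g%02d_c%03d", g, seq_len(group_size)))
    sires <- c(sires, rep(sprintf("sire%02d", g), group_size))
    dams <- c(dams, sprintf("g%02d_d%03d", g, seq_len(group_size)))
  }
  if (n_singles > 0) {
    ids <- c(ids, sprintf("single%03d", seq_len(n_singles)))
    sires <- c(sires, sprintf("lone_sire%03d", seq_len(n_singles)))
    dams <- c(dams, sprintf("lone_dam%03d", seq_len(n_singles)))
  }
  data.frame(animal_id = ids, sire_id = sires, dam_id = dams,
             stringsAsFactors = FALSE)
}

# ridge-regression SNP-BLUP oracle: effects from centered allele counts,
# lambda = sigma_e^2 * s / sigma_a^2, mapped back to individual values
snp_blup_oracle <- function(geno, freqs, resid_gls, sigma_a, sigma_e) {
  p <- freqs[geno$map$snp_id]
  Z <- sweep(geno$geno, 2, 2 * p, "-")
  s <- 2 * sum(p * (1 - p))
  lambda <- sigma_e * s / sigma_a
  a_hat <- solve(crossprod(Z) + diag(lambda, ncol(Z)), crossprod(Z, resid_gls))
  as.numeric(Z %*% a_hat)
}
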