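# simdata: genotype simulation, QTL architecture, phenotype model

test_that("simulate_genotypes returns valid allele counts with the requested shape", {
  cfg <- sim_config(
    n_populations = 2L, n_per_population = c(50L, 50L),
    n_sires_per_population = 5L,
    chromosomes = data.frame(label = paste0("chr", 1:3), n_snps = 100L, length_bp = 1e7),
    feature_chromosomes = "chr1", feature_variance_fractions = 0.5,
    n_qtl = 50L, seed = 3L
  )
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$geno), c(100L, 300L))
  expect_true(all(g$geno %in% 0:2))
  expect_equal(nrow(g$map), 300L)
  expect_setequal(unique(g$samples$population), c("pop1", "pop2"))
  # every non-founder has exactly one sire label; 5 groups per population
  expect_false(anyNA(g$samples$sire_id))
  expect_equal(length(unique(g$samples$sire_id)), 10L)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 99L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$geno$geno, d2$geno$geno)
  expect_identical(d1$tgv, d2$tgv)
  expect_identical(d1$phenotypes, d2$phenotypes)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_sires_per_population = 0L), class = "config_error")
  expect_error(sim_config(feature_chromosomes = "chr99"), class = "config_error")
  expect_error(sim_config(feature_variance_fractions = c(0.8, 0.3, 0.2)),
               class = "config_error")
  expect_error(sim_config(dim_range = c(-5, 100)), class = "config_error")
  expect_error(sim_config(chromosomes = data.frame(
    label = "chr1", n_snps = 1L, length_bp = 1e6
  ), feature_chromosomes = "chr1", feature_variance_fractions = 0.5),
  class = "config_error")
})

test_that("zero drift gives equal expected allele frequencies across populations", {
  # chi-square comparison of allele counts between two populations per SNP.
  # The binomial-sampling oracle needs near-independent allele draws, so this
  # configuration uses one sire per cow and a founder pool much larger than
  # the sample; family structure would otherwise inflate the variance.
  n_reject <- 0L; n_total <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(
      n_populations = 2L, n_per_population = c(150L, 150L),
      n_sires_per_population = 150L, n_founder_haplotypes = 4000L,
      chromosomes = data.frame(label = "chr1", n_snps = 60L, length_bp = 3e7),
      feature_chromosomes = "chr1", feature_variance_fractions = 0.5,
      n_qtl = 20L, drift = 0, seed = seed
    )
    g <- simulate_genotypes(cfg)
    pop <- g$samples$population
    for (j in seq_len(ncol(g$geno))) {
      x1 <- sum(g$geno[pop == "pop1", j]); x2 <- sum(g$geno[pop == "pop2", j])
      n1 <- 2L * sum(pop == "pop1"); n2 <- 2L * sum(pop == "pop2")
      if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
      pv <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2))$p.value)
      n_total <- n_total + 1L
      if (!is.na(pv) && pv < 0.01) n_reject <- n_reject + 1L
    }
  }
  expect_lt(n_reject / n_total, 0.05)
})

test_that("QTL variance shares match the configured fractions within 1 point", {
  d <- small_dataset()  # fractions (0.35, 0.25), rest 0.40, total variance 1
  shares <- apply(d$tgv[, c("chr1", "chr2", "rest")], 2, stats::var)
  shares <- shares / sum(shares) * 100
  expect_lt(max(abs(shares - c(35, 25, 40))), 1)
  # absolute calibration: variances match the fractions themselves
  expect_equal(unname(apply(d$tgv[, c("chr1", "chr2", "rest")], 2, stats::var)),
               c(0.35, 0.25, 0.40), tolerance = 0.011)
  # total = sum of partials, exactly
  expect_equal(d$tgv$total,
               unname(rowSums(d$tgv[, c("chr1", "chr2", "rest")])))
})

test_that("h2_target = 0 yields all-zero genetic values", {
  cfg <- small_cfg(seed = 5L, h2_target = 0)
  d <- simulate_dataset(cfg)
  expect_true(all(d$tgv$total == 0))
})

test_that("per-population QTL scaling scales partial-value variance quadratically", {
  cfg <- sim_config(
    n_populations = 3L, n_per_population = c(400L, 100L, 400L),
    n_sires_per_population = 20L,
    chromosomes = data.frame(label = paste0("chr", 1:2), n_snps = 200L, length_bp = 5e7),
    feature_chromosomes = "chr1", feature_variance_fractions = 0.5,
    n_qtl = 100L, drift = 0,
    qtl_effect_scaling_per_population = c(1, 1, 0.5), seed = 11L
  )
  d <- simulate_dataset(cfg)
  pop <- d$geno$samples$population
  v1 <- stats::var(d$tgv$total[pop == "pop1"])
  v3 <- stats::var(d$tgv$total[pop == "pop3"])
  expect_equal(v3 / v1, 0.25, tolerance = 0.35)
})

test_that("phenotype model recovers the target heritability", {
  h2_emp <- vapply(1:6, function(seed) {
    cfg <- sim_config(
      n_populations = 1L, n_per_population = 1000L, n_sires_per_population = 25L,
      chromosomes = data.frame(label = "chr1", n_snps = 200L, length_bp = 5e7),
      feature_chromosomes = "chr1", feature_variance_fractions = 0.6,
      n_qtl = 80L, h2_target = 0.4, seed = seed
    )
    d <- simulate_dataset(cfg)
    ph <- d$phenotypes
    det <- cfg$mu + cfg$wilmink_b1 * ph$dim + cfg$wilmink_b2 * exp(-0.05 * ph$dim)
    g <- d$tgv$total
    e <- ph$trait - det - g  # residual + parity/herd shifts
    # remove the class effects by within-cell centering before the ratio
    resid <- stats::resid(stats::lm(e ~ factor(ph$parity) + factor(ph$herd)))
    stats::var(g) / (stats::var(g) + stats::var(resid))
  }, numeric(1))
  expect_gt(mean(h2_emp), 0.35)
  expect_lt(mean(h2_emp), 0.45)
})

test_that("degenerate phenotype settings reduce to the genetic value", {
  cfg <- sim_config(
    n_populations = 1L, n_per_population = 120L, n_sires_per_population = 4L,
    chromosomes = data.frame(label = paste0("chr", 1:2), n_snps = 80L, length_bp = 1e7),
    feature_chromosomes = "chr1", feature_variance_fractions = 0.5,
    n_qtl = 40L, wilmink_b1 = 0, wilmink_b2 = 0, parity_levels = 1L,
    n_herds_per_population = 1L, parity_sd = 0, herd_sd = 0,
    h2_target = 0.999999, seed = 8L
  )
  d <- simulate_dataset(cfg)
  expect_equal(d$phenotypes$trait - cfg$mu, d$tgv$total, tolerance = 1e-2)
})

test_that("Wilmink term contributes exactly b2 at DIM = 0", {
  expect_identical(wilmink_covariate(0), 1)
  cfg <- sim_config(
    n_populations = 1L, n_per_population = 60L, n_sires_per_population = 3L,
    chromosomes = data.frame(label = "chr1", n_snps = 40L, length_bp = 1e7),
    feature_chromosomes = "chr1", feature_variance_fractions = 1,
    n_qtl = 10L, dim_range = c(0, 0), wilmink_b1 = 0, wilmink_b2 = 1,
    parity_levels = 1L, n_herds_per_population = 1L, parity_sd = 0, herd_sd = 0,
    h2_target = 0, seed = 2L
  )
  d <- simulate_dataset(cfg)
  # y = mu + 1 * exp(0) + e with unit residual variance; mean near mu + 1
  expect_equal(mean(d$phenotypes$trait), cfg$mu + 1, tolerance = 0.5)
})

test_that("multiplicative residual mode produces mean-dependent spread", {
  cfg <- small_cfg(seed = 13L, residual_cv_multiplicative = 0.3)
  d <- simulate_dataset(cfg)
  ph <- d$phenotypes
  expect_true(all(ph$trait > 0))
  # skewness of a lognormal-multiplied trait is positive
  z <- ph$trait - mean(ph$trait)
  expect_gt(mean(z^3) / stats::sd(z)^3, 0.2)
})

test_that("half-sib groups show genomic relationship near 0.25", {
  g <- small_geno_imputed()
  G <- small_grm()$G
  sire <- small_dataset()$geno$samples$sire_id
  same_sire <- outer(sire, sire, "==")
  off <- upper.tri(G)
  expect_lt(abs(mean(G[off & same_sire]) - 0.25), 0.05)
  expect_lt(abs(mean(G[off & !same_sire])), 0.05)
})

test_that("plink round trip preserves the simulated allele counts", {
  d <- small_dataset()
  prefix <- file.path(tempdir(), "simrt")
  write_plink(d$geno, prefix)
  back <- read_genotypes(prefix, "plink-text")
  expect_equal(unname(back$geno), unname(d$geno$geno))
  expect_equal(back$map$pos, d$geno$map$pos)
  expect_equal(back$samples$sire_id, d$geno$samples$sire_id)
  unlink(paste0(prefix, c(".ped", ".map")))
})
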