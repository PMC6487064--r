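# Multi-population half-sib simulator: genotypes, QTL architectures enriched
# on feature chromosomes, and phenotypes with the dairy fixed-effect structure
# (parity, herd, linear days-in-milk and a Wilmink exponential lactation term).

#' Simulation configuration
#'
#' Defines the simulated world: several related cow populations with half-sib
#' sire groups, a SNP genome partitioned across chromosomes, a quantitative
#' trait whose genetic variance is concentrated on designated "feature"
#' chromosomes, and a phenotype model with parity, herd, days-in-milk (DIM)
#' and Wilmink `exp(-0.05 * DIM)` fixed effects.
#'
#' Founder allele frequencies are drawn from a Beta(2, 2) truncated to
#' \[0.05, 0.95\]; each population perturbs them on the logit scale with
#' variance `drift`, so populations stay closely related for small drift.
#' Linkage disequilibrium arises from gamete mosaics copied in blocks from a
#' finite founder-haplotype pool; block lengths are exponential with mean
#' `block_length_bp`.
#'
#' @param n_populations number of populations
#' @param n_per_population integer vector of cows per population
#' @param n_sires_per_population sires per population (half-sib group count);
#'   must be >= 1
#' @param chromosomes data.frame with columns `label`, `n_snps`, `length_bp`
#' @param feature_chromosomes labels of chromosomes carrying major QTL, each
#'   granted its own random effect downstream
#' @param h2_target narrow-sense heritability of the simulated trait, in
#'   (0, 1); 0 requests a trait with no genetic signal
#' @param feature_variance_fractions fraction of the total genetic variance on
#'   each feature chromosome; the remainder goes to the rest of the genome
#' @param n_qtl total number of causal SNPs
#' @param qtl_effect_scaling_per_population multiplier applied to all QTL
#'   effects within each population (default all 1 = shared architecture)
#' @param parity_levels number of parity classes
#' @param n_herds_per_population herds per population
#' @param dim_range (min, max) days in milk, sampled uniformly
#' @param mu overall trait mean, trait units
#' @param wilmink_b1 regression coefficient on DIM (trait units per day)
#' @param wilmink_b2 regression coefficient on `exp(-0.05 * DIM)`
#' @param parity_sd,herd_sd SD of the normal from which each parity/herd
#'   effect is drawn once
#' @param residual_cv_multiplicative optional coefficient of variation; when
#'   set, residual noise is multiplicative log-normal so the phenotype SD
#'   scales with its mean (the right-skew motivating a log transform)
#' @param drift variance of the logit-scale allele-frequency perturbation
#'   between populations (0 = identical expected frequencies)
#' @param n_founder_haplotypes size of the per-population haplotype pool
#' @param block_length_bp mean length of copied haplotype blocks, bp
#' @param seed integer RNG seed; all simulation randomness derives from it
#'
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_populations = 3L,
                       n_per_population = c(250L, 200L, 500L),
                       n_sires_per_population = 5L,
                       chromosomes = data.frame(
                         label = paste0("chr", 1:5),
                         n_snps = 600L,
                         length_bp = 1e8
                       ),
                       feature_chromosomes = c("chr1", "chr2", "chr3"),
                       h2_target = 0.4,
                       feature_variance_fractions = c(0.3, 0.2, 0.1),
                       n_qtl = 300L,
                       qtl_effect_scaling_per_population = rep(1, n_populations),
                       parity_levels = 3L,
                       n_herds_per_population = 8L,
                       dim_range = c(5, 305),
                       mu = 10,
                       wilmink_b1 = 0.01,
                       wilmink_b2 = -2,
                       parity_sd = 0.5,
                       herd_sd = 0.5,
                       residual_cv_multiplicative = NULL,
                       drift = 0.01,
                       n_founder_haplotypes = 30L,
                       block_length_bp = 2e6,
                       seed = 1L) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    n_per_population = as.integer(n_per_population),
    n_sires_per_population = as.integer(n_sires_per_population),
    chromosomes = chromosomes,
    feature_chromosomes = as.character(feature_chromosomes),
    h2_target = h2_target,
    feature_variance_fractions = feature_variance_fractions,
    n_qtl = as.integer(n_qtl),
    qtl_effect_scaling_per_population = qtl_effect_scaling_per_population,
    parity_levels = as.integer(parity_levels),
    n_herds_per_population = as.integer(n_herds_per_population),
    dim_range = dim_range,
    mu = mu,
    wilmink_b1 = wilmink_b1,
    wilmink_b2 = wilmink_b2,
    parity_sd = parity_sd,
    herd_sd = herd_sd,
    residual_cv_multiplicative = residual_cv_multiplicative,
    drift = drift,
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    block_length_bp = block_length_bp,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ch <- cfg$chromosomes
  if (!all(c("label", "n_snps", "length_bp") %in% names(ch))) {
    gfb_stop("chromosomes needs columns label, n_snps, length_bp", "config_error")
  }
  if (!all(cfg$feature_chromosomes %in% ch$label)) {
    gfb_stop("feature chromosome labels must be a subset of chromosome labels",
             "config_error")
  }
  if (length(cfg$n_per_population) != cfg$n_populations) {
    gfb_stop("n_per_population length must equal n_populations", "config_error")
  }
  if (cfg$n_sires_per_population < 1L) {
    gfb_stop("n_sires_per_population must be >= 1", "config_error")
  }
  if (any(ch$n_snps < 2L)) {
    gfb_stop("each chromosome needs at least 2 SNPs", "config_error")
  }
  fr <- cfg$feature_variance_fractions
  if (length(fr) != length(cfg$feature_chromosomes)) {
    gfb_stop("one variance fraction per feature chromosome required", "config_error")
  }
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    gfb_stop("variance fractions must be nonnegative and sum to <= 1", "config_error")
  }
  if (cfg$h2_target < 0 || cfg$h2_target >= 1) {
    gfb_stop("h2_target must be in [0, 1)", "config_error")
  }
  if (cfg$dim_range[1] < 0) gfb_stop("dim_range minimum must be >= 0", "config_error")
  if (length(cfg$qtl_effect_scaling_per_population) != cfg$n_populations ||
      any(cfg$qtl_effect_scaling_per_population < 0)) {
    gfb_stop("qtl_effect_scaling_per_population: one nonnegative multiplier per population",
             "config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_populations, "populations (",
      paste(x$n_per_population, collapse = "/"), "cows ),",
      sum(x$chromosomes$n_snps), "SNPs on", nrow(x$chromosomes),
      "chromosomes; features:", paste(x$feature_chromosomes, collapse = ", "),
      "\n  h2 =", x$h2_target, "; feature variance fractions:",
      paste(x$feature_variance_fractions, collapse = ", "),
      "; seed =", x$seed, "\n")
  invisible(x)
}

# One gamete as a mosaic over a finite haplotype pool: walk each chromosome,
# copying from a randomly chosen pool haplotype and switching donors at
# exponential(mean block_length_bp) breakpoints.
mosaic_gamete <- function(pool, map, block_length_bp) {
  out <- integer(nrow(map))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    pos <- map$pos[idx]
    len <- max(pos)
    n_seg <- stats::rpois(1L, len / block_length_bp) + 1L
    cuts <- sort(stats::runif(n_seg - 1L, 0, len))
    donors <- sample.int(nrow(pool), n_seg, replace = TRUE)
    seg <- findInterval(pos, cuts) + 1L
    out[idx] <- pool[cbind(donors[seg], idx)]
  }
  out
}

# Recombine two parental haplotypes: Poisson(length_bp / 1e8) crossovers per
# chromosome at uniform positions (about 1 Morgan per 100 Mbp).
recombine_gamete <- function(h1, h2, map) {
  out <- integer(length(h1))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    pos <- map$pos[idx]
    len <- max(pos)
    n_co <- stats::rpois(1L, len / 1e8)
    cuts <- sort(stats::runif(n_co, 0, len))
    segment <- findInterval(pos, cuts)  # 0..n_co
    use_first <- (segment + sample(0:1, 1L)) %% 2L == 0L
    out[idx] <- ifelse(use_first, h1[idx], h2[idx])
  }
  out
}

#' Simulate multi-population half-sib genotypes
#'
#' Draws founder allele frequencies from a shared pool, perturbs them per
#' population (bounded drift keeps cross-population relationships nonzero),
#' builds a per-population founder haplotype pool, and creates cows as
#' sire-by-unknown-dam offspring: the paternal gamete is a recombinant of the
#' sire's two haplotypes (so paternal half sibs have genomic relationship
#' around 0.25) and the maternal gamete is a fresh pool mosaic.
#'
#' @param config a [sim_config()]
#' @return a [genotype_matrix()] with population, sire and dam labels
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genotypes"), {
    ch <- config$chromosomes
    map <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
      pos <- sort(sample.int(as.integer(ch$length_bp[i]), ch$n_snps[i]))
      data.frame(chr = ch$label[i], pos = pos, stringsAsFactors = FALSE)
    }))
    p_total <- nrow(map)
    map$snp_id <- sprintf("%s_snp%06d", map$chr, seq_len(p_total))

    # founder frequencies: Beta(2,2) truncated to [0.05, 0.95] by rejection
    p0 <- numeric(p_total)
    todo <- seq_len(p_total)
    while (length(todo)) {
      draw <- stats::rbeta(length(todo), 2, 2)
      ok <- draw >= 0.05 & draw <= 0.95
      p0[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }

    n_pop <- config$n_populations
    all_geno <- vector("list", n_pop)
    samples <- vector("list", n_pop)
    for (k in seq_len(n_pop)) {
      pk <- if (config$drift > 0) {
        stats::plogis(stats::qlogis(p0) + stats::rnorm(p_total, 0, sqrt(config$drift)))
      } else p0
      pool <- matrix(
        stats::rbinom(config$n_founder_haplotypes * p_total, 1L, rep(pk, each = config$n_founder_haplotypes)),
        nrow = config$n_founder_haplotypes
      )
      n_sires <- config$n_sires_per_population
      sire_h1 <- lapply(seq_len(n_sires), function(s) mosaic_gamete(pool, map, config$block_length_bp))
      sire_h2 <- lapply(seq_len(n_sires), function(s) mosaic_gamete(pool, map, config$block_length_bp))

      n_k <- config$n_per_population[k]
      sire_of <- rep_len(seq_len(n_sires), n_k)
      G <- matrix(0L, nrow = n_k, ncol = p_total)
      for (i in seq_len(n_k)) {
        s <- sire_of[i]
        pat <- recombine_gamete(sire_h1[[s]], sire_h2[[s]], map)
        mat <- mosaic_gamete(pool, map, config$block_length_bp)
        G[i, ] <- pat + mat
      }
      ids <- sprintf("pop%d_cow%04d", k, seq_len(n_k))
      all_geno[[k]] <- G
      samples[[k]] <- data.frame(
        animal_id = ids,
        population = sprintf("pop%d", k),
        sire_id = sprintf("pop%d_sire%02d", k, sire_of),
        dam_id = sprintf("pop%d_dam%04d", k, seq_len(n_k)),
        stringsAsFactors = FALSE
      )
    }
    geno <- do.call(rbind, all_geno)
    smp <- do.call(rbind, samples)
    rownames(geno) <- smp$animal_id
    colnames(geno) <- map$snp_id
    genotype_matrix(geno, map[, c("snp_id", "chr", "pos")], smp)
  })
}

#' Assign QTL effects concentrated on feature chromosomes
#'
#' Samples causal SNPs per chromosome group (each feature chromosome and the
#' pooled rest of the genome, proportional to SNP counts), draws standard
#' normal allele-substitution effects, then rescales each group's effects so
#' the realized variance of its partial genetic value matches the configured
#' fraction of a unit total genetic variance. Optional per-population
#' multipliers scale the effects when genetic architectures differ between
#' populations; they are applied after the variance calibration, which is done
#' at multiplier 1 over all individuals.
#'
#' @param geno a [genotype_matrix()]
#' @param config a [sim_config()]
#' @return list with `effects` (data.frame: snp_id, chr, group, effect) and
#'   `tgv` (data.frame of per-individual total and per-group partial additive
#'   values; the total is the exact sum of the partials)
#' @export
assign_qtl_effects <- function(geno, config) {
  validate_sim_config(config)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!all(config$feature_chromosomes %in% geno$map$chr)) {
    gfb_stop("feature chromosomes missing from the genotype map", "config_error")
  }
  if (config$n_qtl > ncol(geno$geno)) {
    gfb_stop("n_qtl exceeds the number of SNPs", "config_error")
  }
  with_seed(derive_seed(config$seed, "qtl"), {
    feats <- config$feature_chromosomes
    groups <- c(feats, "rest")
    fractions <- c(config$feature_variance_fractions,
                   1 - sum(config$feature_variance_fractions))
    names(fractions) <- groups
    group_of_snp <- ifelse(geno$map$chr %in% feats, geno$map$chr, "rest")

    n_in_group <- table(factor(group_of_snp, levels = groups))
    alloc <- pmax(1L, round(config$n_qtl * as.numeric(n_in_group) / sum(n_in_group)))
    names(alloc) <- groups
    alloc <- pmin(alloc, as.integer(n_in_group))

    n <- nrow(geno$geno)
    partials <- matrix(0, nrow = n, ncol = length(groups),
                       dimnames = list(geno$samples$animal_id, groups))
    eff_list <- list()
    zero_trait <- config$h2_target == 0
    pop_idx <- match(geno$samples$population,
                     sprintf("pop%d", seq_len(config$n_populations)))
    multipliers <- config$qtl_effect_scaling_per_population[pop_idx]
    multipliers[is.na(multipliers)] <- 1

    for (g in groups) {
      snps <- which(group_of_snp == g)
      # only polymorphic candidates can carry variance
      pvar <- apply(geno$geno[, snps, drop = FALSE], 2, stats::var)
      poly <- snps[pvar > 0]
      k <- min(alloc[[g]], length(poly))
      qtl <- if (k > 0) sort(sample(poly, k)) else integer(0)
      a <- stats::rnorm(length(qtl))
      raw <- as.numeric(geno$geno[, qtl, drop = FALSE] %*% a)
      v <- stats::var(raw)
      scale <- if (zero_trait || fractions[[g]] == 0 || v == 0) 0 else sqrt(fractions[[g]] / v)
      a <- a * scale
      part <- as.numeric(geno$geno[, qtl, drop = FALSE] %*% a)
      partials[, g] <- (part - mean(part)) * multipliers
      if (length(qtl)) {
        eff_list[[g]] <- data.frame(
          snp_id = geno$map$snp_id[qtl], chr = geno$map$chr[qtl],
          group = g, effect = a, stringsAsFactors = FALSE
        )
      }
    }
    tgv <- data.frame(animal_id = geno$samples$animal_id,
                      total = rowSums(partials), partials,
                      check.names = FALSE, stringsAsFactors = FALSE)
    list(effects = do.call(rbind, c(eff_list, list(make.row.names = FALSE))),
         tgv = tgv)
  })
}

#' Simulate phenotypes under the dairy fixed-effect model
#'
#' `y = mu + parity + herd + b1 * DIM + b2 * exp(-0.05 * DIM) + g + e`.
#' Parity and herd effects are drawn once per level from normals with the
#' configured SDs; DIM is uniform over `dim_range`; the residual variance is
#' set from the empirical variance of `g` so that `var(g) / (var(g) + var(e))`
#' equals `h2_target`. When `residual_cv_multiplicative` is set the additive
#' deterministic part is multiplied by log-normal noise with that coefficient
#' of variation, giving residual SD proportional to the mean (heteroscedastic,
#' right-skewed; the case where a log transform is warranted).
#'
#' @param geno a [genotype_matrix()]
#' @param tgv the `tgv` element of [assign_qtl_effects()], aligned to `geno`
#' @param config a [sim_config()]
#' @return phenotype data.frame: animal_id, population, sire_id, dam_id, herd,
#'   parity, dim, trait
#' @export
simulate_phenotypes <- function(geno, tgv, config) {
  validate_sim_config(config)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!identical(tgv$animal_id, geno$samples$animal_id)) {
    gfb_stop("tgv is not aligned to the genotype individuals", "alignment_error")
  }
  if (config$dim_range[1] < 0) gfb_stop("dim_range would produce DIM < 0", "config_error")
  with_seed(derive_seed(config$seed, "phenotypes"), {
    n <- nrow(geno$geno)
    smp <- geno$samples
    parity <- sample.int(config$parity_levels, n, replace = TRUE)
    parity_eff <- stats::rnorm(config$parity_levels, 0, config$parity_sd)
    pop_idx <- as.integer(factor(smp$population, levels = unique(smp$population)))
    herd_local <- sample.int(config$n_herds_per_population, n, replace = TRUE)
    herd <- sprintf("%s_herd%02d", smp$population, herd_local)
    herd_levels <- unique(herd)
    herd_eff <- stats::rnorm(length(herd_levels), 0, config$herd_sd)
    names(herd_eff) <- herd_levels
    dim_days <- stats::runif(n, config$dim_range[1], config$dim_range[2])

    g <- tgv$total
    vg <- stats::var(g)
    h2 <- config$h2_target
    ve <- if (vg > 0 && h2 > 0) vg * (1 - h2) / h2 else 1

    det <- config$mu + parity_eff[parity] + herd_eff[herd] +
      config$wilmink_b1 * dim_days +
      config$wilmink_b2 * exp(-0.05 * dim_days) + g
    if (is.null(config$residual_cv_multiplicative)) {
      y <- det + stats::rnorm(n, 0, sqrt(ve))
    } else {
      cv <- config$residual_cv_multiplicative
      sdlog <- sqrt(log(1 + cv^2))
      if (any(det <= 0)) {
        gfb_stop("multiplicative residual mode needs a positive deterministic mean",
                 "config_error")
      }
      y <- det * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    data.frame(
      animal_id = smp$animal_id, population = smp$population,
      sire_id = smp$sire_id, dam_id = smp$dam_id,
      herd = herd, parity = parity, dim = dim_days, trait = y,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genotypes()], [assign_qtl_effects()]
#' and [simulate_phenotypes()] under one configuration.
#'
#' @param config a [sim_config()]
#' @return list with `geno`, `effects`, `tgv`, `phenotypes`
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  qtl <- assign_qtl_effects(geno, config)
  phenos <- simulate_phenotypes(geno, qtl$tgv, config)
  list(geno = geno, effects = qtl$effects, tgv = qtl$tgv, phenotypes = phenos)
}
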