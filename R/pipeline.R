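# Scenario orchestration: single-population GBLUP, combined-population GBLUP
# and combined-population GFBLUP, from raw genotypes and phenotypes to a
# reliability report. One REML on the full analysis set supplies the
# variance components and the heritability; per-replicate BLUPs mask the
# validation cows' phenotypes.

#' Scenario specification
#'
#' @param scenario `"single_gblup"`, `"combined_gblup"`, `"combined_gfblup"`
#'   or `"single_gfblup"`
#' @param target_population the population whose cows are validated (single_*
#'   scenarios use only this population's data; combined_* scenarios add the
#'   other populations to the reference)
#' @param trait phenotype column name (default `"trait"`)
#' @param feature_chromosomes required for gfblup scenarios: chromosomes
#'   granted their own random effect
#' @param transform log-transform the trait before modeling (natural log;
#'   for right-skewed traits with residual SD growing with the mean)
#' @param seed integer seed; all scenario randomness derives from it
#' @return object of class `scenario_spec`
#' @export
scenario_spec <- function(scenario = c("single_gblup", "combined_gblup",
                                       "combined_gfblup", "single_gfblup"),
                          target_population,
                          trait = "trait",
                          feature_chromosomes = NULL,
                          transform = FALSE,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(target_population) != 1L) {
    gfb_stop("target_population must name exactly one population", "config_error")
  }
  if (grepl("gfblup", scenario) && length(feature_chromosomes) < 1L) {
    gfb_stop("gfblup scenarios need at least one feature chromosome", "config_error")
  }
  structure(list(scenario = scenario, target_population = target_population,
                 trait = trait, feature_chromosomes = feature_chromosomes,
                 transform = transform, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Run one genomic-prediction scenario end to end
#'
#' Steps: per-population SNP QC, common-SNP intersection (combined
#' scenarios), DIM filter, optional log transform, mean imputation, GRM
#' construction (whole-genome or feature-partitioned), full-data REML
#' (heritability and, for GFBLUP, variance proportions), validation-plan
#' construction on the target population, per-replicate masked BLUP,
#' corrected phenotypes from the single-population traditional GBLUP fit,
#' and the replicate reliability summary.
#'
#' @param spec a [scenario_spec()]
#' @param geno a multi-population [genotype_matrix()]
#' @param phenos phenotype data.frame (animal_id, population, sire_id,
#'   dam_id, herd, parity, dim, trait columns)
#' @param strategy validation-split strategy, see [make_validation_plan()]
#' @param n_val validation-set size per replicate
#' @param n_reps number of replicates
#' @param maf_min,min_class_count QC thresholds, see [qc_filter()]
#' @param min_dim DIM filter threshold, see [filter_dim()]
#' @param verbose log record counts after each stage
#' @return object of class `scenario_result`: list(spec, reliability
#'   (a `reliability_report`), h2, vc, variance_proportions (gfblup only),
#'   plans, qc_reports, n_records)
#' @export
run_scenario <- function(spec, geno, phenos,
                         strategy = "sire_group_holdout",
                         n_val = 100L, n_reps = 5L,
                         maf_min = 0.05, min_class_count = 10L,
                         min_dim = 60, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(geno, "genotype_matrix"))
  say <- function(...) if (verbose) message("[", spec$scenario, "] ", ...)
  single <- grepl("^single", spec$scenario)
  gfblup <- grepl("gfblup", spec$scenario)
  pops_used <- if (single) spec$target_population else unique(geno$samples$population)
  if (!spec$target_population %in% geno$samples$population) {
    gfb_stop(paste0("target population ", spec$target_population, " not in the data"),
             "config_error")
  }

  # per-population QC, then intersect the post-QC common SNPs
  per_pop <- split_by_population(geno)[pops_used]
  qc <- lapply(per_pop, qc_filter, maf_min = maf_min,
               min_class_count = min_class_count)
  qc_reports <- lapply(qc, `[[`, "report")
  filtered <- lapply(qc, `[[`, "geno")
  g_all <- if (length(filtered) > 1L) intersect_common_snps(filtered) else filtered[[1]]
  say(ncol(g_all$geno), " SNPs after QC", if (length(filtered) > 1L) " + intersection")

  ph <- phenos[phenos$population %in% pops_used, , drop = FALSE]
  ph <- filter_dim(ph, min_dim)
  if (!spec$trait %in% names(ph)) {
    gfb_stop(paste0("trait column ", spec$trait, " missing"), "config_error")
  }
  ph <- ph[!is.na(ph[[spec$trait]]), , drop = FALSE]
  ph <- ph[ph$animal_id %in% g_all$samples$animal_id, , drop = FALSE]
  say(nrow(ph), " phenotyped, genotyped records after the DIM filter")
  if (nrow(ph) < 3L * n_val) {
    warning("analysis set is small relative to the validation size")
  }
  y <- ph[[spec$trait]]
  if (spec$transform) {
    if (any(y <= 0)) gfb_stop("log transform requires strictly positive trait values", "domain_error")
    y <- log(y)
  }
  names(y) <- ph$animal_id

  g_all <- mean_impute_missing(subset_genotypes(g_all, individuals = ph$animal_id))
  freqs <- allele_frequencies(g_all)
  grms <- if (gfblup) {
    grm_components(feature_grms(g_all, spec$feature_chromosomes, freqs))
  } else {
    list(genomic = vanraden_grm(g_all, freqs = freqs))
  }

  X <- build_fixed_design(ph)
  vc <- reml_fit(y, X, grms)
  h2 <- heritability(vc, if (gfblup) "gfblup" else "gblup")
  vprop <- if (gfblup) variance_proportions(vc) else NULL
  say(sprintf("h2 = %.3f (%d genetic component(s))", h2, length(grms)))

  # corrected phenotypes: always single-population traditional GBLUP on all
  # individuals of the target population
  tgt <- ph$population == spec$target_population
  ph_t <- ph[tgt, , drop = FALSE]
  if (single && !gfblup) {
    fit1 <- blup_solve(y, X, grms, vc)
  } else {
    qc_t <- qc_filter(split_by_population(geno)[[spec$target_population]],
                      maf_min, min_class_count)
    g_t <- mean_impute_missing(subset_genotypes(qc_t$geno, individuals = ph_t$animal_id))
    y_t <- y[ph_t$animal_id]
    X_t <- build_fixed_design(ph_t)
    grm_t <- list(genomic = vanraden_grm(g_t))
    vc_t <- reml_fit(y_t, X_t, grm_t)
    fit1 <- blup_solve(y_t, X_t, grm_t, vc_t)
  }
  y_corr_all <- corrected_phenotypes(y[ph_t$animal_id], fit1)

  plans <- make_validation_plan(ph_t, strategy, n_val = n_val, n_reps = n_reps,
                                seed = derive_seed(spec$seed, "validation_plan"))
  entries <- vector("list", length(plans))
  for (k in seq_along(plans)) {
    plan <- plans[[k]]
    masked <- c(plan$validation_ids, plan$excluded_ids)
    fit_k <- blup_solve(y, X, grms, vc, masked_ids = masked)
    entries[[k]] <- prediction_reliability(
      fit_k$gbv_total[plan$validation_ids],
      y_corr_all[plan$validation_ids],
      h2
    )
  }
  report <- summarize_replicates(entries)
  structure(list(spec = spec, reliability = report, h2 = h2, vc = vc,
                 variance_proportions = vprop, plans = plans,
                 qc_reports = qc_reports, n_records = nrow(ph)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result:", x$spec$scenario, "| target", x$spec$target_population,
      "| trait", x$spec$trait, "\n  h2 =", round(x$h2, 3),
      "| mean reliability =", round(x$reliability$mean_reliability, 3),
      "over", x$reliability$n_replicates, "replicates\n")
  invisible(x)
}

#' Compare scenario reliabilities
#'
#' Pairwise differences of mean validation reliabilities between scenario
#' results sharing trait and target population (positive delta = first
#' scenario better), with the SD of per-replicate differences where
#' replicate counts match.
#'
#' @param results named list of [run_scenario()] results
#' @return data.frame(scenario_a, scenario_b, delta, sd_replicate_delta)
#' @export
compare_scenarios <- function(results) {
  if (length(results) < 2L) gfb_stop("need at least two scenario results", "structure_error")
  lapply(results, function(r) stopifnot(inherits(r, "scenario_result")))
  keys <- vapply(results, function(r) paste(r$spec$trait, r$spec$target_population), "")
  if (length(unique(keys)) != 1L) {
    gfb_stop("scenario results do not share trait/population keys", "structure_error")
  }
  nms <- names(results) %||% vapply(results, function(r) r$spec$scenario, "")
  combs <- utils::combn(seq_along(results), 2)
  out <- data.frame()
  for (k in seq_len(ncol(combs))) {
    a <- results[[combs[1, k]]]; b <- results[[combs[2, k]]]
    ra <- a$reliability; rb <- b$reliability
    sd_d <- if (ra$n_replicates == rb$n_replicates) {
      stats::sd(ra$replicates$reliability - rb$replicates$reliability)
    } else NA_real_
    out <- rbind(out, data.frame(
      scenario_a = nms[combs[1, k]], scenario_b = nms[combs[2, k]],
      delta = ra$mean_reliability - rb$mean_reliability,
      sd_replicate_delta = sd_d, stringsAsFactors = FALSE
    ))
  }
  out
}
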