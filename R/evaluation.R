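# Cross-validation design, corrected phenotypes, heritability-scaled
# prediction reliability, variance-proportion partition, bias diagnostics and
# trait preprocessing.

#' Filter records by days in milk
#'
#' Keeps cows at `min_dim` days in milk or more (inclusive threshold).
#'
#' @param phenos phenotype data.frame with a `dim` column
#' @param min_dim minimum DIM, default 60
#' @return filtered data.frame; attribute `n_removed` carries the count
#' @export
filter_dim <- function(phenos, min_dim = 60) {
  if (!"dim" %in% names(phenos)) gfb_stop("phenotype table lacks a dim column", "structure_error")
  keep <- phenos$dim >= min_dim
  out <- phenos[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) message(n_removed, " record(s) removed at DIM < ", min_dim)
  if (!nrow(out)) warning("no records remain after the DIM filter")
  attr(out, "n_removed") <- n_removed
  out
}

#' Milk fatty-acid desaturation indexes
#'
#' `index = unsaturated / (unsaturated + saturated) * 100` for the C14, C16
#' and C18 product/substrate pairs of the SCD enzyme:
#' C14 = C14:1 / (C14:1 + C14:0) * 100, C16 = C16:1 / (C16:1 + C16:0) * 100,
#' C18 = C18:1c9 / (C18:1c9 + C18:0) * 100.
#'
#' @param fa data.frame with columns `c14_0`, `c14_1`, `c16_0`, `c16_1`,
#'   `c18_0`, `c18_1c9` (% wt/wt of total fat)
#' @return data.frame with columns `c14_index`, `c16_index`, `c18_index`;
#'   zero denominators give NA with a warning
#' @export
desaturation_indexes <- function(fa) {
  need <- c("c14_0", "c14_1", "c16_0", "c16_1", "c18_0", "c18_1c9")
  if (!all(need %in% names(fa))) {
    gfb_stop(paste0("fatty-acid table needs columns: ", paste(need, collapse = ", ")),
             "structure_error")
  }
  idx1 <- function(u, s) {
    den <- u + s
    bad <- !is.na(den) & den <= 0
    if (any(bad)) warning(sum(bad), " zero denominator(s); index set to NA")
    out <- u / den * 100
    out[bad] <- NA_real_
    out
  }
  data.frame(
    c14_index = idx1(fa$c14_1, fa$c14_0),
    c16_index = idx1(fa$c16_1, fa$c16_0),
    c18_index = idx1(fa$c18_1c9, fa$c18_0)
  )
}

#' Residual-homogeneity diagnostic
#'
#' Assesses heteroscedasticity of a raw-scale fit by the Spearman correlation
#' between absolute residuals and fitted values; recommends a log transform
#' when the correlation exceeds `rho_min` with p < `p_max` (residual spread
#' growing with the mean, the pattern a log transform removes).
#'
#' @param fit a [blup_solve()] `model_fit` on the raw trait scale
#' @param rho_min correlation threshold (default 0.2)
#' @param p_max p-value threshold (default 0.01)
#' @param min_n minimum number of residuals for a verdict (default 10)
#' @return list(spearman_rho, p_value, recommendation in
#'   \{"log_transform", "keep", "insufficient_data", "undefined"\},
#'   data = data.frame(fitted, residual) for plotting)
#' @export
residual_diagnostics <- function(fit, rho_min = 0.2, p_max = 0.01, min_n = 10L) {
  stopifnot(inherits(fit, "model_fit"))
  res <- fit$residuals
  fitted <- fit$fitted
  dat <- data.frame(fitted = as.numeric(fitted), residual = as.numeric(res))
  if (length(res) < min_n) {
    return(list(spearman_rho = NA_real_, p_value = NA_real_,
                recommendation = "insufficient_data", data = dat))
  }
  if (stats::sd(res) == 0 || stats::sd(fitted) == 0) {
    warning("constant residuals or fitted values; verdict undefined")
    return(list(spearman_rho = NA_real_, p_value = NA_real_,
                recommendation = "undefined", data = dat))
  }
  ct <- suppressWarnings(
    stats::cor.test(abs(res), fitted, method = "spearman", exact = FALSE)
  )
  rec <- if (!is.na(ct$estimate) && ct$estimate > rho_min && ct$p.value < p_max) {
    "log_transform"
  } else "keep"
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
       recommendation = rec, data = dat)
}

validate_plan <- function(plan, phenos) {
  v <- plan$validation_ids; r <- plan$reference_ids; x <- plan$excluded_ids
  if (length(intersect(v, r))) gfb_stop("validation and reference overlap", "plan_error")
  if (length(intersect(v, x)) || length(intersect(r, x))) {
    gfb_stop("excluded ids overlap validation or reference", "plan_error")
  }
  i <- match(v, phenos$animal_id)
  if (anyNA(i)) gfb_stop("validation ids missing from phenotypes", "plan_error")
  if (plan$strategy == "unrelated_subset") {
    sire_tab <- table(phenos$sire_id)
    dam_tab <- table(phenos$dam_id)
    s <- phenos$sire_id[i]
    d <- phenos$dam_id[i]
    sib <- (!is.na(s) & sire_tab[s] > 1) | (!is.na(d) & dam_tab[d] > 1)
    if (any(sib)) {
      gfb_stop("unrelated_subset: a validation cow has a sibling in the dataset", "plan_error")
    }
    if (any(!is.na(d) & d %in% phenos$animal_id)) {
      gfb_stop("unrelated_subset: a validation cow's dam is in the dataset", "plan_error")
    }
  } else {
    i_all <- match(c(v, x), phenos$animal_id)
    sires <- unique(phenos$sire_id[i_all])
    if (length(sires) != 1L) gfb_stop("sire_group_holdout: validation spans several sires", "plan_error")
    ref_sires <- phenos$sire_id[match(r, phenos$animal_id)]
    if (any(ref_sires == sires, na.rm = TRUE)) {
      gfb_stop("sire_group_holdout: same-sire cow left in the reference", "plan_error")
    }
  }
  invisible(TRUE)
}

#' Build replicated reference/validation partitions
#'
#' Two strategies mirroring the study design:
#' \describe{
#'   \item{unrelated_subset}{eligible cows have no sibling (no other cow in
#'     the dataset shares their sire or dam) and their dam is not herself in
#'     the dataset; each replicate samples `n_val` of them for validation and
#'     returns the remaining eligible cows to the reference.}
#'   \item{sire_group_holdout}{each replicate picks one sire group with at
#'     least `n_val` cows, samples `n_val` of them for validation, and
#'     excludes the rest of that group from the reference entirely.}
#' }
#' Validation sets may overlap across replicates (set-level resampling);
#' sampling within a replicate is without replacement.
#'
#' @param phenos phenotype data.frame with `animal_id`, `sire_id`, `dam_id`
#' @param strategy `"unrelated_subset"` or `"sire_group_holdout"`
#' @param n_val validation-set size (default 100)
#' @param n_reps number of replicates (default 5)
#' @param seed RNG seed
#' @return list of `validation_plan` objects: list(replicate, strategy,
#'   validation_ids, reference_ids, excluded_ids)
#' @export
make_validation_plan <- function(phenos,
                                 strategy = c("unrelated_subset", "sire_group_holdout"),
                                 n_val = 100L, n_reps = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  need <- c("animal_id", "sire_id", "dam_id")
  if (!all(need %in% names(phenos))) {
    gfb_stop("phenotype table needs animal_id, sire_id, dam_id", "structure_error")
  }
  ids <- phenos$animal_id
  with_seed(seed, {
    plans <- vector("list", n_reps)
    if (strategy == "unrelated_subset") {
      sire_tab <- table(phenos$sire_id[!is.na(phenos$sire_id)])
      dam_tab <- table(phenos$dam_id[!is.na(phenos$dam_id)])
      has_sib <- (!is.na(phenos$sire_id) & sire_tab[phenos$sire_id] > 1) |
        (!is.na(phenos$dam_id) & dam_tab[phenos$dam_id] > 1)
      has_sib[is.na(has_sib)] <- FALSE
      dam_present <- !is.na(phenos$dam_id) & phenos$dam_id %in% ids
      eligible <- ids[!has_sib & !dam_present]
      if (length(eligible) < n_val) {
        gfb_stop(sprintf(
          "unrelated_subset: only %d cows without siblings and without their dam in the dataset; %d needed",
          length(eligible), n_val), "eligibility_error")
      }
      for (rep_i in seq_len(n_reps)) {
        val <- sample(eligible, n_val)
        plans[[rep_i]] <- structure(list(
          replicate = rep_i, strategy = strategy,
          validation_ids = val,
          reference_ids = setdiff(ids, val),
          excluded_ids = character(0)
        ), class = "validation_plan")
      }
    } else {
      grp <- split(ids, phenos$sire_id)
      big <- grp[vapply(grp, length, 1L) >= n_val]
      if (!length(big)) {
        gfb_stop(sprintf("sire_group_holdout: no sire group with >= %d cows", n_val),
                 "eligibility_error")
      }
      for (rep_i in seq_len(n_reps)) {
        g <- big[[sample.int(length(big), 1L)]]
        val <- sample(g, n_val)
        excluded <- setdiff(g, val)
        plans[[rep_i]] <- structure(list(
          replicate = rep_i, strategy = strategy,
          validation_ids = val,
          reference_ids = setdiff(ids, g),
          excluded_ids = excluded
        ), class = "validation_plan")
      }
    }
    for (p in plans) validate_plan(p, phenos)
    plans
  })
}

#' @export
print.validation_plan <- function(x, ...) {
  cat("validation_plan (", x$strategy, ") replicate", x$replicate, ":",
      length(x$validation_ids), "validation,", length(x$reference_ids),
      "reference,", length(x$excluded_ids), "excluded\n")
  invisible(x)
}

#' Phenotypes corrected for fixed effects
#'
#' `y_corr = y - (mu + parity + herd + b1 DIM + b2 exp(-0.05 DIM))` with the
#' fixed-effect estimates taken from a single-population traditional GBLUP
#' fit on all individuals of the cow's population. The genomic random effect
#' is deliberately not subtracted: y_corr keeps `g + e`.
#'
#' @param y named numeric phenotypes
#' @param fit1 a `model_fit` from the single-population GBLUP on all
#'   individuals; its `fixed_fitted` must cover the ids of `y`
#' @return named numeric corrected phenotypes
#' @export
corrected_phenotypes <- function(y, fit1) {
  stopifnot(inherits(fit1, "model_fit"))
  if (is.null(names(y))) gfb_stop("y must be named by animal id", "alignment_error")
  miss <- setdiff(names(y), names(fit1$fixed_fitted))
  if (length(miss)) {
    gfb_stop(paste0("cow(s) absent from the correcting fit: ",
                    paste(utils::head(miss, 5), collapse = ", ")),
             "alignment_error")
  }
  y - fit1$fixed_fitted[names(y)]
}

#' Prediction reliability of genomic breeding values
#'
#' `reliability = cor(gbv, y_corr)^2 / h2`: the squared correlation between
#' predicted GBVs and fixed-effect-corrected phenotypes, scaled by the
#' heritability estimated on the full data of the same scenario. Values above
#' 1 are possible after scaling and are flagged, not truncated. Also returns
#' the raw correlation and the regression slope of `y_corr` on `gbv`
#' (slope 1 = unbiased dispersion of the predictions).
#'
#' @param gbv numeric predicted breeding values of the validation cows
#' @param y_corr numeric corrected phenotypes, same cows, same order
#' @param h2 heritability used for scaling, in (0, 1]
#' @return list(correlation, reliability, slope, n, flagged)
#' @export
prediction_reliability <- function(gbv, y_corr, h2) {
  if (length(gbv) != length(y_corr)) gfb_stop("gbv and y_corr lengths differ", "structure_error")
  if (length(gbv) < 3L) gfb_stop("need at least 3 validation cows", "structure_error")
  if (!(h2 > 0 && h2 <= 1)) gfb_stop("h2 must lie in (0, 1]", "domain_error")
  if (stats::sd(gbv) == 0 || stats::sd(y_corr) == 0) {
    gfb_stop("zero-variance gbv or corrected phenotype; reliability undefined",
             "degenerate_error")
  }
  r <- stats::cor(gbv, y_corr)
  rel <- r^2 / h2
  slope <- stats::cov(y_corr, gbv) / stats::var(gbv)
  flagged <- rel > 1
  if (flagged) warning("reliability exceeds 1 after heritability scaling")
  list(correlation = r, reliability = rel, slope = slope,
       n = length(gbv), flagged = flagged)
}

#' Genomic variance proportions across features
#'
#' `%var_f = sigma_f^2 / sigma_total^2 * 100` with `sigma_total^2` the sum of
#' all genetic components (features plus rest of genome).
#'
#' @param vc a `variance_components` object (several genetic components)
#' @return data.frame(component, variance, proportion_pct); proportions sum
#'   to 100
#' @export
variance_proportions <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  s <- vc$components
  tot <- sum(s)
  if (tot <= 0) gfb_stop("total genetic variance is zero; proportions undefined", "domain_error")
  data.frame(
    component = names(s),
    variance = as.numeric(s),
    proportion_pct = as.numeric(s) / tot * 100,
    stringsAsFactors = FALSE
  )
}

#' Summarize per-replicate reliability entries
#'
#' Mean reliability over the replicates and the mean absolute deviation (MAD)
#' of the per-replicate correlations from their mean — the replication-spread
#' measure reported alongside average reliabilities.
#'
#' @param entries list of [prediction_reliability()] results
#' @return object of class `reliability_report`: list(n_replicates,
#'   mean_reliability, mean_correlation, mad_correlation, mean_slope,
#'   replicates = data.frame)
#' @export
summarize_replicates <- function(entries) {
  if (!length(entries)) gfb_stop("no replicate entries supplied", "structure_error")
  rel <- vapply(entries, function(e) e$reliability, 1)
  r <- vapply(entries, function(e) e$correlation, 1)
  slope <- vapply(entries, function(e) e$slope, 1)
  structure(list(
    n_replicates = length(entries),
    mean_reliability = mean(rel),
    mean_correlation = mean(r),
    mad_correlation = mean(abs(r - mean(r))),
    mean_slope = mean(slope),
    replicates = data.frame(replicate = seq_along(entries), correlation = r,
                            reliability = rel, slope = slope)
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "reliability_report: %d replicate(s); mean reliability %.3f; mean r %.3f (MAD %.3f); mean slope %.3f\n",
    x$n_replicates, x$mean_reliability, x$mean_correlation,
    x$mad_correlation, x$mean_slope))
  invisible(x)
}
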