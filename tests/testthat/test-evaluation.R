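# evaluation: DIM filter, desaturation indexes, diagnostics, validation
# plans, corrected phenotypes, reliability, proportions, replicate summaries

test_that("filter_dim keeps records at the threshold and above", {
  ph <- data.frame(animal_id = paste0("a", 1:4), dim = c(3, 59, 60, 278))
  out <- suppressMessages(filter_dim(ph))
  expect_equal(out$dim, c(60, 278))
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(nrow(filter_dim(ph, min_dim = 0)), 4L)
  expect_warning(suppressMessages(filter_dim(ph, min_dim = 1000)), "no records")
})

test_that("desaturation indexes follow unsaturated/(unsaturated+saturated)*100", {
  fa <- data.frame(c14_0 = c(9, 1, 0), c14_1 = c(1, 1, 0),
                   c16_0 = c(5, 1, 1), c16_1 = c(0, 1, 1),
                   c18_0 = c(2, 1, 1), c18_1c9 = c(2, 3, 1))
  expect_warning(idx <- desaturation_indexes(fa), "zero denominator")
  expect_equal(idx$c14_index, c(10, 50, NA))
  expect_equal(idx$c16_index[1], 0)
  expect_equal(idx$c18_index[1], 50)
  expect_true(all(idx >= 0 & idx <= 100, na.rm = TRUE))
})

test_that("residual diagnostics flag mean-dependent spread and spare clean fits", {
  make_fit <- function(fitted, residual) {
    structure(list(fitted = fitted, residuals = residual,
                   ids = seq_along(fitted), masked_ids = character(0)),
              class = "model_fit")
  }
  verdicts <- vapply(1:10, function(seed) {
    set.seed(seed)
    mu <- stats::runif(500, 5, 20)
    het <- residual_diagnostics(make_fit(mu, stats::rnorm(500, 0, 0.3 * mu)))
    hom <- residual_diagnostics(make_fit(mu, stats::rnorm(500, 0, 2)))
    c(het$recommendation == "log_transform", hom$recommendation == "keep")
  }, logical(2))
  expect_equal(sum(verdicts[1, ]), 10L)
  expect_gte(sum(verdicts[2, ]), 9L)
  tiny <- residual_diagnostics(make_fit(1:3, c(0.1, -0.2, 0.1)))
  expect_equal(tiny$recommendation, "insufficient_data")
  flat <- residual_diagnostics(make_fit(rep(1, 50), rep(0, 50)))
  expect_warning(residual_diagnostics(make_fit(rep(1, 50), rep(0, 50))), "undefined")
})

test_that("sire-group holdout plans respect the group structure", {
  ped <- toy_pedigree(n_groups = 6, group_size = 150)
  plans <- make_validation_plan(ped, "sire_group_holdout", n_val = 100,
                                n_reps = 5, seed = 21)
  expect_length(plans, 5L)
  for (p in plans) {
    expect_length(p$validation_ids, 100L)
    expect_length(p$excluded_ids, 50L)
    expect_length(p$reference_ids, 750L)
    sires <- ped$sire_id[match(c(p$validation_ids, p$excluded_ids), ped$animal_id)]
    expect_equal(length(unique(sires)), 1L)
    ref_sires <- ped$sire_id[match(p$reference_ids, ped$animal_id)]
    expect_false(unique(sires) %in% ref_sires)
    expect_length(intersect(p$validation_ids, p$reference_ids), 0L)
  }
})

test_that("unrelated-subset plans demand an eligible pool", {
  # every cow has a half sib -> no eligible cows
  ped_sibs <- toy_pedigree(n_groups = 10, group_size = 20)
  expect_error(
    make_validation_plan(ped_sibs, "unrelated_subset", n_val = 10, seed = 1),
    class = "eligibility_error"
  )
  ped_ok <- toy_pedigree(n_groups = 4, group_size = 30, n_singles = 150)
  plans <- make_validation_plan(ped_ok, "unrelated_subset", n_val = 100,
                                n_reps = 5, seed = 5)
  for (p in plans) {
    expect_length(p$validation_ids, 100L)
    expect_true(all(grepl("^single", p$validation_ids)))
    # non-sampled eligible cows return to the reference
    expect_length(p$reference_ids, nrow(ped_ok) - 100L)
    expect_length(p$excluded_ids, 0L)
  }
  # determinism under the same seed
  plans2 <- make_validation_plan(ped_ok, "unrelated_subset", n_val = 100,
                                 n_reps = 5, seed = 5)
  expect_identical(lapply(plans, `[[`, "validation_ids"),
                   lapply(plans2, `[[`, "validation_ids"))
})

test_that("corrected phenotypes subtract exactly the fixed part", {
  d <- small_dataset()
  y <- small_y()
  fit <- blup_solve(y, small_design(), list(genomic = small_grm()), small_vc())
  y_corr <- corrected_phenotypes(y, fit)
  # construction oracle: y_corr should track g + e = y - true fixed part
  ph <- d$phenotypes
  cfg <- small_cfg()
  true_fixed_free <- ph$trait -
    (cfg$mu + cfg$wilmink_b1 * ph$dim + cfg$wilmink_b2 * exp(-0.05 * ph$dim))
  expect_gt(stats::cor(y_corr, true_fixed_free), 0.95)
  # translation invariance: y + c shifts the mean estimate only
  fit_c <- blup_solve(y + 7, small_design(), list(genomic = small_grm()), small_vc())
  expect_equal(corrected_phenotypes(y + 7, fit_c), y_corr, tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero fixed-effect fit returns y unchanged
  fit0 <- fit
  fit0$fixed_fitted[] <- 0
  expect_equal(corrected_phenotypes(y, fit0), y)
  expect_error(corrected_phenotypes(stats::setNames(1:3, c("zz1", "zz2", "zz3")), fit),
               class = "alignment_error")
})

test_that("reliability formula, guards and affine invariance", {
  set.seed(77)
  u <- stats::rnorm(100); u <- (u - mean(u)) / stats::sd(u)
  v <- stats::rnorm(100); v <- stats::resid(stats::lm(v ~ u)); v <- v / stats::sd(v)
  y_corr <- 0.5 * u + sqrt(0.75) * v   # cor(u, y_corr) = 0.5 exactly
  entry <- prediction_reliability(u, y_corr, h2 = 0.25)
  expect_equal(entry$reliability, 1.0, tolerance = 1e-10)
  ident <- suppressWarnings(prediction_reliability(y_corr, y_corr, h2 = 1))
  expect_equal(ident$reliability, 1.0)
  expect_equal(ident$slope, 1.0)
  # affine invariance of the correlation-based reliability
  entry2 <- prediction_reliability(3 * u - 5, y_corr, h2 = 0.25)
  expect_equal(entry2$reliability, entry$reliability, tolerance = 1e-12)
  expect_error(prediction_reliability(rep(1, 10), stats::rnorm(10), 0.5),
               class = "degenerate_error")
  expect_error(prediction_reliability(u, y_corr, h2 = 0), class = "domain_error")
  expect_error(prediction_reliability(u[1:2], y_corr[1:2], 0.5),
               class = "structure_error")
})

test_that("variance proportions sum to 100 and are scale-invariant", {
  vc <- variance_components(c(f14 = 2, f19 = 1, f26 = 1, rest = 4), 1)
  vp <- variance_proportions(vc)
  expect_equal(vp$proportion_pct, c(25, 12.5, 12.5, 50))
  expect_equal(sum(vp$proportion_pct), 100, tolerance = 1e-6)
  vc3 <- variance_components(c(f14 = 6, f19 = 3, f26 = 3, rest = 12), 1)
  expect_equal(variance_proportions(vc3)$proportion_pct, vp$proportion_pct)
  single <- variance_components(c(f14 = 0, rest = 2), 1)
  expect_equal(variance_proportions(single)$proportion_pct, c(0, 100))
  expect_error(variance_proportions(variance_components(c(a = 0), 1)),
               class = "domain_error")
})

test_that("replicate summaries compute mean reliability and correlation MAD", {
  mk <- function(r, rel) list(correlation = r, reliability = rel, slope = 1,
                              n = 100, flagged = FALSE)
  rep5 <- summarize_replicates(lapply(rep(0.3, 5), function(r) mk(r, 0.3)))
  expect_equal(rep5$mad_correlation, 0)
  two <- summarize_replicates(list(mk(0.2, 0.1), mk(0.4, 0.3)))
  expect_equal(two$mean_correlation, 0.3)
  expect_equal(two$mad_correlation, 0.1)
  three <- summarize_replicates(list(mk(0.1, 0.1), mk(0.2, 0.2), mk(0.3, 0.3)))
  expect_equal(three$mean_reliability, 0.2)
})
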