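# genotypes: I/O, per-population QC, common-SNP intersection, imputation

test_that("plink text reading handles a tiny hand-written panel", {
  prefix <- file.path(tempdir(), "tiny")
  writeLines(c("chr1\ts1\t0\t100", "chr1\ts2\t0\t200", "chr2\ts3\t0\t50"),
             paste0(prefix, ".map"))
  writeLines(c(
    "pop1\tcow1\t0\t0\t0\t-9\tA A\tA B\tB B",
    "pop1\tcow2\t0\t0\t0\t-9\tB B\tA A\t0 0"
  ), paste0(prefix, ".ped"))
  g <- read_genotypes(prefix, "plink-text")
  expect_equal(unname(g$geno[1, ]), c(0, 1, 2))
  expect_equal(unname(g$geno[2, ]), c(2, 0, NA))
  expect_equal(g$samples$animal_id, c("cow1", "cow2"))
  unlink(paste0(prefix, c(".ped", ".map")))
})

test_that("plink reading rejects inconsistent record lengths", {
  prefix <- file.path(tempdir(), "badped")
  writeLines(c("chr1\ts1\t0\t100", "chr1\ts2\t0\t200"), paste0(prefix, ".map"))
  writeLines("pop1\tcow1\t0\t0\t0\t-9\tA A", paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, "plink-text"), class = "structure_error")
  unlink(paste0(prefix, c(".ped", ".map")))
})

test_that("vcf reading: missing genotypes become NA, multi-allelic sites drop", {
  path <- file.path(tempdir(), "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcowA\tcowB",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/0",
    "chr1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t1/1\t0/0"
  ), path)
  expect_warning(g <- read_genotypes(path, "vcf"), "multi-allelic")
  expect_equal(dim(g$geno), c(2L, 2L))
  expect_equal(unname(g$geno[, 1]), c(1, NA))
  expect_equal(unname(g$geno[, 2]), c(2, 0))
  expect_error(suppressWarnings(read_genotypes(file.path(tempdir(), "nope.vcf"), "vcf")),
               class = "parse_error")
  unlink(path)
})

test_that("qc_filter applies the MAF and genotype-class rules with exact counts", {
  # 100 individuals: SNP1 (95, 5, 0) -> MAF 0.025, min class 0: removed (both)
  # SNP2 (40, 40, 20) -> MAF 0.4, min class 20: retained
  counts <- cbind(
    c(rep(0, 95), rep(1, 5)),
    c(rep(0, 40), rep(1, 40), rep(2, 20))
  )
  g <- toy_geno(counts)
  out <- qc_filter(g, maf_min = 0.05, min_class_count = 10L)
  expect_equal(out$geno$map$snp_id, "s2")
  expect_equal(out$report$maf, c(0.025, 0.4))
  expect_equal(out$report$min_class_count, c(0L, 20L))
  expect_equal(out$report$removed, c(TRUE, FALSE))
  expect_match(out$report$reason[1], "maf")
})

test_that("qc_filter with zero thresholds is the identity and QC is idempotent", {
  g <- small_dataset()$geno
  g1 <- qc_filter(g, maf_min = 0, min_class_count = 0L)
  expect_equal(g1$geno$geno, g$geno)
  once <- qc_filter(g, 0.05, 10L)
  twice <- qc_filter(once$geno, 0.05, 10L)
  expect_equal(twice$geno$geno, once$geno$geno)
  expect_true(all(!twice$report$removed))
  # every retained SNP satisfies both thresholds simultaneously
  kept <- once$report[!once$report$removed, ]
  expect_true(all(kept$maf >= 0.05 & kept$min_class_count >= 10))
})

test_that("qc_filter refuses multi-population input and flags empty results", {
  cfg <- small_cfg()
  g2 <- simulate_genotypes(sim_config(
    n_populations = 2L, n_per_population = c(30L, 30L), n_sires_per_population = 3L,
    chromosomes = data.frame(label = "chr1", n_snps = 20L, length_bp = 1e6),
    feature_chromosomes = "chr1", feature_variance_fractions = 0.5,
    n_qtl = 5L, seed = 1L
  ))
  expect_error(qc_filter(g2), class = "population_error")
  mono <- toy_geno(matrix(0, nrow = 20, ncol = 3))
  expect_warning(res <- qc_filter(mono), "all SNPs removed")
  expect_equal(ncol(res$geno$geno), 0L)
})

test_that("intersect_common_snps keeps exactly the shared SNPs, order-invariantly", {
  make <- function(ids, snps, pop) {
    p <- length(snps)
    genotype_matrix(
      matrix(rep(1, length(ids) * p), ncol = p),
      data.frame(snp_id = snps, chr = "chr1", pos = match(snps, LETTERS) * 100L),
      data.frame(animal_id = ids, population = pop,
                 sire_id = NA_character_, dam_id = NA_character_)
    )
  }
  g1 <- make(c("x1", "x2"), c("A", "B", "C"), "pop1")
  g2 <- make(c("y1", "y2", "y3"), c("B", "C", "D"), "pop2")
  comb <- intersect_common_snps(list(g1, g2))
  expect_setequal(comb$map$snp_id, c("B", "C"))
  expect_equal(nrow(comb$geno), 5L)
  # shuffled SNP order in one input gives the same combined matrix
  g2_shuf <- make(c("y1", "y2", "y3"), c("D", "C", "B"), "pop2")
  comb2 <- intersect_common_snps(list(g1, g2_shuf))
  expect_equal(comb2$geno, comb$geno)
  expect_equal(comb2$map, comb$map)
  # commutativity up to row order by population
  comb3 <- intersect_common_snps(list(g2, g1))
  expect_equal(comb3$map, comb$map)
  expect_equal(comb3$geno[comb$samples$animal_id, ], comb$geno)
  expect_error(intersect_common_snps(list(g1, g1)), class = "structure_error")
})

test_that("mean imputation fills exactly the missing entries", {
  g <- toy_geno(rbind(c(0, 1, 1), c(2, 1, 1), c(NA, 1, 1), c(NA, NA, 1)))
  out <- mean_impute_missing(g)
  expect_equal(unname(out$geno[, 1]), c(0, 2, 1, 1))
  expect_equal(unname(out$geno[, 2]), c(1, 1, 1, 1))
  expect_equal(out$geno[, 3], g$geno[, 3])
  g_all_na <- toy_geno(rbind(c(NA, 1), c(NA, 0)))
  expect_error(mean_impute_missing(g_all_na), class = "all_missing_error")
  expect_match(tryCatch(mean_impute_missing(g_all_na), error = conditionMessage), "s1")
})
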