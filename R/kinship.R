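# VanRaden (method 1) genomic relationship matrices, whole-genome and
# partitioned across feature chromosomes.

#' Per-SNP allele frequencies
#'
#' `p_j` = mean allele count of SNP j over the supplied individuals, halved.
#'
#' @param geno a [genotype_matrix()]
#' @return named numeric vector of frequencies in \[0, 1\]
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  nmiss <- colSums(is.na(geno$geno))
  if (any(nmiss == nrow(geno$geno))) {
    gfb_stop("allele_frequencies: SNP(s) with all entries missing", "all_missing_error")
  }
  p <- colMeans(geno$geno, na.rm = TRUE) / 2
  names(p) <- geno$map$snp_id
  p
}

#' VanRaden method-1 genomic relationship matrix
#'
#' With M the allele-count matrix over the chosen SNPs and P the matrix of
#' `2 p_j`: `G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j))`. The scaling
#' denominator is recorded on the result so partitioned matrices can be
#' recombined exactly (`sum_f s_f G_f / s_total = G_whole`).
#'
#' @param geno a [genotype_matrix()] with no missing entries (run
#'   [mean_impute_missing()] first)
#' @param snp_ids optional subset of SNP ids (default: all)
#' @param freqs optional named frequency vector used for centering and the
#'   denominator; defaults to [allele_frequencies()] of `geno`. Supply
#'   scenario-wide frequencies when building per-population matrices that
#'   must share a base population.
#' @return object of class `grm`: list(G, ids, snp_ids, denominator)
#' @export
vanraden_grm <- function(geno, snp_ids = NULL, freqs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$geno)) {
    gfb_stop("genotypes contain missing entries; run mean_impute_missing() first",
             "missing_data_error")
  }
  if (is.null(snp_ids)) snp_ids <- geno$map$snp_id
  if (!length(snp_ids)) gfb_stop("empty SNP subset", "structure_error")
  ci <- match(snp_ids, geno$map$snp_id)
  if (anyNA(ci)) gfb_stop("snp_ids not all present in the genotype map", "structure_error")
  if (is.null(freqs)) freqs <- allele_frequencies(geno)
  p <- freqs[snp_ids]
  if (anyNA(p)) gfb_stop("freqs must cover every SNP in the subset", "structure_error")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    gfb_stop("all SNPs in the subset are monomorphic (zero denominator)",
             "monomorphic_error")
  }
  Z <- sweep(geno$geno[, ci, drop = FALSE], 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  structure(list(G = G, ids = geno$samples$animal_id,
                 snp_ids = as.character(snp_ids), denominator = denom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals over", length(x$snp_ids),
      "SNPs; denominator =", format(x$denominator, digits = 6),
      "; mean diagonal =", format(mean(diag(x$G)), digits = 4), "\n")
  invisible(x)
}

#' Feature-partitioned genomic relationship matrices
#'
#' Builds one GRM per feature chromosome plus one rest-of-genome GRM over all
#' remaining SNPs. The SNP sets partition the full set, and all matrices are
#' centered with frequencies computed once over the full analysis set, so the
#' denominator-weighted sum of the members reconstructs the whole-genome GRM
#' exactly.
#'
#' @param geno a [genotype_matrix()] with no missing entries
#' @param feature_chromosomes chromosome labels granted their own GRM
#' @param freqs optional shared frequency vector (default: from `geno`)
#' @return object of class `grm_set`: list(features = named list of `grm`,
#'   rest = `grm`)
#' @export
feature_grms <- function(geno, feature_chromosomes, freqs = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  feature_chromosomes <- as.character(feature_chromosomes)
  if (!all(feature_chromosomes %in% geno$map$chr)) {
    gfb_stop("feature chromosome(s) absent from the SNP map", "structure_error")
  }
  if (is.null(freqs)) freqs <- allele_frequencies(geno)
  feats <- list()
  for (ch in feature_chromosomes) {
    ids <- geno$map$snp_id[geno$map$chr == ch]
    if (!length(ids)) {
      gfb_stop(paste0("feature chromosome ", ch, " has zero SNPs after QC"),
               "structure_error")
    }
    feats[[ch]] <- vanraden_grm(geno, ids, freqs)
  }
  rest_ids <- geno$map$snp_id[!(geno$map$chr %in% feature_chromosomes)]
  if (!length(rest_ids)) {
    gfb_stop("no SNPs left for the rest-of-genome matrix (all chromosomes are features)",
             "structure_error")
  }
  rest <- vanraden_grm(geno, rest_ids, freqs)
  structure(list(features = feats, rest = rest), class = "grm_set")
}

#' @export
print.grm_set <- function(x, ...) {
  cat("grm_set:", length(x$features), "feature GRM(s) [",
      paste(names(x$features), collapse = ", "), "] + rest (",
      length(x$rest$snp_ids), "SNPs )\n")
  invisible(x)
}

#' Flatten a grm_set into the ordered component list used by the solvers
#'
#' @param grm_set a [feature_grms()] result
#' @return named list of `grm` objects (features first, rest last)
#' @export
grm_components <- function(grm_set) {
  stopifnot(inherits(grm_set, "grm_set"))
  c(grm_set$features, list(rest = grm_set$rest))
}

#' Write a GRM as a delimited lower-triangle text file
#'
#' Columns: id_i, id_j, value (i >= j, including the diagonal).
#'
#' @param grm a `grm` object
#' @param path output path
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  lower <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  dt <- data.table::data.table(
    id_i = grm$ids[lower[, 1]], id_j = grm$ids[lower[, 2]],
    value = grm$G[lower]
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
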