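# Pairwise linkage disequilibrium (genotype-correlation r^2) within a
# physical-distance window, and binwise mean LD per chromosome.

#' Pairwise LD r-squared within a distance window
#'
#' For every SNP pair on `chromosome` separated by at most `max_distance` bp,
#' computes r^2 as the squared Pearson correlation of the allele-count
#' vectors over non-missing individuals (composite, phase-free LD).
#' Monomorphic SNPs are skipped; the number of skipped pairs is recorded.
#'
#' @param geno a [genotype_matrix()]
#' @param chromosome chromosome label
#' @param max_distance window in bp (default 1 Mbp)
#' @return data.frame(snp_i, snp_j, distance, r2), attribute
#'   `n_monomorphic_skipped`, attribute `chromosome`
#' @export
pairwise_r2 <- function(geno, chromosome, max_distance = 1e6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  sel <- which(geno$map$chr == chromosome)
  if (length(sel) < 2L) {
    gfb_stop(paste0("need >= 2 SNPs on chromosome ", chromosome), "structure_error")
  }
  ord <- sel[order(geno$map$pos[sel])]
  g <- geno$geno[, ord, drop = FALSE]
  pos <- geno$map$pos[ord]
  ids <- geno$map$snp_id[ord]
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  n_mono <- sum(!poly)
  g <- g[, poly, drop = FALSE]
  pos <- pos[poly]; ids <- ids[poly]
  p <- ncol(g)
  if (p < 2L) gfb_stop("fewer than 2 polymorphic SNPs on the chromosome", "structure_error")
  cm <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  dist <- pos[pairs[, 2]] - pos[pairs[, 1]]
  keep <- dist > 0 & dist <= max_distance
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    snp_i = ids[pairs[, 1]],
    snp_j = ids[pairs[, 2]],
    distance = dist[keep],
    r2 = cm[pairs]^2,
    stringsAsFactors = FALSE
  )
  attr(out, "n_monomorphic_skipped") <- n_mono
  attr(out, "chromosome") <- chromosome
  out
}

#' Binwise mean LD
#'
#' Groups SNP pairs into half-open physical-distance bins
#' `[k * bin_size, (k + 1) * bin_size)` and reports the unweighted mean r^2
#' and pair count per bin. Empty bins inside the covered range are reported
#' with count 0 and NA mean.
#'
#' @param pairs a [pairwise_r2()] result
#' @param bin_size bin width in bp (> 0)
#' @return data.frame(chromosome, bin_start, bin_end, mean_r2, n_pairs)
#' @export
binwise_mean_ld <- function(pairs, bin_size) {
  if (!nrow(pairs)) gfb_stop("no SNP pairs supplied", "structure_error")
  if (bin_size <= 0) gfb_stop("bin_size must be positive", "domain_error")
  bin <- floor(pairs$distance / bin_size)
  n_bins <- max(bin) + 1L
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  agg_mean <- tapply(pairs$r2, bin, mean)
  agg_n <- tapply(pairs$r2, bin, length)
  idx <- as.integer(names(agg_mean)) + 1L
  means[idx] <- agg_mean
  counts[idx] <- agg_n
  data.frame(
    chromosome = attr(pairs, "chromosome") %||% NA_character_,
    bin_start = (seq_len(n_bins) - 1L) * bin_size,
    bin_end = seq_len(n_bins) * bin_size,
    mean_r2 = means,
    n_pairs = counts,
    stringsAsFactors = FALSE
  )
}

#' Binwise LD per population for cross-population comparison
#'
#' @param geno a multi-population [genotype_matrix()]
#' @param chromosomes chromosome labels to analyze
#' @param max_distance window in bp
#' @param bin_size bin width in bp
#' @return data.frame with an extra `population` column
#' @export
binwise_ld_by_population <- function(geno, chromosomes, max_distance = 1e6,
                                     bin_size = 1e6) {
  per_pop <- split_by_population(geno)
  out <- list()
  for (pop in names(per_pop)) {
    for (ch in chromosomes) {
      pr <- pairwise_r2(per_pop[[pop]], ch, max_distance)
      b <- binwise_mean_ld(pr, bin_size)
      b$population <- pop
      out[[paste(pop, ch)]] <- b
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
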