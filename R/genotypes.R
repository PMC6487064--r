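# Genotype container, PLINK-text / VCF input, per-population SNP quality
# control, common-SNP intersection across populations, and mean imputation.

#' Genotype matrix container
#'
#' Individuals x SNPs allele counts in \{0, 1, 2\} (NA = missing) together
#' with the SNP map and per-individual metadata.
#'
#' @param geno numeric/integer matrix, rows = individuals, columns = SNPs;
#'   entries 0/1/2 count a designated "counted" allele, NA = missing
#' @param map data.frame with columns `snp_id`, `chr`, `pos` (1-based bp);
#'   optional `a1`, `a2` allele labels (a2 = counted allele)
#' @param samples data.frame with columns `animal_id`, `population`,
#'   `sire_id`, `dam_id` (last two may be NA)
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  if (nrow(map) != ncol(geno)) {
    gfb_stop("snp_map length must equal the genotype column count", "structure_error")
  }
  if (nrow(samples) != nrow(geno)) {
    gfb_stop("samples must have one row per genotype row", "structure_error")
  }
  if (anyDuplicated(samples$animal_id)) {
    gfb_stop("duplicate individual ids", "structure_error")
  }
  if (any(map$pos <= 0)) gfb_stop("SNP positions must be strictly positive", "structure_error")
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    gfb_stop("allele counts must lie in [0, 2]", "structure_error")
  }
  rownames(geno) <- samples$animal_id
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = as.data.frame(map),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$geno))
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs;",
      length(unique(x$map$chr)), "chromosomes;",
      length(unique(x$samples$population)), "population(s);",
      n_miss, "missing entries\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param geno a [genotype_matrix()]
#' @param individuals animal ids or logical/integer index over rows
#' @param snps snp ids or logical/integer index over columns
#' @return a [genotype_matrix()]
#' @export
subset_genotypes <- function(geno, individuals = NULL, snps = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ri <- seq_len(nrow(geno$geno))
  ci <- seq_len(ncol(geno$geno))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, geno$samples$animal_id) else ri[individuals]
    if (anyNA(ri)) gfb_stop("unknown individual id in subset", "structure_error")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, geno$map$snp_id) else ci[snps]
    if (anyNA(ci)) gfb_stop("unknown SNP id in subset", "structure_error")
  }
  genotype_matrix(geno$geno[ri, ci, drop = FALSE],
                  geno$map[ci, , drop = FALSE],
                  geno$samples[ri, , drop = FALSE])
}

#' Write genotypes as PLINK text (.ped/.map)
#'
#' Alleles are written as `A` (non-counted) / `B` (counted); missing entries
#' as `0 0`. The .map genetic-distance column is written as 0.
#'
#' @param geno a [genotype_matrix()]
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`
#' @return invisibly, the two file paths
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map_dt <- data.table::data.table(
    chr = geno$map$chr, snp_id = geno$map$snp_id, cm = 0, pos = geno$map$pos
  )
  data.table::fwrite(map_dt, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)

  code <- c("A A", "A B", "B B")
  g <- geno$geno
  alle <- matrix("0 0", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  alle[ok] <- code[g[ok] + 1L]
  smp <- geno$samples
  ped <- data.table::data.table(
    fid = smp$population, iid = smp$animal_id,
    pat = ifelse(is.na(smp$sire_id), "0", smp$sire_id),
    mat = ifelse(is.na(smp$dam_id), "0", smp$dam_id),
    sex = 0L, pheno = -9L
  )
  ped <- cbind(ped, data.table::as.data.table(alle))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = "\t", col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Write a phenotype table to a delimited file
#'
#' @param phenos phenotype data.frame
#' @param path output path (tab-separated)
#' @export
write_phenotypes <- function(phenos, path) {
  data.table::fwrite(phenos, path, sep = "\t")
  invisible(path)
}

read_plink_text <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) gfb_stop(paste0("file not found: ", p), "parse_error")
  }
  map <- tryCatch(
    data.table::fread(map_path, header = FALSE,
                      col.names = c("chr", "snp_id", "cm", "pos")),
    error = function(e) gfb_stop(paste0("malformed .map: ", conditionMessage(e)), "parse_error")
  )
  # .ped is whitespace-delimited (allele pairs may be space-separated inside
  # tab-separated fields), so tokenize on any whitespace
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(trimws(lines), "[ \t]+")
  p <- nrow(map)
  expected_cols <- 6L + 2L * p
  lens <- lengths(toks)
  if (any(lens != expected_cols)) {
    bad <- which(lens != expected_cols)[1]
    gfb_stop(sprintf(".ped line %d has %d fields; expected %d for %d SNPs (inconsistent record lengths)",
                     bad, lens[bad], expected_cols, p), "structure_error")
  }
  ped <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  smp <- data.frame(
    animal_id = ped[[2]], population = ped[[1]],
    sire_id = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    dam_id = ifelse(ped[[4]] == "0", NA_character_, ped[[4]]),
    stringsAsFactors = FALSE
  )
  n <- nrow(ped)
  g <- matrix(NA_real_, nrow = n, ncol = p)
  a1 <- character(p); a2 <- character(p)
  for (j in seq_len(p)) {
    x1 <- ped[[6L + 2L * j - 1L]]
    x2 <- ped[[6L + 2L * j]]
    obs <- x1 != "0" & x2 != "0"
    alleles <- sort(unique(c(x1[obs], x2[obs])))
    if (length(alleles) > 2L) {
      warning(sprintf("SNP %s (record %d): more than 2 alleles; dropped as multi-allelic",
                      map$snp_id[j], j))
      next
    }
    if (length(alleles) == 0L) alleles <- c("A", "B")
    if (length(alleles) == 1L) {
      # monomorphic column: 'A' is our writer's non-counted label, so an
      # all-'A' column is 0 copies; any other single allele counts as 2
      alleles <- if (alleles == "A") c("A", "B") else c("A", alleles)
    }
    a1[j] <- alleles[1]; a2[j] <- alleles[2]
    # counted allele = the lexicographically later label (B for our writer)
    g[obs, j] <- (x1[obs] == alleles[2]) + (x2[obs] == alleles[2])
  }
  keep <- !(a1 == "" & a2 == "")
  map_out <- data.frame(snp_id = map$snp_id, chr = as.character(map$chr),
                        pos = map$pos, a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
  genotype_matrix(g[, keep, drop = FALSE], map_out, smp)
}

read_vcf_text <- function(path) {
  if (!file.exists(path)) gfb_stop(paste0("file not found: ", path), "parse_error")
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) gfb_stop("VCF without a #CHROM header line", "parse_error")
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  if (length(cols) < 10L) gfb_stop("VCF has no sample columns", "parse_error")
  ids <- cols[-(1:9)]
  body <- lines[seq.int(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t")
  n <- length(ids)
  keep_rows <- list()
  for (ri in seq_along(recs)) {
    r <- recs[[ri]]
    if (length(r) != length(cols)) {
      gfb_stop(sprintf("VCF record %d has %d fields; expected %d",
                       ri, length(r), length(cols)), "parse_error")
    }
    if (grepl(",", r[5], fixed = TRUE)) {
      warning(sprintf("VCF record %d (%s): multi-allelic site dropped", ri, r[3]))
      next
    }
    gt <- sub(":.*", "", r[-(1:9)])
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    cnt <- ifelse(a %in% c("0", "1") & b %in% c("0", "1"),
                  (a == "1") + (b == "1"), NA_real_)
    keep_rows[[length(keep_rows) + 1L]] <- list(
      chr = r[1], pos = as.integer(r[2]),
      snp_id = if (r[3] == ".") paste0(r[1], ":", r[2]) else r[3],
      a1 = r[4], a2 = r[5], counts = cnt
    )
  }
  if (!length(keep_rows)) gfb_stop("no biallelic records in VCF", "parse_error")
  g <- do.call(cbind, lapply(keep_rows, `[[`, "counts"))
  map <- data.frame(
    snp_id = vapply(keep_rows, `[[`, "", "snp_id"),
    chr = vapply(keep_rows, `[[`, "", "chr"),
    pos = vapply(keep_rows, function(x) x$pos, 1L),
    a1 = vapply(keep_rows, `[[`, "", "a1"),
    a2 = vapply(keep_rows, `[[`, "", "a2"),
    stringsAsFactors = FALSE
  )
  smp <- data.frame(animal_id = ids, population = "pop1",
                    sire_id = NA_character_, dam_id = NA_character_,
                    stringsAsFactors = FALSE)
  genotype_matrix(g, map, smp)
}

#' Read genotypes from PLINK text or VCF
#'
#' Biallelic SNPs are loaded as counts of the alternate (counted) allele;
#' multi-allelic sites are dropped with a warning; missing genotypes
#' (`0 0` in .ped, `./.` in VCF) become NA.
#'
#' @param path for `plink-text`, the file prefix (reads `<path>.ped` and
#'   `<path>.map`); for `vcf`, the path to an uncompressed VCF
#' @param format `"plink-text"` or `"vcf"`
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("plink-text", "vcf")) {
  format <- match.arg(format)
  switch(format,
         "plink-text" = read_plink_text(path),
         "vcf" = read_vcf_text(path))
}

#' Per-population SNP quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min` or with any
#' genotype class (0/1/2) observed fewer than `min_class_count` times.
#' Boundary SNPs (MAF exactly `maf_min`, minimum class exactly
#' `min_class_count`) are retained. Must be applied within a single
#' population; use [intersect_common_snps()] afterwards for combined sets.
#'
#' @param geno a [genotype_matrix()] restricted to one population
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param min_class_count minimum count for each genotype class (default 10)
#' @return list with `geno` (filtered matrix) and `report` (data.frame:
#'   snp_id, maf, min_class_count, removed, reason)
#' @export
qc_filter <- function(geno, maf_min = 0.05, min_class_count = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (length(unique(geno$samples$population)) > 1L) {
    gfb_stop("qc_filter operates within a single population; split first",
             "population_error")
  }
  g <- geno$geno
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  nobs <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * pmax(nobs, 1L))
  maf <- pmin(p, 1 - p)
  min_class <- pmin(n0, n1, n2)
  fail_maf <- maf < maf_min
  fail_class <- min_class < min_class_count
  removed <- fail_maf | fail_class
  reason <- rep("", ncol(g))
  reason[fail_maf] <- "maf"
  reason[fail_class & !fail_maf] <- "class_count"
  reason[fail_class & fail_maf] <- "maf;class_count"
  report <- data.frame(
    snp_id = geno$map$snp_id, maf = maf, min_class_count = as.integer(min_class),
    removed = removed, reason = reason, stringsAsFactors = FALSE
  )
  if (all(removed)) {
    warning("all SNPs removed by QC; returning an empty genotype_matrix")
    out <- genotype_matrix(g[, 0, drop = FALSE], geno$map[0, , drop = FALSE],
                           geno$samples)
    return(list(geno = out, report = report))
  }
  list(geno = subset_genotypes(geno, snps = which(!removed)), report = report)
}

#' Combine populations over their common SNPs
#'
#' Intersects the SNP sets of two or more genotype matrices (matched on
#' SNP id and position) and row-concatenates the individuals, preserving
#' population labels. SNPs are ordered by (chromosome, position).
#'
#' @param genos list of [genotype_matrix()] objects with disjoint individuals
#' @return a combined [genotype_matrix()]
#' @export
intersect_common_snps <- function(genos) {
  if (length(genos) < 2L) gfb_stop("need at least two genotype matrices", "structure_error")
  lapply(genos, function(g) stopifnot(inherits(g, "genotype_matrix")))
  all_ids <- unlist(lapply(genos, function(g) g$samples$animal_id))
  if (anyDuplicated(all_ids)) {
    gfb_stop("individual ids are not disjoint across inputs", "structure_error")
  }
  keys <- lapply(genos, function(g) paste(g$map$snp_id, g$map$pos, sep = "@"))
  common <- Reduce(intersect, keys)
  if (!length(common)) gfb_stop("no common SNPs across inputs", "structure_error")
  # harmonization: allele pairs (when present) must agree for shared ids
  if (all(vapply(genos, function(g) all(c("a1", "a2") %in% names(g$map)), TRUE))) {
    ref <- genos[[1]]$map
    ref_key <- paste(ref$snp_id, ref$pos, sep = "@")
    offenders <- character(0)
    for (g in genos[-1]) {
      k <- paste(g$map$snp_id, g$map$pos, sep = "@")
      shared <- intersect(k, ref_key)
      i1 <- match(shared, ref_key); i2 <- match(shared, k)
      bad <- ref$a1[i1] != g$map$a1[i2] | ref$a2[i1] != g$map$a2[i2]
      offenders <- union(offenders, ref$snp_id[i1][bad])
    }
    if (length(offenders)) {
      gfb_stop(paste0("conflicting alleles for shared SNPs: ",
                      paste(utils::head(offenders, 10), collapse = ", ")),
               "harmonization_error")
    }
  }
  first_map <- genos[[1]]$map
  first_key <- paste(first_map$snp_id, first_map$pos, sep = "@")
  sel <- first_map[match(common, first_key), , drop = FALSE]
  ord <- order(sel$chr, sel$pos)
  sel <- sel[ord, , drop = FALSE]
  rownames(sel) <- NULL
  mats <- lapply(genos, function(g) {
    k <- paste(g$map$snp_id, g$map$pos, sep = "@")
    g$geno[, match(paste(sel$snp_id, sel$pos, sep = "@"), k), drop = FALSE]
  })
  smp <- do.call(rbind, lapply(genos, function(g) g$samples))
  genotype_matrix(do.call(rbind, mats), sel, smp)
}

#' Mean-impute missing genotypes
#'
#' Replaces NA entries by the per-SNP mean allele count over the non-missing
#' individuals; observed entries are unchanged. Required before GRM
#' construction.
#'
#' @param geno a [genotype_matrix()]
#' @return a [genotype_matrix()] with real-valued entries and no NA
#' @export
mean_impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$geno
  nmiss <- colSums(is.na(g))
  if (any(nmiss == nrow(g))) {
    bad <- geno$map$snp_id[nmiss == nrow(g)]
    gfb_stop(paste0("SNP(s) with all entries missing: ",
                    paste(utils::head(bad, 10), collapse = ", ")),
             "all_missing_error")
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  genotype_matrix(g, geno$map, geno$samples)
}

#' Split a genotype matrix by population
#'
#' @param geno a [genotype_matrix()]
#' @return named list of per-population [genotype_matrix()] objects
#' @export
split_by_population <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  pops <- unique(geno$samples$population)
  out <- lapply(pops, function(p) {
    subset_genotypes(geno, individuals = which(geno$samples$population == p))
  })
  names(out) <- pops
  out
}
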