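# Per-site and per-sample statistics on population genotype matrices.
# MAF and observed heterozygosity computed here are the single shared
# implementation consumed by the filtering and segregation-QC modules.

# allele counts per site: matrix sites x (max allele index + 1)
site_allele_counts <- function(pop) {
  m <- n_sites(pop)
  n_all <- if (m == 0) 1L else max(1L + lengths(pop$alt), 2L)
  cnt <- matrix(0, m, n_all)
  for (a in seq_len(n_all) - 1L) {
    cnt[, a + 1L] <- rowSums(pop$a1 == a, na.rm = TRUE) +
      rowSums(pop$a2 == a, na.rm = TRUE)
  }
  cnt
}

#' Per-site minor allele frequency
#'
#' Allele frequencies are computed over non-missing called alleles only. For
#' biallelic sites the MAF is `min(p, 1 - p)`; for multiallelic sites it is
#' the frequency of the second-most-frequent allele. Sites with no called
#' genotype return `NA`.
#'
#' @param pop A `population_vcf`.
#' @return Numeric vector in `[0, 0.5]` (or `NA`), one value per site.
#' @export
site_maf <- function(pop) {
  cnt <- site_allele_counts(pop)
  tot <- rowSums(cnt)
  if (ncol(cnt) == 2) {
    maf <- pmin(cnt[, 1], cnt[, 2]) / tot
  } else {
    second <- apply(cnt, 1, function(x) sort(x, decreasing = TRUE)[2])
    maf <- second / tot
  }
  maf[tot == 0] <- NA_real_
  maf
}

#' Per-site observed heterozygosity
#'
#' Fraction of called genotypes with two distinct allele indices (covers
#' multiallelic heterozygotes). Sites with no called genotype return `NA`.
#'
#' @param pop A `population_vcf`.
#' @return Numeric vector in `[0, 1]` (or `NA`), one value per site.
#' @export
site_observed_het <- function(pop) {
  called <- rowSums(!is.na(pop$a1))
  het <- rowSums(pop$a1 != pop$a2, na.rm = TRUE)
  out <- het / called
  out[called == 0] <- NA_real_
  out
}

# expected heterozygosity 1 - sum p_i^2 (= 2pq for biallelic sites)
site_expected_het <- function(pop) {
  cnt <- site_allele_counts(pop)
  tot <- rowSums(cnt)
  he <- 1 - rowSums((cnt / tot)^2)
  he[tot == 0] <- NA_real_
  he
}

site_n_genotyped <- function(pop) rowSums(!is.na(pop$a1))

#' Per-site Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness of fit of observed genotype counts against the
#' p^2 / 2pq / q^2 expectation, 1 degree of freedom, no continuity
#' correction. Defined for biallelic sites with at least one called
#' genotype; monomorphic sites return statistic 0 and p-value 1, and
#' multiallelic sites return `NA`.
#'
#' @param pop A `population_vcf`.
#' @return `data.frame` with columns `hwe_stat` and `hwe_p`.
#' @export
site_hwe <- function(pop) {
  m <- n_sites(pop)
  stat <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  bi <- lengths(pop$alt) == 1
  n_aa <- rowSums(pop$a1 == 0 & pop$a2 == 0, na.rm = TRUE)
  n_ab <- rowSums(pop$a1 != pop$a2, na.rm = TRUE)
  n_bb <- rowSums(pop$a1 == 1 & pop$a2 == 1, na.rm = TRUE)
  n <- n_aa + n_ab + n_bb
  ok <- bi & n > 0
  p <- (2 * n_aa + n_ab) / (2 * n)
  mono <- ok & (p == 0 | p == 1)
  stat[mono] <- 0
  pval[mono] <- 1
  poly <- which(ok & !mono)
  if (length(poly)) {
    pe <- p[poly]
    ne <- n[poly]
    e_aa <- ne * pe^2
    e_ab <- ne * 2 * pe * (1 - pe)
    e_bb <- ne * (1 - pe)^2
    stat[poly] <- (n_aa[poly] - e_aa)^2 / e_aa +
      (n_ab[poly] - e_ab)^2 / e_ab +
      (n_bb[poly] - e_bb)^2 / e_bb
    pval[poly] <- pchisq(stat[poly], df = 1, lower.tail = FALSE)
  }
  data.frame(hwe_stat = stat, hwe_p = pval)
}

#' Per-site diversity table, optionally stratified by subpopulation
#'
#' For every site: MAF, observed and expected heterozygosity, Hardy-Weinberg
#' chi-square and p-value, and the inbreeding coefficient
#' `Fis = 1 - Ho/He`. When a subpopulation map is supplied the same
#' statistics are added per group, together with Nei-style
#' `Fst = (Ht - mean(Hs)) / Ht`, where `Ht` is the expected heterozygosity of
#' the pooled (grouped) samples; `Fst` is `NA` where `Ht = 0` or a group has
#' no called genotype. Samples absent from the map are excluded from group
#' statistics (but still count in the overall columns).
#'
#' @param pop A `population_vcf`.
#' @param subpop_map Optional: a named character vector (names = samples,
#'   values = group) or a 2-column data.frame (sample, group).
#' @return `data.frame` with one row per site.
#' @export
diversity_table <- function(pop, subpop_map = NULL) {
  altstr <- vapply(pop$alt, paste, character(1), collapse = ",")
  he <- site_expected_het(pop)
  ho <- site_observed_het(pop)
  out <- data.frame(
    chrom = pop$chrom, pos = pop$pos, ref = pop$ref, alt = altstr,
    n_genotyped = site_n_genotyped(pop),
    maf = site_maf(pop), observed_het = ho, expected_het = he,
    site_hwe(pop),
    fis = ifelse(is.na(he) | he == 0, NA_real_, 1 - ho / he),
    stringsAsFactors = FALSE)
  if (is.null(subpop_map)) return(out)
  groups <- normalize_subpop_map(subpop_map, pop$samples)
  gnames <- unique(groups$group)
  subpops <- lapply(gnames, function(g) {
    select_samples(pop, keep = groups$sample[groups$group == g])
  })
  hs <- matrix(NA_real_, n_sites(pop), length(gnames))
  for (i in seq_along(gnames)) {
    sp <- subpops[[i]]
    hs[, i] <- site_expected_het(sp)
    out[[paste0("maf_", gnames[i])]] <- site_maf(sp)
    out[[paste0("observed_het_", gnames[i])]] <- site_observed_het(sp)
    out[[paste0("expected_het_", gnames[i])]] <- hs[, i]
  }
  if (length(gnames) >= 2) {
    pooled <- select_samples(pop, keep = groups$sample)
    ht <- site_expected_het(pooled)
    hs_bar <- rowMeans(hs)              # NA whenever any group uncalled
    fst <- (ht - hs_bar) / ht
    fst[!is.na(ht) & ht == 0] <- NA_real_
    out$fst <- fst
  }
  out
}

normalize_subpop_map <- function(subpop_map, samples) {
  if (is.data.frame(subpop_map)) {
    df <- data.frame(sample = as.character(subpop_map[[1]]),
                     group = as.character(subpop_map[[2]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample = names(subpop_map),
                     group = as.character(subpop_map),
                     stringsAsFactors = FALSE)
  }
  unknown <- setdiff(df$sample, samples)
  if (length(unknown)) {
    stop("subpopulation map names unknown samples: ",
         paste(unknown, collapse = ", "))
  }
  df
}

#' Read a two-column sample-to-subpopulation map
#' @param path Tab-separated file: sample, group (no header).
#' @return data.frame with columns `sample`, `group`.
#' @export
read_subpop_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("subpopulation map needs two columns")
  setNames(df[, 1:2], c("sample", "group"))
}

# genotypes as allele-string pairs, comparable across files whose alternate
# allele lists differ
genotype_strings <- function(pop) {
  m <- n_sites(pop)
  g <- matrix(NA_character_, m, n_samples(pop))
  if (m == 0) return(g)
  for (s in seq_len(m)) {
    alleles <- c(pop$ref[s], pop$alt[[s]])
    called <- !is.na(pop$a1[s, ])
    g[s, called] <- paste(alleles[pop$a1[s, called] + 1L],
                          alleles[pop$a2[s, called] + 1L], sep = "/")
  }
  g
}

#' Pairwise genotype differences between the samples of two files
#'
#' Compares the genotype calls of two population matrices (or one against
#' itself) over the sites shared by both inputs — same (chromosome, position,
#' reference) key — and reports, for every sample pair, the number of
#' co-called differing genotypes, the number of co-called sites, and the
#' number of homozygous differences (both calls homozygous for different
#' alleles), the quantity used for family-integrity screening. Useful to
#' spot duplicated materials (near-zero differences) or direct
#' parent-offspring links (near-zero homozygous differences).
#'
#' @param pop_a A `population_vcf`.
#' @param pop_b Optional second `population_vcf`; defaults to `pop_a`.
#' @return List of class `pairwise_diff` with matrices `differences`,
#'   `comparisons`, `hom_differences` (rows = samples of `pop_a`, columns =
#'   samples of `pop_b`) and `n_shared_sites`.
#' @export
pairwise_differences <- function(pop_a, pop_b = NULL) {
  self <- is.null(pop_b)
  if (self) pop_b <- pop_a
  shared <- intersect(site_keys(pop_a), site_keys(pop_b))
  ia <- match(shared, site_keys(pop_a))
  ib <- match(shared, site_keys(pop_b))
  ga <- genotype_strings(subset_sites(pop_a, ia))
  gb <- if (self) ga else genotype_strings(subset_sites(pop_b, ib))
  hom_a <- {
    p <- subset_sites(pop_a, ia)
    p$a1 == p$a2
  }
  hom_b <- if (self) hom_a else {
    p <- subset_sites(pop_b, ib)
    p$a1 == p$a2
  }
  na <- ncol(ga)
  nb <- ncol(gb)
  d <- matrix(0L, na, nb,
              dimnames = list(pop_a$samples, pop_b$samples))
  cmp <- d
  homd <- d
  for (i in seq_len(na)) {
    gi <- ga[, i]
    hi <- hom_a[, i]
    for (j in seq_len(nb)) {
      both <- !is.na(gi) & !is.na(gb[, j])
      diff <- both & gi != gb[, j]
      cmp[i, j] <- sum(both)
      d[i, j] <- sum(diff)
      homd[i, j] <- sum(diff & hi & hom_b[, j])
    }
  }
  structure(list(differences = d, comparisons = cmp,
                 hom_differences = homd,
                 n_shared_sites = length(shared)),
            class = "pairwise_diff")
}

#' Summary statistics of a population genotype matrix
#'
#' Counts of biallelic SNPs, biallelic indels and other (multiallelic)
#' variants; the MAF distribution (default bin width 0.05); the distribution
#' of sites by number of individuals genotyped; and per-sample counts of
#' genotyped sites, non-reference calls and heterozygous calls.
#'
#' @param pop A `population_vcf`.
#' @param maf_bin_width MAF histogram bin width, default 0.05.
#' @return List of class `pop_summary`.
#' @export
pop_summary <- function(pop, maf_bin_width = 0.05) {
  cls <- table(classify_variants(pop))
  maf <- site_maf(pop)
  breaks <- seq(0, 0.5 + maf_bin_width, by = maf_bin_width)
  breaks <- breaks[breaks <= 0.5 + 1e-9]
  maf_hist <- table(cut(maf[!is.na(maf)], breaks = breaks,
                        include.lowest = TRUE, right = FALSE))
  gcount <- site_n_genotyped(pop)
  gt_hist <- table(factor(gcount, levels = 0:n_samples(pop)))
  called <- !is.na(pop$a1)
  non_ref <- (pop$a1 > 0 | pop$a2 > 0) & called
  het <- pop$a1 != pop$a2 & called
  per_sample <- data.frame(
    sample = pop$samples,
    n_genotyped = colSums(called),
    n_non_reference = colSums(non_ref, na.rm = TRUE),
    n_heterozygous = colSums(het, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    n_sites = n_sites(pop),
    n_biallelic_snps = as.integer(cls[["biallelic_snp"]]),
    n_biallelic_indels = as.integer(cls[["biallelic_indel"]]),
    n_other_variants = as.integer(cls[["other"]]),
    maf_histogram = maf_hist,
    genotyped_count_histogram = gt_hist,
    per_sample = per_sample), class = "pop_summary")
}

#' @export
print.pop_summary <- function(x, ...) {
  cat(sprintf(paste0("pop_summary: %d sites (%d biallelic SNPs, ",
                     "%d biallelic indels, %d other)\n"),
              x$n_sites, x$n_biallelic_snps, x$n_biallelic_indels,
              x$n_other_variants))
  cat("per-sample genotype calls:\n")
  print(head(x$per_sample, 10))
  if (nrow(x$per_sample) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.population_vcf <- function(object, ...) pop_summary(object, ...)
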