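# Mendelian segregation based quality assessment for F1 biparental families
# and MAGIC inbred populations. In an F1 family each SNP follows one of four
# segregation categories determined by the (possibly unobserved) parental
# genotype pair:
#   C1: AAxAA (monomorphic)     expected Ho = 0,   MAF = 0
#   C2: AAxAa                   expected Ho = 0.5, MAF = 0.25
#   C3: AaxAa                   expected Ho = 0.5, MAF = 0.5
#   C4: AAxaa                   expected Ho = 1,   MAF = 0.5
# Sites are classified from the population's observed heterozygosity and
# MAF (robust to missing or erroneous parental genotypes), and genotype
# calls incompatible with the expected segregation of their category are
# counted as errors.

F1_CATEGORIES <- c("C1", "C2", "C3", "C4")

#' Classify SNPs into F1 segregation categories
#'
#' Thresholds: C1 when `Ho < 0.2`; C2 when `0.2 <= Ho <= 0.8` and
#' `MAF <= 0.37`; C3 when `0.2 <= Ho <= 0.8` and `MAF > 0.37`; C4 when
#' `Ho > 0.8` (boundaries inclusive exactly as stated). The thresholds
#' partition the whole `(Ho, MAF)` plane, so every site with at least one
#' called genotype gets exactly one category.
#'
#' @param ho Observed heterozygosity, in `[0, 1]` (vectorised).
#' @param maf Minor allele frequency, in `[0, 0.5]` (vectorised).
#' @return Factor with levels `C1`..`C4` (`NA` in, `NA` out).
#' @export
classify_site <- function(ho, maf) {
  cls <- ifelse(ho < 0.2, "C1",
         ifelse(ho > 0.8, "C4",
         ifelse(maf <= 0.37, "C2", "C3")))
  factor(cls, levels = F1_CATEGORIES)
}

# major allele index per site (ties broken towards the reference allele so
# that a designated "minor" allele always exists)
major_allele <- function(pop) {
  cnt <- site_allele_counts(pop)
  max.col(cnt, ties.method = "first") - 1L
}

#' Count category-specific segregation errors in an F1 family
#'
#' Applies the expected-genotype rules of each segregation category:
#' \describe{
#'   \item{C1 (monomorphic)}{any genotype carrying a minor allele,
#'     heterozygotes included, is an error;}
#'   \item{C2 (AAxAa)}{homozygotes for the minor allele are errors, plus
#'     parental deviations — the parents should be one homozygous-major and
#'     one heterozygous (checked only when both parents are called);}
#'   \item{C3 (AaxAa)}{parental deviations — both parents should be
#'     heterozygous (each called non-heterozygous parent counts);}
#'   \item{C4 (AAxaa)}{heterozygous parents and homozygous offspring are
#'     errors.}
#' }
#'
#' @param pop A `population_vcf` holding parents and offspring.
#' @param parents Character vector of the two parent sample names; parents
#'   absent from the sample list skip the parental checks (with a notice).
#' @param category_map Optional factor of per-site categories (e.g. the
#'   simulator's truth); default: classify from the population's Ho/MAF.
#' @param include_parents_in_stats Compute classification Ho/MAF over all
#'   genotyped samples including the parents (default) or offspring only.
#' @return List of class `category_report`: per-category data frame with
#'   `n_sites`, `n_calls`, `n_errors`, plus the category assignment.
#' @export
count_category_errors <- function(pop, parents, category_map = NULL,
                                  include_parents_in_stats = TRUE) {
  have_parents <- parents %in% pop$samples
  if (!all(have_parents)) {
    message("parent(s) absent from sample list: ",
            paste(parents[!have_parents], collapse = ", "),
            "; parental checks skipped")
  }
  pidx <- match(parents[have_parents], pop$samples)
  oidx <- setdiff(seq_len(n_samples(pop)), pidx)

  if (is.null(category_map)) {
    stat_pop <- if (include_parents_in_stats) pop else
      subset_samples_idx(pop, oidx)
    category_map <- classify_site(site_observed_het(stat_pop),
                                  site_maf(stat_pop))
  }
  stopifnot(length(category_map) == n_sites(pop))

  maj <- major_allele(pop)
  called <- !is.na(pop$a1)
  het <- pop$a1 != pop$a2
  hom <- !het
  carries_minor <- (pop$a1 != maj) | (pop$a2 != maj)
  hom_minor <- hom & pop$a1 != maj
  hom_major <- hom & pop$a1 == maj

  m <- n_sites(pop)
  errors <- matrix(FALSE, m, n_samples(pop))
  parent_extra <- numeric(m)    # C2 parental-pattern deviations (pairwise)

  c1 <- which(category_map == "C1")
  errors[c1, ] <- carries_minor[c1, , drop = FALSE] & called[c1, , drop = FALSE]

  c2 <- which(category_map == "C2")
  errors[c2, ] <- hom_minor[c2, , drop = FALSE]
  if (length(pidx) == 2 && length(c2)) {
    p_het <- het[c2, pidx, drop = FALSE]
    p_hom_major <- hom_major[c2, pidx, drop = FALSE]
    both_called <- rowSums(called[c2, pidx, drop = FALSE]) == 2
    # expected multiset {hom-major, het}: count parents needing change
    match1 <- (p_het[, 1] & p_hom_major[, 2]) |
      (p_het[, 2] & p_hom_major[, 1])
    one_ok <- p_het[, 1] | p_het[, 2] | p_hom_major[, 1] | p_hom_major[, 2]
    dev <- ifelse(match1, 0L, ifelse(one_ok, 1L, 2L))
    # avoid double counting: parental hom-minor cells already flagged above
    already <- rowSums(hom_minor[c2, pidx, drop = FALSE])
    parent_extra[c2] <- ifelse(both_called, pmax(dev - already, 0), 0)
  }

  c3 <- which(category_map == "C3")
  if (length(c3)) {
    errors[c3, pidx] <- called[c3, pidx, drop = FALSE] &
      !het[c3, pidx, drop = FALSE]
  }

  c4 <- which(category_map == "C4")
  if (length(c4)) {
    errors[c4, oidx] <- hom[c4, oidx, drop = FALSE]
    errors[c4, pidx] <- het[c4, pidx, drop = FALSE] &
      called[c4, pidx, drop = FALSE]
  }
  errors[!called] <- FALSE

  per_cat <- data.frame(
    category = F1_CATEGORIES,
    n_sites = as.integer(table(category_map)[F1_CATEGORIES]),
    n_calls = vapply(F1_CATEGORIES, function(cc) {
      sum(called[category_map %in% cc, , drop = FALSE])
    }, numeric(1)),
    n_errors = vapply(F1_CATEGORIES, function(cc) {
      i <- category_map %in% cc
      sum(errors[i, , drop = FALSE]) + sum(parent_extra[i])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_category = per_cat, category_map = category_map,
                 error_matrix = errors),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat("category_report (F1 segregation QC):\n")
  print(x$per_category)
  invisible(x)
}

#' Genotype-quality sweep of the segregation QC
#'
#' For each minimum genotype quality `q`: mask calls below `q`, re-apply the
#' site filters (repeat regions, monomorphic-alternate removal, minimum
#' individuals genotyped), re-classify the surviving sites from the filtered
#' matrix, and re-count category errors. The rows expose the three
#' sensitivity/error curves of the framework: map-useful calls (C2+C3)
#' against their segregation errors, highly heterozygous calls (C4) against
#' false homozygotes, and map-useful calls against errors at monomorphic
#' (C1) sites.
#'
#' @param pop A `population_vcf` with GQ values.
#' @param q_values Numeric vector of minimum genotype qualities.
#' @param parents Two parent sample names.
#' @param min_individuals Minimum individuals genotyped per site after
#'   masking; default 0.
#' @param repeats Optional repeat-region drop list.
#' @param drop_monomorphic_alt Remove monomorphic-alternate sites at each
#'   step; default `TRUE`.
#' @return data.frame with one row per `q`.
#' @export
quality_sweep <- function(pop, q_values, parents, min_individuals = 0,
                          repeats = NULL, drop_monomorphic_alt = TRUE) {
  if (is.null(pop$gq)) stop("quality_sweep requires GQ values")
  cfg <- filter_config(min_individuals_genotyped = min_individuals,
                       drop_monomorphic_alt = drop_monomorphic_alt)
  rows <- lapply(q_values, function(q) {
    fp <- filter_genotype_calls(pop, min_gq = q)
    fp <- filter_sites(fp, cfg, repeats = repeats)
    rep_q <- count_category_errors(fp, parents)$per_category
    data.frame(
      q = q,
      n_sites = sum(rep_q$n_sites),
      sites_c1 = rep_q$n_sites[1], sites_c2 = rep_q$n_sites[2],
      sites_c3 = rep_q$n_sites[3], sites_c4 = rep_q$n_sites[4],
      calls_c2_c3 = rep_q$n_calls[2] + rep_q$n_calls[3],
      errors_c2_c3 = rep_q$n_errors[2] + rep_q$n_errors[3],
      calls_c4 = rep_q$n_calls[4],
      false_hom_c4 = rep_q$n_errors[4],
      errors_c1 = rep_q$n_errors[1])
  })
  do.call(rbind, rows)
}

#' Heterozygosity-based quality assessment for MAGIC populations
#'
#' In a multiparent population bred by single-seed descent, residual
#' heterozygosity halves at each selfing generation, so after `g`
#' generations the per-site heterozygous fraction should fall in
#' `initial_range * 2^-g`. Excess heterozygous calls above this analytic
#' band are very likely genotyping errors. The report contrasts total
#' genotype calls with heterozygous calls, and total SNPs with SNPs whose
#' observed heterozygosity exceeds `ho_threshold`.
#'
#' @param pop A `population_vcf` of the inbred population.
#' @param selfing_generations Number of selfing generations `g` since the
#'   final intercross (F5 lines: 4).
#' @param initial_range Assumed range of the per-site heterozygous fraction
#'   at the intercross stage; default `c(0.25, 0.5)` (random mating of the
#'   founders).
#' @param ho_threshold Per-site Ho above which a SNP is counted as
#'   suspiciously heterozygous; default 0.05.
#' @return List of class `magic_het_report`.
#' @export
magic_het_assessment <- function(pop, selfing_generations = 4,
                                 initial_range = c(0.25, 0.5),
                                 ho_threshold = 0.05) {
  stopifnot(selfing_generations >= 0)
  called <- !is.na(pop$a1)
  het <- pop$a1 != pop$a2 & called
  ho <- site_observed_het(pop)
  band <- initial_range * 2^(-selfing_generations)
  structure(list(
    n_calls = sum(called),
    n_het_calls = sum(het, na.rm = TRUE),
    het_fraction = sum(het, na.rm = TRUE) / sum(called),
    n_snps = n_sites(pop),
    n_snps_high_ho = sum(ho > ho_threshold, na.rm = TRUE),
    ho_threshold = ho_threshold,
    ho_distribution = ho,
    selfing_generations = selfing_generations,
    expected_het_band = band), class = "magic_het_report")
}

#' @export
print.magic_het_report <- function(x, ...) {
  cat(sprintf(paste0("magic_het_report: %d calls, %d heterozygous ",
                     "(%.2f%%); expected band after %d selfing ",
                     "generations: %.3f%% - %.3f%%\n"),
              x$n_calls, x$n_het_calls, 100 * x$het_fraction,
              x$selfing_generations, 100 * x$expected_het_band[1],
              100 * x$expected_het_band[2]))
  cat(sprintf("  SNPs with Ho > %.2f: %d of %d\n", x$ho_threshold,
              x$n_snps_high_ho, x$n_snps))
  invisible(x)
}

#' Family-integrity screen from homozygous differences
#'
#' For each offspring, the fraction of co-called sites where the offspring
#' is homozygous for an allele absent from a parent's homozygous genotype —
#' impossible under Mendelian inheritance, so in a true offspring the
#' fraction only reflects genotyping error. Offspring whose worst fraction
#' across the two parents exceeds `threshold` are flagged as putatively
#' unrelated.
#'
#' @param pop A `population_vcf` with parents and offspring.
#' @param parents Two parent sample names (must be present).
#' @param threshold Flagging threshold on the maximum fraction; default
#'   0.05.
#' @return data.frame: one row per offspring with per-parent fractions,
#'   `max_fraction` and `flagged`.
#' @export
family_integrity <- function(pop, parents, threshold = 0.05) {
  if (!all(parents %in% pop$samples)) {
    stop("parents must be present in the sample list")
  }
  pidx <- match(parents, pop$samples)
  oidx <- setdiff(seq_len(n_samples(pop)), pidx)
  hom <- pop$a1 == pop$a2
  res <- lapply(pidx, function(p) {
    p_hom <- hom[, p] & !is.na(pop$a1[, p])
    p_allele <- pop$a1[, p]
    vapply(oidx, function(o) {
      o_hom <- hom[, o] & !is.na(pop$a1[, o])
      co <- p_hom & o_hom
      if (!sum(co)) return(NA_real_)
      sum(co & pop$a1[, o] != p_allele) / sum(co)
    }, numeric(1))
  })
  frac <- do.call(cbind, res)
  colnames(frac) <- paste0("hom_diff_vs_", parents)
  mx <- apply(frac, 1, max, na.rm = TRUE)
  data.frame(sample = pop$samples[oidx], frac,
             max_fraction = mx, flagged = mx > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
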