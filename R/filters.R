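# Layered filtering of population genotype matrices: per-call masking on
# quality/depth, sample selection, and site-level filters (individuals
# genotyped, MAF, regions, variant type, heterozygosity, inter-marker
# distance, GC content, monomorphic-alternate removal, annotations).

#' Filter configuration for site-level filtering
#'
#' All thresholds default to their permissive extremes, so an empty
#' configuration is the identity transformation. Region lists are data frames
#' with columns `chrom`, `start`, `end` (1-based inclusive; see
#' [read_region_file()] for BED-like input).
#'
#' @param min_individuals_genotyped Minimum number of samples with a called
#'   genotype.
#' @param min_maf,max_maf Minor allele frequency bounds in `[0, 0.5]`,
#'   computed over non-missing alleles; sites with zero called alleles fail
#'   any active MAF bound.
#' @param min_distance_bp Minimum distance from the previously retained site
#'   on the same chromosome (greedy left-to-right scan, first site kept).
#' @param keep_regions,drop_regions Interval data frames; `keep_regions`
#'   restricts to sites inside the intervals, `drop_regions` removes sites
#'   inside them (e.g. repeat-masked regions).
#' @param biallelic_snps_only Keep only biallelic SNPs.
#' @param min_observed_het,max_observed_het Observed heterozygosity bounds.
#' @param drop_monomorphic_alt Remove sites where every called genotype is
#'   homozygous for the alternate allele.
#' @param gc_window Total width (bp) of the reference window centred on each
#'   site used by the GC filter; default 100.
#' @param min_gc,max_gc GC-content bounds in `[0, 1]`; activating them
#'   requires a reference sequence.
#' @param annotation_whitelist Character vector of INFO tags; when set, only
#'   sites whose INFO annotation contains at least one tag are kept.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_individuals_genotyped = 0,
                          min_maf = 0, max_maf = 0.5,
                          min_distance_bp = 0,
                          keep_regions = NULL, drop_regions = NULL,
                          biallelic_snps_only = FALSE,
                          min_observed_het = 0, max_observed_het = 1,
                          drop_monomorphic_alt = FALSE,
                          gc_window = 100, min_gc = 0, max_gc = 1,
                          annotation_whitelist = NULL) {
  stopifnot(min_maf >= 0, min_maf <= max_maf, max_maf <= 0.5,
            min_gc >= 0, max_gc <= 1, min_gc <= max_gc,
            gc_window >= 1, min_distance_bp >= 0,
            min_observed_het >= 0, max_observed_het <= 1)
  for (r in list(keep_regions, drop_regions)) {
    if (!is.null(r) && any(r$start > r$end)) {
      stop("malformed interval (start > end)")
    }
  }
  structure(as.list(environment()), class = "filter_config")
}

#' Mask genotype calls below quality or depth thresholds
#'
#' Calls with GQ below `min_gq` or DP below `min_dp` are set to missing;
#' the number of sites and samples is unchanged. A call lacking the
#' corresponding FORMAT value fails any strictly positive threshold.
#'
#' @param pop A `population_vcf`.
#' @param min_gq Minimum genotype quality (phred); 0 disables.
#' @param min_dp Minimum read depth; 0 disables.
#' @return Filtered `population_vcf`.
#' @export
filter_genotype_calls <- function(pop, min_gq = 0, min_dp = 0) {
  mask <- matrix(FALSE, n_sites(pop), n_samples(pop))
  if (min_gq > 0) {
    if (is.null(pop$gq)) {
      mask[] <- TRUE
    } else {
      mask <- mask | is.na(pop$gq) | pop$gq < min_gq
    }
  }
  if (min_dp > 0) {
    if (is.null(pop$dp)) {
      mask[] <- TRUE
    } else {
      mask <- mask | is.na(pop$dp) | pop$dp < min_dp
    }
  }
  pop$a1[mask] <- NA_integer_
  pop$a2[mask] <- NA_integer_
  # a masked call carries no per-genotype fields either
  if (!is.null(pop$gq)) pop$gq[mask] <- NA_integer_
  if (!is.null(pop$dp)) pop$dp[mask] <- NA_integer_
  pop
}

#' Select or remove samples
#'
#' @param pop A `population_vcf`.
#' @param keep,drop Character vectors of sample names (give one of the two).
#'   An unknown name is an error. Site-level statistics become recomputable
#'   on the subset; sites themselves are retained (re-filter separately).
#' @return `population_vcf` restricted to the selected samples.
#' @export
select_samples <- function(pop, keep = NULL, drop = NULL) {
  if (!is.null(keep) && !is.null(drop)) stop("give either keep or drop")
  target <- c(keep, drop)
  unknown <- setdiff(target, pop$samples)
  if (length(unknown)) {
    stop("unknown sample name(s): ", paste(unknown, collapse = ", "))
  }
  j <- if (!is.null(keep)) {
    match(keep, pop$samples)
  } else {
    which(!(pop$samples %in% drop))
  }
  subset_samples_idx(pop, j)
}

#' Read a BED-like interval file
#'
#' Three-column tab-separated text (chromosome, start, end) in the BED
#' convention — 0-based, half-open — converted internally to the package's
#' 1-based inclusive coordinates.
#'
#' @param path Path to the interval file.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_region_file <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("region file needs at least 3 columns: ", path)
  data.frame(chrom = as.character(df[[1]]),
             start = as.integer(df[[2]]) + 1L,   # 0-based -> 1-based
             end = as.integer(df[[3]]),          # half-open -> inclusive
             stringsAsFactors = FALSE)
}

sites_in_regions <- function(pop, regions) {
  sites <- GenomicRanges::GRanges(pop$chrom,
                                  IRanges::IRanges(pop$pos, pop$pos))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  IRanges::overlapsAny(sites, gr)
}

site_gc_content <- function(pop, reference, gc_window) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  missing_chrom <- setdiff(unique(pop$chrom), names(reference))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chrom, collapse = ", "))
  }
  half <- gc_window %/% 2
  len <- Biostrings::width(reference)[match(pop$chrom, names(reference))]
  start <- pmax(1L, pop$pos - half)
  end <- pmin(len, pop$pos + (gc_window - half) - 1L)
  win <- Biostrings::subseq(reference[pop$chrom], start = start, end = end)
  as.numeric(Biostrings::letterFrequency(win, "GC")) / (end - start + 1L)
}

#' Site-level filtering
#'
#' Retains the sites passing all enabled criteria of the configuration:
#' individuals genotyped, MAF bounds, region selection/removal (plus an
#' explicit `repeats` drop list), variant type, observed heterozygosity,
#' monomorphic-alternate removal, GC content of the reference window, INFO
#' annotation whitelist, and finally the inter-marker distance filter
#' (greedy left-to-right, order-dependent by construction). All other
#' criteria are set intersections and therefore commute.
#'
#' @param pop A `population_vcf`.
#' @param cfg A [filter_config()].
#' @param repeats Optional extra drop-region data frame (e.g. repeat-masked
#'   intervals), combined with `cfg$drop_regions`.
#' @param reference Optional reference sequence (`DNAStringSet` or FASTA
#'   path); required when the GC filter is active.
#' @return Filtered `population_vcf`.
#' @export
filter_sites <- function(pop, cfg = filter_config(), repeats = NULL,
                         reference = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  m <- n_sites(pop)
  keep <- rep(TRUE, m)
  if (cfg$min_individuals_genotyped > 0) {
    keep <- keep & site_n_genotyped(pop) >= cfg$min_individuals_genotyped
  }
  if (cfg$min_maf > 0 || cfg$max_maf < 0.5) {
    maf <- site_maf(pop)
    keep <- keep & !is.na(maf) & maf >= cfg$min_maf & maf <= cfg$max_maf
  }
  drop_regions <- rbind(cfg$drop_regions, repeats)
  if (!is.null(drop_regions) && nrow(drop_regions) > 0) {
    keep <- keep & !sites_in_regions(pop, drop_regions)
  }
  if (!is.null(cfg$keep_regions)) {
    keep <- keep & sites_in_regions(pop, cfg$keep_regions)
  }
  if (cfg$biallelic_snps_only) {
    keep <- keep & classify_variants(pop) == "biallelic_snp"
  }
  if (cfg$min_observed_het > 0 || cfg$max_observed_het < 1) {
    ho <- site_observed_het(pop)
    keep <- keep & !is.na(ho) & ho >= cfg$min_observed_het &
      ho <= cfg$max_observed_het
  }
  if (cfg$drop_monomorphic_alt) {
    cnt <- site_allele_counts(pop)
    tot <- rowSums(cnt)
    mono_alt <- tot > 0 & cnt[, 1] == 0 &
      apply(cnt[, -1, drop = FALSE] > 0, 1, sum) == 1 &
      site_observed_het(pop) == 0
    keep <- keep & !mono_alt
  }
  if (cfg$min_gc > 0 || cfg$max_gc < 1) {
    if (is.null(reference)) {
      stop("GC filtering requires a reference sequence")
    }
    gc <- site_gc_content(pop, reference, cfg$gc_window)
    keep <- keep & gc >= cfg$min_gc & gc <= cfg$max_gc
  }
  if (!is.null(cfg$annotation_whitelist)) {
    info <- pop$info %||% rep(".", m)
    pat <- paste(cfg$annotation_whitelist, collapse = "|")
    keep <- keep & grepl(pat, info)
  }
  pop <- subset_sites(pop, which(keep))
  if (cfg$min_distance_bp > 0) {
    pop <- subset_sites(pop, distance_scan(pop, cfg$min_distance_bp))
  }
  pop
}

# greedy scan: keep the first site of each chromosome, then the next site at
# least d bp downstream of the last retained one
distance_scan <- function(pop, d) {
  keep <- logical(n_sites(pop))
  last_chrom <- ""
  last_pos <- -Inf
  for (s in seq_len(n_sites(pop))) {
    if (pop$chrom[s] != last_chrom || pop$pos[s] - last_pos >= d) {
      keep[s] <- TRUE
      last_chrom <- pop$chrom[s]
      last_pos <- pop$pos[s]
    }
  }
  which(keep)
}
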