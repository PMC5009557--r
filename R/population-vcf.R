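# Multi-sample genotype data model: the population VCF matrix every other
# module transforms. Genotypes are stored as two integer allele-index
# matrices (sites x samples, NA = missing call) plus optional GQ/DP matrices.
# Allele indices follow VCF: 0 = reference, 1.. = alternate alleles. Calls are
# unphased; allele pairs are normalised so a1 <= a2.

#' Construct a population genotype matrix
#'
#' The central container of the package: an ordered sample list plus variant
#' records sorted by (chromosome, position), with per-call genotype quality
#' (GQ) and read depth (DP) carried alongside the allele matrices.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference alleles.
#' @param alt List of character vectors (or a character vector for
#'   biallelic-only data) of alternate alleles per site.
#' @param a1,a2 Integer matrices (sites x samples) of allele indices;
#'   `NA` marks a missing call. Pairs are reordered so `a1 <= a2`.
#' @param gq,dp Optional integer matrices of genotype qualities / depths.
#' @param info Optional character vector of per-site INFO annotations,
#'   passed through opaquely on write.
#' @param imputed Optional logical matrix flagging imputed calls.
#' @param sort Sort records by (chromosome, position)? Default `TRUE`.
#' @return An object of class `population_vcf`.
#' @export
population_vcf <- function(samples, chrom, pos, ref, alt, a1, a2,
                           gq = NULL, dp = NULL, info = NULL,
                           imputed = NULL, sort = TRUE) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (!is.list(alt)) alt <- as.list(as.character(alt))
  m <- length(pos)
  n <- length(samples)
  a1 <- matrix(as.integer(a1), m, n)
  a2 <- matrix(as.integer(a2), m, n)
  stopifnot(length(chrom) == m, length(ref) == m, length(alt) == m)
  if (!is.null(gq)) gq <- matrix(as.integer(gq), m, n)
  if (!is.null(dp)) dp <- matrix(as.integer(dp), m, n)
  if (!is.null(imputed)) imputed <- matrix(as.logical(imputed), m, n)

  # partially-missing and phased calls normalised: missing if either side NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  pop <- structure(
    list(samples = samples, chrom = as.character(chrom),
         pos = as.integer(pos), ref = toupper(as.character(ref)),
         alt = lapply(alt, function(x) toupper(as.character(x))),
         a1 = a1, a2 = a2, gq = gq, dp = dp,
         info = if (is.null(info)) NULL else as.character(info),
         imputed = imputed),
    class = "population_vcf")
  if (sort) pop <- sort_sites(pop)
  validate_population_vcf(pop)
  pop
}

validate_population_vcf <- function(pop) {
  m <- length(pop$pos)
  n <- length(pop$samples)
  stopifnot(
    identical(dim(pop$a1), c(m, n)) || (m == 0L),
    identical(dim(pop$a2), dim(pop$a1))
  )
  if (m > 0) {
    n_alleles <- 1L + lengths(pop$alt)
    mx <- suppressWarnings(apply(pop$a2, 1, max, na.rm = TRUE))
    bad <- which(is.finite(mx) & mx >= n_alleles)
    if (length(bad)) {
      stop("allele index out of range at ", pop$chrom[bad[1]], ":",
           pop$pos[bad[1]])
    }
    if (any(lengths(pop$alt) == 0)) stop("empty alternate allele list")
    empty_alt <- vapply(pop$alt, function(x) any(!nzchar(x)), logical(1))
    if (any(empty_alt)) stop("empty alternate allele string")
    same <- mapply(function(r, a) any(a == r), pop$ref, pop$alt)
    if (any(same)) stop("alternate allele equal to reference")
  }
  invisible(pop)
}

sort_sites <- function(pop) {
  o <- order(pop$chrom, pop$pos)
  if (!identical(o, seq_along(o))) pop <- subset_sites(pop, o)
  pop
}

#' @export
print.population_vcf <- function(x, ...) {
  cat(sprintf("population_vcf: %d sites x %d samples\n",
              n_sites(x), n_samples(x)))
  cls <- table(classify_variants(x))
  cat(sprintf("  biallelic SNPs: %d, biallelic indels: %d, other: %d\n",
              cls[["biallelic_snp"]], cls[["biallelic_indel"]],
              cls[["other"]]))
  cat(sprintf("  missing genotype calls: %.1f%%\n",
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Number of variant sites / samples
#' @param pop A `population_vcf`.
#' @return Integer count.
#' @export
n_sites <- function(pop) length(pop$pos)

#' @rdname n_sites
#' @export
n_samples <- function(pop) length(pop$samples)

# row/column subsetting keep every parallel slot aligned

subset_sites <- function(pop, i) {
  pop$chrom <- pop$chrom[i]
  pop$pos <- pop$pos[i]
  pop$ref <- pop$ref[i]
  pop$alt <- pop$alt[i]
  for (f in c("a1", "a2", "gq", "dp", "imputed")) {
    if (!is.null(pop[[f]])) pop[[f]] <- pop[[f]][i, , drop = FALSE]
  }
  if (!is.null(pop$info)) pop$info <- pop$info[i]
  pop
}

subset_samples_idx <- function(pop, j) {
  pop$samples <- pop$samples[j]
  for (f in c("a1", "a2", "gq", "dp", "imputed")) {
    if (!is.null(pop[[f]])) pop[[f]] <- pop[[f]][, j, drop = FALSE]
  }
  pop
}

site_keys <- function(pop) paste(pop$chrom, pop$pos, pop$ref, sep = "\t")

#' Classify variants as biallelic SNPs, biallelic indels or other
#'
#' The three-way discrimination used throughout the summary statistics:
#' a single-base reference with a single single-base alternate is a biallelic
#' SNP; any other single-alternate site is a biallelic indel; sites with two
#' or more alternate alleles are "other" (multiallelic).
#'
#' @param pop A `population_vcf`.
#' @return Factor with levels `biallelic_snp`, `biallelic_indel`, `other`.
#' @export
classify_variants <- function(pop) {
  nalt <- lengths(pop$alt)
  alt1 <- vapply(pop$alt, `[`, character(1), 1)
  cls <- ifelse(nalt > 1, "other",
         ifelse(nchar(pop$ref) == 1 & nchar(alt1) == 1,
                "biallelic_snp", "biallelic_indel"))
  factor(cls, levels = c("biallelic_snp", "biallelic_indel", "other"))
}

# io --------------------------------------------------------------------------

#' Read a multi-sample VCF file
#'
#' Loads a VCF 4.x file into the package's genotype matrix. Only the GT, GQ
#' and DP FORMAT fields are retained; `./.` and `.` genotypes (and any
#' half-missing call) become missing. Records are sorted by (chromosome,
#' position) if the file is unsorted. Phasing separators are ignored.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @return A [population_vcf()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_header(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (nrow(v@fix) == 0) {
    return(population_vcf(samples, character(0), integer(0), character(0),
                          list(), matrix(integer(0), 0, length(samples)),
                          matrix(integer(0), 0, length(samples))))
  }
  fmt <- v@gt[, "FORMAT"]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(x) "GT" %in% x, logical(1))
  if (!all(has_gt)) {
    stop("GT field absent from FORMAT at record ", which(!has_gt)[1])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  a1c <- sub("[/|].*$", "", gt)
  a2c <- sub("^[^/|]*[/|]", "", gt)   # haploid GT left unchanged -> a2 == a1
  a1 <- suppressWarnings(matrix(as.integer(a1c), nrow(gt), ncol(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2c), nrow(gt), ncol(gt)))
  gq <- extract_numeric_format(v, "GQ")
  dp <- extract_numeric_format(v, "DP")
  alt <- strsplit(v@fix[, "ALT"], ",", fixed = TRUE)
  info <- v@fix[, "INFO"]
  info[is.na(info)] <- "."
  population_vcf(samples, v@fix[, "CHROM"],
                 as.integer(v@fix[, "POS"]), v@fix[, "REF"], alt,
                 a1, a2, gq = gq, dp = dp, info = info)
}

check_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0 || !grepl("^##fileformat=VCF", first)) {
    stop("malformed VCF header at line 1 of ", path,
         ": expected '##fileformat=VCFv4.x'")
  }
  invisible(TRUE)
}

extract_numeric_format <- function(v, element) {
  fmt <- v@gt[, "FORMAT"]
  if (!any(grepl(element, fmt, fixed = TRUE))) return(NULL)
  x <- suppressWarnings(
    vcfR::extract.gt(v, element = element, as.numeric = TRUE))
  matrix(as.integer(round(x)), nrow(x), ncol(x))
}

#' Write a population genotype matrix as VCF
#'
#' Emits a standard-conforming plain-text VCF 4.2 file. GQ and DP are written
#' for every call where they are known, so that downstream quality filtering
#' keeps working on re-read files; missing calls are written as `./.`.
#' Imputed calls (when flagged) carry an `IM` FORMAT subfield.
#'
#' @param pop A `population_vcf`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(pop, path) {
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=gbspop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fields <- "GT"
  if (!is.null(pop$gq)) {
    meta <- c(meta, paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                           "Description=\"Genotype quality\">"))
    fields <- c(fields, "GQ")
  }
  if (!is.null(pop$dp)) {
    meta <- c(meta, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                           "Description=\"Read depth\">"))
    fields <- c(fields, "DP")
  }
  if (!is.null(pop$imputed)) {
    meta <- c(meta, paste0("##FORMAT=<ID=IM,Number=1,Type=Integer,",
                           "Description=\"Genotype imputed (1) or ",
                           "observed (0)\">"))
    fields <- c(fields, "IM")
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", pop$samples), collapse = "\t")
  m <- n_sites(pop)
  if (m == 0) {
    writeLines(c(meta, header), path)
    return(invisible(path))
  }
  gtcell <- ifelse(is.na(pop$a1), "./.", paste0(pop$a1, "/", pop$a2))
  cells <- gtcell
  if (!is.null(pop$gq)) {
    cells <- paste0(cells, ":", ifelse(is.na(pop$gq) | is.na(pop$a1),
                                       ".", pop$gq))
  }
  if (!is.null(pop$dp)) {
    cells <- paste0(cells, ":", ifelse(is.na(pop$dp), ".", pop$dp))
  }
  if (!is.null(pop$imputed)) {
    cells <- paste0(cells, ":", as.integer(pop$imputed))
  }
  cells <- matrix(cells, m, n_samples(pop))
  altstr <- vapply(pop$alt, paste, character(1), collapse = ",")
  info <- pop$info %||% rep(".", m)
  fixed <- paste(pop$chrom, pop$pos, ".", pop$ref, altstr, ".", ".",
                 info, paste(fields, collapse = ":"), sep = "\t")
  body <- do.call(paste, c(list(fixed),
                           lapply(seq_len(ncol(cells)),
                                  function(j) cells[, j]),
                           list(sep = "\t")))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

# merge -----------------------------------------------------------------------

#' Merge per-sample (or per-batch) VCF matrices into one population matrix
#'
#' Site identity is (chromosome, position, reference allele); the merged site
#' set is the union of the inputs' sites, alternate-allele lists are unioned
#' with allele-index remapping, and a sample with no record at a union site
#' receives a missing call. Two inputs disagreeing on the reference allele at
#' the same coordinate are an error.
#'
#' @param pops List of `population_vcf` objects with disjoint sample sets.
#' @return A merged `population_vcf`.
#' @export
merge_population <- function(pops) {
  stopifnot(length(pops) >= 1)
  for (p in pops) {
    if (!inherits(p, "population_vcf")) stop("inputs must be population_vcf")
    if (n_samples(p) < 1) stop("every input must contain at least one sample")
  }
  samples <- unlist(lapply(pops, `[[`, "samples"))
  if (anyDuplicated(samples)) {
    stop("duplicate sample names across inputs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  # union site table, with reference-conflict detection
  coord <- unique(do.call(rbind, lapply(pops, function(p) {
    data.frame(chrom = p$chrom, pos = p$pos, ref = p$ref,
               stringsAsFactors = FALSE)
  })))
  dup <- duplicated(coord[, c("chrom", "pos")])
  if (any(dup)) {
    stop("conflicting reference allele at ", coord$chrom[dup][1], ":",
         coord$pos[dup][1])
  }
  coord <- coord[order(coord$chrom, coord$pos), , drop = FALSE]
  ukey <- paste(coord$chrom, coord$pos, coord$ref, sep = "\t")
  m <- length(ukey)
  alt_union <- vector("list", m)
  for (p in pops) {
    idx <- match(site_keys(p), ukey)
    for (s in seq_along(idx)) {
      alt_union[[idx[s]]] <- union(alt_union[[idx[s]]], p$alt[[s]])
    }
  }
  n <- length(samples)
  a1 <- matrix(NA_integer_, m, n)
  a2 <- matrix(NA_integer_, m, n)
  any_gq <- any(vapply(pops, function(p) !is.null(p$gq), logical(1)))
  any_dp <- any(vapply(pops, function(p) !is.null(p$dp), logical(1)))
  gq <- if (any_gq) matrix(NA_integer_, m, n) else NULL
  dp <- if (any_dp) matrix(NA_integer_, m, n) else NULL
  col0 <- 0L
  dropped_info <- FALSE
  for (p in pops) {
    jj <- col0 + seq_len(n_samples(p))
    idx <- match(site_keys(p), ukey)
    same <- vapply(seq_along(idx), function(s) {
      identical(p$alt[[s]], alt_union[[idx[s]]])
    }, logical(1))
    pa1 <- p$a1
    pa2 <- p$a2
    if (!all(same)) {
      for (s in which(!same)) {
        map <- c(0L, match(p$alt[[s]], alt_union[[idx[s]]]))
        pa1[s, ] <- map[pa1[s, ] + 1L]
        pa2[s, ] <- map[pa2[s, ] + 1L]
      }
    }
    a1[idx, jj] <- pa1
    a2[idx, jj] <- pa2
    if (any_gq && !is.null(p$gq)) gq[idx, jj] <- p$gq
    if (any_dp && !is.null(p$dp)) dp[idx, jj] <- p$dp
    if (!is.null(p$info) && any(p$info != ".")) dropped_info <- TRUE
    col0 <- col0 + n_samples(p)
  }
  if (dropped_info) message("merge_population: INFO annotations dropped")
  population_vcf(samples, coord$chrom, coord$pos, coord$ref, alt_union,
                 a1, a2, gq = gq, dp = dp, sort = FALSE)
}

#' Split a population matrix into single-sample matrices
#'
#' Inverse companion of [merge_population()]: each output keeps the full site
#' list (missing calls included) so that merging the pieces reproduces the
#' joint matrix exactly.
#'
#' @param pop A `population_vcf`.
#' @return Named list of single-sample `population_vcf` objects.
#' @export
split_by_sample <- function(pop) {
  out <- lapply(seq_along(pop$samples),
                function(j) subset_samples_idx(pop, j))
  names(out) <- pop$samples
  out
}
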