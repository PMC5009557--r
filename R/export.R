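# Exporters towards downstream analysis tools: distance/dendrogram
# software (per-sample allele-count table), outbred full-sib genetic
# mapping (CP-coded loci), and genomic selection (numeric -1/0/1 matrix).

#' Export a genotype matrix to a downstream-analysis format
#'
#' \describe{
#'   \item{`gs_numeric`}{tab-separated numeric matrix for genomic selection
#'     (rrBLUP-style): one row per sample, one column per biallelic SNP,
#'     coded 1 = homozygous reference, 0 = heterozygous, -1 = homozygous
#'     alternate (reference-major convention), missing written as
#'     `missing_sentinel`.}
#'   \item{`distance_dendrogram`}{tab-separated allele-count table (one row
#'     per sample, alternate-allele count 0/1/2 per site) for
#'     distance-based dendrogram tools.}
#'   \item{`mapping_cp`}{outbred full-sib (CP) coded loci for genetic-map
#'     construction: segregation classes lmxll / nnxnp / hkxhk inferred
#'     from the designated parental genotypes; sites with uncalled or
#'     uninformative parents are skipped.}
#' }
#'
#' `mapping_cp` and `gs_numeric` require biallelic SNPs only — filter
#' first.
#'
#' @param pop A `population_vcf`.
#' @param format One of `"distance_dendrogram"`, `"mapping_cp"`,
#'   `"gs_numeric"`.
#' @param path Output path.
#' @param parents Two parent sample names (required for `mapping_cp`).
#' @param missing_sentinel Value written for missing calls in the numeric
#'   exports; default `NA`.
#' @return Invisibly, `path`.
#' @export
export_matrix <- function(pop, format = c("distance_dendrogram",
                                          "mapping_cp", "gs_numeric"),
                          path, parents = NULL, missing_sentinel = NA) {
  format <- match.arg(format)
  if (format %in% c("mapping_cp", "gs_numeric") &&
      !all(classify_variants(pop) == "biallelic_snp")) {
    stop(format, " export requires biallelic SNPs only; filter first")
  }
  site_names <- paste0(pop$chrom, "_", pop$pos)
  switch(format,
    gs_numeric = {
      dosage <- 1L - (pop$a1 + pop$a2)     # 1 / 0 / -1
      mat <- t(dosage)
      mat[is.na(mat)] <- missing_sentinel
      df <- data.frame(sample = pop$samples, mat,
                       stringsAsFactors = FALSE)
      colnames(df) <- c("sample", site_names)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    distance_dendrogram = {
      cnt <- t((pop$a1 > 0) + (pop$a2 > 0)) # alternate-allele count 0/1/2
      cnt[is.na(cnt)] <- missing_sentinel
      df <- data.frame(sample = pop$samples, cnt,
                       stringsAsFactors = FALSE)
      colnames(df) <- c("sample", site_names)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    mapping_cp = {
      if (is.null(parents) || length(parents) != 2) {
        stop("mapping_cp export requires two designated parent samples")
      }
      if (!all(parents %in% pop$samples)) {
        stop("unknown parent sample(s): ",
             paste(setdiff(parents, pop$samples), collapse = ", "))
      }
      write_cp_loci(pop, parents, path)
    })
  invisible(path)
}

# CP locus coding: per site, infer the segregation class from the parental
# genotype pair; offspring are coded per class, incompatible genotypes as
# missing ("--")
write_cp_loci <- function(pop, parents, path) {
  pidx <- match(parents, pop$samples)
  oidx <- setdiff(seq_len(n_samples(pop)), pidx)
  offspring <- pop$samples[oidx]
  code <- pop$a1 + pop$a2                  # 0 hom-ref, 1 het, 2 hom-alt
  lines <- character(0)
  header <- paste(c("locus", "segregation", offspring), collapse = "\t")
  for (s in seq_len(n_sites(pop))) {
    p <- code[s, pidx]
    if (any(is.na(p))) next
    o <- code[s, oidx]
    if (p[1] == 1 && p[2] == 1) {          # hkxhk
      seg <- "<hkxhk>"
      g <- c("hh", "hk", "kk")[o + 1]
    } else if (p[1] == 1 && p[2] != 1) {   # first parent heterozygous
      seg <- "<lmxll>"
      g <- ifelse(o == 1, "lm", ifelse(o == p[2], "ll", "--"))
    } else if (p[2] == 1 && p[1] != 1) {   # second parent heterozygous
      seg <- "<nnxnp>"
      g <- ifelse(o == 1, "np", ifelse(o == p[1], "nn", "--"))
    } else {
      next                                  # both homozygous: uninformative
    }
    g[is.na(o)] <- "--"
    lines <- c(lines, paste(c(paste0(pop$chrom[s], "_", pop$pos[s]), seg,
                              g), collapse = "\t"))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
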