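# Small fixtures built in code. Genotype codes: 0 = hom-ref, 1 = het,
# 2 = hom-alt, NA = missing.

pop_from_codes <- function(codes, samples = NULL, gq = NULL, dp = NULL,
                           chrom = NULL, pos = NULL, ref = NULL,
                           alt = NULL) {
  codes <- as.matrix(codes)
  m <- nrow(codes)
  n <- ncol(codes)
  samples <- samples %||% sprintf("S%02d", seq_len(n))
  a1 <- ifelse(codes == 2L, 1L, 0L)
  a2 <- ifelse(codes >= 1L, 1L, 0L)
  a1[is.na(codes)] <- NA_integer_
  a2[is.na(codes)] <- NA_integer_
  population_vcf(samples,
                 chrom %||% rep("1", m),
                 pos %||% (seq_len(m) * 100L),
                 ref %||% rep("A", m),
                 alt %||% rep("T", m),
                 a1, a2, gq = gq, dp = dp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact infinite-population offspring genotype distributions of the four
# F1 parental crosses, represented as finite cohorts with the exact
# Mendelian proportions
cross_offspring_codes <- list(
  AAxAA = c(0, 0, 0, 0),
  AAxAa = c(0, 0, 1, 1),
  AaxAa = c(0, 1, 1, 2),
  AAxaa = c(1, 1, 1, 1))

cross_offspring_pop <- function(cross) {
  pop_from_codes(matrix(cross_offspring_codes[[cross]], nrow = 1))
}

expect_pop_equal <- function(a, b) {
  expect_identical(a$samples, b$samples)
  expect_identical(a$chrom, b$chrom)
  expect_identical(a$pos, b$pos)
  expect_identical(a$ref, b$ref)
  expect_identical(a$alt, b$alt)
  expect_identical(a$a1, b$a1)
  expect_identical(a$a2, b$a2)
  expect_identical(is.null(a$gq), is.null(b$gq))
  if (!is.null(a$gq)) expect_identical(a$gq, b$gq)
}
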