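# data model, VCF read/write, merging, exporters

test_that("a toy VCF loads with counts, field mapping and missing calls", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", ".", ".", "GT:GQ",
          "0/1:40", "0|0:17", "./.", sep = "\t"),
    paste("1", "250", ".", "G", "C,GA", ".", ".", ".", "GT:GQ",
          "1/2:12", "0/0:60", ".", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  pop <- read_vcf(f)
  expect_equal(n_samples(pop), 3)
  expect_equal(n_sites(pop), 2)
  expect_equal(pop$a1[1, 1], 0L)         # "0/1", GQ 40
  expect_equal(pop$a2[1, 1], 1L)
  expect_equal(pop$gq[1, 1], 40L)
  expect_equal(pop$a1[1, 2], 0L)         # phased "0|0" read as unphased
  expect_true(is.na(pop$a1[1, 3]))       # "./." and "." are missing
  expect_true(is.na(pop$a1[2, 3]))
  expect_equal(pop$a2[2, 1], 2L)         # multiallelic indices preserved
  expect_equal(pop$alt[[2]], c("C", "GA"))
})

test_that("reading rejects malformed headers and GT-less records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "#CHROM\tPOS"), f)
  expect_error(read_vcf(f), "malformed VCF header")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "100", ".", "A", "T", ".", ".", ".", "GQ", "40",
          sep = "\t")), f)
  expect_error(read_vcf(f), "GT")
})

test_that("write/read round trip is lossless on GT, GQ and site fields", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 12, n_sites = 80,
                                   seed = 42))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$observed, f)
  back <- read_vcf(f)
  expect_pop_equal(back, sim$observed)
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("an empty record list writes a valid header-only VCF", {
  pop <- pop_from_codes(matrix(c(0, 1), 1), samples = c("A", "B"))
  empty <- filter_sites(pop, filter_config(min_maf = 0.4, max_maf = 0.4))
  expect_equal(n_sites(empty), 0)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, f)
  back <- read_vcf(f)
  expect_equal(n_sites(back), 0)
  expect_equal(back$samples, c("A", "B"))
})

test_that("missing calls are written as ./.", {
  pop <- pop_from_codes(matrix(c(0, NA), 1), samples = c("A", "B"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pop, f)
  body <- readLines(f)
  expect_match(body[length(body)], "\\./\\.$")
})

test_that("merging single-sample files has union-of-sites semantics", {
  # shared sites: two single-sample files -> 2 samples, same site count
  joint <- pop_from_codes(rbind(c(0, 1), c(2, 0), c(1, 1)),
                          samples = c("A", "B"))
  parts <- split_by_sample(joint)
  merged <- merge_population(parts)
  expect_pop_equal(merged, joint)

  # disjoint sites: union with MISSING fill
  x <- pop_from_codes(matrix(0, 1), samples = "A", pos = 100L)
  y <- pop_from_codes(matrix(2, 1), samples = "B", pos = 900L)
  m <- merge_population(list(x, y))
  expect_equal(n_sites(m), 2)
  expect_equal(sum(is.na(m$a1)), 2)
  expect_true(is.na(m$a1[2, 1]) && is.na(m$a1[1, 2]))
})

test_that("merge unions alternate-allele lists with index remapping", {
  x <- population_vcf("A", "1", 100L, "A", list("T"),
                      matrix(1L), matrix(1L))          # T/T
  y <- population_vcf("B", "1", 100L, "A", list(c("G", "T")),
                      matrix(0L), matrix(2L))          # A/T (T has index 2)
  m <- merge_population(list(x, y))
  expect_equal(n_sites(m), 1)
  expect_setequal(m$alt[[1]], c("T", "G"))
  # both samples' "T" allele maps to the same merged index
  t_idx <- match("T", m$alt[[1]])
  expect_equal(c(m$a1[1, 1], m$a2[1, 1]), c(t_idx, t_idx))
  expect_setequal(c(m$a1[1, 2], m$a2[1, 2]), c(0L, t_idx))
})

test_that("merge is order-invariant up to sample order and rejects clashes", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 5, n_sites = 40,
                                   seed = 7))
  parts <- split_by_sample(sim$observed)
  m1 <- merge_population(parts)
  m2 <- merge_population(rev(parts))
  m2 <- select_samples(m2, keep = m1$samples)
  expect_pop_equal(m1, m2)

  expect_error(merge_population(list(parts[[1]], parts[[1]])),
               "duplicate sample")
  z <- population_vcf("Z", "1", parts[[1]]$pos[1], "C", list("T"),
                      matrix(0L), matrix(0L))
  expect_error(merge_population(list(parts[[1]], z)),
               "conflicting reference")
})

test_that("gs_numeric export codes AA/Aa/aa as 1/0/-1 with right shape", {
  pop <- pop_from_codes(rbind(c(0, 1, 2), c(2, NA, 0)),
                        samples = c("X", "Y", "Z"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(pop, "gs_numeric", f)
  tab <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(dim(tab), c(3, 1 + 2))     # samples x (name + sites)
  expect_equal(tab[[2]], c(1, 0, -1))     # AA, Aa, aa
  expect_equal(tab[[3]], c(-1, NA, 1))
  expect_error(export_matrix(
    population_vcf("A", "1", 1L, "A", list("AT"), matrix(0L), matrix(1L)),
    "gs_numeric", f), "biallelic SNPs only")
})

test_that("mapping_cp export infers CP classes from parental genotypes", {
  codes <- rbind(c(0, 1, 0, 1),   # AA x Aa -> nnxnp (parent 2 het)
                 c(1, 1, 0, 2),   # Aa x Aa -> hkxhk
                 c(1, 0, 1, 0),   # Aa x AA -> lmxll
                 c(0, 0, 0, 0))   # uninformative, skipped
  pop <- pop_from_codes(codes, samples = c("P1", "P2", "O1", "O2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(pop, "mapping_cp", f, parents = c("P1", "P2"))
  out <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(out), 3)
  expect_equal(out$segregation,
               c("<nnxnp>", "<hkxhk>", "<lmxll>"))
  expect_equal(unlist(out[1, 3:4], use.names = FALSE), c("nn", "np"))
  expect_equal(unlist(out[2, 3:4], use.names = FALSE), c("hh", "kk"))
  expect_error(export_matrix(pop, "mapping_cp", f), "parent")
})

test_that("distance export reports per-sample alternate allele counts", {
  pop <- pop_from_codes(rbind(c(0, 1, 2)), samples = c("X", "Y", "Z"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(pop, "distance_dendrogram", f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab[[2]], c(0, 1, 2))
})
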