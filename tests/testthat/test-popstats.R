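# MAF, heterozygosity, HWE, diversity, pairwise comparison, summaries

test_that("site_maf counts alleles over non-missing calls", {
  # AA, Aa, Aa, aa -> 4 of 8 alternate alleles -> 0.5
  expect_equal(site_maf(pop_from_codes(matrix(c(0, 1, 1, 2), 1))), 0.5)
  # all AA -> 0
  expect_equal(site_maf(pop_from_codes(matrix(c(0, 0, 0), 1))), 0)
  # AAxAa offspring distribution (half AA, half Aa) -> 0.25
  expect_equal(site_maf(cross_offspring_pop("AAxAa")), 0.25)
  # missing calls excluded from the denominator
  expect_equal(site_maf(pop_from_codes(matrix(c(0, 1, NA, NA), 1))),
               0.25)
  expect_true(is.na(site_maf(pop_from_codes(matrix(NA, 1, 3)))))
})

test_that("site_observed_het is the heterozygous fraction of called genotypes", {
  expect_equal(site_observed_het(cross_offspring_pop("AAxAa")), 0.5)
  expect_equal(site_observed_het(cross_offspring_pop("AAxaa")), 1)
  expect_equal(site_observed_het(pop_from_codes(matrix(c(0, 2, 0), 1))),
               0)
  expect_equal(site_observed_het(pop_from_codes(matrix(c(1, NA), 1))), 1)
})

test_that("multiallelic sites use the second-most-frequent allele", {
  # alleles: ref x4, alt1 x3, alt2 x1 -> maf = 3/8
  pop <- population_vcf(c("a", "b", "c", "d"), "1", 100L, "A",
                        list(c("C", "G")),
                        matrix(c(0L, 0L, 1L, 1L), 1),
                        matrix(c(0L, 1L, 1L, 2L), 1))
  expect_equal(site_maf(pop), 3 / 8)
  expect_equal(site_observed_het(pop), 2 / 4)
})

test_that("HWE chi-square matches hand computation and a normal-tail oracle", {
  # counts (AA, Aa, aa) = (30, 40, 30): expected (25, 50, 25) ->
  # 25/25 + 100/50 + 25/25 = 4.0
  pop <- pop_from_codes(matrix(rep(c(0, 1, 2), c(30, 40, 30)), 1))
  hwe <- site_hwe(pop)
  expect_equal(hwe$hwe_stat, 4.0)
  # df = 1 chi-square upper tail equals the folded standard normal tail:
  # an implementation-independent closed form
  expect_equal(hwe$hwe_p, 2 * pnorm(sqrt(4.0), lower.tail = FALSE),
               tolerance = 1e-9)

  # exactly at HWE proportions -> statistic 0
  pop0 <- pop_from_codes(matrix(rep(c(0, 1, 2), c(25, 50, 25)), 1))
  expect_equal(site_hwe(pop0)$hwe_stat, 0)
  # monomorphic -> (0, 1)
  popm <- pop_from_codes(matrix(c(0, 0), 1))
  expect_equal(unlist(site_hwe(popm)), c(hwe_stat = 0, hwe_p = 1))

  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    pop_i <- pop_from_codes(matrix(sample(0:2, n, replace = TRUE), 1))
    h <- site_hwe(pop_i)
    expect_equal(h$hwe_p, 2 * pnorm(sqrt(h$hwe_stat),
                                    lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("fst hits its analytic extremes and closed form", {
  groups <- data.frame(sample = sprintf("S%02d", 1:8),
                       group = rep(c("g1", "g2"), each = 4))
  # fixed opposite alleles -> fst 1
  fixed <- pop_from_codes(matrix(rep(c(0, 2), each = 4), 1))
  expect_equal(diversity_table(fixed, groups)$fst, 1)
  # identical allele frequencies -> fst 0
  same <- pop_from_codes(matrix(rep(c(0, 0, 1, 2), 2), 1))
  expect_equal(diversity_table(same, groups)$fst, 0)

  # closed form on known frequencies: p1 = 1/8, p2 = 6/8 (allele counts)
  codes <- matrix(c(0, 0, 0, 1, 2, 2, 1, 1), 1)
  p1 <- 1 / 8
  p2 <- 6 / 8
  hs <- mean(c(2 * p1 * (1 - p1), 2 * p2 * (1 - p2)))
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  expect_equal(diversity_table(pop_from_codes(codes), groups)$fst,
               (ht - hs) / ht)
})

test_that("diversity table He is 2pq and Fis follows Ho/He", {
  pop <- pop_from_codes(matrix(c(0, 1, 1, 2), 1))
  d <- diversity_table(pop)
  expect_equal(d$expected_het, 0.5)      # p = 0.5 -> 2pq = 0.5
  expect_equal(d$fis, 1 - 0.5 / 0.5)
  expect_equal(d$maf, site_maf(pop))     # shared implementation surfaces
})

test_that("pairwise self-comparison has a zero-difference diagonal", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 10, n_sites = 150,
                                   seed = 23))
  pd <- pairwise_differences(sim$observed)
  expect_equal(unname(diag(pd$differences)), rep(0L, 12))
  expect_equal(unname(diag(pd$comparisons)),
               unname(colSums(!is.na(sim$observed$a1))))
  expect_equal(pd$differences, t(pd$differences))   # symmetry
})

test_that("a duplicated sample shows its simulated discordance rate", {
  # one true genotype vector observed twice under independent 1% hom/het
  # flip errors: the copies differ wherever exactly one flipped (rate
  # 2 * 0.01 * 0.99; double-flip collisions are second order)
  sim <- simulate_f1(f1_sim_config(n_offspring = 40, n_sites = 2000,
                                   error_rate = 0, missing_rate = 0,
                                   seed = 27))
  truth_col <- match("O001", sim$truth$samples)
  o1 <- sim$truth$a1[, truth_col] + sim$truth$a2[, truth_col]
  set.seed(29)
  observe_once <- function(g) {
    flip <- runif(length(g)) < 0.01
    ifelse(flip, ifelse(g == 1, sample(c(0, 2), length(g),
                                       replace = TRUE), 1), g)
  }
  p_obs <- pop_from_codes(cbind(observe_once(o1), observe_once(o1)),
                          samples = c("O001", "O001dup"),
                          pos = sim$observed$pos)
  pd <- pairwise_differences(p_obs)
  frac <- pd$differences["O001", "O001dup"] /
    pd$comparisons["O001", "O001dup"]
  expected <- 2 * 0.01 * 0.99
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("disjoint site sets yield zero comparisons", {
  a <- pop_from_codes(matrix(0, 2, 2), pos = c(100L, 200L))
  b <- pop_from_codes(matrix(1, 2, 2), pos = c(300L, 400L))
  pd <- pairwise_differences(a, b)
  expect_true(all(pd$comparisons == 0))
  expect_equal(pd$n_shared_sites, 0)
})

test_that("summary counts variant classes, histograms and per-sample calls", {
  pop <- population_vcf(
    c("X", "Y", "Z"), rep("1", 4), c(10L, 20L, 30L, 40L),
    c("A", "C", "G", "T"),
    list("T", "G", "GA", c("A", "C")),       # 2 SNPs, 1 indel, 1 multi
    rbind(c(0L, 0L, 1L), c(0L, 1L, NA), c(0L, 0L, 0L), c(1L, 2L, 0L)),
    rbind(c(0L, 1L, 1L), c(0L, 1L, NA), c(1L, 0L, 0L), c(1L, 2L, 0L)))
  s <- pop_summary(pop)
  expect_equal(s$n_biallelic_snps, 2)
  expect_equal(s$n_biallelic_indels, 1)
  expect_equal(s$n_other_variants, 1)
  expect_equal(s$n_biallelic_snps + s$n_biallelic_indels +
                 s$n_other_variants, s$n_sites)
  # hand tally per sample: genotyped, non-reference, heterozygous
  expect_equal(s$per_sample$n_genotyped, c(4, 4, 3))
  expect_equal(s$per_sample$n_non_reference, c(2, 3, 1))
  expect_equal(s$per_sample$n_heterozygous, c(1, 1, 0))
  expect_equal(sum(s$genotyped_count_histogram), s$n_sites)

  e <- pop_summary(filter_sites(pop_from_codes(matrix(0, 1, 2)),
                                filter_config(min_maf = 0.3)))
  expect_equal(e$n_sites, 0)
  expect_equal(e$per_sample$n_genotyped, c(0, 0))
})
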