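# segregation-category classification, error counting, MAGIC heterozygosity
# assessment, family integrity

test_that("classification thresholds follow the printed boundaries", {
  expect_equal(as.character(classify_site(0.5, 0.25)), "C2")
  expect_equal(as.character(classify_site(1.0, 0.5)), "C4")
  expect_equal(as.character(classify_site(0, 0)), "C1")
  expect_equal(as.character(classify_site(0.5, 0.5)), "C3")
  # boundary cases exactly as printed: Ho in [0.2, 0.8] inclusive,
  # MAF 0.37 inclusive for C2
  expect_equal(as.character(classify_site(0.2, 0.37)), "C2")
  expect_equal(as.character(classify_site(0.2, 0.3700001)), "C3")
  expect_equal(as.character(classify_site(0.8, 0.37)), "C2")
  expect_equal(as.character(classify_site(0.8000001, 0.37)), "C4")
  expect_equal(as.character(classify_site(0.1999999, 0.5)), "C1")
})

test_that("classification partitions the (Ho, MAF) plane", {
  grid <- expand.grid(ho = seq(0, 1, by = 0.01),
                      maf = seq(0, 0.5, by = 0.01))
  cls <- classify_site(grid$ho, grid$maf)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), c("C1", "C2", "C3", "C4"))
})

test_that("analytic cross distributions reproduce the expected (Ho, MAF) and land in their own categories", {
  expected <- list(AAxAA = c(0, 0), AAxAa = c(0.5, 0.25),
                   AaxAa = c(0.5, 0.5), AAxaa = c(1, 0.5))
  for (cross in names(expected)) {
    pop <- cross_offspring_pop(cross)
    ho <- site_observed_het(pop)
    maf <- site_maf(pop)
    expect_equal(c(ho, maf), expected[[cross]], info = cross)
  }
  cats <- vapply(names(expected), function(cross) {
    pop <- cross_offspring_pop(cross)
    as.character(classify_site(site_observed_het(pop), site_maf(pop)))
  }, character(1))
  expect_equal(unname(cats), c("C1", "C2", "C3", "C4"))
})

test_that("category error rules follow the expected genotypes", {
  # C4 (AAxaa): perfect segregation -> zero errors; then inject 3
  # homozygous siblings
  codes <- rbind(c(0, 2, rep(1, 10)))
  pop <- pop_from_codes(codes, samples = c("P1", "P2",
                                           sprintf("O%02d", 1:10)))
  rep0 <- count_category_errors(pop, c("P1", "P2"))
  expect_equal(rep0$per_category$n_errors[4], 0)
  bad <- pop
  bad$a2[1, c(4, 6, 9)] <- bad$a1[1, c(4, 6, 9)]
  rep1 <- count_category_errors(bad, c("P1", "P2"),
                                category_map = factor("C4",
                                                      F1_CATEGORIES))
  expect_equal(rep1$per_category$n_errors[4], 3)
  # a heterozygous parent at a C4 site is an error too
  bad2 <- pop
  bad2$a1[1, 1] <- 0L
  bad2$a2[1, 1] <- 1L
  rep2 <- count_category_errors(bad2, c("P1", "P2"),
                                category_map = factor("C4",
                                                      F1_CATEGORIES))
  expect_equal(rep2$per_category$n_errors[4], 1)

  # C1: one heterozygous call is one error (minor-allele rule)
  mono <- pop_from_codes(rbind(rep(0, 12)),
                         samples = c("P1", "P2", sprintf("O%02d", 1:10)))
  mono$a2[1, 5] <- 1L
  repc1 <- count_category_errors(mono, c("P1", "P2"))
  expect_equal(repc1$per_category$n_errors[1], 1)

  # C2: minor-allele homozygotes are errors, parental deviations counted
  c2codes <- rbind(c(0, 1, rep(c(0, 1), 5)))
  c2pop <- pop_from_codes(c2codes, samples = c("P1", "P2",
                                               sprintf("O%02d", 1:10)))
  expect_equal(count_category_errors(
    c2pop, c("P1", "P2"))$per_category$n_errors[2], 0)
  c2bad <- c2pop
  c2bad$a1[1, 7] <- 1L                    # minor-allele homozygote
  c2bad$a2[1, 7] <- 1L
  expect_equal(count_category_errors(
    c2bad, c("P1", "P2"),
    category_map = factor("C2", F1_CATEGORIES))$per_category$n_errors[2],
    1)
  c2par <- c2pop                          # both parents hom-major
  c2par$a1[1, 2] <- 0L
  c2par$a2[1, 2] <- 0L
  expect_equal(count_category_errors(
    c2par, c("P1", "P2"),
    category_map = factor("C2", F1_CATEGORIES))$per_category$n_errors[2],
    1)

  # C3: non-heterozygous parents are deviations
  c3codes <- rbind(c(1, 0, 0, 1, 1, 2, 0, 1, 2, 1))
  c3pop <- pop_from_codes(c3codes, samples = c("P1", "P2",
                                               sprintf("O%02d", 1:8)))
  expect_equal(count_category_errors(
    c3pop, c("P1", "P2"),
    category_map = factor("C3", F1_CATEGORIES))$per_category$n_errors[3],
    1)
})

test_that("absent parents skip parental checks with a notice", {
  pop <- cross_offspring_pop("AaxAa")
  expect_message(count_category_errors(pop, c("P1", "P2")), "skipped")
})

test_that("error-free simulated families give zero errors in all categories", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 120, n_sites = 2000,
                                   error_rate = 0, missing_rate = 0,
                                   seed = 61))
  rep0 <- count_category_errors(sim$observed, sim$parents)
  expect_equal(rep0$per_category$n_errors, rep(0, 4))
})

test_that("injected rule violations are recovered exactly by count", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 80, n_sites = 1500,
                                   error_rate = 0, missing_rate = 0.05,
                                   seed = 67))
  inj <- inject_segregation_violations(sim, c(C1 = 12, C2 = 25, C4 = 9),
                                       seed = 68)
  rep1 <- count_category_errors(inj$pop, sim$parents,
                                category_map = sim$site_truth$category)
  expect_equal(rep1$per_category$n_errors,
               c(inj$injected[["C1"]], inj$injected[["C2"]], 0,
                 inj$injected[["C4"]]))
})

test_that("quality sweeps are monotone and reproduce the unfiltered report at q = 0", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 60, n_sites = 800,
                                   seed = 71))
  sw <- quality_sweep(sim$observed, c(0, 20, 40, 60), sim$parents,
                      min_individuals = 40)
  expect_equal(nrow(sw), 4)
  # q = 0 equals the direct unfiltered computation
  direct <- count_category_errors(
    filter_sites(sim$observed,
                 filter_config(min_individuals_genotyped = 40,
                               drop_monomorphic_alt = TRUE)),
    sim$parents)$per_category
  expect_equal(sw$calls_c2_c3[1], direct$n_calls[2] + direct$n_calls[3])
  expect_equal(sw$errors_c2_c3[1],
               direct$n_errors[2] + direct$n_errors[3])
  # counts monotone non-increasing in q
  expect_true(all(diff(sw$calls_c2_c3) <= 0))
  expect_true(all(diff(sw$calls_c4) <= 0))
  expect_true(all(diff(sw$n_sites) <= 0))
})

test_that("error fraction at q = 0 reflects the injected error rate", {
  eps <- 0.02
  sim <- simulate_f1(f1_sim_config(n_offspring = 100, n_sites = 2000,
                                   category_mix = c(C1 = 0, C2 = 0,
                                                    C3 = 0, C4 = 1),
                                   error_rate = eps, missing_rate = 0,
                                   seed = 73))
  # in C4 every hom/het flip of an offspring call is a detectable error
  rep0 <- count_category_errors(sim$observed, sim$parents,
                                category_map = sim$site_truth$category)
  n_calls <- rep0$per_category$n_calls[4]
  frac <- rep0$per_category$n_errors[4] / n_calls
  # every flip at an AAxaa site violates the category rule, so the error
  # count recovers the injected flips exactly
  expect_equal(rep0$per_category$n_errors[4], sum(sim$flipped))
  se <- sqrt(eps * (1 - eps) / n_calls)
  expect_lt(abs(frac - eps), 4 * se)
})

test_that("MAGIC heterozygosity assessment computes the analytic band", {
  sim <- simulate_magic(magic_sim_config(n_lines = 50, n_sites = 300,
                                         seed = 79))
  rep4 <- magic_het_assessment(sim$truth, selfing_generations = 4)
  expect_equal(rep4$expected_het_band, c(0.25, 0.5) * 2^-4)
  expect_equal(rep4$expected_het_band, c(0.015625, 0.03125))
  rep0 <- magic_het_assessment(sim$truth, selfing_generations = 0)
  expect_equal(rep0$expected_het_band, c(0.25, 0.5))
  expect_equal(rep4$n_het_calls,
               sum(sim$truth$a1 != sim$truth$a2, na.rm = TRUE))
})

test_that("realized MAGIC heterozygosity falls in the analytic band", {
  sim <- simulate_magic(magic_sim_config(seed = 83))
  rep4 <- magic_het_assessment(sim$truth)
  line_het <- colMeans(sim$truth$a1 != sim$truth$a2)
  se <- sd(line_het) / sqrt(length(line_het))
  band <- rep4$expected_het_band
  expect_gt(rep4$het_fraction, band[1] - 3 * se)
  expect_lt(rep4$het_fraction, band[2] + 3 * se)
})

test_that("family integrity flags unrelated samples, not true offspring", {
  sim <- simulate_f1(f1_sim_config(n_offspring = 40, n_sites = 1500,
                                   error_rate = 0.005, missing_rate = 0.1,
                                   seed = 89))
  fam <- family_integrity(sim$observed, sim$parents, threshold = 0.05)
  expect_false(any(fam$flagged))
  # impossible-homozygote fraction is of the order of the error rate
  expect_lt(max(fam$max_fraction), 0.03)

  # an unrelated line: genotypes drawn independently of the family
  set.seed(90)
  alien_codes <- sample(0:2, 1500, replace = TRUE)
  pop2 <- sim$observed
  pop2$a1 <- cbind(pop2$a1, ifelse(alien_codes == 2, 1L, 0L))
  pop2$a2 <- cbind(pop2$a2, ifelse(alien_codes >= 1, 1L, 0L))
  pop2$gq <- cbind(pop2$gq, rep(60L, 1500))
  pop2$samples <- c(sim$observed$samples, "ALIEN")
  fam2 <- family_integrity(pop2, sim$parents, threshold = 0.05)
  expect_true(fam2$flagged[fam2$sample == "ALIEN"])

  # a parent as pseudo-offspring under zero error has fraction 0
  sim0 <- simulate_f1(f1_sim_config(n_offspring = 10, n_sites = 300,
                                    error_rate = 0, missing_rate = 0,
                                    seed = 91))
  fam0 <- family_integrity(sim0$truth, sim0$parents)
  expect_equal(max(fam0$max_fraction), 0)
  expect_error(family_integrity(sim0$truth, c("P1", "nope")), "present")
})
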