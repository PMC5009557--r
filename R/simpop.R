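# Ground-truth simulators: F1 biparental families, 8-founder MAGIC
# populations bred by single-seed descent, selfing-decay cohorts, and
# barcoded sequencing lanes. Every generator is deterministic given its
# seed, and returns truth tables so downstream modules can be scored
# exactly.

# genotype codes used internally by the simulators: 0 = hom ref,
# 1 = het, 2 = hom alt

codes_to_pop <- function(codes, samples, gq = NULL, chrom = "1",
                         pos = NULL) {
  m <- nrow(codes)
  pos <- pos %||% cumsum(sample(50:150, m, replace = TRUE))
  a1 <- matrix(ifelse(codes == 2L, 1L, 0L), m, ncol(codes))
  a2 <- matrix(ifelse(codes >= 1L, 1L, 0L), m, ncol(codes))
  a1[is.na(codes)] <- NA_integer_
  a2[is.na(codes)] <- NA_integer_
  ref_alt <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE),
                    m, 2)
  clash <- ref_alt[, 1] == ref_alt[, 2]
  ref_alt[clash, 2] <- chartr("ACGT", "CGTA", ref_alt[clash, 1])
  population_vcf(samples, rep(chrom, m), pos, ref_alt[, 1],
                 as.list(ref_alt[, 2]), a1, a2, gq = gq, sort = FALSE)
}

# stochastic GQ model: correct calls draw from a high-mean normal,
# erroneous calls from a low-mean one, so quality sweeps are meaningful
draw_gq <- function(is_error, gq_model) {
  n <- length(is_error)
  gq <- numeric(n)
  gq[!is_error] <- rnorm(sum(!is_error), gq_model$correct[1],
                         gq_model$correct[2])
  gq[is_error] <- rnorm(sum(is_error), gq_model$error[1],
                        gq_model$error[2])
  as.integer(clamp(round(gq), 0, 99))
}

# flip a call between homozygous and heterozygous (the dominant error mode
# between genotyping pipelines); hets flip to either homozygote with equal
# probability
flip_codes <- function(codes, flip_idx) {
  cur <- codes[flip_idx]
  new <- integer(length(cur))
  new[cur != 1L] <- 1L
  hets <- cur == 1L
  new[hets] <- sample(c(0L, 2L), sum(hets), replace = TRUE)
  codes[flip_idx] <- new
  codes
}

observe_codes <- function(truth_codes, error_rate, missing_rate, gq_model) {
  m <- nrow(truth_codes)
  n <- ncol(truth_codes)
  obs <- truth_codes
  flip <- matrix(runif(m * n) < error_rate, m, n)
  flip[is.na(obs)] <- FALSE
  if (any(flip)) obs <- flip_codes(obs, which(flip))
  gq <- matrix(draw_gq(as.vector(flip), gq_model), m, n)
  miss <- matrix(runif(m * n) < missing_rate, m, n)
  obs[miss] <- NA_integer_
  gq[miss | is.na(obs)] <- NA_integer_
  list(codes = obs, gq = gq, flipped = flip & !miss)
}

#' Configuration for the F1 family simulator
#'
#' Defaults emulate a GBS experiment on a biparental full-sib family of an
#' outcrossing species: 137 offspring (a typical family size), mostly
#' map-informative sites, a 1% genotyping error rate and 10% missing calls.
#'
#' @param n_offspring Number of full sibs; default 137.
#' @param n_sites Number of SNP sites; default 5000.
#' @param category_mix Proportions of the four segregation categories
#'   (C1 AAxAA, C2 AAxAa, C3 AaxAa, C4 AAxaa); must sum to 1.
#' @param error_rate Per-call flip probability; default 0.01.
#' @param missing_rate Per-call missing probability; default 0.10.
#' @param gq_model List with `correct` and `error` = (mean, sd) of the GQ
#'   distributions for correct and erroneous calls.
#' @param seed Random seed.
#' @return List of class `f1_sim_config`.
#' @export
f1_sim_config <- function(n_offspring = 137, n_sites = 5000,
                          category_mix = c(C1 = 0.10, C2 = 0.35,
                                           C3 = 0.35, C4 = 0.20),
                          error_rate = 0.01, missing_rate = 0.10,
                          gq_model = list(correct = c(60, 15),
                                          error = c(25, 10)),
                          seed = 1) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-9,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "f1_sim_config")
}

#' Simulate a genotyped F1 biparental family
#'
#' Parental genotypes are drawn per segregation category (C1 AAxAA, C2
#' AAxAa, C3 AaxAa, C4 AAxaa, with A the reference allele and the
#' heterozygous parent of C2 chosen at random); offspring genotypes follow
#' Mendelian sampling; the observed matrix adds hom/het flip errors and
#' missing calls, with erroneous calls drawing stochastically lower GQ.
#'
#' @param cfg A [f1_sim_config()].
#' @return List of class `f1_sim`: `truth` and `observed`
#'   (`population_vcf`s over samples P1, P2, O001...), `site_truth`
#'   (per-site category and parental genotypes), `flipped` (logical matrix
#'   of injected flips over all samples) and `n_flipped`.
#' @export
simulate_f1 <- function(cfg = f1_sim_config()) {
  set.seed(cfg$seed)
  m <- cfg$n_sites
  n <- cfg$n_offspring
  category <- factor(sample(F1_CATEGORIES, m, replace = TRUE,
                            prob = cfg$category_mix),
                     levels = F1_CATEGORIES)
  # parental genotype codes per category
  p1 <- integer(m)
  p2 <- integer(m)
  p1[category == "C2"] <- 0L
  p2[category == "C2"] <- 1L
  swap <- category == "C2" & runif(m) < 0.5
  p1[swap] <- 1L
  p2[swap] <- 0L
  p1[category == "C3"] <- 1L
  p2[category == "C3"] <- 1L
  c4swap <- runif(m) < 0.5
  p1[category == "C4"] <- ifelse(c4swap[category == "C4"], 2L, 0L)
  p2[category == "C4"] <- ifelse(c4swap[category == "C4"], 0L, 2L)

  # offspring: one Mendelian allele draw per parent
  gam <- function(pcode) {
    u <- matrix(runif(m * n), m, n)
    (pcode == 2L) + (pcode == 1L) * (u < 0.5)
  }
  off <- gam(p1) + gam(p2)
  truth_codes <- cbind(p1, p2, off)
  samples <- c("P1", "P2", sprintf("O%03d", seq_len(n)))

  obs <- observe_codes(truth_codes, cfg$error_rate, cfg$missing_rate,
                       cfg$gq_model)
  pos <- cumsum(sample(50:150, m, replace = TRUE))
  truth <- codes_to_pop(truth_codes, samples, pos = pos)
  observed <- codes_to_pop(obs$codes, samples, gq = obs$gq, pos = pos)
  # identical site annotation for both matrices
  observed$ref <- truth$ref
  observed$alt <- truth$alt
  site_truth <- data.frame(chrom = truth$chrom, pos = truth$pos,
                           category = category,
                           parent1 = p1, parent2 = p2,
                           stringsAsFactors = FALSE)
  structure(list(truth = truth, observed = observed,
                 site_truth = site_truth, flipped = obs$flipped,
                 n_flipped = sum(obs$flipped), parents = c("P1", "P2"),
                 cfg = cfg), class = "f1_sim")
}

#' Inject category-rule-violating genotypes into an F1 matrix
#'
#' Flips currently-called, currently-valid offspring genotypes to calls that
#' violate their site's segregation rule (C1: to heterozygous; C2: to the
#' minor-allele homozygote; C4: to a homozygote), with exact bookkeeping of
#' how many violations each category received. C3 sites admit no
#' offspring-level violation and are skipped.
#'
#' @param sim An error-free [simulate_f1()] result (use `error_rate = 0`).
#' @param n_per_category Named integer vector, e.g. `c(C1 = 5, C4 = 3)`.
#' @param seed Random seed.
#' @return List: `pop` (modified observed matrix), `injected` (named counts
#'   actually injected per category).
#' @export
inject_segregation_violations <- function(sim, n_per_category, seed = 1) {
  set.seed(seed)
  pop <- sim$observed
  category <- sim$site_truth$category
  n_par <- 2L
  injected <- setNames(integer(length(n_per_category)),
                       names(n_per_category))
  for (cc in names(n_per_category)) {
    if (cc == "C3") next
    rows <- which(category == cc)
    cells <- as.matrix(expand.grid(row = rows,
                                   col = (n_par + 1):n_samples(pop)))
    called <- !is.na(pop$a1[cells])
    het <- pop$a1[cells] != pop$a2[cells]
    eligible <- switch(cc,
      C1 = cells[called & !het, , drop = FALSE],   # valid C1 calls are hom
      C2 = cells[called & het, , drop = FALSE],    # het -> hom-minor
      C4 = cells[called & het, , drop = FALSE])    # het -> hom
    nn <- min(n_per_category[[cc]], nrow(eligible))
    pick <- eligible[sample(nrow(eligible), nn), , drop = FALSE]
    idx <- pick[, 1] + (pick[, 2] - 1L) * n_sites(pop)
    if (cc == "C1") {
      pop$a1[idx] <- 0L
      pop$a2[idx] <- 1L
    } else {
      # C2: minor allele is the alternate (hom-alt is the violation);
      # C4: any homozygote violates, use hom-ref
      pop$a1[idx] <- if (cc == "C2") 1L else 0L
      pop$a2[idx] <- pop$a1[idx]
    }
    injected[cc] <- nn
  }
  list(pop = pop, injected = injected)
}

#' Configuration for the MAGIC population simulator
#'
#' Defaults emulate a multiparent advanced generation intercross of 8 inbred
#' founders combined by pairwise crosses and crosses of F1 plants, then
#' advanced by single-seed descent for 4 selfing generations (F5 lines).
#'
#' @param n_founders Number of inbred founders; default 8.
#' @param n_lines Number of derived lines; default 200.
#' @param n_sites Number of biallelic SNP sites; default 2000.
#' @param selfing_generations Single-seed-descent generations after the
#'   final intercross; default 4 (F5).
#' @param recombination_rate Per-interval, per-meiosis crossover
#'   probability; default 0.001 (long founder blocks, as in a dense GBS map
#'   of one chromosome).
#' @param error_rate,missing_rate,gq_model As in [f1_sim_config()]; missing
#'   defaults to 0.2, typical of GBS coverage.
#' @param seed Random seed.
#' @return List of class `magic_sim_config`.
#' @export
magic_sim_config <- function(n_founders = 8, n_lines = 200, n_sites = 2000,
                             selfing_generations = 4,
                             recombination_rate = 0.001,
                             error_rate = 0.005, missing_rate = 0.2,
                             gq_model = list(correct = c(60, 15),
                                             error = c(25, 10)),
                             seed = 1) {
  stopifnot(n_founders >= 2, selfing_generations >= 0,
            recombination_rate >= 0, recombination_rate <= 0.5)
  structure(as.list(environment()), class = "magic_sim_config")
}

# one meiosis on founder-ID haplotypes: Markov switching between the two
# parental haplotypes with per-interval crossover probability r
meiosis <- function(hap_a, hap_b, r) {
  m <- length(hap_a)
  sw <- c(runif(1) < 0.5, runif(m - 1) < r)
  use_a <- cumsum(sw) %% 2 == 0
  ifelse(use_a, hap_a, hap_b)
}

#' Simulate a MAGIC population of inbred lines
#'
#' Founder haplotypes are inbred (homozygous); each line descends through
#' its own randomised funnel (pairwise crosses, crosses of the F1s, an
#' 8-way intercross) followed by `selfing_generations` rounds of
#' single-seed descent. Residual heterozygosity halves per selfing
#' generation in expectation. Founder mosaics of every line are retained as
#' imputation ground truth. Per site, the number of founders carrying the
#' alternate allele is uniform on 1..(n_founders - 1).
#'
#' @param cfg A [magic_sim_config()].
#' @return List of class `magic_sim`: `truth` and `observed`
#'   `population_vcf`s over lines L001... (plus the founders F1..F8 as
#'   samples of a separate `founders` matrix), founder mosaics (two
#'   sites x lines matrices of founder indices), the founder allele matrix,
#'   and `flipped`.
#' @export
simulate_magic <- function(cfg = magic_sim_config()) {
  set.seed(cfg$seed)
  m <- cfg$n_sites
  k <- cfg$n_founders
  r <- cfg$recombination_rate
  # founder alleles: x alt carriers per site, x ~ U{1..k-1}
  x <- sample(k - 1, m, replace = TRUE)
  founder_alleles <- matrix(0L, m, k)
  for (s in seq_len(m)) {
    founder_alleles[s, sample(k, x[s])] <- 1L
  }
  hapA <- matrix(0L, m, cfg$n_lines)
  hapB <- matrix(0L, m, cfg$n_lines)
  for (l in seq_len(cfg$n_lines)) {
    # each line descends through its own randomised funnel: founders are
    # paired, the F1s are paired, ... until one intercross individual
    # remains (gametes of inbred founders need no meiosis, but the
    # recombination machinery handles them uniformly)
    funnel <- sample(k)
    gen <- lapply(funnel, function(i) list(rep(i, m), rep(i, m)))
    while (length(gen) > 1) {
      nxt <- lapply(seq_len(length(gen) %/% 2), function(i) {
        list(meiosis(gen[[2 * i - 1]][[1]], gen[[2 * i - 1]][[2]], r),
             meiosis(gen[[2 * i]][[1]], gen[[2 * i]][[2]], r))
      })
      if (length(gen) %% 2) nxt <- c(nxt, gen[length(gen)])
      gen <- nxt
    }
    ind <- gen[[1]]
    for (g in seq_len(cfg$selfing_generations)) {
      ind <- list(meiosis(ind[[1]], ind[[2]], r),
                  meiosis(ind[[1]], ind[[2]], r))
    }
    hapA[, l] <- ind[[1]]
    hapB[, l] <- ind[[2]]
  }
  allele_of <- function(hap) {
    founder_alleles[cbind(rep(seq_len(m), cfg$n_lines), as.vector(hap))]
  }
  al_a <- matrix(allele_of(hapA), m, cfg$n_lines)
  al_b <- matrix(allele_of(hapB), m, cfg$n_lines)
  truth_codes <- al_a + al_b
  samples <- sprintf("L%03d", seq_len(cfg$n_lines))
  obs <- observe_codes(truth_codes, cfg$error_rate, cfg$missing_rate,
                       cfg$gq_model)
  pos <- cumsum(sample(50:150, m, replace = TRUE))
  truth <- codes_to_pop(truth_codes, samples, pos = pos)
  observed <- codes_to_pop(obs$codes, samples, gq = obs$gq, pos = pos)
  observed$ref <- truth$ref
  observed$alt <- truth$alt
  founders <- codes_to_pop(2L * founder_alleles,
                           paste0("F", seq_len(k)), pos = pos)
  founders$ref <- truth$ref
  founders$alt <- truth$alt
  structure(list(truth = truth, observed = observed, founders = founders,
                 mosaic_a = hapA, mosaic_b = hapB,
                 founder_alleles = founder_alleles,
                 flipped = obs$flipped, cfg = cfg), class = "magic_sim")
}

#' Selfing decay of heterozygosity on unlinked sites
#'
#' Direct Mendelian machinery behind the halving law: individuals start
#' heterozygous at each site independently with probability `initial_het`,
#' and at every selfing generation a heterozygous site stays heterozygous
#' with probability 1/2 (otherwise it fixes). Unlinked sites make the
#' realized fractions binomial, so the analytic expectation
#' `initial_het * 2^-g` can be checked against binomial standard errors.
#'
#' @param n_lines,n_sites Cohort dimensions; defaults 200 x 2000.
#' @param initial_het Initial per-site heterozygosity; default 0.5.
#' @param generations Number of selfing generations; default 4.
#' @param seed Random seed.
#' @return data.frame with `generation` (0..g) and realized `het_fraction`,
#'   plus attributes `n_cells` and `expected_final`.
#' @export
simulate_selfing_decay <- function(n_lines = 200, n_sites = 2000,
                                   initial_het = 0.5, generations = 4,
                                   seed = 1) {
  stopifnot(generations >= 0, initial_het >= 0, initial_het <= 1)
  set.seed(seed)
  het <- matrix(runif(n_sites * n_lines) < initial_het, n_sites, n_lines)
  frac <- numeric(generations + 1)
  frac[1] <- mean(het)
  for (g in seq_len(generations)) {
    het <- het & matrix(runif(n_sites * n_lines) < 0.5, n_sites, n_lines)
    frac[g + 1] <- mean(het)
  }
  out <- data.frame(generation = 0:generations, het_fraction = frac)
  attr(out, "n_cells") <- n_sites * n_lines
  attr(out, "expected_final") <- initial_het * 2^(-generations)
  out
}

#' Simulate a barcoded GBS sequencing lane
#'
#' Reads are random sequences prefixed with their sample's barcode; a
#' configurable fraction carries the adapter tag at a random offset in the
#' post-barcode portion (offset 0 yields an empty read after trimming, which
#' demultiplexing discards). Background sequence is screened so the tag
#' never occurs by chance, keeping the recorded trim points exact.
#'
#' @param barcodes A [barcode_map()].
#' @param n_reads Total reads in the lane; default 5000.
#' @param adapter_fraction Fraction of reads carrying the adapter tag;
#'   default 0.35, the contamination level typical of the Elshire GBS
#'   protocol.
#' @param read_length Total read length including the barcode; default 64.
#' @param tag Adapter tag; default `"AGATCG"`.
#' @param out_dir Directory for the FASTQ and barcode files.
#' @param seed Random seed.
#' @return List of class `lane_sim`: `fastq` and `barcode_file` paths and a
#'   `truth` data frame (read id, sample, `has_adapter`, post-barcode
#'   `trim_offset`).
#' @export
simulate_lane <- function(barcodes, n_reads = 5000, adapter_fraction = 0.35,
                          read_length = 64, tag = "AGATCG",
                          out_dir = tempfile("lane"), seed = 1) {
  stopifnot(inherits(barcodes, "barcode_map"),
            adapter_fraction >= 0, adapter_fraction <= 1)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample_of <- sample(barcodes$sample, n_reads, replace = TRUE)
  bc <- barcodes$barcode[match(sample_of, barcodes$sample)]
  body_len <- read_length - nchar(bc)
  stopifnot(all(body_len > nchar(tag)))
  rand_seq <- function(len) {
    vapply(len, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  screen <- function(seqs) {
    bad <- grepl(tag, seqs, fixed = TRUE)
    while (any(bad)) {
      seqs[bad] <- rand_seq(nchar(seqs[bad]))
      bad <- grepl(tag, seqs, fixed = TRUE)
    }
    seqs
  }
  body <- screen(rand_seq(body_len))
  has_adapter <- runif(n_reads) < adapter_fraction
  offset <- rep(NA_integer_, n_reads)
  ai <- which(has_adapter)
  offset[ai] <- vapply(body_len[ai] - nchar(tag), function(mx) {
    sample.int(mx + 1L, 1L) - 1L
  }, integer(1))
  body[ai] <- paste0(substr(body[ai], 1, offset[ai]), tag,
                     substr(body[ai], offset[ai] + nchar(tag) + 1L,
                            body_len[ai]))
  # screening guarantee also for the sequence left of the inserted tag
  reads <- paste0(bc, body)
  ids <- sprintf("read%05d", seq_len(n_reads))
  quals <- vapply(nchar(reads), function(l) {
    paste(rawToChar(as.raw(33 + sample(25:40, l, replace = TRUE)),
                    multiple = FALSE), collapse = "")
  }, character(1))
  fastq <- file.path(out_dir, "lane.fastq")
  write_fastq(ids, reads, quals, fastq)
  barcode_file <- file.path(out_dir, "barcodes.tsv")
  writeLines(paste(barcodes$barcode, barcodes$sample, sep = "\t"),
             barcode_file)
  structure(list(fastq = fastq, barcode_file = barcode_file,
                 truth = data.frame(id = ids, sample = sample_of,
                                    has_adapter = has_adapter,
                                    trim_offset = offset,
                                    stringsAsFactors = FALSE)),
            class = "lane_sim")
}
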