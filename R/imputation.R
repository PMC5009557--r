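# Genotype imputation for populations of inbred lines with a haploid
# haplotype-cluster hidden Markov model. Latent states are K ancestral
# haplotype clusters; emissions are per-cluster alternate-allele
# frequencies theta(c, m); the transition across marker interval i keeps
# the current cluster with probability exp(-rho_i) and otherwise switches
# to cluster c' with probability alpha_i(c'). Parameters are estimated by
# EM on scaled forward-backward recursions; posteriors drive the imputation
# of missing calls.

#' Collapse a diploid matrix of inbred lines to haploid alleles
#'
#' Inbred lines are effectively homozygous, so each genotype is reduced to a
#' single allele: homozygous reference to 0, homozygous alternate to 1, and
#' heterozygous or missing calls to `NA`. The number of heterozygous calls
#' converted to missing is reported so the information loss is visible.
#'
#' @param pop A `population_vcf` containing only biallelic SNPs.
#' @return List of class `haploid_matrix`: `alleles` (sites x samples matrix
#'   of 0/1/`NA`), `n_het_masked`, site coordinates, samples, and the source
#'   matrix.
#' @export
haploidize <- function(pop) {
  if (!all(classify_variants(pop) == "biallelic_snp")) {
    stop("haploidize requires biallelic SNPs only; filter first")
  }
  het <- pop$a1 != pop$a2
  alleles <- pop$a1
  alleles[which(het)] <- NA_integer_
  structure(list(alleles = alleles,
                 n_het_masked = sum(het, na.rm = TRUE),
                 chrom = pop$chrom, pos = pop$pos,
                 samples = pop$samples, source = pop),
            class = "haploid_matrix")
}

#' @export
print.haploid_matrix <- function(x, ...) {
  cat(sprintf(paste0("haploid_matrix: %d sites x %d samples; ",
                     "%d heterozygous calls masked; %.1f%% missing\n"),
              nrow(x$alleles), ncol(x$alleles), x$n_het_masked,
              100 * mean(is.na(x$alleles))))
  invisible(x)
}

# one scaled forward-backward sweep over all samples simultaneously.
# obs: sites x samples matrix of 0/1/NA. Returns the log-likelihood and,
# when collect = TRUE, the expected sufficient statistics for the M-step;
# when posteriors = TRUE, the per-sample cluster posteriors gamma.
hmm_em_pass <- function(obs, theta, alpha, rho,
                        collect = TRUE, posteriors = FALSE) {
  m <- nrow(obs)
  n <- ncol(obs)
  k <- nrow(theta)
  emission <- function(t) {
    e <- matrix(1, n, k)
    o <- obs[t, ]
    i1 <- which(!is.na(o) & o == 1L)
    i0 <- which(!is.na(o) & o == 0L)
    if (length(i1)) e[i1, ] <- matrix(theta[, t], length(i1), k,
                                      byrow = TRUE)
    if (length(i0)) e[i0, ] <- matrix(1 - theta[, t], length(i0), k,
                                      byrow = TRUE)
    e
  }
  fwd <- array(0, c(n, k, m))
  loglik <- numeric(n)
  f <- matrix(alpha[, 1], n, k, byrow = TRUE) * emission(1)
  s <- rowSums(f)
  f <- f / s
  loglik <- loglik + log(s)
  fwd[, , 1] <- f
  for (t in seq_len(m)[-1]) {
    q <- exp(-rho[t - 1L])
    pred <- q * f + (1 - q) * matrix(alpha[, t], n, k, byrow = TRUE)
    f <- pred * emission(t)
    s <- rowSums(f)
    f <- f / s
    loglik <- loglik + log(s)
    fwd[, , t] <- f
  }
  out <- list(loglik = sum(loglik), loglik_per_sample = loglik)
  if (!collect && !posteriors) return(out)

  b <- matrix(1, n, k)
  gam <- fwd[, , m, drop = FALSE][, , 1] * b
  gam <- gam / rowSums(gam)
  if (posteriors) {
    gamma_arr <- array(0, c(n, k, m))
    gamma_arr[, , m] <- gam
  }
  if (collect) {
    theta_num <- matrix(0, k, m)
    theta_den <- matrix(0, k, m)
    switch_in <- matrix(0, k, m)      # expected switch-ins per interval
    switch_prob <- numeric(m)         # mean switch probability per interval
    acc <- function(t, g) {
      o <- obs[t, ]
      i1 <- !is.na(o) & o == 1L
      i01 <- !is.na(o)
      theta_num[, t] <<- colSums(g[i1, , drop = FALSE])
      theta_den[, t] <<- colSums(g[i01, , drop = FALSE])
    }
    acc(m, gam)
  }
  for (t in rev(seq_len(m)[-1])) {
    e <- emission(t)
    u <- e * b
    q <- exp(-rho[t - 1L])
    if (collect) {
      stay <- q * fwd[, , t - 1L] * u
      sw <- (1 - q) * u * matrix(alpha[, t], n, k, byrow = TRUE)
      z <- rowSums(stay) + rowSums(sw)
      switch_in[, t] <- colSums(sw / z)
      switch_prob[t] <- sum(rowSums(sw) / z) / n
    }
    w <- as.numeric(u %*% alpha[, t])
    b <- q * u + (1 - q) * w
    b <- b / rowSums(b)
    gam <- fwd[, , t - 1L] * b
    gam <- gam / rowSums(gam)
    if (posteriors) gamma_arr[, , t - 1L] <- gam
    if (collect) acc(t - 1L, gam)
  }
  if (collect) {
    out$theta_num <- theta_num
    out$theta_den <- theta_den
    out$switch_in <- switch_in
    out$switch_prob <- switch_prob
    out$alpha1 <- colMeans(gam)       # gamma at first marker
  }
  if (posteriors) out$gamma <- gamma_arr
  out
}

#' Fit the haplotype-cluster HMM by expectation-maximization
#'
#' @param hap A [haploidize()]d matrix.
#' @param k Number of haplotype clusters; default 8.
#' @param max_iter Maximum EM iterations; default 50.
#' @param seed Random seed for initialisation (required, for
#'   reproducibility).
#' @param tol Relative log-likelihood improvement below which EM stops;
#'   default 1e-4.
#' @param theta_floor Emission frequencies are kept in
#'   `[theta_floor, 1 - theta_floor]`; default 1e-3.
#' @param rho_init Initial switch intensity per interval; default 0.05.
#' @param n_starts Number of EM runs from different random
#'   initialisations; the fit with the best final log-likelihood is
#'   returned. Default 1.
#' @return Object of class `cluster_hmm`: `k`, `theta` (k x sites), `alpha`
#'   (k x sites; column 1 is the initial cluster distribution, column t the
#'   switch weights into marker t), `rho` (per-interval switch intensity,
#'   length sites - 1), the log-likelihood trace, and convergence info.
#'   The log-likelihood trace is non-decreasing (exact constrained M-steps).
#' @export
hmm_fit <- function(hap, k = 8, max_iter = 50, seed,
                    tol = 1e-4, theta_floor = 1e-3, rho_init = 0.05,
                    n_starts = 1) {
  stopifnot(inherits(hap, "haploid_matrix"), k >= 1, n_starts >= 1)
  if (missing(seed)) stop("seed is required")
  if (n_starts > 1) {
    fits <- lapply(seq_len(n_starts), function(i) {
      hmm_fit(hap, k = k, max_iter = max_iter, seed = seed + i - 1L,
              tol = tol, theta_floor = theta_floor, rho_init = rho_init)
    })
    return(fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]])
  }
  obs <- hap$alleles
  m <- nrow(obs)
  n <- ncol(obs)
  if (m < 2 || n < 2) stop("need at least 2 sites and 2 samples")
  if (all(is.na(obs))) stop("degenerate matrix: all alleles missing")
  set.seed(seed)

  freq <- rowMeans(obs, na.rm = TRUE)
  freq[is.nan(freq)] <- 0.5
  freq <- clamp(freq, theta_floor, 1 - theta_floor)
  if (k == 1) {
    theta <- matrix(freq, 1, m)
  } else {
    # seed clusters from random sample haplotypes, shrunk towards the
    # population frequency at uninformative cells
    centers <- sample(n, k, replace = k > n)
    theta <- matrix(0, k, m)
    for (c in seq_len(k)) {
      o <- obs[, centers[c]]
      theta[c, ] <- ifelse(is.na(o), freq, 0.2 + 0.6 * o) +
        runif(m, -0.05, 0.05)
    }
    theta <- clamp(theta, theta_floor, 1 - theta_floor)
  }
  alpha <- matrix(1 / k, k, m)
  rho <- rep(rho_init, max(m - 1, 1))

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    pass <- hmm_em_pass(obs, theta, alpha, rho, collect = TRUE)
    ll_trace <- c(ll_trace, pass$loglik)
    if (iter > 1) {
      rel <- (pass$loglik - ll_trace[iter - 1]) /
        (abs(ll_trace[iter - 1]) + 1e-12)
      if (abs(rel) < tol) {
        converged <- TRUE
        break
      }
    }
    # exact constrained M-steps (monotone by construction)
    new_theta <- pass$theta_num / pass$theta_den
    keep <- pass$theta_den > 0
    theta[keep] <- clamp(new_theta[keep], theta_floor, 1 - theta_floor)
    alpha[, 1] <- pmax(pass$alpha1, 1e-9)
    alpha[, 1] <- alpha[, 1] / sum(alpha[, 1])
    if (m > 1) {
      for (t in 2:m) {
        tot <- sum(pass$switch_in[, t])
        if (tot > 1e-12) {
          a <- pmax(pass$switch_in[, t] / tot, 1e-9)
          alpha[, t] <- a / sum(a)
        }
        p_sw <- clamp(pass$switch_prob[t], 0, 1 - 1e-9)
        rho[t - 1L] <- -log(1 - p_sw)
      }
    }
  }
  structure(list(k = k, theta = theta, alpha = alpha, rho = rho,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 n_iter = length(ll_trace), converged = converged,
                 chrom = hap$chrom, pos = hap$pos,
                 theta_floor = theta_floor), class = "cluster_hmm")
}

#' @export
print.cluster_hmm <- function(x, ...) {
  cat(sprintf(paste0("cluster_hmm: k = %d over %d markers; ",
                     "log-likelihood %.2f after %d EM iterations (%s)\n"),
              x$k, ncol(x$theta), x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Cluster posteriors and log-likelihood under a fitted model
#'
#' Scaled forward-backward recursion; the posteriors returned here are the
#' module's interface for exact-oracle checks and for imputation.
#'
#' @param model A `cluster_hmm`.
#' @param obs Vector (one haplotype) or sites x samples matrix of 0/1/`NA`
#'   alleles, aligned to the model's marker list.
#' @return List with `gamma` (k x sites matrix for a vector input, samples x
#'   k x sites array otherwise) and `loglik` (per sample).
#' @export
hmm_posteriors <- function(model, obs) {
  single <- is.null(dim(obs))
  if (single) obs <- matrix(obs, ncol = 1)
  stopifnot(nrow(obs) == ncol(model$theta))
  pass <- hmm_em_pass(obs, model$theta, model$alpha, model$rho,
                      collect = FALSE, posteriors = TRUE)
  if (single) {
    list(gamma = matrix(pass$gamma[1, , ], nrow = model$k),
         loglik = pass$loglik_per_sample)
  } else {
    list(gamma = pass$gamma, loglik = pass$loglik_per_sample)
  }
}

#' Log-likelihood of a haploid matrix under a fitted model
#' @param model A `cluster_hmm`.
#' @param hap A `haploid_matrix` (or 0/1/`NA` matrix) on the same markers.
#' @return Total log-likelihood.
#' @export
hmm_loglik <- function(model, hap) {
  obs <- if (inherits(hap, "haploid_matrix")) hap$alleles else hap
  hmm_em_pass(obs, model$theta, model$alpha, model$rho,
              collect = FALSE)$loglik
}

#' Impute missing genotypes of an inbred population
#'
#' For each sample, forward-backward posteriors over clusters give a
#' posterior alternate-allele probability at every marker; each originally
#' missing cell is assigned the homozygous diploid genotype of the allele
#' with maximal posterior probability, written with an imputation flag and a
#' phred-scaled posterior-derived quality. Observed calls are never changed;
#' heterozygous source calls (masked during haploidization) are kept as-is
#' unless `replace_het = TRUE`.
#'
#' @param hap A [haploidize()]d matrix (carries its source `population_vcf`).
#' @param model A `cluster_hmm` fitted on the same marker list.
#' @param replace_het Also re-impute heterozygous source calls? Default
#'   `FALSE`.
#' @return Imputed `population_vcf` with an `imputed` flag matrix.
#' @export
hmm_impute <- function(hap, model, replace_het = FALSE) {
  stopifnot(inherits(hap, "haploid_matrix"), inherits(model, "cluster_hmm"))
  if (!identical(hap$chrom, model$chrom) ||
      !identical(hap$pos, model$pos)) {
    stop("site list mismatch between matrix and model")
  }
  obs <- hap$alleles
  m <- nrow(obs)
  n <- ncol(obs)
  post <- hmm_posteriors(model, obs)
  p_alt <- matrix(0, m, n)
  for (t in seq_len(m)) {
    p_alt[t, ] <- post$gamma[, , t] %*% model$theta[, t]
  }
  pop <- hap$source
  target <- is.na(pop$a1)
  if (replace_het) target <- target | (pop$a1 != pop$a2)
  target[is.na(target)] <- FALSE
  allele <- ifelse(p_alt >= 0.5, 1L, 0L)
  gq <- matrix(phred_quality(pmin(p_alt, 1 - p_alt)), m, n)
  pop$a1[target] <- allele[target]
  pop$a2[target] <- allele[target]
  if (is.null(pop$gq)) pop$gq <- matrix(NA_integer_, m, n)
  pop$gq[target] <- gq[target]
  pop$imputed <- target
  pop
}

#' Mask a fraction of called genotypes (imputation test harness)
#'
#' @param pop A `population_vcf`.
#' @param fraction Fraction of currently-called cells to set missing.
#' @param seed Random seed.
#' @return List: `pop` (masked matrix) and `mask` (logical sites x samples
#'   matrix of the cells that were masked).
#' @export
mask_genotypes <- function(pop, fraction, seed) {
  set.seed(seed)
  called <- which(!is.na(pop$a1))
  n_mask <- round(fraction * length(called))
  cells <- sample(called, n_mask)
  mask <- matrix(FALSE, n_sites(pop), n_samples(pop))
  mask[cells] <- TRUE
  pop$a1[cells] <- NA_integer_
  pop$a2[cells] <- NA_integer_
  list(pop = pop, mask = mask)
}

#' Compare two imputation outputs over originally-missing cells
#'
#' @param a,b `population_vcf` objects with identical samples and sites
#'   (e.g. two imputation results, or an imputation result and the simulated
#'   truth).
#' @param mask Logical sites x samples matrix marking the originally-missing
#'   (or deliberately masked) cells the comparison is restricted to.
#' @return List of class `imputation_comparison`: cell counts and the
#'   fractions of cells that are identical in both outputs, called
#'   differently with exactly one heterozygous call, called differently
#'   otherwise, or imputed in one output but left missing in the other (or
#'   both); plus `concordance` over cells called in both.
#' @export
compare_imputations <- function(a, b, mask) {
  stopifnot(identical(a$samples, b$samples),
            identical(site_keys(a), site_keys(b)))
  ga <- genotype_strings(a)[mask]
  gb <- genotype_strings(b)[mask]
  het_a <- (a$a1 != a$a2)[mask]
  het_b <- (b$a1 != b$a2)[mask]
  n <- length(ga)
  both <- !is.na(ga) & !is.na(gb)
  same <- both & ga == gb
  diff <- both & !same
  one_het <- diff & (het_a != het_b)
  miss <- !both
  structure(list(
    n_cells = n,
    frac_identical = if (n) sum(same) / n else NA_real_,
    frac_discordant = if (n) sum(diff) / n else NA_real_,
    frac_one_het = if (n) sum(one_het) / n else NA_real_,
    frac_missing_either = if (n) sum(miss) / n else NA_real_,
    concordance = if (sum(both)) sum(same) / sum(both) else NA_real_),
    class = "imputation_comparison")
}

#' @export
print.imputation_comparison <- function(x, ...) {
  cat(sprintf(paste0("imputation_comparison: %d cells; %.1f%% identical, ",
                     "%.1f%% discordant (%.1f%% with one het), ",
                     "%.1f%% missing in at least one\n"),
              x$n_cells, 100 * x$frac_identical, 100 * x$frac_discordant,
              100 * x$frac_one_het, 100 * x$frac_missing_either))
  invisible(x)
}
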