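# Independent brute-force oracle for the haplotype-cluster HMM: exhaustive
# enumeration over all k^m cluster paths. Only feasible for tiny instances;
# deliberately shares no code with the package's scaled recursions.

oracle_emission <- function(theta, obs, c, t) {
  if (is.na(obs[t])) return(1)
  if (obs[t] == 1) theta[c, t] else 1 - theta[c, t]
}

oracle_path_prob <- function(theta, alpha, rho, obs, path) {
  m <- length(obs)
  pr <- alpha[path[1], 1] * oracle_emission(theta, obs, path[1], 1)
  if (m > 1) {
    for (t in 2:m) {
      q <- exp(-rho[t - 1])
      trans <- q * (path[t] == path[t - 1]) + (1 - q) * alpha[path[t], t]
      pr <- pr * trans * oracle_emission(theta, obs, path[t], t)
    }
  }
  pr
}

oracle_posteriors <- function(theta, alpha, rho, obs) {
  k <- nrow(theta)
  m <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  probs <- apply(paths, 1, function(p) {
    oracle_path_prob(theta, alpha, rho, obs, p)
  })
  total <- sum(probs)
  gamma <- matrix(0, k, m)
  for (t in seq_len(m)) {
    for (c in seq_len(k)) {
      gamma[c, t] <- sum(probs[paths[, t] == c]) / total
    }
  }
  list(gamma = gamma, loglik = log(total))
}

# random valid parameter set for a given instance size
random_hmm_params <- function(k, m) {
  theta <- matrix(runif(k * m, 0.05, 0.95), k, m)
  alpha <- matrix(runif(k * m, 0.2, 1), k, m)
  alpha <- sweep(alpha, 2, colSums(alpha), "/")
  rho <- runif(max(m - 1, 1), 0.01, 1.5)
  list(theta = theta, alpha = alpha, rho = rho)
}

as_cluster_hmm <- function(params) {
  m <- ncol(params$theta)
  structure(list(k = nrow(params$theta), theta = params$theta,
                 alpha = params$alpha, rho = params$rho,
                 chrom = rep("1", m), pos = seq_len(m) * 100L),
            class = "cluster_hmm")
}
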