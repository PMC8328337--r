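# Shared fixtures and independent oracle implementations.
# Oracles deliberately avoid the package's computational path: plain double
# loops over ordered pairs with stats::plogis / log().

# 3-node network with edges 1->2, 2->1, 1->3
toy_net3 <- function() {
  Y <- matrix(0L, 3, 3)
  Y[1, 2] <- 1L; Y[2, 1] <- 1L; Y[1, 3] <- 1L
  directed_network(Y)
}

# deterministic small random model state
toy_state <- function(n, p = 0, d = 2, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * d, 0, 0.3), n, d)
  gamma <- rgamma(n, 2); gamma <- gamma / sum(gamma)
  beta <- if (p > 0) rnorm(p, 0, 0.5) else numeric(0)
  list(Z = Z, gamma = gamma, beta = beta, sigma2 = 0.1,
       tau2 = rep(2, p), lambda = rep(2, p))
}

random_covariates <- function(n, p, seed = 2) {
  set.seed(seed)
  attrs <- data.frame(a1 = rnorm(n))
  if (p >= 2) attrs$a2 <- sample(c("A", "B", "C"), n, replace = TRUE)
  pairwise_covariates(attrs[, seq_len(p), drop = FALSE])
}

random_net <- function(n, dens = 0.2, seed = 3) {
  set.seed(seed)
  Y <- matrix(rbinom(n * n, 1, dens), n, n)
  diag(Y) <- 0L
  directed_network(Y)
}

# brute-force Bernoulli log-likelihood over ordered pairs
oracle_loglik <- function(net, Z, X, beta, gamma, beta0 = 1) {
  n <- nrow(Z)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xb <- if (length(beta)) sum(beta * X$X[i, j, ]) else 0
    eta <- beta0 + xb - sqrt(sum((Z[i, ] - Z[j, ])^2)) / gamma[j]
    pr <- stats::plogis(eta)
    s <- s + if (net$adjacency[i, j] == 1L) log(pr) else log(1 - pr)
  }
  s
}

# batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# scalar chain
batch_se <- function(x, n_batch = 40) {
  m <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# brute-force AUC: fraction of concordant (edge, non-edge) ordered-pair
# score comparisons, ties counted 1/2
oracle_auc <- function(phat, net) {
  Y <- net$adjacency
  off <- row(Y) != col(Y)
  s1 <- phat[off][Y[off] == 1]
  s0 <- phat[off][Y[off] == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}
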