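# Importance-sampling oracle for the 4-node toy posterior: proposes from
# the joint prior and weights by the exponentiated Bernoulli likelihood.
# Completely independent of the sampler code path (vectorized plain R).
#
# Returns weighted posterior means and their Monte-Carlo standard errors
# for: beta, log(sigma2), the latent distance d(1,2), and each gamma_j.
is_oracle_4node <- function(net, x12, nu, phi, xi, delta, n_draws = 1.5e6,
                            chunk = 1e5, seed = 1) {
  set.seed(seed)
  Y <- net$adjacency
  n <- 4L
  pairs <- which(row(Y) != col(Y), arr.ind = TRUE)
  sums <- NULL
  wsum <- 0; w2sum <- 0
  acc <- list()
  for (start in seq(1, n_draws, by = chunk)) {
    m <- min(chunk, n_draws - start + 1)
    sigma2 <- 1 / rgamma(m, shape = nu, rate = phi)
    Z <- array(rnorm(m * n * 2, 0, sqrt(sigma2)), dim = c(m, n, 2))
    tau2 <- rgamma(m, shape = xi, rate = delta)
    beta <- rnorm(m, 0, 1 / sqrt(tau2))
    G <- matrix(rgamma(m * n, 1), m, n)
    G <- G / rowSums(G)
    ll <- numeric(m)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      d <- sqrt((Z[, i, 1] - Z[, j, 1])^2 + (Z[, i, 2] - Z[, j, 2])^2)
      eta <- 1 + beta * x12[i, j] - d / G[, j]
      ll <- ll + if (Y[i, j] == 1L) stats::plogis(eta, log.p = TRUE)
            else stats::plogis(-eta, log.p = TRUE)
    }
    w <- exp(ll)   # bounded above by 1; no overflow
    d12 <- sqrt((Z[, 1, 1] - Z[, 2, 1])^2 + (Z[, 1, 2] - Z[, 2, 2])^2)
    fs <- cbind(beta = beta, log_sigma2 = log(sigma2), d12 = d12, G)
    wsum <- wsum + sum(w)
    w2sum <- w2sum + sum(w^2)
    acc[[length(acc) + 1]] <- list(wf = colSums(w * fs),
                                   w = w, fs = fs)
  }
  wf <- Reduce(`+`, lapply(acc, `[[`, "wf"))
  est <- wf / wsum
  # weighted-variance SE with effective sample size
  varw <- rep(0, length(est))
  for (a in acc)
    varw <- varw + colSums(a$w^2 * sweep(a$fs, 2, est)^2)
  se <- sqrt(varw) / wsum
  names(se) <- names(est) <- c("beta", "log_sigma2", "d12",
                               paste0("gamma", 1:4))
  ess <- wsum^2 / w2sum
  list(mean = est, se = se, ess = ess)
}
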