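# Probability model: linear predictor, Bernoulli likelihood, and the
# unnormalized full-conditional (log) kernels used by the samplers.
# Everything here is pure computation in log space; edge probabilities are
# never materialized during kernel evaluation.

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= -33.27
  hi <- x >= 33.28
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

cov_term <- function(X, beta) {
  # sum_k beta_k X[, , k] as an n x n matrix; 0 matrix when p = 0
  if (is.null(X) || length(beta) == 0L)
    return(0)
  p <- length(beta)
  M <- matrix(0, dim(X$X)[1], dim(X$X)[2])
  for (k in seq_len(p)) M <- M + beta[k] * X$X[, , k]
  M
}

#' Linear predictor of the latent-distance model
#'
#' Log-odds of a directed edge:
#' \deqn{\eta_{ij} = \beta_0 + \beta' x_{ij} - \|z_i - z_j\| / \gamma_j,}
#' where \eqn{\gamma_j \in (0,1)} is the popularity scale of the target
#' node (the latent distance is divided by it, so popular nodes are easier
#' to follow) and \eqn{\beta_0} is fixed at 1 for identification.
#'
#' @param Z `n x d` latent coordinates.
#' @param X [pairwise_covariates()] or `NULL` for a covariate-free model.
#' @param beta regression coefficients (length `p`).
#' @param gamma popularity scales, positive, summing to 1.
#' @param beta0 intercept (fixed at 1 by the identification constraint).
#' @param i,j optional node indices; when supplied the scalar
#'   \eqn{\eta_{ij}} is returned, otherwise the full `n x n` matrix with a
#'   masked (`NA`) diagonal.
#' @return scalar or matrix of log-odds.
#' @export
linear_predictor <- function(Z, X = NULL, beta = numeric(0), gamma,
                             beta0 = 1, i = NULL, j = NULL) {
  if (any(gamma <= 0)) stop("gamma components must be positive")
  if (!is.null(i) && !is.null(j)) {
    if (i == j) stop("diagonal pairs are not modeled (i must differ from j)")
    d_ij <- sqrt(sum((Z[i, ] - Z[j, ])^2))
    xb <- if (length(beta)) sum(beta * X$X[i, j, ]) else 0
    return(beta0 + xb - d_ij / gamma[j])
  }
  D <- as.matrix(stats::dist(Z))
  eta <- beta0 + cov_term(X, beta) - sweep(D, 2L, gamma, "/")
  diag(eta) <- NA_real_
  eta
}

#' Bernoulli log-likelihood of a directed network
#'
#' \deqn{\ell = \sum_{i \ne j} \eta_{ij} y_{ij} - \log(1 + e^{\eta_{ij}}),}
#' computed with an overflow-safe log1p-exp formulation.
#'
#' @param net a [directed_network()].
#' @param eta matrix of log-odds from [linear_predictor()] (diagonal
#'   ignored).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(net, eta) {
  Y <- net$adjacency
  off <- row(eta) != col(eta)
  sum(eta[off] * Y[off] - log1pexp(eta[off]))
}

# log density helpers -------------------------------------------------------

ldnorm_iso <- function(z, mean = 0, s2) {
  # isotropic multivariate normal, z a vector
  d <- length(z)
  -0.5 * d * log(2 * pi * s2) - sum((z - mean)^2) / (2 * s2)
}

ldlaplace <- function(x, rate) log(rate / 2) - rate * abs(x)

lddirichlet <- function(x, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Unnormalized log full conditional of one latent position
#'
#' Sum of the \eqn{2(n-1)} pair Bernoulli log-probabilities involving node
#' `i` plus the latent prior log density at the candidate — the Gaussian
#' \eqn{N_d(0, \sigma^2 I)} prior, or the node's mixture-component prior
#' when `state$mixture` is present.
#'
#' @param i node index.
#' @param zi candidate coordinate vector (length `d`).
#' @param net,X data.
#' @param state list with `Z`, `beta`, `gamma`, `sigma2` (and optionally
#'   `mixture = list(weights, mu, s2, labels)`).
#' @param beta0 fixed intercept.
#' @return unnormalized log density.
#' @export
logpost_z <- function(i, zi, net, X, state, beta0 = 1) {
  Z <- state$Z
  n <- nrow(Z)
  Y <- net$adjacency
  lp <- 0
  for (j in seq_len(n)[-i]) {
    d_ij <- sqrt(sum((zi - Z[j, ])^2))
    xb_ij <- if (length(state$beta)) sum(state$beta * X$X[i, j, ]) else 0
    xb_ji <- if (length(state$beta)) sum(state$beta * X$X[j, i, ]) else 0
    e_ij <- beta0 + xb_ij - d_ij / state$gamma[j]
    e_ji <- beta0 + xb_ji - d_ij / state$gamma[i]
    lp <- lp + Y[i, j] * e_ij - log1pexp(e_ij) +
      Y[j, i] * e_ji - log1pexp(e_ji)
  }
  if (!is.null(state$mixture)) {
    mix <- state$mixture
    g <- mix$labels[i]
    lp + ldnorm_iso(zi, mix$mu[g, ], mix$s2[g])
  } else {
    lp + ldnorm_iso(zi, 0, state$sigma2)
  }
}

#' Unnormalized log full conditional of one regression coefficient
#'
#' Full Bernoulli log-likelihood with \eqn{\beta_k} set to the candidate,
#' plus the Normal prior \eqn{N(0, 1/\tau_k^2)} (ridge) or Laplace prior
#' \eqn{Lap(0, 1/\lambda_k)} (adaptive LASSO) log density.
#'
#' @param k coefficient index.
#' @param bk candidate value.
#' @param net,X data.
#' @param state list with `Z`, `beta`, `gamma` and `tau2` (ridge) or
#'   `lambda` (lasso).
#' @param penalty `"ridge"` or `"lasso"`.
#' @param beta0 fixed intercept.
#' @return unnormalized log density.
#' @export
logpost_beta <- function(k, bk, net, X, state,
                         penalty = c("ridge", "lasso"), beta0 = 1) {
  penalty <- match.arg(penalty)
  beta <- state$beta
  beta[k] <- bk
  eta <- linear_predictor(state$Z, X, beta, state$gamma, beta0)
  ll <- log_likelihood(net, eta)
  prior <- if (penalty == "ridge") {
    tau2 <- state$tau2[k]
    0.5 * log(tau2 / (2 * pi)) - tau2 * bk^2 / 2
  } else {
    ldlaplace(bk, state$lambda[k])
  }
  ll + prior
}

#' Unnormalized log full conditional of the popularity vector
#'
#' Full Bernoulli log-likelihood under a candidate \eqn{\gamma} on the open
#' simplex, plus the Dirichlet(\eqn{\alpha}) prior log density.
#'
#' @param gamma candidate popularity vector.
#' @param net,X data.
#' @param state list with `Z`, `beta`.
#' @param alpha Dirichlet hyperparameter (length `n`; default flat).
#' @param beta0 fixed intercept.
#' @return unnormalized log density.
#' @export
logpost_gamma <- function(gamma, net, X, state, alpha = NULL, beta0 = 1) {
  n <- length(gamma)
  if (any(gamma <= 0) || any(gamma >= 1))
    stop("gamma components must lie strictly in (0, 1)")
  if (is.null(alpha)) alpha <- rep(1, n)
  eta <- linear_predictor(state$Z, X, state$beta, gamma, beta0)
  log_likelihood(net, eta) + lddirichlet(gamma, alpha)
}

#' Cluster membership probabilities under a Gaussian-mixture latent prior
#'
#' \deqn{P(k_i = g \mid z_i, \cdot) \propto \delta_g\,
#'   f_{N_d(\mu_g, \sigma_g^2 I)}(z_i),}
#' normalized in log space so that heavy underflow never yields `NaN`.
#'
#' @param zi latent coordinate vector.
#' @param mix list with `weights` (simplex, length `G`), `mu` (`G x d`),
#'   `s2` (length `G` variances).
#' @return numeric vector of `G` probabilities summing to 1.
#' @export
cluster_membership_probs <- function(zi, mix) {
  G <- length(mix$weights)
  lp <- vapply(seq_len(G), function(g)
    log(mix$weights[g]) + ldnorm_iso(zi, mix$mu[g, ], mix$s2[g]),
    numeric(1))
  lp <- lp - max(lp)
  w <- exp(lp)
  w / sum(w)
}
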