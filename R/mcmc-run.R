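#' Sampler configuration
#'
#' Defaults follow the simulation regime of the model's reference studies:
#' 15,000 burn-in iterations, 50,000 monitoring iterations, Dirichlet
#' proposal concentration \eqn{M = 5 \times 10^6}, thinning stride 10.
#'
#' @param burn_in discarded initial iterations.
#' @param monitor monitored iterations after burn-in.
#' @param thin thinning stride for storage.
#' @param M Dirichlet proposal concentration for the popularity update
#'   (must exceed `n` so every proposal concentration exceeds 1 near the
#'   flat configuration).
#' @param step_z latent random-walk sd; `NULL` = `0.05 * sqrt(sigma2_0)`.
#' @param step_beta coefficient random-walk scale.
#' @param adapt Robbins-Monro-style step scaling during burn-in only,
#'   targeting roughly 30% acceptance; frozen at monitoring start so the
#'   monitored chain is valid MH.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param d latent dimension.
#' @param mixture_G number of Gaussian mixture components for the latent
#'   prior (1 = plain Gaussian prior).
#' @param procrustes align coordinates to the initial MDS configuration
#'   once per iteration after the latent sweep.
#' @param likelihood internal switch; `FALSE` samples the priors alone
#'   (used by sampler diagnostics).
#' @return list of class `phlsm_config`.
#' @export
phlsm_config <- function(burn_in = 15000L, monitor = 50000L, thin = 10L,
                         M = 5e6, step_z = NULL, step_beta = 0.1,
                         adapt = TRUE, seed = NULL, d = 2L,
                         mixture_G = 1L, procrustes = TRUE,
                         likelihood = TRUE) {
  stopifnot(burn_in >= 0, monitor >= 0, thin >= 1, M > 0, d >= 1,
            mixture_G >= 1)
  structure(list(burn_in = as.integer(burn_in),
                 monitor = as.integer(monitor), thin = as.integer(thin),
                 M = M, step_z = step_z, step_beta = step_beta,
                 adapt = adapt, seed = seed, d = as.integer(d),
                 mixture_G = as.integer(mixture_G),
                 procrustes = procrustes, likelihood = likelihood),
            class = "phlsm_config")
}

#' Prior hyperparameters
#'
#' Defaults: \eqn{\nu = 2} with \eqn{\phi} targeting the sample variance of
#' the initial coordinates; Gamma rates \eqn{\delta_\tau = 0.05},
#' \eqn{\delta_\lambda = 0.1}; Gamma shapes by covariate type —
#' \eqn{\xi_\tau = 4, \xi_\lambda = 8} for categorical and
#' \eqn{\xi_\tau = 2, \xi_\lambda = 4} for continuous covariates; flat
#' Dirichlet for the popularity vector.
#'
#' @param types character vector of covariate types
#'   (`"continuous"`/`"categorical"`), length `p`.
#' @param n number of nodes (for the Dirichlet prior length).
#' @param nu,phi Inverse-Gamma shape and scale for \eqn{\sigma^2}.
#' @param xi_tau,delta_tau Gamma shape/rate for the ridge precisions
#'   (`NULL` = per-type defaults).
#' @param xi_lambda,delta_lambda Gamma shape/rate for the LASSO tuning
#'   parameters (`NULL` = per-type defaults).
#' @param alpha Dirichlet hyperparameter (scalar recycled, default flat 1).
#' @return list of class `phlsm_hyper`.
#' @export
phlsm_hyper <- function(types = character(0), n, nu = 2, phi = 1,
                        xi_tau = NULL, delta_tau = NULL,
                        xi_lambda = NULL, delta_lambda = NULL,
                        alpha = 1) {
  p <- length(types)
  if (is.null(xi_tau)) xi_tau <- ifelse(types == "categorical", 4, 2)
  if (is.null(xi_lambda)) xi_lambda <- ifelse(types == "categorical", 8, 4)
  if (is.null(delta_tau)) delta_tau <- rep(0.05, p)
  if (is.null(delta_lambda)) delta_lambda <- rep(0.1, p)
  out <- list(nu = nu, phi = phi,
              xi_tau = rep_len(xi_tau, p), delta_tau = rep_len(delta_tau, p),
              xi_lambda = rep_len(xi_lambda, p),
              delta_lambda = rep_len(delta_lambda, p),
              alpha = rep_len(alpha, n))
  if (any(unlist(out) <= 0)) stop("all hyperparameters must be positive")
  structure(out, class = "phlsm_hyper")
}

empty_covariates <- function(n) {
  structure(list(X = array(0, dim = c(n, n, 0L)), names = character(0),
                 types = character(0), epsilon = 1e-3),
            class = "pairwise_covariates")
}

#' Fit a penalized homophily latent space model
#'
#' Runs the MH-within-Gibbs sampler: per iteration a latent random-walk
#' sweep (followed by one Procrustes alignment to the MDS start), a Gibbs
#' draw of \eqn{\sigma^2}, random-walk updates of each \eqn{\beta_k}, Gibbs
#' draws of the penalty parameters (\eqn{\tau_k^2} ridge /
#' \eqn{\lambda_k} lasso), and a joint Dirichlet-proposal update of the
#' popularity vector \eqn{\gamma}. With `mixture_G > 1` the Gaussian latent
#' prior is replaced by a `G`-component mixture and a conjugate mixture
#' sweep (labels, weights, means, variances) is appended.
#'
#' Initialization follows the model's standard strategies: geodesic MDS for
#' `Z`, in-degree-proportional `gamma`, logistic regression for `beta`, and
#' the coordinate sample variance for `sigma2`.
#'
#' @param net a [directed_network()].
#' @param attrs optional node attribute data.frame (rows in node order);
#'   transformed through [pairwise_covariates()].
#' @param X optional pre-built [pairwise_covariates()] (overrides `attrs`).
#' @param penalty `"ridge"` (Normal prior on coefficients) or `"lasso"`
#'   (adaptive-LASSO Laplace prior).
#' @param config a [phlsm_config()].
#' @param hyper a [phlsm_hyper()]; built with defaults when `NULL`.
#' @param epsilon floor of the continuous-attribute rescaling.
#' @return object of class `phlsm_fit`: stored draws (`Z` an
#'   `n x d x S` array aligned by Procrustes, `beta`, `gamma`, `sigma2`,
#'   `tau2`/`lambda`, mixture draws when enabled), the per-iteration
#'   log-likelihood trace, acceptance rates per block, the initial state,
#'   and the configuration.
#' @export
phlsm_fit <- function(net, attrs = NULL, X = NULL,
                      penalty = c("ridge", "lasso"),
                      config = phlsm_config(), hyper = NULL,
                      epsilon = 1e-3) {
  penalty <- match.arg(penalty)
  n <- n_nodes(net)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(X))
    X <- if (is.null(attrs)) empty_covariates(n)
         else pairwise_covariates(attrs, epsilon = epsilon)
  p <- length(X$types)

  # initialization strategies
  Z0 <- init_latent(net, d = config$d)
  gamma0 <- init_gamma(net)
  sigma20 <- init_sigma2(Z0)
  if (is.null(hyper))
    hyper <- phlsm_hyper(types = X$types, n = n, phi = sigma20)
  binit <- init_beta(net, X, penalty, hyper)
  beta0v <- binit$beta
  pen0 <- if (penalty == "ridge") binit$tau2 else binit$lambda
  step_z <- if (is.null(config$step_z)) 0.05 * sqrt(sigma20) else config$step_z

  G <- config$mixture_G
  if (G > 1L) {
    km <- stats::kmeans(Z0, centers = G, nstart = 5L)
    mix_w <- as.numeric(table(factor(km$cluster, levels = seq_len(G)))) / n
    mix_w <- pmax(mix_w, 1 / (2 * n)); mix_w <- mix_w / sum(mix_w)
    mix_mu <- km$centers
    mix_s2 <- rep(max(sigma20, 1e-8), G)
    labels0 <- km$cluster - 1L
  } else {
    mix_w <- 1; mix_mu <- matrix(0, 1, config$d); mix_s2 <- sigma20
    labels0 <- integer(n)
  }

  eta0 <- linear_predictor(Z0, if (p) X else NULL, beta0v, gamma0)
  ll0 <- log_likelihood(net, eta0)
  if (!is.finite(ll0))
    stop("non-finite log-likelihood at initialization; check inputs")

  t0 <- proc.time()[["elapsed"]]
  res <- phlsm_mcmc_cpp(
    Y = net$adjacency, X = X$X, Z = Z0, beta = beta0v, gamma = gamma0,
    sigma2 = sigma20, pen = pen0,
    penalty = if (penalty == "ridge") 0L else 1L, beta0 = 1,
    nu = hyper$nu, phi = hyper$phi,
    xi = if (penalty == "ridge") hyper$xi_tau else hyper$xi_lambda,
    delta = if (penalty == "ridge") hyper$delta_tau else hyper$delta_lambda,
    alpha = hyper$alpha,
    burn_in = config$burn_in, monitor = config$monitor, thin = config$thin,
    M = config$M, step_z = step_z, step_b = config$step_beta,
    adapt = config$adapt, use_lik = config$likelihood,
    do_procrustes = config$procrustes, Zref = Z0,
    G = G, mix_w = mix_w, mix_mu = mix_mu, mix_s2 = mix_s2,
    labels = labels0,
    mu_prior_var = 10 * sigma20, s2_prior_a = 2, s2_prior_b = sigma20)
  wall <- proc.time()[["elapsed"]] - t0

  S <- res$n_kept
  if (S == 0L) {  # burn-in-only runs: drop the placeholder slice
    res$Z <- array(0, dim = c(n, config$d, 0L))
    res$sigma2 <- numeric(0)
    if (G > 1L) res$mix_mu <- array(0, dim = c(G, config$d, 0L))
  }
  fit <- list(
    Z = res$Z, beta = res$beta, gamma = res$gamma,
    sigma2 = as.numeric(res$sigma2), loglik = as.numeric(res$loglik),
    n_samples = S, penalty = penalty,
    acceptance = list(z = res$acc_z, beta = res$acc_beta,
                      gamma = res$acc_gamma),
    steps = list(z = res$step_z, beta = res$step_beta),
    init = list(Z0 = Z0, gamma0 = gamma0, sigma20 = sigma20,
                beta0 = beta0v),
    config = config, hyper = hyper, X = X,
    node_ids = net$node_ids, wall_time = wall)
  if (penalty == "ridge") fit$tau2 <- res$pen else fit$lambda <- res$pen
  if (G > 1L) {
    fit$mixture <- list(G = G, labels = res$labels, weights = res$mix_w,
                        mu = res$mix_mu, s2 = res$mix_s2)
  }
  class(fit) <- "phlsm_fit"
  fit
}

#' @export
print.phlsm_fit <- function(x, ...) {
  cat(sprintf("phlsm_fit: %d nodes, %d covariates, %s penalty\n",
              length(x$node_ids), ncol(x$beta), x$penalty))
  cat(sprintf("  %d stored draws (burn-in %d, monitor %d, thin %d)\n",
              x$n_samples, x$config$burn_in, x$config$monitor,
              x$config$thin))
  cat(sprintf("  acceptance: z %.2f, beta %s, gamma %.2f\n",
              x$acceptance$z,
              if (is.na(x$acceptance$beta)) "-" else sprintf("%.2f", x$acceptance$beta),
              x$acceptance$gamma))
  invisible(x)
}

#' Posterior summaries of scalar parameters
#'
#' @param object a [phlsm_fit()].
#' @param probs quantiles to report.
#' @param ... unused.
#' @return data.frame with posterior mean, sd and quantiles per parameter
#'   (`beta`, `sigma2`, `gamma`).
#' @export
summary.phlsm_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  blocks <- list()
  if (ncol(object$beta) > 0)
    blocks$beta <- `colnames<-`(object$beta,
                                paste0("beta", seq_len(ncol(object$beta))))
  blocks$sigma2 <- matrix(object$sigma2, ncol = 1,
                          dimnames = list(NULL, "sigma2"))
  blocks$gamma <- `colnames<-`(object$gamma,
                               paste0("gamma[", object$node_ids, "]"))
  draws <- do.call(cbind, blocks)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    row.names = NULL)
  qs <- t(apply(draws, 2L, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  cbind(out, qs)
}

#' Posterior-mean edge probabilities
#'
#' The fitted probability matrix \eqn{\hat P}: the Monte-Carlo average of
#' \eqn{p_{ij} = \mathrm{logit}^{-1}(\eta_{ij})} over the stored draws
#' (a posterior predictive mean, not the probability at the posterior-mean
#' parameters). Diagonal is `NA`.
#'
#' @param object a [phlsm_fit()].
#' @param ... unused.
#' @return `n x n` probability matrix with node ids as dimnames.
#' @export
predict.phlsm_fit <- function(object, ...) {
  if (object$n_samples == 0L) stop("no stored draws to average")
  P <- posterior_mean_prob_cpp(object$Z, object$beta, object$gamma,
                               object$X$X, beta0 = 1)
  dimnames(P) <- list(object$node_ids, object$node_ids)
  P
}
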