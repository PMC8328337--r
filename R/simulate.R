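# Generative model for directed networks with power-law in-degree
# heterogeneity ("semi-scale-free": heavy-tailed in-degrees, negligible
# out-degree heterogeneity), with full ground truth retained.

#' Sample power-law Dirichlet concentrations
#'
#' I.i.d. draws from the truncated discrete power law
#' \eqn{P(l) \propto l^{-\theta}} on \eqn{l \in \{1, \dots, l_{max}\}}.
#' These integers serve as the Dirichlet concentration of the popularity
#' vector; a heavy tail (small \eqn{\theta}) produces rare nodes with a
#' dominant share of the popularity mass.
#'
#' @param n number of draws.
#' @param theta power-law exponent, > 1.
#' @param l_max support cap (default `n`, keeping concentrations bounded).
#' @return integer vector of length `n`.
#' @export
sample_powerlaw_alpha <- function(n, theta, l_max = n) {
  if (theta <= 1) stop("theta must exceed 1")
  if (l_max < 1) stop("l_max must be at least 1")
  support <- seq_len(l_max)
  if (l_max == 1L) return(rep(1L, n))
  sample(support, n, replace = TRUE, prob = support^(-theta))
}

#' Simulate a directed network from the latent-distance model
#'
#' Generative process: \eqn{\alpha_i} i.i.d. truncated power law with
#' exponent `theta`; \eqn{\gamma \sim Dirichlet(\alpha)};
#' \eqn{z_i \sim N_d(0, \sigma^2 I)}; node attributes per `attr_types`
#' (`"continuous"` = standard Normal, `"binary"` = Bernoulli(0.5));
#' pairwise covariates via [pairwise_covariates()]; then independently for
#' every ordered pair
#' \eqn{y_{ij} \sim Bernoulli(\mathrm{logit}^{-1}(\beta_0 + \beta' x_{ij}
#'   - \|z_i - z_j\|/\gamma_j))}.
#'
#' @param n number of nodes (>= 10).
#' @param theta power-law exponent (> 1).
#' @param sigma2 latent coordinate variance (default `3e-4`, the
#'   benchmark setting).
#' @param beta true coefficient vector (`NULL` for a covariate-free
#'   network).
#' @param attr_types `"continuous"`/`"binary"` per coefficient.
#' @param beta0 intercept (1 under the identification constraint).
#' @param l_max power-law support cap (default `n`).
#' @param d latent dimension.
#' @param seed optional RNG seed.
#' @param epsilon rescaling floor passed to [pairwise_covariates()].
#' @return object of class `simulated_network`: `net`
#'   (a [directed_network()]), `attrs`, `X`, and `truth` (list with `Z`,
#'   `gamma`, `alpha`, `beta`, `sigma2`, `beta0`, `theta`).
#' @export
simulate_network <- function(n, theta, sigma2 = 3e-4, beta = NULL,
                             attr_types = NULL, beta0 = 1, l_max = n,
                             d = 2L, seed = NULL, epsilon = 1e-3) {
  if (n < 10) stop("n must be at least 10")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  if (p > 0 && length(attr_types) != p)
    stop("attr_types must give one type per coefficient")

  alpha <- sample_powerlaw_alpha(n, theta, l_max)
  gamma <- rdirichlet1(alpha)
  Z <- matrix(stats::rnorm(n * d, 0, sqrt(sigma2)), n, d)

  ids <- paste0("v", seq_len(n))
  if (p > 0) {
    attrs <- as.data.frame(lapply(seq_len(p), function(k) {
      if (attr_types[k] == "continuous") stats::rnorm(n)
      else stats::rbinom(n, 1L, 0.5)
    }))
    names(attrs) <- paste0("a", seq_len(p))
    rownames(attrs) <- ids
    types <- ifelse(attr_types == "continuous", "continuous", "categorical")
    X <- pairwise_covariates(attrs, types = types, epsilon = epsilon)
  } else {
    attrs <- NULL
    X <- empty_covariates(n)
  }

  eta <- beta0 + cov_term(if (p) X else NULL, beta) -
    sweep(as.matrix(stats::dist(Z)), 2L, gamma, "/")
  pr <- stats::plogis(eta)
  diag(pr) <- 0
  Y <- matrix(stats::rbinom(n * n, 1L, as.vector(pr)), n, n)
  diag(Y) <- 0L

  structure(list(net = directed_network(Y, node_ids = ids),
                 attrs = attrs, X = X,
                 truth = list(Z = Z, gamma = gamma, alpha = alpha,
                              beta = beta, sigma2 = sigma2, beta0 = beta0,
                              theta = theta)),
            class = "simulated_network")
}

#' Sparse true coefficient vectors for the variable-selection designs
#'
#' Presets reproduce the benchmark high-dimensional designs: with `p = 40`
#' (first 20 attributes binary, last 20 continuous) positions 5, 15, 25, 35
#' are active; with `p = 150` (75 binary + 75 continuous) 7 evenly spaced
#' positions in each half are active. Active values alternate +1/-1 by
#' default (the designs specify only which coefficients are nonzero).
#'
#' @param p covariate dimension.
#' @param active 1-based indices of nonzero coefficients; `NULL` uses the
#'   preset for `p` in \{40, 150\}.
#' @param values nonzero values, recycled over `active`.
#' @return numeric vector of length `p`.
#' @export
make_sparse_beta <- function(p, active = NULL, values = c(1, -1)) {
  if (is.null(active)) {
    active <- if (p == 40L) c(5L, 15L, 25L, 35L)
    else if (p == 150L) c(seq(5L, 65L, 10L), 75L + seq(5L, 65L, 10L))
    else integer(0)
  }
  if (length(active) && max(active) > p) stop("active index exceeds p")
  beta <- rep(0, p)
  if (length(active)) beta[active] <- rep_len(values, length(active))
  beta
}

#' Simulation presets for the benchmark designs
#'
#' \describe{
#'   \item{`table1`}{`n = 500`, no covariates, `sigma2 = 3e-4`; `theta`
#'     chosen by the caller (1.7 / 2.0 / 2.3 in the benchmark).}
#'   \item{`example2`}{`n = 500`, `theta = 2`, `beta = c(0.5, -1)` on one
#'     continuous and one binary attribute.}
#'   \item{`lasso40`}{`n = 50`, `theta = 2`, `p = 40` sparse design
#'     (4 active).}
#'   \item{`lasso150`}{`n = 50`, `theta = 2`, `p = 150` sparse design
#'     (14 active, 7 per attribute type).}
#' }
#'
#' @param preset preset name.
#' @param theta power-law exponent; defaults to 2 except where the caller
#'   must choose (`table1`).
#' @param n override the preset's node count (e.g. for scaled-down runs).
#' @param seed optional RNG seed.
#' @return a `simulated_network`.
#' @export
simulate_preset <- function(preset = c("table1", "example2", "lasso40",
                                       "lasso150"),
                            theta = NULL, n = NULL, seed = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    table1 = {
      if (is.null(theta)) stop("preset 'table1' needs an explicit theta")
      simulate_network(n = if (is.null(n)) 500L else n, theta = theta,
                       sigma2 = 3e-4, seed = seed)
    },
    example2 = simulate_network(
      n = if (is.null(n)) 500L else n,
      theta = if (is.null(theta)) 2 else theta, sigma2 = 3e-4,
      beta = c(0.5, -1), attr_types = c("continuous", "binary"),
      seed = seed),
    lasso40 = simulate_network(
      n = if (is.null(n)) 50L else n,
      theta = if (is.null(theta)) 2 else theta, sigma2 = 3e-4,
      beta = make_sparse_beta(40L),
      attr_types = rep(c("binary", "continuous"), each = 20L),
      seed = seed),
    lasso150 = simulate_network(
      n = if (is.null(n)) 50L else n,
      theta = if (is.null(theta)) 2 else theta, sigma2 = 3e-4,
      beta = make_sparse_beta(150L),
      attr_types = rep(c("binary", "continuous"), each = 75L),
      seed = seed))
}
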