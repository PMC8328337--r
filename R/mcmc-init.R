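# Initialization strategies and the exact Gibbs conditionals.

#' Initialize latent positions by classical MDS on geodesic distances
#'
#' Shortest-path distances in the directed graph are symmetrized by
#' \eqn{d(i,j) \leftarrow \min\{d(i{\to}j), d(j{\to}i)\}}, pairs unreachable
#' in both directions are capped at (max finite distance + 1), the matrix
#' is rescaled by \eqn{1/n}, and classical multidimensional scaling
#' (double-centering + top-`d` eigenvectors) gives column-centered starting
#' coordinates.
#'
#' @param net a [directed_network()].
#' @param d latent dimension (default 2).
#' @return `n x d` matrix of initial coordinates, column means zero.
#' @export
init_latent <- function(net, d = 2L) {
  n <- n_nodes(net)
  if (n < 3L) stop("MDS initialization needs at least 3 nodes")
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  D <- igraph::distances(g, mode = "out")   # D[i, j] = geodesic i -> j
  D <- pmin(D, t(D))                        # symmetrize
  finite <- is.finite(D)
  cap <- if (any(finite & D > 0)) max(D[finite]) + 1 else 1
  D[!finite] <- cap
  diag(D) <- 0
  D <- D / n
  Z <- stats::cmdscale(D, k = d)
  if (ncol(Z) < d)  # degenerate configurations can drop dimensions
    Z <- cbind(Z, matrix(0, n, d - ncol(Z)))
  sweep(Z, 2L, colMeans(Z))
}

#' Initialize popularity scales from in-degrees
#'
#' \deqn{\gamma_j^{(0)} = (1 + d_j^{in}) / (n + \sum_h d_h^{in}),}
#' strictly positive and summing to 1 exactly.
#'
#' @param x a [directed_network()] or [degrees()] summary.
#' @return numeric vector on the open simplex.
#' @export
init_gamma <- function(x) {
  d_in <- if (inherits(x, "degree_summary")) x$d_in
          else degrees(x, n_hubs = 0L)$d_in
  n <- length(d_in)
  (1 + d_in) / (n + sum(d_in))
}

#' Initialize the latent-prior variance
#'
#' \deqn{\sigma^{2(0)} = \frac{1}{2n}\sum_i \|z_i^{(0)}\|^2,} the sample
#' variance of the starting coordinates (per axis, `d = 2`). The same value
#' serves as the Inverse-Gamma scale \eqn{\phi} with \eqn{\nu = 2}, so that
#' \eqn{E(\sigma^2) = \phi/(\nu-1)} targets it.
#'
#' @param Z0 initial coordinates.
#' @return positive scalar (floored at `1e-8` with a warning if `Z0` is
#'   all-zero).
#' @export
init_sigma2 <- function(Z0) {
  s2 <- sum(Z0^2) / (2 * nrow(Z0))
  if (s2 <= 0) {
    warning("initial coordinates are all zero; sigma2 floored at 1e-8")
    s2 <- 1e-8
  }
  s2
}

#' Initialize regression coefficients by logistic regression
#'
#' Plain logistic regression of the vectorized off-diagonal \eqn{y_{ij}} on
#' the pairwise covariates, with the intercept fixed at `beta0` (as an
#' offset) and the latent/popularity terms omitted. One Gibbs draw of the
#' penalty parameters at \eqn{\beta^{(0)}} completes the block.
#'
#' @param net,X data.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param hyper a [phlsm_hyper()] list.
#' @param beta0 fixed intercept.
#' @return list `beta` and `tau2` (ridge) or `lambda` (lasso).
#' @export
init_beta <- function(net, X, penalty = c("ridge", "lasso"),
                      hyper, beta0 = 1) {
  penalty <- match.arg(penalty)
  p <- length(X$types)
  if (p == 0L) {
    out <- list(beta = numeric(0))
    out[[if (penalty == "ridge") "tau2" else "lambda"]] <- numeric(0)
    return(out)
  }
  n <- n_nodes(net)
  off <- which(row(net$adjacency) != col(net$adjacency))
  y <- net$adjacency[off]
  Xmat <- vapply(seq_len(p), function(k) X$X[, , k][off],
                 numeric(length(off)))
  beta <- tryCatch({
    fit <- suppressWarnings(
      stats::glm.fit(Xmat, y, family = stats::binomial(),
                     offset = rep(beta0, length(y)), intercept = FALSE))
    b <- unname(fit$coefficients)
    b[!is.finite(b)] <- 0
    if (!fit$converged || any(abs(b) > 20)) {
      warning("logistic initialization unstable (possible separation); beta0 set to 0")
      rep(0, p)
    } else b
  }, error = function(e) {
    warning("logistic initialization failed; beta0 set to 0")
    rep(0, p)
  })
  out <- list(beta = beta)
  if (penalty == "ridge")
    out$tau2 <- vapply(seq_len(p), function(k)
      gibbs_tau2(beta[k], hyper$xi_tau[k], hyper$delta_tau[k]), numeric(1))
  else
    out$lambda <- vapply(seq_len(p), function(k)
      gibbs_lambda(beta[k], hyper$xi_lambda[k], hyper$delta_lambda[k]), numeric(1))
  out
}

#' Gibbs draw of the latent-prior variance
#'
#' One exact draw from the Inverse-Gamma full conditional
#' \eqn{IG(\nu + n,\; \phi + \frac12 \sum_i \|z_i\|^2)}.
#'
#' @param Z current latent coordinates.
#' @param nu,phi Inverse-Gamma prior shape and scale.
#' @return positive scalar draw.
#' @export
gibbs_sigma2 <- function(Z, nu, phi) {
  shape <- nu + nrow(Z)
  rate <- phi + 0.5 * sum(Z^2)
  1 / stats::rgamma(1L, shape = shape, rate = rate)
}

#' Gibbs draw of a ridge precision
#'
#' \eqn{\tau_k^2 \mid \beta_k \sim Gamma(\xi_\tau + \frac12,\;
#' \delta_\tau + \beta_k^2/2)} (rate parameterization).
#'
#' @param beta_k current coefficient.
#' @param xi,delta Gamma prior shape and rate.
#' @return positive scalar draw.
#' @export
gibbs_tau2 <- function(beta_k, xi, delta) {
  stats::rgamma(1L, shape = xi + 0.5, rate = delta + beta_k^2 / 2)
}

#' Gibbs draw of an adaptive-LASSO tuning parameter
#'
#' \eqn{\lambda_k \mid \beta_k \sim Gamma(\xi_\lambda + 1,\;
#' \delta_\lambda + |\beta_k|)} (rate parameterization).
#'
#' @param beta_k current coefficient.
#' @param xi,delta Gamma prior shape and rate.
#' @return positive scalar draw.
#' @export
gibbs_lambda <- function(beta_k, xi, delta) {
  stats::rgamma(1L, shape = xi + 1, rate = delta + abs(beta_k))
}
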