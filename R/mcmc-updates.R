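# Reference R implementations of the Metropolis-Hastings block updates and
# Procrustes alignment. These are the readable single-step counterparts of
# the compiled sampler loop (see src/sampler.cpp) and are used directly in
# toy-scale correctness checks.

#' Metropolis-Hastings update of one latent position
#'
#' Gaussian random-walk proposal; accepted with probability
#' \eqn{\min(1, \exp \Delta)} where \eqn{\Delta} is the change in
#' [logpost_z()]. The proposal is symmetric, so no correction term enters.
#'
#' @param i node index.
#' @param state list with `Z`, `beta`, `gamma`, `sigma2` (and optionally
#'   `mixture`).
#' @param net,X data.
#' @param step random-walk standard deviation.
#' @param beta0 fixed intercept.
#' @param likelihood set `FALSE` to target the prior alone (diagnostics).
#' @return list `state` (updated), `accepted` (logical).
#' @export
mh_update_z <- function(i, state, net, X = NULL, step, beta0 = 1,
                        likelihood = TRUE) {
  zi <- state$Z[i, ]
  prop <- zi + stats::rnorm(length(zi), 0, step)
  if (likelihood) {
    delta <- logpost_z(i, prop, net, X, state, beta0) -
      logpost_z(i, zi, net, X, state, beta0)
  } else if (!is.null(state$mixture)) {
    g <- state$mixture$labels[i]
    delta <- ldnorm_iso(prop, state$mixture$mu[g, ], state$mixture$s2[g]) -
      ldnorm_iso(zi, state$mixture$mu[g, ], state$mixture$s2[g])
  } else {
    delta <- ldnorm_iso(prop, 0, state$sigma2) - ldnorm_iso(zi, 0, state$sigma2)
  }
  accepted <- log(stats::runif(1L)) < delta
  if (accepted) state$Z[i, ] <- prop
  list(state = state, accepted = accepted)
}

#' Metropolis-Hastings update of one regression coefficient
#'
#' Symmetric random walk against [logpost_beta()]: a Normal walk in ridge
#' mode, a Laplace walk in lasso mode (both symmetric, no correction term).
#'
#' @param k coefficient index.
#' @param state list with `Z`, `beta`, `gamma` and `tau2`/`lambda`.
#' @param net,X data.
#' @param step walk scale.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param beta0 fixed intercept.
#' @param likelihood set `FALSE` to target the prior alone.
#' @return list `state`, `accepted`.
#' @export
mh_update_beta <- function(k, state, net, X, step,
                           penalty = c("ridge", "lasso"), beta0 = 1,
                           likelihood = TRUE) {
  penalty <- match.arg(penalty)
  bk <- state$beta[k]
  prop <- if (penalty == "ridge") bk + stats::rnorm(1L, 0, step)
  else bk + step * sample(c(-1, 1), 1L) * stats::rexp(1L)
  if (likelihood) {
    delta <- logpost_beta(k, prop, net, X, state, penalty, beta0) -
      logpost_beta(k, bk, net, X, state, penalty, beta0)
  } else {
    delta <- if (penalty == "ridge")
      -state$tau2[k] * (prop^2 - bk^2) / 2
    else
      -state$lambda[k] * (abs(prop) - abs(bk))
  }
  accepted <- log(stats::runif(1L)) < delta
  if (accepted) state$beta[k] <- prop
  list(state = state, accepted = accepted)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Metropolis-Hastings update of the popularity vector
#'
#' Proposes \eqn{\gamma^* \sim Dirichlet(M\gamma)} (concentration around the
#' current value; large `M` means small moves). Because the simplex
#' constraint couples all components, the whole vector is kept or rejected
#' jointly, and the acceptance ratio carries the asymmetric-proposal
#' correction \eqn{Dir(\gamma \mid M\gamma^*) / Dir(\gamma^* \mid M\gamma)}
#' times the kernel ratio from [logpost_gamma()].
#'
#' @param state list with `Z`, `beta`, `gamma`.
#' @param net,X data.
#' @param M Dirichlet proposal concentration.
#' @param alpha Dirichlet prior (default flat).
#' @param beta0 fixed intercept.
#' @param likelihood set `FALSE` to target the prior alone.
#' @return list `state`, `accepted`.
#' @export
mh_update_gamma <- function(state, net, X = NULL, M = 5e6, alpha = NULL,
                            beta0 = 1, likelihood = TRUE) {
  gamma <- state$gamma
  n <- length(gamma)
  if (is.null(alpha)) alpha <- rep(1, n)
  prop <- rdirichlet1(M * gamma)
  if (any(prop < 1e-12)) {  # floating-point underflow guard
    prop <- pmax(prop, 1e-12)
    prop <- prop / sum(prop)
  }
  kern <- if (likelihood) {
    logpost_gamma(prop, net, X, state, alpha, beta0) -
      logpost_gamma(gamma, net, X, state, alpha, beta0)
  } else {
    sum((alpha - 1) * (log(prop) - log(gamma)))
  }
  corr <- lddirichlet(gamma, M * prop) - lddirichlet(prop, M * gamma)
  accepted <- log(stats::runif(1L)) < kern + corr
  if (accepted) state$gamma <- prop
  list(state = state, accepted = accepted)
}

#' Procrustes alignment of latent coordinates
#'
#' Optimal rigid motion (translation plus rotation/reflection, no scaling)
#' minimizing the Frobenius distance to a reference configuration. All
#' pairwise distances — and hence the likelihood — are preserved. Used to
#' remove the rotation/translation non-identifiability of latent positions.
#'
#' @param Z coordinates to align (`n x d`).
#' @param Z_ref reference configuration of the same shape.
#' @return aligned `n x d` matrix.
#' @export
procrustes_align <- function(Z, Z_ref) {
  stopifnot(all(dim(Z) == dim(Z_ref)))
  mz <- colMeans(Z); mr <- colMeans(Z_ref)
  Zc <- sweep(Z, 2L, mz)
  Rc <- sweep(Z_ref, 2L, mr)
  s <- svd(crossprod(Zc, Rc))
  Q <- s$u %*% t(s$v)
  sweep(Zc %*% Q, 2L, mr, "+")
}
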