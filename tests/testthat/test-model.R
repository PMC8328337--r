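# Linear predictor, likelihood and full-conditional kernels, checked
# against brute-force oracles on small fixtures.

test_that("linear predictor matches the log-odds formula", {
  Z <- rbind(c(0, 0), c(0, 0), c(3, 4))
  gamma <- c(0.5, 0.3, 0.2)
  # zero distance, no covariates: eta = beta0 = 1, p ~ 0.7311
  expect_equal(linear_predictor(Z, gamma = gamma, i = 1, j = 2), 1)
  expect_equal(stats::plogis(1), 0.7311, tolerance = 1e-4)
  # distance 5 scaled by gamma_3 = 0.2
  expect_equal(linear_predictor(Z, gamma = gamma, i = 1, j = 3), 1 - 25)
  # gamma_j -> 0 with positive distance: probability -> 0
  g0 <- c(0.5, 0.5 - 1e-12, 1e-12)
  expect_equal(stats::plogis(linear_predictor(Z, gamma = g0, i = 1, j = 3)), 0)
  # gamma_j = 1 reduces to the unscaled latent-distance predictor
  expect_equal(linear_predictor(Z, gamma = c(1, 1, 1), i = 1, j = 3), 1 - 5)
  expect_error(linear_predictor(Z, gamma = c(0.5, 0, 0.5), i = 1, j = 2),
               "positive")
  expect_error(linear_predictor(Z, gamma = gamma, i = 2, j = 2), "differ")
})

test_that("full-matrix predictor agrees with the scalar version", {
  st <- toy_state(6, p = 2)
  X <- random_covariates(6, 2)
  eta <- linear_predictor(st$Z, X, st$beta, st$gamma)
  expect_true(all(is.na(diag(eta))))
  for (i in 1:6) for (j in setdiff(1:6, i))
    expect_equal(eta[i, j],
                 linear_predictor(st$Z, X, st$beta, st$gamma, i = i, j = j))
})

test_that("predictor is invariant under rigid motions of Z", {
  st <- toy_state(8, p = 1)
  X <- random_covariates(8, 1)
  ang <- 1.1
  Q <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  refl <- diag(c(1, -1))
  for (Tf in list(Q, Q %*% refl)) {
    Z2 <- sweep(st$Z %*% Tf, 2, c(2.5, -1), "+")
    e1 <- linear_predictor(st$Z, X, st$beta, st$gamma)
    e2 <- linear_predictor(Z2, X, st$beta, st$gamma)
    expect_lt(max(abs(e1 - e2), na.rm = TRUE), 1e-10)
  }
})

test_that("log-likelihood sums eta*y - log(1+exp(eta)) over ordered pairs", {
  # two nodes, eta = 0 on both ordered pairs, one edge observed:
  # each pair contributes -log 2 regardless of y
  Y <- matrix(0L, 2, 2); Y[1, 2] <- 1L
  net2 <- directed_network(Y)
  eta <- matrix(0, 2, 2); diag(eta) <- NA
  expect_equal(log_likelihood(net2, eta), -2 * log(2))

  # 3 nodes, all eta = 1, 3 edges: 3*1 - 6*log(1+e)
  eta3 <- matrix(1, 3, 3); diag(eta3) <- NA
  expect_equal(log_likelihood(toy_net3(), eta3), 3 - 6 * log(1 + exp(1)))

  # overflow-safe at extreme eta
  eta3[1, 2] <- 800; eta3[2, 1] <- -800
  expect_true(is.finite(log_likelihood(toy_net3(), eta3)))
})

test_that("log-likelihood agrees with the brute-force oracle on random fixtures", {
  for (seed in 1:4) {
    st <- toy_state(7, p = 2, seed = seed)
    X <- random_covariates(7, 2, seed = seed + 10)
    net <- random_net(7, seed = seed + 20)
    eta <- linear_predictor(st$Z, X, st$beta, st$gamma)
    expect_equal(log_likelihood(net, eta),
                 oracle_loglik(net, st$Z, X, st$beta, st$gamma),
                 tolerance = 1e-10)
  }
})

test_that("logpost_z equals the full-likelihood difference plus prior", {
  st <- toy_state(4, p = 1)
  X <- random_covariates(4, 1)
  net <- random_net(4, seed = 5)
  zcand <- c(0.4, -0.2)
  for (i in 1:4) {
    Zc <- st$Z; Zc[i, ] <- zcand
    delta_oracle <- oracle_loglik(net, Zc, X, st$beta, st$gamma) -
      oracle_loglik(net, st$Z, X, st$beta, st$gamma) +
      (-sum(zcand^2) + sum(st$Z[i, ]^2)) / (2 * st$sigma2)
    delta_kernel <- logpost_z(i, zcand, net, X, st) -
      logpost_z(i, st$Z[i, ], net, X, st)
    expect_equal(delta_kernel, delta_oracle, tolerance = 1e-9)
  }
  # far-away candidate in a fully connected graph: density -> -Inf
  K <- matrix(1L, 4, 4); diag(K) <- 0L
  lp_far <- logpost_z(1, c(1e8, 0), directed_network(K), X, st)
  expect_lt(lp_far, -1e7)
})

test_that("logpost_z kernel matches brute force along a 1-D grid (oracle)", {
  # 3-node toy in a 1-D latent space; moving z_1 along a grid, the kernel
  # must equal full loglik + prior up to one additive constant
  set.seed(8)
  st <- list(Z = matrix(c(0, 0.5, -0.7), 3, 1), gamma = c(0.3, 0.4, 0.3),
             beta = numeric(0), sigma2 = 0.5)
  net <- toy_net3()
  grid <- seq(-3, 3, length.out = 61)
  kern <- vapply(grid, function(z) logpost_z(1, z, net, NULL, st), numeric(1))
  brute <- vapply(grid, function(z) {
    Zc <- st$Z; Zc[1, ] <- z
    oracle_loglik(net, Zc, NULL, numeric(0), st$gamma) +
      dnorm(z, 0, sqrt(st$sigma2), log = TRUE)
  }, numeric(1))
  expect_lt(diff(range(kern - brute)), 1e-9)
})

test_that("logpost_beta carries the full likelihood and the stated priors", {
  st <- toy_state(4, p = 2)
  X <- random_covariates(4, 2)
  net <- random_net(4, seed = 6)
  b_new <- 0.9
  for (penalty in c("ridge", "lasso")) {
    for (k in 1:2) {
      bvec <- st$beta; bvec[k] <- b_new
      prior_old <- if (penalty == "ridge")
        -st$tau2[k] * st$beta[k]^2 / 2 else -st$lambda[k] * abs(st$beta[k])
      prior_new <- if (penalty == "ridge")
        -st$tau2[k] * b_new^2 / 2 else -st$lambda[k] * abs(b_new)
      delta_oracle <- oracle_loglik(net, st$Z, X, bvec, st$gamma) -
        oracle_loglik(net, st$Z, X, st$beta, st$gamma) +
        prior_new - prior_old
      delta_kernel <- logpost_beta(k, b_new, net, X, st, penalty) -
        logpost_beta(k, st$beta[k], net, X, st, penalty)
      expect_equal(delta_kernel, delta_oracle, tolerance = 1e-9)
    }
  }
  # Laplace prior value at beta_k = 0 is log(lambda_k / 2)
  st0 <- toy_state(4, p = 1)
  X1 <- random_covariates(4, 1)
  netp <- random_net(4, seed = 7)
  lp0 <- logpost_beta(1, 0, netp, X1, st0, "lasso")
  bvec <- st0$beta; bvec[1] <- 0
  expect_equal(lp0 - oracle_loglik(netp, st0$Z, X1, bvec, st0$gamma),
               log(st0$lambda[1] / 2), tolerance = 1e-9)
})

test_that("logpost_gamma is likelihood plus Dirichlet prior on the open simplex", {
  st <- toy_state(4, p = 0)
  net <- random_net(4, seed = 8)
  g2 <- c(0.4, 0.3, 0.2, 0.1)
  alpha <- c(2, 1, 1, 3)
  delta_oracle <- oracle_loglik(net, st$Z, NULL, numeric(0), g2) -
    oracle_loglik(net, st$Z, NULL, numeric(0), st$gamma) +
    sum((alpha - 1) * (log(g2) - log(st$gamma)))
  delta_kernel <- logpost_gamma(g2, net, NULL, st, alpha) -
    logpost_gamma(st$gamma, net, NULL, st, alpha)
  expect_equal(delta_kernel, delta_oracle, tolerance = 1e-9)

  # flat prior: kernel difference is pure likelihood difference
  dflat <- logpost_gamma(g2, net, NULL, st) -
    logpost_gamma(st$gamma, net, NULL, st)
  expect_equal(dflat,
               oracle_loglik(net, st$Z, NULL, numeric(0), g2) -
                 oracle_loglik(net, st$Z, NULL, numeric(0), st$gamma),
               tolerance = 1e-9)
  expect_error(logpost_gamma(c(0.5, 0.5, 0, 0), net, NULL, st), "strictly")

  # n = 2 instantiation: loglik of the two ordered pairs plus constant prior
  Y2 <- matrix(0L, 2, 2); Y2[1, 2] <- 1L
  net2 <- directed_network(Y2)
  st2 <- list(Z = matrix(c(0, 0.2, 0, 0), 2, 2), beta = numeric(0))
  lp <- logpost_gamma(c(0.5, 0.5), net2, NULL, st2)
  expect_equal(lp, oracle_loglik(net2, st2$Z, NULL, numeric(0), c(0.5, 0.5)),
               tolerance = 1e-9)
})

test_that("increasing a popular node's gamma raises the kernel on a star graph", {
  # star: everyone follows node 1
  n <- 5
  Y <- matrix(0L, n, n); Y[2:n, 1] <- 1L
  net <- directed_network(Y)
  set.seed(3)
  st <- list(Z = matrix(rnorm(2 * n, 0, 0.5), n, 2), beta = numeric(0))
  g_lo <- rep(1 / n, n)
  g_hi <- c(0.6, rep(0.4 / (n - 1), n - 1))
  expect_gt(logpost_gamma(g_hi, net, NULL, st),
            logpost_gamma(g_lo, net, NULL, st))
})

test_that("cluster membership probabilities normalize and relabel consistently", {
  mix <- list(weights = c(0.5, 0.5), mu = rbind(c(0, 0), c(10, 0)),
              s2 = c(1, 1))
  expect_equal(cluster_membership_probs(c(0, 0), list(
    weights = 1, mu = matrix(0, 1, 2), s2 = 2)), 1)
  # equidistant between symmetric components
  expect_equal(cluster_membership_probs(c(5, 3), mix), c(0.5, 0.5))
  # at a component mean with the other far away
  p <- cluster_membership_probs(c(0, 0), mix)
  expect_equal(p[1], 1, tolerance = 1e-10)
  # sums to one and survives heavy underflow
  mix2 <- list(weights = c(0.3, 0.7), mu = rbind(c(0, 0), c(2000, 0)),
               s2 = c(1e-6, 1e-6))
  p2 <- cluster_membership_probs(c(1000, 0), mix2)
  expect_false(anyNA(p2))
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  # relabeling components with their parameters permutes the output
  perm <- c(2, 1)
  mixp <- list(weights = mix$weights[perm], mu = mix$mu[perm, ],
               s2 = mix$s2[perm])
  z <- c(1.3, -0.4)
  expect_equal(cluster_membership_probs(z, mixp),
               cluster_membership_probs(z, mix)[perm], tolerance = 1e-12)
})
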