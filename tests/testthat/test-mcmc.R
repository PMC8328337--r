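# Initialization strategies, Gibbs conditionals, MH block updates,
# Procrustes alignment, and sampler determinism.

test_that("MDS initialization reproduces simple geometries and is centered", {
  # triangle of mutual edges: equilateral configuration
  K <- matrix(1L, 3, 3); diag(K) <- 0L
  Z <- init_latent(directed_network(K))
  dists <- as.numeric(dist(Z))
  expect_equal(max(dists) / min(dists), 1, tolerance = 1e-8)
  expect_equal(colMeans(Z), c(0, 0), tolerance = 1e-12)

  # path 1->2->3: collinear with node 2 in the middle
  Yp <- matrix(0L, 3, 3); Yp[1, 2] <- 1L; Yp[2, 3] <- 1L
  Zp <- init_latent(directed_network(Yp))
  D <- as.matrix(dist(Zp))
  expect_equal(D[1, 3], D[1, 2] + D[2, 3], tolerance = 1e-8)
  expect_equal(D[1, 2], D[2, 3], tolerance = 1e-8)
  expect_equal(colMeans(Zp), c(0, 0), tolerance = 1e-12)

  # disconnected networks are handled through the distance cap
  Yd <- matrix(0L, 4, 4); Yd[1, 2] <- 1L; Yd[2, 1] <- 1L
  Zd <- init_latent(directed_network(Yd))
  expect_true(all(is.finite(Zd)))
})

test_that("popularity initialization follows the in-degree formula", {
  # edgeless graph: all gamma = 1/n
  expect_equal(unname(init_gamma(directed_network(matrix(0L, 5, 5)))), rep(0.2, 5))
  # n = 2 with d_in = (1, 0): gamma = (2/3, 1/3)
  Y <- matrix(0L, 2, 2); Y[2, 1] <- 1L
  expect_equal(unname(init_gamma(directed_network(Y))), c(2 / 3, 1 / 3))
  # sums to 1 exactly on random networks
  for (seed in 1:4) {
    g <- init_gamma(random_net(11, seed = seed))
    expect_equal(sum(g), 1, tolerance = 1e-15)
    expect_true(all(g > 0))
  }
})

test_that("sigma2 initialization is the coordinate sample variance", {
  Z0 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(init_sigma2(Z0), 0.5)
  set.seed(2)
  Z1 <- matrix(rnorm(20), 10, 2)
  expect_equal(init_sigma2(3 * Z1), 9 * init_sigma2(Z1))
  expect_warning(s0 <- init_sigma2(matrix(0, 4, 2)), "floored")
  expect_equal(s0, 1e-8)
})

test_that("logistic initialization matches an independent IRLS oracle", {
  sim <- simulate_network(20, theta = 2, sigma2 = 0.01,
                          beta = c(0.8, -0.6),
                          attr_types = c("continuous", "binary"), seed = 31)
  hyper <- phlsm_hyper(sim$X$types, n = 20, phi = 1)
  b <- init_beta(sim$net, sim$X, "ridge", hyper)

  # plain IRLS on the vectorized pairs with offset 1, no intercept column
  off <- which(row(sim$net$adjacency) != col(sim$net$adjacency))
  y <- sim$net$adjacency[off]
  Xm <- cbind(sim$X$X[, , 1][off], sim$X$X[, , 2][off])
  bb <- c(0, 0)
  for (it in 1:50) {
    eta <- 1 + Xm %*% bb
    mu <- stats::plogis(eta)
    w <- as.numeric(mu * (1 - mu))
    z <- (y - mu) / w
    bb <- bb + solve(crossprod(Xm, w * Xm), crossprod(Xm, w * z))
  }
  expect_equal(b$beta, as.numeric(bb), tolerance = 1e-5)
  expect_length(b$tau2, 2)
  expect_true(all(b$tau2 > 0))

  # p = 0 is a no-op
  b0 <- init_beta(sim$net, structure(list(X = array(0, c(20, 20, 0)),
                                          types = character(0)),
                                     class = "pairwise_covariates"),
                  "lasso", hyper)
  expect_length(b0$beta, 0)
  expect_length(b0$lambda, 0)
})

test_that("Gibbs conditionals have the stated closed forms", {
  set.seed(99)
  # sigma2 | Z: Inverse-Gamma(nu + n, phi + sum||z||^2 / 2)
  Z <- matrix(rnorm(16, 0, 0.4), 8, 2)
  nu <- 2; phi <- 0.3
  draws <- replicate(1e5, gibbs_sigma2(Z, nu, phi))
  expect_true(all(draws > 0))
  m_theory <- (phi + sum(Z^2) / 2) / (nu + 8 - 1)
  expect_equal(mean(draws), m_theory, tolerance = 0.02)
  # Z = 0 reduces to IG(nu + n, phi)
  d0 <- replicate(1e5, gibbs_sigma2(matrix(0, 8, 2), nu, phi))
  expect_equal(mean(d0), phi / (nu + 8 - 1), tolerance = 0.02)

  # tau2 | beta ~ Gamma(xi + 1/2, delta + beta^2/2); lambda similar
  t_draws <- replicate(1e5, gibbs_tau2(0.7, xi = 4, delta = 0.05))
  expect_equal(mean(t_draws), (4 + 0.5) / (0.05 + 0.49 / 2), tolerance = 0.01)
  l_draws <- replicate(1e5, gibbs_lambda(0.7, xi = 8, delta = 0.1))
  expect_equal(mean(l_draws), (8 + 1) / (0.1 + 0.7), tolerance = 0.01)
  # larger |beta| makes lambda stochastically smaller
  l_big <- replicate(1e4, gibbs_lambda(3, xi = 8, delta = 0.1))
  expect_lt(mean(l_big), mean(l_draws))
})

test_that("random-walk updates honor degenerate proposals and the MH rule", {
  st <- toy_state(4, p = 1)
  X <- random_covariates(4, 1)
  net <- random_net(4, seed = 12)
  set.seed(1)
  # zero step: proposal equals current point, always accepted, chain constant
  for (rep in 1:5) {
    up <- mh_update_z(2, st, net, X, step = 0)
    expect_true(up$accepted)
    expect_equal(up$state$Z, st$Z)
  }
  upb <- mh_update_beta(1, st, net, X, step = 0)
  expect_true(upb$accepted)
  expect_equal(upb$state$beta, st$beta)
  # gamma update keeps the simplex closed
  set.seed(2)
  for (rep in 1:20) {
    upg <- mh_update_gamma(st, net, X, M = 1e4)
    st <- upg$state
    expect_equal(sum(st$gamma), 1, tolerance = 1e-12)
    expect_true(all(st$gamma > 0 & st$gamma < 1))
  }
})

test_that("single-site latent updates sample the grid-integrated conditional", {
  # 1-D latent toy: long-run draws of z_1 must match the conditional
  # density integrated on a grid (all other blocks held fixed)
  net <- toy_net3()
  st <- list(Z = matrix(c(0, 0.4, -0.6), 3, 1), gamma = c(0.34, 0.33, 0.33),
             beta = numeric(0), sigma2 = 0.4)
  grid <- seq(-4, 4, length.out = 801)
  dens <- vapply(grid, function(z) logpost_z(1, z, net, NULL, st), numeric(1))
  dens <- exp(dens - max(dens))
  cdf <- cumsum(dens) / sum(dens)

  set.seed(42)
  n_iter <- 20000
  keep <- numeric(n_iter)
  cur <- st
  for (t in seq_len(n_iter)) {
    cur <- mh_update_z(1, cur, net, NULL, step = 0.8)$state
    keep[t] <- cur$Z[1, 1]
  }
  keep <- keep[seq(1000, n_iter, by = 10)]
  # Kolmogorov-Smirnov distance against the grid CDF
  ks <- max(abs(vapply(sort(keep), function(x)
    cdf[findInterval(x, grid)], numeric(1)) -
      seq_along(keep) / length(keep)))
  expect_lt(ks, 0.05)
})

test_that("gamma updates with the likelihood off sample the Dirichlet prior", {
  net <- toy_net3()
  st <- list(Z = matrix(0, 3, 1), gamma = rep(1 / 3, 3), beta = numeric(0),
             sigma2 = 1)
  alpha <- c(2, 3, 4)
  set.seed(7)
  n_iter <- 20000
  draws <- matrix(0, n_iter, 3)
  for (t in seq_len(n_iter)) {
    st <- mh_update_gamma(st, net, NULL, M = 300, alpha = alpha,
                          likelihood = FALSE)$state
    draws[t, ] <- st$gamma
  }
  draws <- draws[-(1:2000), ]
  for (j in 1:3) {
    se <- batch_se(draws[, j])
    expect_lt(abs(mean(draws[, j]) - alpha[j] / sum(alpha)), 4 * se + 0.005)
  }
})

test_that("Procrustes alignment is an optimal rigid motion", {
  set.seed(21)
  Zref <- matrix(rnorm(20), 10, 2)
  # identity on itself
  expect_equal(procrustes_align(Zref, Zref), Zref, tolerance = 1e-12)
  # recovers a rotated + translated copy exactly
  ang <- 0.7
  Q <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  Zrot <- sweep(Zref %*% Q, 2, c(3, -2), "+")
  expect_equal(procrustes_align(Zrot, Zref), Zref, tolerance = 1e-10)
  # preserves pairwise distances
  Z <- matrix(rnorm(20), 10, 2)
  A <- procrustes_align(Z, Zref)
  expect_lt(max(abs(dist(A) - dist(Z))), 1e-10)
  # beats 100 random rigid motions in Frobenius distance
  fro <- function(M) sqrt(sum((M - Zref)^2))
  best <- fro(A)
  for (r in 1:100) {
    a <- runif(1, 0, 2 * pi)
    Qr <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    if (runif(1) < 0.5) Qr <- Qr %*% diag(c(1, -1))
    cand <- sweep(Z %*% Qr, 2, rnorm(2, 0, 0.5), "+")
    expect_gte(fro(cand), best - 1e-10)
  }
})

test_that("the sampler is deterministic, constraint-preserving, and logs traces", {
  sim <- simulate_network(20, theta = 2, sigma2 = 0.01, seed = 77)
  cfg <- phlsm_config(burn_in = 200, monitor = 400, thin = 4, seed = 5,
                      M = 1e4)
  f1 <- phlsm_fit(sim$net, config = cfg)
  f2 <- phlsm_fit(sim$net, config = cfg)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_equal(f1$n_samples, 100)

  # constraints on every stored draw
  expect_equal(rowSums(f1$gamma), rep(1, 100), tolerance = 1e-9)
  expect_true(all(f1$gamma > 0 & f1$gamma < 1))
  expect_true(all(f1$sigma2 > 0))
  # per-iteration log-likelihood trace and acceptance bookkeeping
  expect_length(f1$loglik, 600)
  expect_true(all(is.finite(f1$loglik)))
  expect_true(f1$acceptance$z > 0 && f1$acceptance$z < 1)
  expect_true(f1$acceptance$gamma > 0)

  # the exp-free cached trace agrees with a direct evaluation at the end
  last <- f1$Z[, , 100]
  eta_last <- linear_predictor(last, NULL, numeric(0), f1$gamma[100, ])
  expect_equal(f1$loglik[600], log_likelihood(sim$net, eta_last),
               tolerance = 1e-6)
})

test_that("burn-in-only runs return empty sample stores without crashing", {
  sim <- simulate_network(12, theta = 2, sigma2 = 0.01, seed = 3)
  f <- phlsm_fit(sim$net, config = phlsm_config(burn_in = 50, monitor = 0,
                                                thin = 1, seed = 1, M = 1e3))
  expect_equal(f$n_samples, 0)
  expect_equal(dim(f$Z)[3], 0)
  expect_length(f$sigma2, 0)
  expect_length(f$loglik, 50)
})

test_that("Procrustes alignment never changes a likelihood value", {
  set.seed(13)
  net <- random_net(12, seed = 13)
  Zref <- init_latent(net)
  for (rep in 1:5) {
    st <- toy_state(12, p = 1, seed = rep)
    X <- random_covariates(12, 1, seed = rep)
    ll_before <- log_likelihood(net,
      linear_predictor(st$Z, X, st$beta, st$gamma))
    Za <- procrustes_align(st$Z, Zref)
    ll_after <- log_likelihood(net,
      linear_predictor(Za, X, st$beta, st$gamma))
    expect_equal(ll_before, ll_after, tolerance = 1e-8)
  }
})
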