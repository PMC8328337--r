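# Link-prediction, variable-selection and parameter-recovery metrics.

#' Thresholded link-prediction rates
#'
#' Classifies \eqn{\hat p_{ij} \ge} `threshold` as a predicted edge over
#' all ordered pairs \eqn{i \ne j} and reports the total correct rate
#' (TCR), true positive rate (TPR) and false positive rate (FPR).
#'
#' @param phat fitted probability matrix (diagonal ignored), e.g. from
#'   [predict.phlsm_fit()].
#' @param net the observed [directed_network()].
#' @param threshold classification cut in (0, 1) (default 0.5; the rates
#'   depend on it, so it is exposed).
#' @return list `TCR`, `TPR`, `FPR` and the confusion counts `TP`, `FP`,
#'   `TN`, `FN`. A class absent from `Y` yields a flagged `NaN` rate.
#' @export
link_metrics <- function(phat, net, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  Y <- net$adjacency
  off <- row(Y) != col(Y)
  y <- Y[off]
  yhat <- as.integer(phat[off] >= threshold)
  TP <- sum(yhat == 1 & y == 1); FP <- sum(yhat == 1 & y == 0)
  TN <- sum(yhat == 0 & y == 0); FN <- sum(yhat == 0 & y == 1)
  list(TCR = (TP + TN) / length(y),
       TPR = if (TP + FN > 0) TP / (TP + FN) else NaN,
       FPR = if (FP + TN > 0) FP / (FP + TN) else NaN,
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' ROC curve and AUC for link prediction
#'
#' Rank-based (Mann-Whitney) area under the ROC curve over ordered pairs,
#' with midrank tie handling; curve points are returned for plotting or
#' export.
#'
#' @param phat fitted probability matrix (diagonal ignored).
#' @param net the observed [directed_network()].
#' @return list `auc` and `curve` (data.frame with `threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(phat, net) {
  Y <- net$adjacency
  off <- row(Y) != col(Y)
  y <- Y[off]
  s <- phat[off]
  if (length(unique(y)) < 2L)
    stop("network contains a single class; AUC undefined")
  r <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  list(auc = as.numeric(r$auc),
       curve = data.frame(threshold = r$thresholds,
                          tpr = r$sensitivities,
                          fpr = 1 - r$specificities))
}

#' Variable-selection metrics over replicates
#'
#' A coefficient counts as "estimated as non-zero" when its equal-tailed
#' \eqn{(1 - \text{level})} posterior credible interval excludes 0 (the
#' standard surrogate for exact zeros, which a sampled LASSO posterior
#' never produces). Per replicate, `C` counts true non-zeros kept and `IC`
#' true zeros kept wrongly; across replicates, Under-fit is the fraction
#' missing at least one true non-zero, Over-fit the fraction including at
#' least one true zero, Correct-fit the fraction with exact support
#' recovery.
#'
#' @param beta_draws a draws matrix (`S x p`) for one replicate, or a list
#'   of such matrices over replicates.
#' @param true_beta true coefficient vector.
#' @param level total tail probability of the credible interval
#'   (default 0.05, i.e. a 95% interval).
#' @return list with per-replicate `C` and `IC` vectors, their means, and
#'   the `underfit`, `overfit`, `correctfit` rates; `selected` is the
#'   logical inclusion matrix (replicates x coefficients).
#' @export
selection_metrics <- function(beta_draws, true_beta, level = 0.05) {
  if (is.matrix(beta_draws)) beta_draws <- list(beta_draws)
  nz <- true_beta != 0
  sel <- t(vapply(beta_draws, function(B) {
    q <- apply(B, 2L, stats::quantile, probs = c(level / 2, 1 - level / 2))
    q[1, ] > 0 | q[2, ] < 0
  }, logical(length(true_beta))))
  C <- as.integer(sel %*% nz)
  IC <- as.integer(sel %*% !nz)
  under <- rowSums(!sel[, nz, drop = FALSE]) > 0
  over <- IC > 0
  list(C = C, IC = IC, C_mean = mean(C), IC_mean = mean(IC),
       underfit = mean(under), overfit = mean(over),
       correctfit = mean(!under & !over), selected = sel)
}

#' Parameter-recovery diagnostics against simulation truth
#'
#' Mean squared errors of the estimated pairwise latent distances and
#' popularity scales, the edge-wise estimate/truth ratios
#' \eqn{\hat d(i,j)/d(i,j)} and \eqn{\hat\gamma_j/\gamma_j} (for density
#' diagnostics; concentration near 1 indicates good recovery), and the
#' Spearman rank correlation of \eqn{\hat\gamma} with the in-degrees.
#'
#' @param fit a [phlsm_fit()] (its posterior means are the estimates), or a
#'   list with elements `Z` (`n x d` estimate) and `gamma`.
#' @param sim the `simulated_network` that produced the data (or any list
#'   with `net` and `truth`).
#' @return list `mse_dist`, `mse_gamma`, `dist_ratio`, `gamma_ratio`,
#'   `spearman_gamma_indeg`, `n_excluded` (edges dropped from the distance
#'   ratios because the true distance is zero).
#' @export
recovery_metrics <- function(fit, sim) {
  if (inherits(fit, "phlsm_fit")) {
    Zhat <- apply(fit$Z, c(1, 2), mean)
    ghat <- colMeans(fit$gamma)
  } else {
    Zhat <- fit$Z
    ghat <- fit$gamma
  }
  truth <- sim$truth
  Dhat <- as.matrix(stats::dist(Zhat))
  Dtrue <- as.matrix(stats::dist(truth$Z))
  off <- row(Dhat) != col(Dhat)
  mse_dist <- mean((Dhat[off] - Dtrue[off])^2)
  mse_gamma <- mean((ghat - truth$gamma)^2)
  Y <- sim$net$adjacency
  e <- which(Y == 1L, arr.ind = TRUE)
  dt <- Dtrue[e]
  ok <- dt > 0
  d_in <- degrees(sim$net, n_hubs = 0L)$d_in
  list(mse_dist = mse_dist, mse_gamma = mse_gamma,
       dist_ratio = Dhat[e][ok] / dt[ok],
       gamma_ratio = ghat[e[, 2]] / truth$gamma[e[, 2]],
       spearman_gamma_indeg = stats::cor(ghat, d_in, method = "spearman"),
       n_excluded = sum(!ok))
}
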