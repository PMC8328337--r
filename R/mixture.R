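# Label-switching post-processing for the mixture latent prior.

perms_of <- function(G) {
  if (G == 1L) return(matrix(1L, 1, 1))
  sub <- perms_of(G - 1L)
  do.call(rbind, lapply(seq_len(G), function(pos) {
    cbind_pos <- function(row) append(row, G, after = pos - 1L)
    t(apply(sub, 1L, cbind_pos))
  }))
}

#' Resolve label switching in mixture posterior samples
#'
#' A mixture posterior is invariant to permutations of its component
#' labels, so raw chains can switch labels mid-run. For each stored draw
#' this computes the per-node membership probability matrix, then applies
#' the permutation of \eqn{\{1..G\}} minimizing the Kullback-Leibler
#' divergence from a running reference (the mean of the already-relabeled
#' draws), exhaustively over the \eqn{G!} permutations (`G <= 8` enforced).
#'
#' @param fit a [phlsm_fit()] run with `mixture_G > 1`.
#' @return the fit with relabeled `mixture` draws, plus
#'   `mixture$membership` (an `n x G` posterior membership probability
#'   matrix averaged over relabeled draws) and `mixture$kl_trace` (the
#'   objective per draw after relabeling).
#' @export
relabel_clusters <- function(fit) {
  if (is.null(fit$mixture)) stop("fit has no mixture component")
  G <- fit$mixture$G
  if (G > 8L)
    stop("exhaustive KL relabeling supports G <= 8; ",
         "use a pivot-based scheme for larger G")
  S <- fit$n_samples
  n <- dim(fit$Z)[1]
  P <- perms_of(G)
  ref <- NULL
  kl_trace <- numeric(S)
  eps <- 1e-12
  for (s in seq_len(S)) {
    mix <- list(weights = fit$mixture$weights[s, ],
                mu = fit$mixture$mu[, , s, drop = FALSE][, , 1],
                s2 = fit$mixture$s2[s, ])
    if (G == 1L) mix$mu <- matrix(mix$mu, nrow = 1)
    Q <- t(vapply(seq_len(n), function(i)
      cluster_membership_probs(fit$Z[i, , s], mix), numeric(G)))
    if (is.null(ref)) {
      ref <- Q
      kl_trace[s] <- 0
      best <- seq_len(G)
    } else {
      obj <- apply(P, 1L, function(pm) {
        Qp <- Q[, pm, drop = FALSE]
        sum(Qp * (log(Qp + eps) - log(ref + eps)))
      })
      b <- which.min(obj)
      best <- P[b, ]
      kl_trace[s] <- obj[b]
      Q <- Q[, best, drop = FALSE]
      ref <- ((s - 1) * ref + Q) / s
    }
    # apply the permutation to the stored draw
    inv <- order(best)
    fit$mixture$labels[s, ] <- inv[fit$mixture$labels[s, ]]
    fit$mixture$weights[s, ] <- fit$mixture$weights[s, best]
    fit$mixture$mu[, , s] <- fit$mixture$mu[best, , s]
    fit$mixture$s2[s, ] <- fit$mixture$s2[s, best]
  }
  fit$mixture$membership <- ref
  fit$mixture$kl_trace <- kl_trace
  fit
}
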