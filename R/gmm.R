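# Finite Gaussian mixture fitted by expectation-maximization with full
# covariances, multiple k-means-initialized restarts and ridge
# regularization of degenerate covariances.  Fills the model-based
# clustering role (the Mclust role) natively, with no cross-language
# runtime dependency.

mvn_logdens <- function(x, mean, cov, reg = 1e-6) {
  d <- ncol(x)
  for (i in 0:6) {
    ch <- tryCatch(chol(cov + diag(reg * 10^i, d)), error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) mvc_stop("covariance not positive definite", "mvc_cluster_error")
  xc <- sweep(x, 2, mean)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_em <- function(x, k, resp, max_iter = 100, tol = 1e-6, reg = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- pmax(colSums(resp), 1e-10)
    pi_k <- nk / n
    means <- t(resp) %*% x / nk
    logd <- matrix(0, n, k)
    covs <- vector("list", k)
    for (j in seq_len(k)) {
      xc <- sweep(x, 2, means[j, ])
      covs[[j]] <- crossprod(xc * resp[, j], xc) / nk[j] + diag(reg, d)
      logd[, j] <- mvn_logdens(x, means[j, ], covs[[j]], reg) + log(pi_k[j])
    }
    # E-step with log-sum-exp
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    if (abs(ll - ll_old) < tol * abs(ll_old + 1)) break
    ll_old <- ll
  }
  list(resp = resp, loglik = ll, means = means, covs = covs, weights = pi_k)
}

#' Fit a Gaussian mixture model by EM with restarts
#'
#' @param x n x d data matrix
#' @param k number of components (>= 2)
#' @param seed RNG seed (controls the k-means initializations)
#' @param restarts number of restarts; the best log-likelihood fit wins
#' @param max_iter EM iterations per restart
#' @param reg covariance ridge
#' @return list with `labels` (0-based), `loglik`, `means`, `resp`
#' @export
fit_gmm <- function(x, k, seed = 0, restarts = 10, max_iter = 100,
                    reg = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2) mvc_validation_error("k must be >= 2")
  if (n <= k) mvc_validation_error("need more points than clusters")
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    init_lab <- tryCatch(
      stats::kmeans(x, centers = k, nstart = 1, iter.max = 50)$cluster,
      error = function(e) sample(rep_len(seq_len(k), n)))
    resp <- matrix(1e-6, n, k)
    resp[cbind(seq_len(n), init_lab)] <- 1
    resp <- resp / rowSums(resp)
    fit <- tryCatch(gmm_em(x, k, resp, max_iter = max_iter, reg = reg),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    mvc_stop("EM failed in every restart", "mvc_cluster_error")
  labels <- max.col(best$resp, ties.method = "first") - 1L
  list(labels = labels, loglik = best$loglik, means = best$means,
       resp = best$resp)
}

#' Cluster a latent embedding with a Gaussian mixture
#'
#' Hard assignments from the best-likelihood EM fit; deterministic given
#' the seed.
#'
#' @inheritParams fit_gmm
#' @return integer label vector in `0..k-1`
#' @export
cluster_embedding <- function(x, k, seed = 0, restarts = 10) {
  fit_gmm(x, k, seed = seed, restarts = restarts)$labels
}
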