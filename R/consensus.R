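#' Consensus matrix from per-view partitions
#'
#' Entry (i, j) is the fraction of clusterings in which spots i and j share
#' a label — the average of the per-view binary co-clustering indicator
#' matrices.  Invariant to relabeling any view's cluster ids, which is what
#' makes alignment-free integration of partitions valid.
#'
#' @param view_labels list of equal-length integer label vectors
#' @return spots x spots symmetric matrix with unit diagonal, entries in
#'   multiples of `1/length(view_labels)`
#' @export
consensus_matrix <- function(view_labels) {
  if (length(view_labels) < 1) mvc_validation_error("need >= 1 label vectors")
  n <- length(view_labels[[1]])
  if (!all(vapply(view_labels, length, 1L) == n))
    mvc_validation_error("label vectors differ in length")
  c_mat <- matrix(0, n, n)
  for (y in view_labels) c_mat <- c_mat + outer(y, y, "==")
  c_mat / length(view_labels)
}

#' Final labels by hierarchical clustering of the consensus matrix
#'
#' Agglomerative clustering with average linkage on the dissimilarity
#' `1 - C`, cut at `n_clusters`.  Deterministic; degenerate consensus
#' matrices (all ones) produce an arbitrary split with a warning.
#'
#' @param c_mat consensus matrix
#' @param n_clusters number of clusters to cut
#' @param linkage linkage method for [stats::hclust()]
#' @return integer label vector in `0..n_clusters-1`
#' @export
consensus_cluster <- function(c_mat, n_clusters, linkage = "average") {
  d <- stats::as.dist(1 - c_mat)
  if (all(d == 0))
    warning("consensus matrix is degenerate (all spots co-cluster everywhere)")
  hc <- stats::hclust(d, method = linkage)
  lab <- stats::cutree(hc, k = n_clusters)
  if (length(unique(lab)) < n_clusters)
    warning("hierarchical cut yielded fewer than n_clusters groups")
  canonicalize_labels(lab)
}

#' Cluster every view's embedding and merge by consensus
#'
#' Step 1 clusters each latent embedding with the Gaussian mixture model;
#' step 2 averages the co-clustering indicators into the consensus matrix;
#' step 3 cuts its average-linkage dendrogram at `n_clusters`.  With
#' `use_consensus = FALSE` the labels of the view with the best mixture
#' log-likelihood are returned instead (the no-consensus ablation).
#'
#' @param embeddings list of `view_embedding` objects (or bare matrices)
#' @param n_clusters number of domains
#' @param seed RNG seed for the per-view clusterers
#' @param restarts EM restarts per view
#' @param use_consensus merge views (default) or return the single
#'   best-likelihood view's labels
#' @param linkage linkage for the consensus cut
#' @return a `consensus_result` with `view_labels`, `consensus_matrix`,
#'   `final_labels`, `n_views`, `n_clusters`
#' @export
run_consensus <- function(embeddings, n_clusters, seed = 0, restarts = 10,
                          use_consensus = TRUE, linkage = "average") {
  if (length(embeddings) < 1) mvc_validation_error("need >= 1 embeddings")
  zs <- lapply(embeddings, function(e)
    if (inherits(e, "view_embedding")) e$z else as.matrix(e))
  ids <- vapply(seq_along(embeddings), function(i) {
    e <- embeddings[[i]]
    if (inherits(e, "view_embedding")) e$view_id %||% paste0("view", i)
    else names(embeddings)[i] %||% paste0("view", i)
  }, character(1))
  fits <- lapply(zs, fit_gmm, k = n_clusters, seed = seed, restarts = restarts)
  view_labels <- stats::setNames(lapply(fits, `[[`, "labels"), ids)
  c_mat <- consensus_matrix(view_labels)
  final <- if (use_consensus) {
    consensus_cluster(c_mat, n_clusters, linkage)
  } else {
    best <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
    canonicalize_labels(view_labels[[best]])
  }
  structure(list(view_labels = view_labels, consensus_matrix = c_mat,
                 final_labels = final, n_views = length(embeddings),
                 n_clusters = n_clusters,
                 view_logliks = vapply(fits, `[[`, numeric(1), "loglik")),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d views, %d spots, %d clusters\n",
              x$n_views, length(x$final_labels), x$n_clusters))
  invisible(x)
}
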