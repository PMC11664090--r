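#' Spot-adjacency "views"
#'
#' A view is one binary symmetric spot x spot adjacency matrix with zero
#' diagonal, built either from spatial coordinates (fixed radius or k
#' nearest neighbors) or from expression similarity (Spearman or cosine).
#' The spatial searches are exact, so the ball-tree and kd-tree backends
#' return identical neighbor sets; `backend` is recorded as construction
#' metadata.
#'
#' @name view_graphs
NULL

new_view_graph <- function(adjacency, method, backend, param, view_id) {
  dimnames(adjacency) <- NULL
  structure(list(adjacency = adjacency, method = method, backend = backend,
                 param = param, view_id = view_id),
            class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat(sprintf("view_graph '%s': %s (%s), param=%s, %d spots, %d edges\n",
              x$view_id, x$method, x$backend, format(x$param),
              nrow(x$adjacency), sum(x$adjacency) / 2))
  invisible(x)
}

pairwise_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Build a fixed-radius spatial graph
#'
#' Spots i and j are connected iff `0 < d(i,j) < r` (strict inequality).
#'
#' @param coords spots x 2 coordinate matrix
#' @param r positive radius
#' @param backend `"balltree"` or `"kdtree"`; exact search either way,
#'   recorded as metadata
#' @return a `view_graph`
#' @export
build_radius_graph <- function(coords, r, backend = c("balltree", "kdtree")) {
  backend <- match.arg(backend)
  if (!is.numeric(r) || r <= 0) mvc_validation_error("r must be positive")
  d <- pairwise_dist(coords)
  a <- (d < r) * 1
  diag(a) <- 0
  if (sum(a) == 0) warning("radius graph has no edges; r may be too small")
  new_view_graph(a, "radius", backend, r,
                 paste0("radius_", substr(backend, 1, 4)))
}

#' k nearest neighbors of every row of a distance/similarity matrix
#'
#' For distances the k smallest are taken; ties at the boundary are broken
#' by lower spot index, so results are deterministic across platforms.
#' @noRd
knn_select <- function(score, k, largest = FALSE) {
  n <- nrow(score)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    s <- score[i, ]
    s[i] <- if (largest) -Inf else Inf
    ord <- order(if (largest) -s else s, seq_len(n))
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

or_symmetrize <- function(idx, n) {
  a <- matrix(0, n, n)
  for (i in seq_len(nrow(idx))) a[i, idx[i, ]] <- 1
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

#' Build a k-nearest-neighbor spatial graph
#'
#' Directed kNN (self excluded) symmetrized by OR: an edge exists if either
#' endpoint selects the other.  Distance ties at the k-boundary are broken
#' by lower spot index.
#'
#' @param coords spots x 2 coordinate matrix
#' @param k neighbors per spot, `1 <= k < n`
#' @param backend `"balltree"` or `"kdtree"` (metadata; search is exact)
#' @return a `view_graph`
#' @export
build_knn_graph <- function(coords, k, backend = c("balltree", "kdtree")) {
  backend <- match.arg(backend)
  n <- nrow(coords)
  if (k < 1 || k >= n) mvc_validation_error("need 1 <= k < number of spots")
  d <- pairwise_dist(coords)
  idx <- knn_select(d, k, largest = FALSE)
  new_view_graph(or_symmetrize(idx, n), "knn", backend, k,
                 paste0("knn_", substr(backend, 1, 4)))
}

#' Spearman rank correlation between all spot pairs
#'
#' Each spot's feature vector is rank-transformed (average ranks on ties)
#' and the Pearson correlation of rank vectors is computed — the classical
#' rank correlation, equal to `1 - 6*sum(d_i^2)/(n(n^2-1))` when there are
#' no ties (n = number of features).  Constant spots get correlation -Inf
#' so they are never selected as neighbors.
#'
#' @param x spots x features matrix
#' @return spots x spots correlation matrix
#' @export
spearman_similarity <- function(x) {
  if (ncol(x) < 2) mvc_validation_error("need >= 2 feature columns")
  r <- t(apply(x, 1, rank))            # average ranks on ties
  rc <- r - rowMeans(r)
  ss <- sqrt(rowSums(rc^2))
  const <- ss == 0
  if (any(const)) {
    warning(sprintf("%d constant spot vectors; their correlations set to -Inf",
                    sum(const)))
    ss[const] <- 1
  }
  s <- (rc %*% t(rc)) / outer(ss, ss)
  s[const, ] <- -Inf
  s[, const] <- -Inf
  s
}

#' Cosine similarity between all spot pairs
#'
#' @param x spots x features matrix
#' @return spots x spots similarity matrix; zero-norm spots get similarity
#'   0 with a warning
#' @export
cosine_similarity <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d zero-norm spot vectors; similarity set to 0", sum(zero)))
    nrm[zero] <- 1
  }
  s <- (x %*% t(x)) / outer(nrm, nrm)
  s[zero, ] <- 0
  s[, zero] <- 0
  s
}

build_similarity_graph <- function(x, k, method, simfun) {
  n <- nrow(x)
  if (k < 1 || k >= n) mvc_validation_error("need 1 <= k < number of spots")
  s <- simfun(x)
  idx <- knn_select(s, k, largest = TRUE)
  new_view_graph(or_symmetrize(idx, n), method, "none", k, method)
}

#' Build an expression-similarity graph using Spearman correlation
#'
#' For each spot the k spots with the largest rank correlation become its
#' neighbors; the directed graph is OR-symmetrized.  Ties break by lower
#' spot index.
#'
#' @param x spots x features matrix (augmented expression)
#' @param k neighbors per spot
#' @return a `view_graph`
#' @export
build_spearman_graph <- function(x, k) {
  build_similarity_graph(x, k, "spearman", spearman_similarity)
}

#' Build an expression-similarity graph using cosine similarity
#'
#' @inheritParams build_spearman_graph
#' @return a `view_graph`
#' @export
build_cosine_graph <- function(x, k) {
  build_similarity_graph(x, k, "cosine", cosine_similarity)
}

#' Symmetrically normalize an adjacency matrix with self-loops
#'
#' Computes `A_hat = A + I`, degrees `D = rowSums(A_hat)` and the
#' propagation matrix `D^{-1/2} A_hat D^{-1/2}` used by every graph
#' convolution in the model.  Self-loops guarantee positive degrees.
#'
#' @param g a `view_graph` (or a bare binary adjacency matrix)
#' @return a `normalized_graph` with fields `a_hat`, `degree`, `norm`
#' @export
normalize_adjacency <- function(g) {
  a <- if (inherits(g, "view_graph")) g$adjacency else as.matrix(g)
  a_hat <- a + diag(nrow(a))
  deg <- rowSums(a_hat)
  inv_sqrt <- 1 / sqrt(deg)
  nrm <- a_hat * outer(inv_sqrt, inv_sqrt)
  structure(list(a_hat = a_hat, degree = deg, norm = nrm,
                 adjacency = a,
                 view_id = if (inherits(g, "view_graph")) g$view_id else "graph"),
            class = "normalized_graph")
}

#' Default radius: 1.5 x the median nearest-neighbor distance
#'
#' On a unit-spacing hexagonal lattice this reproduces the six-neighbor
#' Visium structure.
#'
#' @param coords spots x 2 coordinate matrix
#' @return radius value
#' @export
default_radius <- function(coords) {
  d <- pairwise_dist(coords)
  diag(d) <- Inf
  1.5 * stats::median(apply(d, 1, min))
}

#' Build a named list of views from view specifications
#'
#' @param ds an [st_dataset] (coordinates for spatial views)
#' @param x spots x features matrix for expression views (augmented
#'   expression); defaults to `ds$expression`
#' @param specs list of specs, each `list(method=, backend=, param=)`;
#'   method one of radius/knn/spearman/cosine.  `param = NULL` uses the
#'   default (radius from [default_radius()], k = 6)
#' @return named list of `view_graph` objects
#' @export
build_views <- function(ds, specs = default_view_specs(), x = NULL) {
  if (length(specs) == 0) mvc_validation_error("need at least one view spec")
  if (is.null(x)) x <- ds$expression
  lapply(stats::setNames(specs, vapply(specs, view_spec_id, character(1))),
         function(sp) {
           method <- sp$method
           if (method == "radius") {
             r <- sp$param %||% default_radius(ds$coords)
             build_radius_graph(ds$coords, r, sp$backend %||% "balltree")
           } else if (method == "knn") {
             build_knn_graph(ds$coords, sp$param %||% 6L,
                             sp$backend %||% "balltree")
           } else if (method == "spearman") {
             build_spearman_graph(x, sp$param %||% 6L)
           } else if (method == "cosine") {
             build_cosine_graph(x, sp$param %||% 6L)
           } else {
             mvc_config_error(sprintf("unknown view method '%s'", method))
           }
         })
}

view_spec_id <- function(sp) {
  if (sp$method %in% c("radius", "knn"))
    paste0(sp$method, "_", substr(sp$backend %||% "balltree", 1, 4))
  else sp$method
}

#' The default view set: radius ball-tree + kNN ball-tree + kNN kd-tree
#'
#' The three-view spatial combination that performs best in practice.
#' @return list of view specs
#' @export
default_view_specs <- function() {
  list(list(method = "radius", backend = "balltree", param = NULL),
       list(method = "knn", backend = "balltree", param = NULL),
       list(method = "knn", backend = "kdtree", param = NULL))
}

#' Export a view graph as an edge-list TSV
#'
#' @param g a `view_graph`
#' @param path output TSV path
#' @return invisibly, the number of edges written
#' @export
write_edge_list <- function(g, path) {
  e <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
  utils::write.table(data.frame(from = e[, 1], to = e[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(e))
}
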