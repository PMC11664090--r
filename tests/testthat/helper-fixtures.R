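# Shared fixtures and independent oracles used across test files.

# Small synthetic dataset, fast to regenerate.
tiny_dataset <- function(seed = 0, k = 3, n_rows = 12, n_cols = 12,
                         n_genes = 60, ...) {
  simulate_dataset(sim_config(n_rows = n_rows, n_cols = n_cols,
                              n_genes = n_genes, k_domains = k,
                              markers_per_domain = min(6L, n_genes %/% k),
                              seed = seed, ...))
}

# A fast model configuration for unit tests.
tiny_model <- function(seed = 0, ...) {
  args <- utils::modifyList(
    list(fc_dims = c(24, 12), gcn_hidden = 12, latent_dim = 6,
         pretrain_epochs = 30, train_epochs = 30, dec_interval = 10,
         seed = seed),
    list(...))
  do.call(model_config, args)
}

# ---- independent oracles (deliberately different algorithms) ---------------

# O(n^2) pair-counting Rand index adjustment, no contingency-table formula.
oracle_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) c <- c + 1
      else d <- d + 1
    }
  }
  ri_exp <- (a + b) * (a + c) / (a + b + c + d)
  ri_max <- ((a + b) + (a + c)) / 2
  if (ri_max == ri_exp) return(1)
  (a - ri_exp) / (ri_max - ri_exp)
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

oracle_joint_entropy <- function(x, y) {
  p <- table(paste(x, y)) / length(x)
  -sum(p * log(p))
}

oracle_nmi <- function(truth, pred) {
  ht <- oracle_entropy(truth); hp <- oracle_entropy(pred)
  if (ht == 0 || hp == 0) return(0)
  mi <- ht + hp - oracle_joint_entropy(truth, pred)
  mi / ((ht + hp) / 2)
}

oracle_hs <- function(truth, pred) {
  ht <- oracle_entropy(truth)
  if (ht == 0) return(1)
  htp <- oracle_joint_entropy(truth, pred) - oracle_entropy(pred)
  1 - htp / ht
}

oracle_purity <- function(truth, pred) {
  total <- 0
  for (cl in unique(pred)) {
    total <- total + max(table(truth[pred == cl]))
  }
  total / length(truth)
}

# Brute-force neighbor graphs.
oracle_radius_graph <- function(coords, r) {
  n <- nrow(coords)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < r) a[i, j] <- 1
  }
  a
}

oracle_knn_graph <- function(coords, k) {
  n <- nrow(coords)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    a[i, nb] <- 1
  }
  a <- pmax(a, t(a))
  diag(a) <- 0
  a
}

# Brute-force consensus matrix (direct triple loop over views and pairs).
oracle_consensus <- function(view_labels) {
  n <- length(view_labels[[1]])
  c_mat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    agree <- 0
    for (y in view_labels) if (y[i] == y[j]) agree <- agree + 1
    c_mat[i, j] <- agree / length(view_labels)
  }
  c_mat
}

random_partition <- function(n, k) sample.int(k, n, replace = TRUE) - 1L
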