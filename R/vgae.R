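#' Model configuration for the per-view variational graph auto-encoder
#'
#' Architecture: a fully connected stack (`fc_dims`) maps the augmented
#' expression to `Zf`; one graph convolution (width `gcn_hidden`) yields
#' `Zg`; two sibling graph convolutions produce the posterior mean and
#' log-variance (width `latent_dim`) — they act on the same `Zg`, i.e.
#' share the first-layer weights but have distinct second-layer weights.
#' An inner-product decoder reconstructs the adjacency and a mirror linear
#' stack reconstructs the features.  Training is two-phase: plain VGAE
#' pretraining, then joint training with the deep-embedded-clustering head.
#'
#' @param fc_dims widths of the linear stack producing `Zf`
#' @param gcn_hidden width of the first graph convolution
#' @param latent_dim latent width (posterior mean / log-variance)
#' @param dropout kept for interface compatibility (unused at desk scale)
#' @param lr Adam learning rate
#' @param weight_decay L2 penalty added to weight-matrix gradients
#' @param pretrain_epochs phase-1 epochs (no self-supervision)
#' @param train_epochs phase-2 epochs (full loss)
#' @param dec_interval epochs between target-distribution refreshes
#' @param lambda1,lambda2,lambda3,lambda4 loss weights: adjacency MSE,
#'   feature MSE, variational term (balanced cross-entropy + Gaussian KL),
#'   clustering KL
#' @param seed RNG seed; training is deterministic given the seed
#' @param conv_type only `"gcn"` (symmetric-normalized graph convolution);
#'   attention variants are an extension point
#' @param activation only `"relu"`
#' @return a `model_config` list
#' @export
model_config <- function(fc_dims = c(1000, 500, 30), gcn_hidden = 64,
                         latent_dim = 8, dropout = 0, lr = 1e-3,
                         weight_decay = 1e-4, pretrain_epochs = 200,
                         train_epochs = 200, dec_interval = 20,
                         lambda1 = 1, lambda2 = 1, lambda3 = 1,
                         lambda4 = 0.1, seed = 0, conv_type = "gcn",
                         activation = "relu") {
  conv_type <- match.arg(conv_type, "gcn")
  activation <- match.arg(activation, "relu")
  lam <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(lam < 0)) mvc_validation_error("loss weights must be >= 0")
  if (all(lam == 0)) mvc_validation_error("at least one loss weight must be > 0")
  if (latent_dim < 2) mvc_validation_error("latent_dim must be >= 2")
  structure(list(fc_dims = as.integer(fc_dims), gcn_hidden = as.integer(gcn_hidden),
                 latent_dim = as.integer(latent_dim), dropout = dropout, lr = lr,
                 weight_decay = weight_decay,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 train_epochs = as.integer(train_epochs),
                 dec_interval = as.integer(dec_interval),
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, seed = as.integer(seed),
                 conv_type = conv_type, activation = activation),
            class = "model_config")
}

#' Initialize VGAE parameters (Glorot uniform, zero biases)
#'
#' @param n_features input feature count
#' @param cfg a [model_config()]
#' @return nested parameter list
#' @export
vgae_init <- function(n_features, cfg) {
  dims <- c(n_features, cfg$fc_dims)
  fc <- lapply(seq_len(length(dims) - 1),
               function(i) linear_init(dims[i], dims[i + 1]))
  dec_dims <- c(cfg$latent_dim, rev(cfg$fc_dims), n_features)
  dec <- lapply(seq_len(length(dec_dims) - 1),
                function(i) linear_init(dec_dims[i], dec_dims[i + 1]))
  list(fc = fc,
       gcn1 = list(W = glorot(utils::tail(dims, 1), cfg$gcn_hidden)),
       gcn_mu = list(W = glorot(cfg$gcn_hidden, cfg$latent_dim)),
       gcn_sig = list(W = glorot(cfg$gcn_hidden, cfg$latent_dim)),
       dec = dec)
}

#' Encode features on a graph into a Gaussian posterior
#'
#' @param x spots x features matrix
#' @param g a `normalized_graph` (see [normalize_adjacency()])
#' @param params parameters from [vgae_init()]
#' @return list with `mu`, `logvar` (spots x latent) and the forward cache
#' @export
encode <- function(x, g, params) {
  s <- g$norm
  h <- x
  fc_cache <- vector("list", length(params$fc))
  for (i in seq_along(params$fc)) {
    fc_cache[[i]] <- dense_forward(h, params$fc[[i]])
    h <- fc_cache[[i]]$out
  }
  zf <- h
  p1 <- s %*% (zf %*% params$gcn1$W)
  zg <- relu(p1)
  szg <- s %*% zg
  mu <- szg %*% params$gcn_mu$W
  logvar <- szg %*% params$gcn_sig$W
  if (!all(is.finite(mu)) || !all(is.finite(logvar)))
    mvc_training_error("non-finite activations in encoder")
  list(mu = mu, logvar = logvar,
       cache = list(fc = fc_cache, zf = zf, p1 = p1, zg = zg, szg = szg))
}

#' Reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * noise`.  With `noise = NULL` (evaluation
#' mode) returns `mu`.
#'
#' @param mu,logvar posterior parameters
#' @param noise standard-normal matrix of the same shape, or NULL
#' @return latent matrix `z`
#' @export
reparameterize <- function(mu, logvar, noise = NULL) {
  if (is.null(noise)) return(mu)
  stopifnot(all(dim(mu) == dim(noise)), all(dim(mu) == dim(logvar)))
  mu + exp(0.5 * logvar) * noise
}

#' Inner-product decoder: edge probabilities from latent positions
#'
#' @param z spots x latent matrix
#' @return spots x spots matrix `sigmoid(z z^T)`
#' @export
decode_adjacency <- function(z) {
  1 / (1 + exp(-(z %*% t(z))))
}

decoder_forward <- function(z, params) {
  h <- z
  L <- length(params$dec)
  cache <- vector("list", L)
  for (i in seq_len(L)) {
    cache[[i]] <- dense_forward(h, params$dec[[i]], activation = i < L)
    h <- cache[[i]]$out
  }
  list(x_recon = h, cache = cache)
}

#' Reconstruct features from the latent space
#'
#' Mirror linear stack, ReLU on hidden layers, linear output.
#'
#' @param z spots x latent matrix
#' @param params parameters from [vgae_init()]
#' @return spots x features reconstruction
#' @export
decode_features <- function(z, params) {
  decoder_forward(z, params)$x_recon
}

#' VGAE loss terms
#'
#' * `l_a`: mean squared error between the binary adjacency (self-loops
#'   excluded) and the decoded edge probabilities, edges re-weighted by the
#'   non-edge/edge ratio so sparse graphs do not collapse to "no edge".
#' * `l_x`: mean squared error of the feature reconstruction.
#' * `l_kl`: the negated evidence lower bound — balanced binary
#'   cross-entropy of the decoded adjacency plus the Gaussian KL
#'   `-mean(1 + logvar - mu^2 - exp(logvar)) / 2` (always >= 0).
#'
#' @param x input features
#' @param g `normalized_graph`
#' @param mu,logvar posterior parameters
#' @param z latent sample
#' @param x_recon feature reconstruction
#' @param a_recon optional precomputed `decode_adjacency(z)`
#' @return list with `l_a`, `l_x`, `l_kl`, plus components `l_bce`,
#'   `l_gauss`
#' @export
loss_terms <- function(x, g, mu, logvar, z, x_recon, a_recon = NULL) {
  a0 <- g$adjacency
  n <- nrow(a0)
  mask <- 1 - diag(n)
  n_off <- n * n - n
  n_edge <- sum(a0)
  pw <- if (n_edge > 0) (n_off - n_edge) / n_edge else 1
  if (is.null(a_recon)) a_recon <- decode_adjacency(z)
  w <- mask * (1 + (pw - 1) * a0)
  l_a <- sum(w * (a0 - a_recon)^2) / n_off
  l_x <- mean((x - x_recon)^2)
  eps <- 1e-12
  bce <- sum(mask * (pw * a0 * -log(a_recon + eps) +
                     (1 - a0) * -log(1 - a_recon + eps))) / n_off
  l_gauss <- -0.5 * mean(1 + logvar - mu^2 - exp(logvar))
  list(l_a = l_a, l_x = l_x, l_kl = bce + l_gauss,
       l_bce = bce, l_gauss = l_gauss)
}

# ---- deep-embedded-clustering head -----------------------------------------

#' Student-t soft cluster assignment
#'
#' `q_ij` is the degree-1 Student-t kernel between spot i's latent vector
#' and center j, normalized over centers; rows sum to 1.
#'
#' @param z spots x latent matrix
#' @param centers clusters x latent matrix
#' @return spots x clusters soft assignment
#' @export
dec_soft_assign <- function(z, centers) {
  k <- dec_kernel(z, centers)
  k / rowSums(k)
}

dec_kernel <- function(z, centers) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(z)), rowSums(centers^2)) - 2 * z %*% t(centers)
  1 / (1 + pmax(d2, 0))
}

#' DEC target distribution
#'
#' Squares the soft assignment and renormalizes by cluster frequency,
#' emphasizing high-confidence assignments.  Empty clusters (zero
#' frequency) contribute zero columns with a warning.
#'
#' @param q spots x clusters soft assignment (rows sum to 1)
#' @return spots x clusters target distribution
#' @export
dec_target_distribution <- function(q) {
  f <- colSums(q)
  if (any(f == 0)) {
    warning("empty cluster in target distribution")
    f[f == 0] <- Inf                   # q^2/f -> 0 for empty clusters
  }
  w <- sweep(q^2, 2, f, "/")
  w / rowSums(w)
}

#' Clustering KL divergence between target and soft assignment
#'
#' `sum_i sum_j p_ij log(p_ij / q_ij)` with `0 log 0 = 0`; zero q where
#' p > 0 is clamped by a small epsilon with a warning.
#'
#' @param p target distribution
#' @param q soft assignment
#' @return non-negative scalar
#' @export
dec_loss <- function(p, q) {
  stopifnot(all(dim(p) == dim(q)))
  if (any(q == 0 & p > 0)) {
    warning("q contains zeros where p > 0; clamping")
    q <- pmax(q, 1e-12)
  }
  terms <- p * (log(p + (p == 0)) - log(q))
  sum(terms[p > 0])
}

#' Initialize DEC centers from a clustering of the latent space
#'
#' @param z spots x latent matrix (noise-free embedding)
#' @param n_clusters number of clusters
#' @param seed RNG seed for the mixture-model clusterer
#' @param restarts EM restarts
#' @return list with `centers` (clusters x latent), `labels`, `n_clusters`
#' @export
init_centers <- function(z, n_clusters, seed = 0, restarts = 10) {
  labels <- cluster_embedding(z, n_clusters, seed = seed, restarts = restarts)
  grp <- split(seq_len(nrow(z)), labels)
  if (length(grp) < n_clusters) {
    labels <- cluster_embedding(z, n_clusters, seed = seed + 1000L,
                                restarts = restarts)
    grp <- split(seq_len(nrow(z)), labels)
    if (length(grp) < n_clusters)
      mvc_training_error("clusterer produced fewer groups than n_clusters")
  }
  centers <- t(vapply(grp, function(i) colMeans(z[i, , drop = FALSE]),
                      numeric(ncol(z))))
  list(centers = centers, labels = labels, n_clusters = n_clusters)
}

# ---- backward pass ----------------------------------------------------------

#' @noRd
# Full backward pass for one epoch.  Returns parameter gradients (same
# structure as params) plus the gradient for DEC centers if active.
vgae_backward <- function(x, g, params, enc, z, dec_fwd, noise, cfg,
                          a_recon, dec_state = NULL) {
  a0 <- g$adjacency
  s <- g$norm
  n <- nrow(a0)
  mask <- 1 - diag(n)
  n_off <- n * n - n
  n_edge <- sum(a0)
  pw <- if (n_edge > 0) (n_off - n_edge) / n_edge else 1
  w <- mask * (1 + (pw - 1) * a0)
  eps <- 1e-12

  # gradient wrt the inner-product logits (two adjacency-fit terms)
  g_logit <- cfg$lambda1 * (2 * w * (a_recon - a0) * a_recon * (1 - a_recon)) / n_off
  # balanced BCE: d/dlogit = sigma*(weight for 0-class) - pw*a0*(1-sigma)
  g_logit <- g_logit + cfg$lambda3 *
    (mask * (pw * a0 * (a_recon - 1) + (1 - a0) * a_recon)) / n_off
  dz <- (g_logit + t(g_logit)) %*% z

  # feature-reconstruction path through the mirror stack
  grads_dec <- vector("list", length(params$dec))
  dout <- cfg$lambda2 * 2 * (dec_fwd$x_recon - x) / length(x)
  for (i in rev(seq_along(params$dec))) {
    bk <- dense_backward(dout, params$dec[[i]], dec_fwd$cache[[i]])
    grads_dec[[i]] <- list(W = bk$W, b = bk$b)
    dout <- bk$dx
  }
  dz <- dz + dout

  grad_centers <- NULL
  if (!is.null(dec_state) && cfg$lambda4 > 0) {
    k <- dec_kernel(z, dec_state$centers)
    q <- k / rowSums(k)
    pq <- k * (dec_state$p - q)
    # d/dz_i sum p log(p/q) = 2 sum_j k_ij (p_ij - q_ij)(z_i - mu_j)
    dz_dec <- 2 * (rowSums(pq) * z - pq %*% dec_state$centers)
    dz <- dz + cfg$lambda4 * dz_dec
    # centers gradient: -2 sum_i k_ij (p_ij - q_ij)(z_i - mu_j)
    grad_centers <- cfg$lambda4 *
      -2 * (t(pq) %*% z - colSums(pq) * dec_state$centers)
  }

  # z -> mu, logvar
  dmu <- dz
  dlv <- matrix(0, n, cfg$latent_dim)
  if (!is.null(noise)) dlv <- dz * noise * 0.5 * exp(0.5 * enc$logvar)
  # Gaussian KL term
  nl <- n * cfg$latent_dim
  dmu <- dmu + cfg$lambda3 * enc$mu / nl
  dlv <- dlv + cfg$lambda3 * 0.5 * (exp(enc$logvar) - 1) / nl

  cache <- enc$cache
  s_dmu <- s %*% dmu
  s_dlv <- s %*% dlv
  g_mu <- list(W = crossprod(cache$zg, s_dmu))
  g_sig <- list(W = crossprod(cache$zg, s_dlv))
  dzg <- s_dmu %*% t(params$gcn_mu$W) + s_dlv %*% t(params$gcn_sig$W)
  dp1 <- dzg * (cache$p1 > 0)
  s_dp1 <- s %*% dp1
  g_gcn1 <- list(W = crossprod(cache$zf, s_dp1))
  dzf <- s_dp1 %*% t(params$gcn1$W)

  grads_fc <- vector("list", length(params$fc))
  dout <- dzf
  for (i in rev(seq_along(params$fc))) {
    bk <- dense_backward(dout, params$fc[[i]], cache$fc[[i]])
    grads_fc[[i]] <- list(W = bk$W, b = bk$b)
    dout <- bk$dx
  }

  list(grads = list(fc = grads_fc, gcn1 = g_gcn1, gcn_mu = g_mu,
                    gcn_sig = g_sig, dec = grads_dec),
       grad_centers = grad_centers)
}

#' Train one view's variational graph auto-encoder
#'
#' Phase 1 (`pretrain_epochs`) minimizes the three reconstruction /
#' variational terms; the self-supervised head is intentionally omitted.
#' Phase 2 initializes cluster centers from a Gaussian-mixture clustering
#' of the noise-free embedding, then minimizes the full weighted loss,
#' refreshing the target distribution every `dec_interval` epochs.  The
#' soft assignment is computed from the sampled latent during training and
#' from the posterior mean at evaluation.
#'
#' @param x spots x features input (augmented expression)
#' @param g a `normalized_graph`
#' @param n_clusters number of domains (used by the clustering head)
#' @param cfg a [model_config()]
#' @param verbose log phase transitions
#' @return a `view_embedding`: `z` (= posterior mean, noise-free), `mu`,
#'   `logvar`, `x_recon`, `history` (per-epoch loss terms), `view_id`
#' @export
train_view <- function(x, g, n_clusters, cfg = model_config(),
                       verbose = FALSE) {
  stopifnot(inherits(g, "normalized_graph"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (nrow(g$norm) != n) mvc_validation_error("x and graph disagree on spots")
  set.seed(cfg$seed)
  params <- vgae_init(ncol(x), cfg)
  opt <- adam_init(params)
  dec_state <- NULL
  centers_opt <- NULL
  total_epochs <- cfg$pretrain_epochs + cfg$train_epochs
  hist <- vector("list", total_epochs)
  use_dec <- cfg$lambda4 > 0 && cfg$train_epochs > 0

  for (epoch in seq_len(total_epochs)) {
    phase <- if (epoch <= cfg$pretrain_epochs) 1L else 2L
    if (use_dec && epoch == cfg$pretrain_epochs + 1L) {
      enc0 <- encode(x, g, params)
      init <- init_centers(enc0$mu, n_clusters, seed = cfg$seed)
      q0 <- dec_soft_assign(enc0$mu, init$centers)
      dec_state <- list(centers = init$centers, p = dec_target_distribution(q0))
      centers_opt <- adam_init(list(centers = init$centers))
      mvc_log(sprintf("view %s: DEC centers initialized", g$view_id),
              verbose = verbose)
    }
    noise <- matrix(stats::rnorm(n * cfg$latent_dim), n, cfg$latent_dim)
    enc <- encode(x, g, params)
    z <- reparameterize(enc$mu, enc$logvar, noise)
    dec_fwd <- decoder_forward(z, params)
    a_recon <- decode_adjacency(z)
    lt <- loss_terms(x, g, enc$mu, enc$logvar, z, dec_fwd$x_recon, a_recon)
    l_dec <- 0
    if (phase == 2L && use_dec) {
      if ((epoch - cfg$pretrain_epochs - 1L) %% cfg$dec_interval == 0L) {
        q_nf <- dec_soft_assign(z, dec_state$centers)
        dec_state$p <- dec_target_distribution(q_nf)
      }
      q <- dec_soft_assign(z, dec_state$centers)
      l_dec <- dec_loss(dec_state$p, q)
    }
    total <- cfg$lambda1 * lt$l_a + cfg$lambda2 * lt$l_x +
      cfg$lambda3 * lt$l_kl + cfg$lambda4 * l_dec
    if (!is.finite(total) || total > 1e6)
      mvc_training_error(paste0("training diverged at epoch ", epoch,
                                " (loss = ", format(total), ")"))
    hist[[epoch]] <- data.frame(epoch = epoch, phase = phase,
                                l_a = lt$l_a, l_x = lt$l_x, l_kl = lt$l_kl,
                                l_dec = l_dec, total = total)
    bk <- vgae_backward(x, g, params, enc, z, dec_fwd, noise, cfg, a_recon,
                        if (phase == 2L && use_dec) dec_state else NULL)
    st <- adam_step(params, bk$grads, opt, lr = cfg$lr,
                    weight_decay = cfg$weight_decay)
    params <- st$params
    opt <- st$state
    if (!is.null(bk$grad_centers)) {
      cs <- adam_step(list(centers = dec_state$centers),
                      list(centers = bk$grad_centers), centers_opt,
                      lr = cfg$lr)
      dec_state$centers <- cs$params$centers
      centers_opt <- cs$state
    }
  }

  enc <- encode(x, g, params)
  x_recon <- decode_features(enc$mu, params)
  structure(list(z = enc$mu, mu = enc$mu, logvar = enc$logvar,
                 x_recon = x_recon, history = do.call(rbind, hist),
                 view_id = g$view_id, params = params,
                 dec_centers = dec_state$centers),
            class = "view_embedding")
}

#' @export
print.view_embedding <- function(x, ...) {
  cat(sprintf("view_embedding '%s': %d spots x %d latent, %d epochs\n",
              x$view_id, nrow(x$z), ncol(x$z), nrow(x$history)))
  invisible(x)
}
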