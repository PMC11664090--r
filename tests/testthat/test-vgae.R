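small_graph <- function(n = 10, seed = 20) {
  set.seed(seed)
  normalize_adjacency(build_knn_graph(matrix(runif(n * 2), n, 2), 2))
}

test_that("encoder respects shapes, zero inputs and permutation equivariance", {
  cfg <- model_config(fc_dims = c(6, 5), gcn_hidden = 4, latent_dim = 3)
  g <- small_graph(10)
  set.seed(1)
  params <- spatialmvc:::vgae_init(7, cfg)
  x <- matrix(rnorm(70), 10, 7)
  enc <- encode(x, g, params)
  expect_equal(dim(enc$mu), c(10L, 3L))
  expect_equal(dim(enc$logvar), c(10L, 3L))

  # zero input with zero biases -> zero posterior
  enc0 <- encode(x * 0, g, params)
  expect_equal(enc0$mu, matrix(0, 10, 3))
  expect_equal(enc0$logvar, matrix(0, 10, 3))

  # permuting spots together with the graph permutes mu rows identically
  perm <- sample(10)
  gp <- g
  gp$norm <- g$norm[perm, perm]
  encp <- encode(x[perm, ], gp, params)
  expect_equal(encp$mu, enc$mu[perm, ], tolerance = 1e-12)
})

test_that("reparameterization matches its closed form", {
  mu <- matrix(1:6 / 3, 2, 3)
  lv <- matrix(0, 2, 3)
  expect_identical(reparameterize(mu, lv, NULL), mu)
  eps <- matrix(rnorm(6), 2, 3)
  expect_equal(reparameterize(mu, lv, eps), mu + eps)

  # empirical std at logvar = ln 4 is 2
  set.seed(2)
  n <- 1e5
  z <- reparameterize(matrix(0, n, 1), matrix(log(4), n, 1),
                      matrix(rnorm(n), n, 1))
  expect_equal(sd(z), 2, tolerance = 0.02)
})

test_that("inner-product decoder is a symmetric sigmoid", {
  expect_equal(decode_adjacency(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  z <- matrix(c(2, -2), 2, 1)
  a <- decode_adjacency(z)
  expect_equal(a[1, 2], 1 / (1 + exp(4)), tolerance = 1e-12)
  set.seed(3)
  z2 <- matrix(rnorm(12), 4, 3)
  a2 <- decode_adjacency(z2)
  expect_lt(max(abs(a2 - t(a2))), 1e-12)
  expect_true(all(a2 > 0 & a2 < 1))
})

test_that("loss terms match scalar hand-arithmetic on a 3-node toy", {
  # A has the single edge 1-2; z fixed
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
  g <- normalize_adjacency(a)
  z <- matrix(c(1, 0.5, -1, 0, 1, 0.2), 3, 2)
  mu <- z; lv <- matrix(0.3, 3, 2)
  x <- matrix(1, 3, 4); xr <- matrix(0.5, 3, 4)
  ar <- decode_adjacency(z)
  lt <- loss_terms(x, g, mu, lv, z, xr, ar)

  sig <- function(t) 1 / (1 + exp(-t))
  s12 <- sig(sum(z[1, ] * z[2, ])); s13 <- sig(sum(z[1, ] * z[3, ]))
  s23 <- sig(sum(z[2, ] * z[3, ]))
  pw <- (6 - 2) / 2                      # 4 non-edges / 2 edges
  l_a_hand <- (2 * pw * (1 - s12)^2 + 2 * (0 - s13)^2 + 2 * (0 - s23)^2) / 6
  expect_equal(lt$l_a, l_a_hand, tolerance = 1e-12)
  expect_equal(lt$l_x, 0.25, tolerance = 1e-12)
  bce_hand <- (2 * pw * -log(s12 + 1e-12) + 2 * -log(1 - s13 + 1e-12) +
               2 * -log(1 - s23 + 1e-12)) / 6
  gauss_hand <- -0.5 * mean(1 + lv - mu^2 - exp(lv))
  expect_equal(lt$l_kl, bce_hand + gauss_hand, tolerance = 1e-12)

  # prior match: mu = 0, logvar = 0 -> Gaussian KL component 0
  lt0 <- loss_terms(x, g, mu * 0, lv * 0, z, x)
  expect_equal(lt0$l_gauss, 0)
  expect_equal(lt0$l_x, 0)
})

test_that("Gaussian KL component is non-negative everywhere", {
  set.seed(4)
  for (i in 1:20) {
    mu <- matrix(rnorm(12), 4, 3)
    lv <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_gte(-0.5 * mean(1 + lv - mu^2 - exp(lv)), 0)
  }
})

test_that("DEC soft assignment matches hand arithmetic", {
  centers <- matrix(c(-1, 1, 3), 3, 1)
  q <- dec_soft_assign(matrix(0, 1, 1), centers)
  expect_equal(as.vector(q), c(5 / 11, 5 / 11, 1 / 11), tolerance = 1e-12)

  # z exactly at a center -> that column is the row maximum
  q2 <- dec_soft_assign(matrix(c(3), 1, 1), centers)
  expect_equal(which.max(q2), 3L)

  # equidistant from all centers -> uniform
  ctr <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  q3 <- dec_soft_assign(matrix(0, 1, 2), ctr)
  expect_equal(as.vector(q3), rep(0.25, 4))
  expect_equal(rowSums(dec_soft_assign(matrix(rnorm(10), 5, 2), ctr)),
               rep(1, 5), tolerance = 1e-9)
})

test_that("DEC target distribution sharpens and handles edge cases", {
  q <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  p <- dec_target_distribution(q)
  # f = (1.2, 0.8); unnormalized row 1: (0.64/1.2, 0.04/0.8)
  u1 <- c(0.64 / 1.2, 0.04 / 0.8)
  u2 <- c(0.16 / 1.2, 0.36 / 0.8)
  expect_equal(p[1, ], u1 / sum(u1), tolerance = 1e-12)
  expect_equal(p[2, ], u2 / sum(u2), tolerance = 1e-12)

  onehot <- diag(3)
  expect_equal(dec_target_distribution(onehot), onehot)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(dec_target_distribution(unif), unif)

  # sharpening: mean row entropy of p never exceeds that of q
  rowent <- function(m) mean(apply(m, 1, function(r) {
    r <- r[r > 0]; -sum(r * log(r))
  }))
  set.seed(5)
  for (i in 1:20) {
    qq <- matrix(rexp(40), 10, 4)
    qq <- qq / rowSums(qq)
    expect_lte(rowent(dec_target_distribution(qq)), rowent(qq) + 1e-12)
  }
})

test_that("DEC loss is a KL divergence", {
  q <- matrix(1 / 4, 6, 4)
  expect_equal(dec_loss(q, q), 0)
  p_hard <- matrix(0, 6, 4); p_hard[cbind(1:6, rep(1:2, 3))] <- 1
  expect_equal(dec_loss(p_hard, q), 6 * log(4), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    p <- matrix(rexp(20), 5, 4); p <- p / rowSums(p)
    qq <- matrix(rexp(20), 5, 4); qq <- qq / rowSums(qq)
    expect_gte(dec_loss(p, qq), 0)
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(42)
  n <- 8; f <- 5; k <- 3
  x <- matrix(rnorm(n * f), n, f)
  g <- small_graph(n, seed = 42)
  cfg <- model_config(fc_dims = c(4), gcn_hidden = 4, latent_dim = 3,
                      lambda1 = 0.7, lambda2 = 1.3, lambda3 = 0.9,
                      lambda4 = 0.5, seed = 1)
  set.seed(1)
  params <- spatialmvc:::vgae_init(f, cfg)
  noise <- matrix(rnorm(n * 3), n, 3)
  centers <- matrix(rnorm(k * 3), k, 3)
  enc0 <- encode(x, g, params)
  z0 <- reparameterize(enc0$mu, enc0$logvar, noise)
  p <- dec_target_distribution(dec_soft_assign(z0, centers))
  lossfun <- function(params, centers) {
    enc <- encode(x, g, params)
    z <- reparameterize(enc$mu, enc$logvar, noise)
    lt <- loss_terms(x, g, enc$mu, enc$logvar, z, decode_features(z, params))
    q <- dec_soft_assign(z, centers)
    cfg$lambda1 * lt$l_a + cfg$lambda2 * lt$l_x + cfg$lambda3 * lt$l_kl +
      cfg$lambda4 * dec_loss(p, q)
  }
  enc <- encode(x, g, params)
  z <- reparameterize(enc$mu, enc$logvar, noise)
  dfw <- spatialmvc:::decoder_forward(z, params)
  bk <- spatialmvc:::vgae_backward(x, g, params, enc, z, dfw, noise, cfg,
                                   decode_adjacency(z),
                                   list(centers = centers, p = p))
  h <- 1e-6
  check_grad <- function(ana, get, set) {
    v <- get(params)
    idx <- seq_len(min(length(v), 12))
    gnum <- vapply(idx, function(i) {
      v1 <- v; v1[i] <- v1[i] + h
      v2 <- v; v2[i] <- v2[i] - h
      (lossfun(set(params, v1), centers) -
         lossfun(set(params, v2), centers)) / (2 * h)
    }, numeric(1))
    expect_equal(as.vector(ana)[idx], gnum, tolerance = 1e-5)
  }
  check_grad(bk$grads$fc[[1]]$W, function(p) p$fc[[1]]$W,
             function(p, v) { p$fc[[1]]$W[seq_along(v)] <- v; p })
  check_grad(bk$grads$gcn1$W, function(p) p$gcn1$W,
             function(p, v) { p$gcn1$W[seq_along(v)] <- v; p })
  check_grad(bk$grads$gcn_mu$W, function(p) p$gcn_mu$W,
             function(p, v) { p$gcn_mu$W[seq_along(v)] <- v; p })
  check_grad(bk$grads$gcn_sig$W, function(p) p$gcn_sig$W,
             function(p, v) { p$gcn_sig$W[seq_along(v)] <- v; p })
  check_grad(bk$grads$dec[[2]]$W, function(p) p$dec[[2]]$W,
             function(p, v) { p$dec[[2]]$W[seq_along(v)] <- v; p })
  # centers
  gc_num <- vapply(seq_along(centers), function(i) {
    c1 <- centers; c1[i] <- c1[i] + h
    c2 <- centers; c2[i] <- c2[i] - h
    (lossfun(params, c1) - lossfun(params, c2)) / (2 * h)
  }, numeric(1))
  expect_equal(as.vector(bk$grad_centers), gc_num, tolerance = 1e-5)
})

test_that("training is seed-deterministic, descends, and logs additively", {
  ds <- tiny_dataset(seed = 8)
  pp <- preprocess_dataset(ds, preprocess_config(min_cells = 3, n_hvg = 30))
  g <- normalize_adjacency(build_radius_graph(pp$coords, 1.5))
  cfg <- tiny_model(seed = 4)
  emb1 <- train_view(pp$expression, g, 3, cfg)
  emb2 <- train_view(pp$expression, g, 3, cfg)
  expect_identical(emb1$z, emb2$z)

  h <- emb1$history
  expect_true(all(is.finite(h$total)))
  expect_lt(mean(tail(h$total, 10)), mean(head(h$total, 10)))
  expect_true(all(h$l_dec >= 0))
  # logged total equals the weighted sum of the logged terms
  expect_equal(h$total,
               cfg$lambda1 * h$l_a + cfg$lambda2 * h$l_x +
                 cfg$lambda3 * h$l_kl + cfg$lambda4 * h$l_dec,
               tolerance = 1e-6)
  # evaluation embedding is the noise-free posterior mean
  expect_identical(emb1$z, emb1$mu)

  # lambda4 = 0 runs the no-self-supervision path (no DEC column activity)
  emb0 <- train_view(pp$expression, g, 3, tiny_model(seed = 4, lambda4 = 0))
  expect_true(all(emb0$history$l_dec == 0))
  expect_null(emb0$dec_centers)
})

test_that("trained reconstruction beats the null reconstruction", {
  ds <- tiny_dataset(seed = 9, k = 2, n_rows = 8, n_cols = 8, n_genes = 40)
  pp <- preprocess_dataset(ds, preprocess_config(min_cells = 3, n_hvg = 30))
  g <- normalize_adjacency(build_radius_graph(pp$coords, 1.5))
  emb <- train_view(pp$expression, g, 2,
                    tiny_model(seed = 1, pretrain_epochs = 60,
                               train_epochs = 0))
  x <- pp$expression
  expect_lt(sum((x - emb$x_recon)^2), sum(x^2))
})

test_that("init_centers recovers blob means", {
  set.seed(30)
  z <- rbind(matrix(rnorm(40, mean = 0, sd = 0.05), 20, 2),
             matrix(rnorm(40, mean = 5, sd = 0.05), 20, 2))
  st <- init_centers(z, 2, seed = 0)
  ctr <- st$centers[order(st$centers[, 1]), ]
  expect_equal(unname(ctr[1, ]), c(0, 0), tolerance = 0.1)
  expect_equal(unname(ctr[2, ]), c(5, 5), tolerance = 0.1)
  expect_equal(st$n_clusters, 2L)
})
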