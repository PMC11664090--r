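test_that("radius graph uses a strict inequality at the boundary", {
  co <- rbind(c(0, 0), c(1, 0))
  g <- suppressWarnings(build_radius_graph(co, 1.0))
  expect_equal(sum(g$adjacency), 0)
  expect_warning(build_radius_graph(co, 0.5), "no edges")
  g2 <- suppressWarnings(build_radius_graph(rbind(c(0, 0), c(0.5, 0)), 1.0))
  expect_equal(g2$adjacency, matrix(c(0, 1, 1, 0), 2))
})

test_that("radius graph equals the brute-force scan on random points", {
  set.seed(10)
  co <- matrix(runif(100), 50, 2)
  oracle <- oracle_radius_graph(co, 0.3)
  for (be in c("balltree", "kdtree")) {
    g <- build_radius_graph(co, 0.3, backend = be)
    expect_identical(unname(g$adjacency), oracle)
  }
})

test_that("knn graph matches hand enumeration and the brute-force oracle", {
  co <- cbind(c(0, 1, 3), 0)
  g <- build_knn_graph(co, 1)
  expect_equal(g$adjacency,
               matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))  # edges 1-2, 2-3

  set.seed(11)
  co2 <- matrix(rnorm(80), 40, 2)
  for (k in c(1, 3, 6)) {
    oracle <- oracle_knn_graph(co2, k)
    for (be in c("balltree", "kdtree")) {
      g <- build_knn_graph(co2, k, backend = be)
      expect_identical(unname(g$adjacency), oracle)
      expect_true(all(rowSums(g$adjacency) >= k))
    }
  }
  g_full <- build_knn_graph(co2, 39)
  expect_true(all(g_full$adjacency[upper.tri(g_full$adjacency)] == 1))
  expect_error(build_knn_graph(co2, 40), class = "mvc_validation_error")
})

test_that("knn distance ties break deterministically by lower index", {
  # spots 2 and 3 equidistant from spot 1; lower index (2) must be chosen.
  # spot 3's own nearest neighbor is spot 4, so symmetrization cannot
  # reintroduce the 1-3 edge.
  co <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(-1.1, 0))
  for (be in c("balltree", "kdtree")) {
    g <- build_knn_graph(co, 1, backend = be)
    expect_equal(g$adjacency[1, 2], 1)
    expect_equal(g$adjacency[1, 3], 0)
  }
})

test_that("spearman graph reproduces the rank-correlation oracle", {
  x_id <- rbind(1:8, (1:8) * 2 + 3)          # identical rankings
  expect_equal(spearman_similarity(x_id)[1, 2], 1)
  x_rev <- rbind(1:8, 8:1)
  expect_equal(spearman_similarity(x_rev)[1, 2], -1)

  set.seed(12)
  x <- matrix(rnorm(48), 6, 8)
  s <- spearman_similarity(x)
  oracle <- stats::cor(t(x), method = "spearman")
  expect_equal(unname(s), unname(oracle), tolerance = 1e-12)

  g <- build_spearman_graph(x, 2)
  # oracle: top-2 by rho per spot, OR-symmetrized
  a <- matrix(0, 6, 6)
  for (i in 1:6) {
    sc <- oracle[i, ]; sc[i] <- -Inf
    a[i, order(-sc, 1:6)[1:2]] <- 1
  }
  a <- pmax(a, t(a)); diag(a) <- 0
  expect_identical(unname(g$adjacency), a)

  xc <- rbind(rep(1, 8), 1:8, 8:1)
  expect_warning(sc <- spearman_similarity(xc), "constant")
  expect_true(all(sc[1, ] == -Inf))
})

test_that("cosine graph reproduces the normalized-dot-product oracle", {
  x <- rbind(c(1, 2, 0), c(2, 4, 0), c(0, 0, 3))
  s <- cosine_similarity(x)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], 0)

  set.seed(13)
  x2 <- matrix(rnorm(48), 6, 8)
  s2 <- cosine_similarity(x2)
  oracle <- x2 %*% t(x2) / outer(sqrt(rowSums(x2^2)), sqrt(rowSums(x2^2)))
  expect_equal(unname(s2), unname(oracle), tolerance = 1e-12)
  g <- build_cosine_graph(x2, 2)
  expect_true(isSymmetric(g$adjacency))

  x3 <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 2, 3))
  expect_warning(s3 <- cosine_similarity(x3), "zero-norm")
  expect_true(all(s3[1, ] == 0))
})

test_that("adjacency normalization matches hand computations", {
  # edgeless two-spot graph: A_hat = I, norm = I
  g0 <- suppressWarnings(build_radius_graph(rbind(c(0, 0), c(9, 0)), 0.1))
  n0 <- normalize_adjacency(g0)
  expect_equal(n0$norm, diag(2))

  # single edge: degrees (2, 2), norm all 0.5
  n1 <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(n1$degree, c(2, 2))
  expect_equal(n1$norm, matrix(0.5, 2, 2))

  # spectral bound: eigenvalues of the normalized matrix lie in (-1, 1],
  # entries in [0, 1]
  set.seed(14)
  for (i in 1:10) {
    n <- 15
    a <- matrix(rbinom(n * n, 1, 0.2), n, n)
    a <- pmax(a, t(a)); diag(a) <- 0
    nm <- normalize_adjacency(a)
    expect_true(isSymmetric(nm$norm))
    expect_true(all(nm$norm >= 0 & nm$norm <= 1))
    ev <- eigen(nm$norm, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-12)
  }
})

test_that("every builder yields symmetric zero-diagonal binary graphs", {
  set.seed(15)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    co <- matrix(runif(n * 2), n, 2)
    x <- matrix(rnorm(n * 6), n, 6)
    graphs <- list(
      suppressWarnings(build_radius_graph(co, runif(1, 0.1, 0.5))),
      build_knn_graph(co, sample(1:(n - 1), 1)),
      build_spearman_graph(x, 2),
      build_cosine_graph(x, 2))
    for (g in graphs) {
      a <- g$adjacency
      expect_true(all(a %in% c(0, 1)))
      expect_identical(a, t(a))
      expect_true(all(diag(a) == 0))
    }
  }
})

test_that("hex lattice with default radius recovers six-neighbor structure", {
  co <- generate_hex_lattice(8, 8)
  r <- default_radius(co)
  expect_equal(r, 1.5)
  g <- build_radius_graph(co, r)
  deg <- rowSums(g$adjacency)
  interior <- co[, 1] > 1 & co[, 1] < 6.4 & co[, 2] > 1 & co[, 2] < 5.1
  expect_true(all(deg[interior] == 6))
})

test_that("build_views assembles the requested views with defaults", {
  ds <- tiny_dataset(k = 2, n_rows = 6, n_cols = 6, n_genes = 20)
  vs <- build_views(ds, c(default_view_specs(),
                          list(list(method = "cosine", param = 3))))
  expect_named(vs, c("radius_ball", "knn_ball", "knn_kdtr", "cosine"))
  expect_identical(vs$knn_ball$adjacency, vs$knn_kdtr$adjacency)
  expect_error(build_views(ds, list(list(method = "bogus"))),
               class = "mvc_config_error")
})
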