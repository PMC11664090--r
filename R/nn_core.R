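# Minimal dense neural-network machinery: Glorot init, linear layers with
# ReLU, batch normalization, and an Adam optimizer over nested parameter
# lists.  Written in plain matrix algebra with hand-derived gradients —
# everything here runs full-batch at desk scale, so dense BLAS is plenty.

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

linear_init <- function(n_in, n_out, bias = TRUE) {
  l <- list(W = glorot(n_in, n_out))
  if (bias) l$b <- rep(0, n_out)
  l
}

bn_init <- function(n_out) list(gamma = rep(1, n_out), beta = rep(0, n_out))

relu <- function(x) pmax(x, 0)

#' @noRd
# Forward through affine -> optional BN -> optional ReLU; returns output
# plus a cache for the backward pass.
dense_forward <- function(x, layer, bn = NULL, activation = TRUE,
                          bn_eps = 1e-5) {
  a <- x %*% layer$W
  if (!is.null(layer$b)) a <- sweep(a, 2, layer$b, "+")
  cache <- list(x = x, a = a)
  h <- a
  if (!is.null(bn)) {
    m <- colMeans(h)
    v <- colMeans(sweep(h, 2, m)^2)           # biased variance, batch stats
    xhat <- sweep(sweep(h, 2, m), 2, sqrt(v + bn_eps), "/")
    h <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    cache$bn <- list(m = m, v = v, xhat = xhat, eps = bn_eps)
  }
  if (activation) {
    cache$pre <- h
    h <- relu(h)
  }
  cache$out <- h
  cache
}

#' @noRd
# Backward companion of dense_forward.  `dout` is dL/d(output); returns
# dL/dx and parameter gradients.
dense_backward <- function(dout, layer, cache, bn = NULL) {
  grads <- list()
  if (!is.null(cache$pre)) dout <- dout * (cache$pre > 0)
  if (!is.null(bn)) {
    b <- cache$bn
    n <- nrow(dout)
    grads$bn <- list(gamma = colSums(dout * b$xhat), beta = colSums(dout))
    dxhat <- sweep(dout, 2, bn$gamma, "*")
    inv_sd <- 1 / sqrt(b$v + b$eps)
    # standard batch-norm backward (batch statistics)
    t1 <- dxhat
    t2 <- matrix(colMeans(dxhat), n, ncol(dxhat), byrow = TRUE)
    t3 <- b$xhat * matrix(colMeans(dxhat * b$xhat), n, ncol(dxhat), byrow = TRUE)
    dout <- sweep(t1 - t2 - t3, 2, inv_sd, "*")
  }
  grads$W <- crossprod(cache$x, dout)
  if (!is.null(layer$b)) grads$b <- colSums(dout)
  grads$dx <- dout %*% t(layer$W)
  grads
}

# ---- Adam over nested lists of numeric arrays -------------------------------

map_params <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- lapply(seq_along(xs[[1]]), function(i)
      do.call(map_params, c(list(f), lapply(xs, `[[`, i))))
    names(out) <- names(xs[[1]])
    out
  } else {
    do.call(f, xs)
  }
}

adam_init <- function(params) {
  list(m = map_params(function(p) p * 0, params),
       v = map_params(function(p) p * 0, params),
       t = 0L)
}

#' @noRd
# One Adam step.  `grads` mirrors the structure of `params`; entries missing
# from grads are treated as zero-gradient.  Weight decay is plain L2 added
# to matrix-valued gradients.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.null(g)) g <- p * 0
    if (weight_decay > 0 && is.matrix(p)) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p_new <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p_new, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- lapply(seq_along(p), function(i)
        walk(p[[i]], if (is.null(g)) NULL else g[[i]], m[[i]], v[[i]]))
      names(res) <- names(p)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

sum_finite <- function(x) all(is.finite(unlist(x, use.names = FALSE)))
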