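#' Histology augmentation configuration
#'
#' @param alpha1 weight of the aligned image features
#' @param alpha2 weight of the preprocessed expression
#' @param tile_size tile side in pixels
#' @param ae_hidden widths of the aligner's encoder layers; the last entry
#'   is replaced by the target dimension at fit time
#' @param ae_epochs aligner training epochs
#' @param ae_lr aligner learning rate
#' @param seed RNG seed
#' @return an `augment_config` list
#' @export
augment_config <- function(alpha1 = 0.3, alpha2 = 1.0, tile_size = 16,
                           ae_hidden = c(512), ae_epochs = 100,
                           ae_lr = 1e-3, seed = 0) {
  if (alpha1 < 0 || alpha2 < 0) mvc_validation_error("alpha weights must be >= 0")
  if (alpha1 + alpha2 <= 0) mvc_validation_error("alpha1 + alpha2 must be > 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 tile_size = as.integer(tile_size),
                 ae_hidden = as.integer(ae_hidden),
                 ae_epochs = as.integer(ae_epochs), ae_lr = ae_lr,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Cut per-spot tiles from the dataset's image
#'
#' One `tile_size x tile_size` crop centered at each spot's pixel position,
#' zero-padded at image edges, in spot order.
#'
#' @param ds an [st_dataset] with `image` and `pixel_coords`
#' @param tile_size tile side in pixels
#' @return list of `tile_size x tile_size x 3` arrays
#' @export
cut_tiles <- function(ds, tile_size = 16) {
  if (is.null(ds$image) || is.null(ds$pixel_coords))
    mvc_config_error("dataset has no image/pixel_coords; disable augmentation")
  img <- ds$image
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- tile_size %/% 2
  lapply(seq_len(nrow(ds$pixel_coords)), function(i) {
    cy <- round(ds$pixel_coords[i, 1]); cx <- round(ds$pixel_coords[i, 2])
    tile <- array(0, dim = c(tile_size, tile_size, 3))
    ys <- (cy - half + 1):(cy - half + tile_size)
    xs <- (cx - half + 1):(cx - half + tile_size)
    ok_y <- ys >= 1 & ys <= h
    ok_x <- xs >= 1 & xs <= w
    tile[which(ok_y), which(ok_x), ] <- img[ys[ok_y], xs[ok_x], , drop = FALSE]
    tile
  })
}

#' Built-in deterministic tile feature extractor
#'
#' A no-download stand-in for a pre-trained CNN: per-channel means and
#' standard deviations plus per-channel 16-bin intensity histograms
#' (54 dimensions).  Tiles are min-max auto-contrasted first.
#'
#' @return a feature-extractor function with an `out_dim` attribute
#' @export
builtin_extractor <- function() {
  f <- function(tile) {
    t01 <- tile / max(1, max(tile))           # to [0,1] whatever input scale
    rng <- range(t01)
    if (rng[2] > rng[1]) t01 <- (t01 - rng[1]) / (rng[2] - rng[1])
    feats <- numeric(0)
    for (ch in 1:3) {
      v <- as.vector(t01[, , ch])
      hst <- graphics::hist(v, breaks = seq(0, 1, length.out = 17),
                            plot = FALSE)$counts / length(v)
      feats <- c(feats, mean(v), stats::sd(v), hst)
    }
    feats
  }
  attr(f, "out_dim") <- 54L
  attr(f, "name") <- "builtin"
  f
}

#' Extract per-spot image features
#'
#' Applies a pluggable extractor (one RGB tile -> fixed-length vector) to
#' every tile.  Deterministic for a deterministic extractor.
#'
#' @param tiles list of RGB tile arrays
#' @param extractor extractor function; default [builtin_extractor()]
#' @return spots x d0 feature matrix
#' @export
extract_cnn_features <- function(tiles, extractor = builtin_extractor()) {
  feats <- lapply(tiles, extractor)
  lens <- vapply(feats, length, 1L)
  if (length(unique(lens)) != 1)
    mvc_validation_error("extractor output length varies across tiles")
  m <- do.call(rbind, feats)
  attr(m, "extractor_name") <- attr(extractor, "name") %||% "custom"
  m
}

#' Align raw image features to the expression dimension
#'
#' Trains a small fully connected autoencoder (each hidden layer is
#' ReLU(BatchNorm(affine))) that expands the raw features through a
#' target-dimension layer and reconstructs them through a symmetric
#' decoder, minimizing squared reconstruction error.  The aligned feature
#' matrix `MS` is the target-dimension layer's activations, z-scored per
#' feature so its scale is comparable with log-expression before
#' weighting.
#'
#' @param raw_features spots x d0 matrix
#' @param target_dim output dimension (the expression feature count)
#' @param cfg an [augment_config()]
#' @return spots x target_dim aligned feature matrix with attribute
#'   `"history"` (per-epoch reconstruction loss)
#' @export
align_features <- function(raw_features, target_dim, cfg = augment_config()) {
  if (target_dim < 1) mvc_validation_error("target_dim must be >= 1")
  x <- as.matrix(raw_features)
  # standardize inputs; constant columns to zero
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sd, "/")
  d0 <- ncol(x)
  widths <- c(d0, cfg$ae_hidden, target_dim)      # encoder (expansion)
  dec_widths <- c(target_dim, rev(cfg$ae_hidden), d0)
  set.seed(cfg$seed)
  enc <- lapply(seq_len(length(widths) - 1),
                function(i) linear_init(widths[i], widths[i + 1]))
  enc_bn <- lapply(widths[-1], bn_init)
  dec <- lapply(seq_len(length(dec_widths) - 1),
                function(i) linear_init(dec_widths[i], dec_widths[i + 1]))
  dec_bn <- lapply(seq_len(length(dec_widths) - 1), function(i)
    if (i < length(dec_widths) - 1) bn_init(dec_widths[i + 1]) else NULL)
  params <- list(enc = enc, enc_bn = enc_bn, dec = dec,
                 dec_bn = dec_bn[!vapply(dec_bn, is.null, TRUE)])
  opt <- adam_init(params)
  history <- numeric(cfg$ae_epochs)
  n_dec_bn <- length(params$dec_bn)

  forward <- function(params) {
    h <- x
    ec <- vector("list", length(params$enc))
    for (i in seq_along(params$enc)) {
      ec[[i]] <- dense_forward(h, params$enc[[i]], bn = params$enc_bn[[i]])
      h <- ec[[i]]$out
    }
    ms <- h
    dc <- vector("list", length(params$dec))
    for (i in seq_along(params$dec)) {
      last <- i == length(params$dec)
      dc[[i]] <- dense_forward(h, params$dec[[i]],
                               bn = if (!last) params$dec_bn[[i]] else NULL,
                               activation = !last)
      h <- dc[[i]]$out
    }
    list(ms = ms, recon = h, ec = ec, dc = dc)
  }

  for (epoch in seq_len(cfg$ae_epochs)) {
    fw <- forward(params)
    loss <- mean((x - fw$recon)^2)
    if (!is.finite(loss))
      mvc_training_error(sprintf("aligner loss non-finite at epoch %d", epoch))
    history[epoch] <- loss
    dout <- 2 * (fw$recon - x) / length(x)
    g_dec <- vector("list", length(params$dec))
    g_dec_bn <- vector("list", n_dec_bn)
    for (i in rev(seq_along(params$dec))) {
      last <- i == length(params$dec)
      bn <- if (!last) params$dec_bn[[i]] else NULL
      bk <- dense_backward(dout, params$dec[[i]], fw$dc[[i]], bn = bn)
      g_dec[[i]] <- list(W = bk$W, b = bk$b)
      if (!last) g_dec_bn[[i]] <- bk$bn
      dout <- bk$dx
    }
    g_enc <- vector("list", length(params$enc))
    g_enc_bn <- vector("list", length(params$enc_bn))
    for (i in rev(seq_along(params$enc))) {
      bk <- dense_backward(dout, params$enc[[i]], fw$ec[[i]],
                           bn = params$enc_bn[[i]])
      g_enc[[i]] <- list(W = bk$W, b = bk$b)
      g_enc_bn[[i]] <- bk$bn
      dout <- bk$dx
    }
    st <- adam_step(params,
                    list(enc = g_enc, enc_bn = g_enc_bn, dec = g_dec,
                         dec_bn = g_dec_bn),
                    opt, lr = cfg$ae_lr)
    params <- st$params
    opt <- st$state
  }
  fw <- forward(params)
  ms <- fw$ms
  # z-score per feature; constant features stay zero
  m2 <- colMeans(ms); s2 <- apply(ms, 2, stats::sd)
  s2[s2 < 1e-12] <- 1
  ms <- sweep(sweep(ms, 2, m2), 2, s2, "/")
  attr(ms, "history") <- history
  ms
}

#' Weighted augmentation of expression with aligned image features
#'
#' `GE_aug = alpha1 * MS + alpha2 * GE`, elementwise.
#'
#' @param ms aligned image features (spots x features)
#' @param ge preprocessed expression (same shape)
#' @param alpha1 weight of `ms`
#' @param alpha2 weight of `ge`
#' @return the augmented matrix
#' @export
augment_expression <- function(ms, ge, alpha1 = 0.3, alpha2 = 1.0) {
  ms <- as.matrix(ms); ge <- as.matrix(ge)
  if (!all(dim(ms) == dim(ge)))
    mvc_validation_error("MS and GE must have identical shapes")
  alpha1 * ms + alpha2 * ge
}
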