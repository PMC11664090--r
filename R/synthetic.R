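#' Simulation configuration for the Visium-like layered tissue generator
#'
#' @param n_rows,n_cols hexagonal lattice dimensions
#' @param n_genes number of genes
#' @param k_domains number of contiguous layered domains (>= 2)
#' @param markers_per_domain disjoint marker genes per domain
#' @param log_fold_change log2 fold change of a marker inside its domain
#' @param baseline_mean negative-binomial mean outside the marked domain
#' @param dropout_rate independent Bernoulli zero-masking probability
#' @param noise_dispersion negative-binomial size parameter (smaller =
#'   noisier)
#' @param seed RNG seed; the generator is deterministic given the seed
#' @param make_tiles also render per-spot pseudo-histology tiles
#' @param tile_size tile side length in pixels
#' @return a `sim_config` list
#' @export
sim_config <- function(n_rows = 24, n_cols = 25, n_genes = 150, k_domains = 4,
                       markers_per_domain = 10, log_fold_change = 2.5,
                       baseline_mean = 2, dropout_rate = 0.3,
                       noise_dispersion = 2, seed = 0, make_tiles = FALSE,
                       tile_size = 16) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              n_genes = as.integer(n_genes), k_domains = as.integer(k_domains),
              markers_per_domain = as.integer(markers_per_domain),
              log_fold_change = log_fold_change, baseline_mean = baseline_mean,
              dropout_rate = dropout_rate, noise_dispersion = noise_dispersion,
              seed = as.integer(seed), make_tiles = isTRUE(make_tiles),
              tile_size = as.integer(tile_size))
  if (cfg$k_domains < 2) mvc_validation_error("k_domains must be >= 2")
  if (cfg$n_rows * cfg$n_cols < 10L * cfg$k_domains)
    mvc_validation_error("lattice too small: need >= 10 spots per domain")
  if (cfg$markers_per_domain * cfg$k_domains > cfg$n_genes)
    mvc_validation_error("markers_per_domain * k_domains exceeds n_genes")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    mvc_validation_error("dropout_rate must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate an offset-row hexagonal lattice
#'
#' Rows are spaced sqrt(3)/2 apart and odd rows are shifted by half a unit,
#' giving unit nearest-neighbor distance: each interior spot has exactly
#' six neighbors at distance 1, the Visium capture-array geometry.
#'
#' @param n_rows,n_cols lattice dimensions (>= 1)
#' @return spots x 2 coordinate matrix, row-major spot order
#' @export
generate_hex_lattice <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) mvc_validation_error("lattice dims must be >= 1")
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x <- col + 0.5 * (row %% 2L)
  y <- row * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Assign contiguous layered domains by slicing the y-range into bands
#'
#' Mirrors laminar tissue (e.g. cortical layers): the vertical extent is cut
#' into `k_domains` equal bands; all spots in a band share a label, so every
#' domain is spatially connected on the lattice by construction.
#'
#' @param coords spots x 2 coordinate matrix
#' @param k_domains number of bands (>= 2)
#' @return integer label vector in `0..k-1`, non-decreasing in y
#' @export
assign_layered_domains <- function(coords, k_domains) {
  if (k_domains < 2) mvc_validation_error("k_domains must be >= 2")
  y <- coords[, 2]
  rng <- range(y)
  if (rng[1] == rng[2])
    mvc_validation_error("degenerate y-range; use a taller lattice")
  lab <- pmin(k_domains - 1L,
              as.integer(floor((y - rng[1]) / (rng[2] - rng[1]) * k_domains)))
  if (length(unique(lab)) < k_domains)
    mvc_validation_error("a domain band is empty; use a larger lattice")
  lab
}

#' Simulate domain-structured count data
#'
#' Each domain receives `markers_per_domain` disjoint marker genes drawn
#' negative-binomial with mean `baseline_mean * 2^log_fold_change` inside
#' the domain and `baseline_mean` outside; non-marker genes are baseline
#' everywhere.  Independent Bernoulli dropout zero-masks entries, mimicking
#' the sparsity of real spot-level data.
#'
#' @param labels integer domain labels, length = spots
#' @param cfg a [sim_config()]
#' @return list with `counts` (spots x genes integer matrix) and `markers`
#'   (named list: domain -> marker gene indices)
#' @export
simulate_expression <- function(labels, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- length(labels)
  g <- cfg$n_genes
  doms <- sort(unique(labels))
  mu <- matrix(cfg$baseline_mean, n, g)
  markers <- list()
  next_gene <- 1L
  for (d in doms) {
    idx <- next_gene:(next_gene + cfg$markers_per_domain - 1L)
    next_gene <- next_gene + cfg$markers_per_domain
    markers[[as.character(d)]] <- idx
    mu[labels == d, idx] <- cfg$baseline_mean * 2^cfg$log_fold_change
  }
  counts <- matrix(stats::rnbinom(n * g, mu = as.vector(mu),
                                  size = cfg$noise_dispersion), n, g)
  if (cfg$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(n * g, 1L, 1 - cfg$dropout_rate), n, g)
    counts <- counts * keep
  }
  colnames(counts) <- paste0("gene", seq_len(g))
  rownames(counts) <- paste0("spot", seq_len(n))
  list(counts = counts, markers = markers)
}

#' Render pseudo-histology tiles with domain-specific base colors
#'
#' Stands in for H&E tile cutting in tests: each spot's tile is a flat
#' domain color plus Gaussian pixel noise, so same-domain tiles are close
#' in mean color and different-domain tiles are separated.
#'
#' @param labels integer domain labels
#' @param cfg a [sim_config()] with `make_tiles = TRUE`
#' @param noise_sd pixel noise standard deviation on the 0-255 scale
#' @return list of `tile_size x tile_size x 3` arrays with values in 0..255
#' @export
render_pseudo_tiles <- function(labels, cfg, noise_sd = 8) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$make_tiles) mvc_config_error("cfg$make_tiles is not set")
  set.seed(cfg$seed + 1L)
  doms <- sort(unique(labels))
  k <- length(doms)
  # evenly spaced hues -> well separated base colors
  base <- t(sapply(seq_along(doms), function(i) {
    h <- (i - 1) / k
    grDevices::col2rgb(grDevices::hsv(h, 0.6, 0.85))[, 1]
  }))
  ts <- cfg$tile_size
  lapply(labels, function(lb) {
    bc <- base[match(lb, doms), ]
    tile <- array(rep(bc, each = ts * ts), dim = c(ts, ts, 3))
    tile <- tile + array(stats::rnorm(ts * ts * 3, 0, noise_sd),
                         dim = c(ts, ts, 3))
    pmax(pmin(tile, 255), 0)
  })
}

#' Generate a complete synthetic layered-tissue dataset
#'
#' @param cfg a [sim_config()]
#' @return an [st_dataset] with truth labels (and tiles if requested)
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  coords <- generate_hex_lattice(cfg$n_rows, cfg$n_cols)
  labels <- assign_layered_domains(coords, cfg$k_domains)
  sim <- simulate_expression(labels, cfg)
  tiles <- if (cfg$make_tiles) render_pseudo_tiles(labels, cfg) else NULL
  ds <- st_dataset(sim$counts, coords, truth_labels = labels, tiles = tiles)
  attr(ds, "markers") <- sim$markers
  ds
}

#' Write a synthetic dataset as an on-disk fixture
#'
#' Emits a 10x-style matrix directory (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`), a coordinates CSV, a labels CSV and optional per-spot
#' PNG tiles, i.e. exactly what the readers in this package consume.
#'
#' @param ds an [st_dataset]
#' @param out_dir output directory
#' @param genes_by_spots store the MTX genes x spots (the 10x convention);
#'   set `FALSE` to store spots x genes
#' @return invisibly, `out_dir`
#' @export
write_fixture <- function(ds, out_dir, genes_by_spots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(if (genes_by_spots) t(ds$expression) else ds$expression,
                      sparse = TRUE)
  Matrix::writeMM(m, file.path(out_dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(out_dir, "barcodes.tsv"))
  utils::write.table(data.frame(id = ds$gene_ids, name = ds$gene_ids,
                                type = "Gene Expression"),
                     file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1],
                              y = ds$coords[, 2]),
                   file.path(out_dir, "coords.csv"), row.names = FALSE)
  if (!is.null(ds$truth_labels))
    utils::write.csv(data.frame(spot_id = ds$spot_ids, label = ds$truth_labels),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
  if (!is.null(ds$tiles) && requireNamespace("png", quietly = TRUE)) {
    td <- file.path(out_dir, "tiles")
    dir.create(td, showWarnings = FALSE)
    for (i in seq_along(ds$tiles))
      png::writePNG(ds$tiles[[i]] / 255,
                    file.path(td, paste0(ds$spot_ids[i], ".png")))
  }
  invisible(out_dir)
}
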