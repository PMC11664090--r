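#' Preprocessing configuration
#'
#' Defaults follow the standard spot-level recipe: drop genes seen in fewer
#' than 50 spots, library-size normalize to the median total, log1p, keep
#' the 3000 most dispersed genes.
#'
#' @param min_cells minimum number of count-positive spots per gene
#' @param n_hvg number of highly variable genes to keep
#' @param target_sum library-size target, a positive number or `"median"`
#' @param hvg_method only `"dispersion"` (mean-binned normalized dispersion)
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(min_cells = 50, n_hvg = 3000,
                              target_sum = "median",
                              hvg_method = "dispersion") {
  if (min_cells < 0) mvc_validation_error("min_cells must be >= 0")
  if (n_hvg < 1) mvc_validation_error("n_hvg must be >= 1")
  hvg_method <- match.arg(hvg_method, "dispersion")
  structure(list(min_cells = as.integer(min_cells), n_hvg = as.integer(n_hvg),
                 target_sum = target_sum, hvg_method = hvg_method),
            class = "preprocess_config")
}

subset_genes <- function(ds, keep) {
  ds$expression <- ds$expression[, keep, drop = FALSE]
  ds$gene_ids <- ds$gene_ids[keep]
  ds
}

#' Remove genes expressed in fewer than `min_cells` spots
#'
#' @param ds an [st_dataset]
#' @param min_cells threshold on the number of count-positive spots
#' @return the filtered [st_dataset]; spot set and order unchanged
#' @export
filter_genes <- function(ds, min_cells = 50) {
  n_pos <- colSums(ds$expression > 0)
  keep <- n_pos >= min_cells
  if (!any(keep))
    mvc_validation_error("all genes removed by filter_genes; lower min_cells")
  subset_genes(ds, keep)
}

#' Library-size normalize and log1p-transform
#'
#' Each spot's counts are scaled so its total equals `target_sum` (or the
#' median library size), then `log(1 + x)` is applied.  All-zero spots are
#' left as zeros with a warning.
#'
#' @param ds an [st_dataset]
#' @param target_sum positive number or `"median"`
#' @return the transformed [st_dataset]
#' @export
normalize_log <- function(ds, target_sum = "median") {
  x <- ds$expression
  if (any(x < 0)) mvc_validation_error("negative expression values")
  lib <- rowSums(x)
  zero <- lib == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero spots left unnormalized", sum(zero)))
    lib[zero] <- 1
  }
  target <- if (identical(target_sum, "median")) {
    if (all(zero)) 1 else stats::median(lib[!zero])
  } else {
    if (!is.numeric(target_sum) || target_sum <= 0)
      mvc_validation_error("target_sum must be positive or \"median\"")
    target_sum
  }
  ds$expression <- log1p(x / lib * target)
  ds
}

#' Normalized-dispersion statistics per gene
#'
#' Seurat-style ranking: dispersion = variance/mean per gene, z-scored
#' within 20 equal-frequency mean bins.  Genes with zero mean get
#' dispersion 0.
#'
#' @param x spots x genes matrix (normalized/log scale)
#' @param n_bins number of mean bins
#' @return data.frame with mean, dispersion, dispersion_norm
#' @export
gene_dispersion <- function(x, n_bins = 20) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # keep ~10 genes per bin at least; tiny panels collapse to one bin
  n_bins <- max(1L, min(n_bins, floor(length(mu) / 10)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
         else factor(rep(1L, length(mu)))
  dn <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    dn[i] <- if (is.na(s) || s == 0) disp[i] - m else (disp[i] - m) / s
  }
  data.frame(mean = mu, dispersion = disp, dispersion_norm = dn)
}

#' Keep the `n_hvg` most variable genes by normalized dispersion
#'
#' @param ds an [st_dataset] on the normalized/log scale
#' @param n_hvg number of genes to keep; if fewer exist, all are kept with
#'   a warning
#' @return the subset [st_dataset], genes in original relative order
#' @export
select_hvg <- function(ds, n_hvg = 3000) {
  g <- ncol(ds$expression)
  if (n_hvg >= g) {
    if (n_hvg > g) warning(sprintf("n_hvg = %d >= %d genes; keeping all", n_hvg, g))
    return(ds)
  }
  st <- gene_dispersion(ds$expression)
  ord <- order(-st$dispersion_norm, seq_len(g))  # ties by gene position
  keep <- sort(ord[seq_len(n_hvg)])
  subset_genes(ds, keep)
}

#' Full preprocessing: filter, normalize+log, HVG selection
#'
#' @param ds an [st_dataset] of raw counts
#' @param cfg a [preprocess_config()]
#' @return the preprocessed [st_dataset]
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  ds <- filter_genes(ds, cfg$min_cells)
  ds <- normalize_log(ds, cfg$target_sum)
  select_hvg(ds, cfg$n_hvg)
}
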