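#' Spot-level spatial transcriptomics dataset
#'
#' The universal container moved through the pipeline: a spots x genes
#' non-negative expression matrix, per-spot 2-D coordinates, and optional
#' image tiles / pixel positions / ground-truth domain labels.
#'
#' @param expression numeric matrix, spots x genes, non-negative and finite
#' @param coords numeric matrix, spots x 2, array coordinates (same unit on
#'   both axes)
#' @param gene_ids character vector, unique, length `ncol(expression)`
#' @param spot_ids character vector, unique, length `nrow(expression)`
#' @param pixel_coords optional spots x 2 matrix in image pixel space, used
#'   only for tile cutting
#' @param image optional RGB raster, a `height x width x 3` array in `[0,1]`
#'   or `0..255`
#' @param tiles optional list of per-spot RGB tile arrays (spot order)
#' @param truth_labels optional vector of domain annotations; canonicalized
#'   to 0-based contiguous integers on construction
#' @param layer_names optional named character vector mapping canonical
#'   label -> human-readable domain name
#' @return an object of class `st_dataset`
#' @export
st_dataset <- function(expression, coords, gene_ids = colnames(expression),
                       spot_ids = rownames(expression), pixel_coords = NULL,
                       image = NULL, tiles = NULL, truth_labels = NULL,
                       layer_names = NULL) {
  expression <- as.matrix(expression)
  coords <- as.matrix(coords)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expression)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(expression)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (nrow(expression) != nrow(coords) || nrow(expression) != length(spot_ids))
    mvc_validation_error("expression, coords and spot_ids disagree on spot count")
  if (ncol(coords) != 2L)
    mvc_validation_error("coords must have exactly two columns")
  if (length(gene_ids) != ncol(expression))
    mvc_validation_error("gene_ids length must equal gene count")
  if (anyDuplicated(spot_ids)) mvc_validation_error("spot_ids must be unique")
  if (anyDuplicated(gene_ids)) mvc_validation_error("gene_ids must be unique")
  if (!all(is.finite(expression)) || any(expression < 0))
    mvc_validation_error("expression must be finite and non-negative")
  if (!is.null(truth_labels)) {
    if (length(truth_labels) != nrow(expression))
      mvc_validation_error("truth_labels length must equal spot count")
    truth_labels <- canonicalize_labels(truth_labels)
  }
  if (!is.null(pixel_coords)) {
    pixel_coords <- as.matrix(pixel_coords)
    if (nrow(pixel_coords) != nrow(expression) || ncol(pixel_coords) != 2L)
      mvc_validation_error("pixel_coords must be spots x 2")
  }
  dimnames(expression) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  structure(list(expression = expression, coords = coords,
                 gene_ids = gene_ids, spot_ids = spot_ids,
                 pixel_coords = pixel_coords, image = image, tiles = tiles,
                 truth_labels = truth_labels, layer_names = layer_names),
            class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d spots x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  if (!is.null(x$truth_labels))
    cat(sprintf("  truth labels: %d domains\n", length(unique(x$truth_labels))))
  if (!is.null(x$image)) cat("  image: present\n")
  if (!is.null(x$tiles)) cat(sprintf("  tiles: %d\n", length(x$tiles)))
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$expression)

read_maybe_gz <- function(dir, base) {
  for (cand in c(base, paste0(base, ".gz"))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a 10x Genomics-style matrix directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or
#' `genes.tsv`), each optionally gzipped.  The on-disk MTX may be stored
#' either genes x spots (the 10x convention) or spots x genes; orientation
#' is resolved from the barcode/feature counts and the returned expression
#' matrix is always spots x genes with barcode order preserved.  A Visium
#' `tissue_positions` CSV (headered or 6-column headerless dialect) is used
#' for coordinates when present; otherwise coordinates must be attached
#' separately.
#'
#' @param path directory containing the matrix triplet
#' @param positions_path optional explicit path to a tissue positions CSV
#' @return an [st_dataset] (with zero-filled coords if no positions file)
#' @export
read_tenx_matrix_dir <- function(path, positions_path = NULL) {
  if (!dir.exists(path)) mvc_io_error(sprintf("directory not found: %s", path))
  mtx <- read_maybe_gz(path, "matrix.mtx")
  bc <- read_maybe_gz(path, "barcodes.tsv")
  ft <- read_maybe_gz(path, "features.tsv") %||% read_maybe_gz(path, "genes.tsv")
  if (is.null(mtx)) mvc_io_error(sprintf("missing matrix.mtx[.gz] in %s", path))
  if (is.null(bc)) mvc_io_error(sprintf("missing barcodes.tsv[.gz] in %s", path))
  if (is.null(ft)) mvc_io_error(sprintf("missing features.tsv[.gz] in %s", path))
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  feat <- utils::read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(feat[[min(2L, ncol(feat))]])
  if (anyDuplicated(gene_ids)) gene_ids <- make.unique(gene_ids)
  nb <- length(barcodes); ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- t(m)                       # stored genes x spots; orient spots x genes
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    mvc_validation_error(sprintf(
      "matrix dims %dx%d match neither barcodes (%d) x features (%d) orientation",
      nrow(m), ncol(m), nb, ng))
  }
  coords <- matrix(0, nb, 2)
  pixel_coords <- NULL
  pos <- positions_path %||% read_maybe_gz(path, "tissue_positions_list.csv") %||%
    read_maybe_gz(path, "tissue_positions.csv")
  if (!is.null(pos)) {
    tp <- read_tissue_positions(pos)
    missing_bc <- setdiff(barcodes, tp$barcode)
    if (length(missing_bc) > 0)
      mvc_validation_error(paste0("barcodes absent from positions file: ",
                                  paste(utils::head(missing_bc, 5), collapse = ", "),
                                  if (length(missing_bc) > 5) " ..."))
    idx <- match(barcodes, tp$barcode)
    coords <- cbind(tp$array_row[idx], tp$array_col[idx])
    pixel_coords <- cbind(tp$pxl_row[idx], tp$pxl_col[idx])
  }
  st_dataset(m, coords, gene_ids = gene_ids, spot_ids = barcodes,
             pixel_coords = pixel_coords)
}

#' Read a Visium tissue positions table, either dialect
#'
#' Supports the headerless 6-column `tissue_positions_list.csv`
#' (barcode, in_tissue, array_row, array_col, pxl_row, pxl_col) and the
#' headered `tissue_positions.csv` used by newer Space Ranger releases.
#'
#' @param path CSV path
#' @return data.frame with barcode, in_tissue, array_row, array_col,
#'   pxl_row, pxl_col
#' @export
read_tissue_positions <- function(path) {
  first <- readLines(path, n = 1)
  headered <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = headered, stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    mvc_validation_error("tissue positions table must have 6 columns")
  names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row", "pxl_col")
  df
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) mvc_io_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a dataset from plain CSV/TSV tables
#'
#' The expression table holds spot ids in its first column and genes in the
#' remaining columns; the coordinates table holds spot id, x, y.  Spots are
#' aligned by id intersection in expression-file order; unmatched spots are
#' dropped with a logged count.
#'
#' @param expr_path expression CSV/TSV (spots x genes, id column first)
#' @param coords_path coordinates CSV/TSV (id, x, y)
#' @param labels_path optional labels CSV/TSV (id, label)
#' @param verbose log dropped-spot counts
#' @return an [st_dataset]
#' @export
read_table_dataset <- function(expr_path, coords_path, labels_path = NULL,
                               verbose = TRUE) {
  ex <- read_delim_auto(expr_path)
  co <- read_delim_auto(coords_path)
  spot_ids <- as.character(ex[[1]])
  mat <- as.matrix(ex[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(ex[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(ex[[bad + 1]]))))[1]
    mvc_validation_error(sprintf(
      "non-numeric expression value at row %d, column '%s'",
      badrow %||% 1L, names(ex)[bad + 1]))
  }
  co_ids <- as.character(co[[1]])
  keep <- spot_ids %in% co_ids
  if (!any(keep)) mvc_validation_error("no overlapping spot ids between expression and coordinates")
  dropped <- sum(!keep)
  if (dropped > 0)
    mvc_log(sprintf("read_table_dataset: dropped %d spots without coordinates", dropped),
            verbose = verbose)
  spot_ids <- spot_ids[keep]
  mat <- mat[keep, , drop = FALSE]
  coords <- as.matrix(co[match(spot_ids, co_ids), 2:3, drop = FALSE])
  truth <- NULL
  if (!is.null(labels_path)) {
    lb <- read_delim_auto(labels_path)
    lb_ids <- as.character(lb[[1]])
    if (!all(spot_ids %in% lb_ids))
      mvc_validation_error("labels file does not cover all retained spots")
    truth <- lb[[2]][match(spot_ids, lb_ids)]
  }
  st_dataset(mat, coords, gene_ids = colnames(mat), spot_ids = spot_ids,
             truth_labels = truth)
}

write_matrix_csv_gz <- function(m, ids, path) {
  df <- data.frame(spot_id = ids, as.data.frame(m), check.names = FALSE)
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write pipeline results to a directory
#'
#' Emits per-view labels, consensus labels, the consensus matrix, per-view
#' embeddings and the denoised expression as CSV / gzipped-CSV files keyed
#' by spot id.  Overwrites idempotently.
#'
#' @param dataset the [st_dataset] the result was computed on
#' @param result a `consensus_result` (see [run_consensus()])
#' @param out_dir output directory, created if absent
#' @param embeddings optional list of `view_embedding` objects to dump
#' @return invisibly, the vector of files written
#' @export
write_results <- function(dataset, result, out_dir, embeddings = NULL) {
  n <- length(dataset$spot_ids)
  if (length(result$final_labels) != n)
    mvc_validation_error("result label length does not match dataset spot count")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) mvc_io_error(sprintf("cannot create %s", out_dir))
  files <- character(0)
  lab <- data.frame(spot_id = dataset$spot_ids,
                    consensus = result$final_labels)
  for (i in seq_along(result$view_labels)) {
    if (length(result$view_labels[[i]]) != n)
      mvc_validation_error("per-view label length mismatch")
    lab[[names(result$view_labels)[i] %||% paste0("view", i)]] <-
      result$view_labels[[i]]
  }
  f <- file.path(out_dir, "labels.csv")
  utils::write.csv(lab, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "consensus_matrix.csv.gz")
  write_matrix_csv_gz(result$consensus_matrix, dataset$spot_ids, f)
  files <- c(files, f)
  for (i in seq_along(embeddings)) {
    emb <- embeddings[[i]]
    vid <- emb$view_id %||% paste0("view", i)
    f <- file.path(out_dir, sprintf("embedding_%s.csv.gz", vid))
    write_matrix_csv_gz(emb$z, dataset$spot_ids, f)
    files <- c(files, f)
    if (!is.null(emb$x_recon)) {
      f <- file.path(out_dir, sprintf("denoised_%s.csv.gz", vid))
      write_matrix_csv_gz(emb$x_recon, dataset$spot_ids, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
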