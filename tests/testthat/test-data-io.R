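test_that("fixture round-trips through the 10x-style reader, both orientations", {
  ds <- st_dataset(matrix(c(0, 1, 2, 3, 4, 0, 5, 6, 7, 0, 8, 9), 4, 3),
                   cbind(1:4, rep(0, 4)),
                   gene_ids = c("g1", "g2", "g3"),
                   spot_ids = c("a", "b", "c", "d"))
  for (gxs in c(TRUE, FALSE)) {
    dir <- withr::local_tempdir()
    write_fixture(ds, dir, genes_by_spots = gxs)
    rd <- read_tenx_matrix_dir(dir)
    expect_equal(dim(rd$expression), c(4L, 3L))
    expect_equal(unname(rd$expression), unname(ds$expression))
    expect_equal(rd$spot_ids, ds$spot_ids)
    expect_equal(rd$gene_ids, ds$gene_ids)
  }
})

test_that("missing matrix files raise I/O errors naming the file", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(k = 2, n_rows = 5, n_cols = 5, n_genes = 10)
  write_fixture(ds, dir)
  file.remove(file.path(dir, "features.tsv"))
  expect_error(read_tenx_matrix_dir(dir), "features", class = "mvc_io_error")
  expect_error(read_tenx_matrix_dir(file.path(dir, "nope")),
               class = "mvc_io_error")
})

test_that("tissue positions are matched to barcodes in both dialects", {
  dir <- withr::local_tempdir()
  ds <- st_dataset(matrix(1:6, 3, 2), cbind(1:3, 4:6),
                   spot_ids = c("a", "b", "c"))
  write_fixture(ds, dir)
  # headerless 6-column dialect, scrambled order
  pos <- data.frame(b = c("c", "a", "b"), t = 1, ar = c(30, 10, 20),
                    ac = c(3, 1, 2), pr = c(300, 100, 200),
                    pc = c(30, 10, 20))
  pfile <- file.path(dir, "tissue_positions_list.csv")
  utils::write.table(pos, pfile, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  rd <- read_tenx_matrix_dir(dir)
  expect_equal(unname(rd$coords[, 1]), c(10, 20, 30))  # barcode order kept
  expect_equal(unname(rd$pixel_coords[, 1]), c(100, 200, 300))
  # headered dialect
  file.remove(pfile)
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row_in_fullres", "pxl_col_in_fullres")
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE)
  rd2 <- read_tenx_matrix_dir(dir)
  expect_equal(rd2$coords, rd$coords)
  # a barcode missing from positions is a validation error
  utils::write.csv(pos[1:2, ], file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE)
  expect_error(read_tenx_matrix_dir(dir), "absent",
               class = "mvc_validation_error")
})

test_that("table reader aligns by id intersection and reports parse errors", {
  dir <- withr::local_tempdir()
  ex <- data.frame(spot = paste0("s", 1:5), g1 = 1:5, g2 = 5:1)
  co <- data.frame(spot = paste0("s", 1:5), x = 1:5, y = 0)
  write.csv(ex, file.path(dir, "expr.csv"), row.names = FALSE)
  write.csv(co, file.path(dir, "coords.csv"), row.names = FALSE)
  ds <- read_table_dataset(file.path(dir, "expr.csv"),
                           file.path(dir, "coords.csv"))
  expect_equal(nrow(ds$expression), 5L)

  write.csv(co[1:4, ], file.path(dir, "coords4.csv"), row.names = FALSE)
  expect_message(
    ds4 <- read_table_dataset(file.path(dir, "expr.csv"),
                              file.path(dir, "coords4.csv")),
    "dropped 1")
  expect_equal(ds4$spot_ids, paste0("s", 1:4))

  co_bad <- data.frame(spot = paste0("t", 1:5), x = 1:5, y = 0)
  write.csv(co_bad, file.path(dir, "coords_bad.csv"), row.names = FALSE)
  expect_error(read_table_dataset(file.path(dir, "expr.csv"),
                                  file.path(dir, "coords_bad.csv")),
               "overlap", class = "mvc_validation_error")

  ex_bad <- ex; ex_bad$g1 <- c("1", "2", "oops", "4", "5")
  write.csv(ex_bad, file.path(dir, "expr_bad.csv"), row.names = FALSE)
  expect_error(read_table_dataset(file.path(dir, "expr_bad.csv"),
                                  file.path(dir, "coords.csv")),
               "non-numeric", class = "mvc_validation_error")
})

test_that("write_results is idempotent and validates label lengths", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(k = 2, n_rows = 5, n_cols = 4, n_genes = 10)
  n <- nrow(ds$expression)
  res <- structure(list(view_labels = list(v1 = rep(0:1, length.out = n)),
                        consensus_matrix = diag(n),
                        final_labels = rep(0:1, length.out = n),
                        n_views = 1L, n_clusters = 2L),
                   class = "consensus_result")
  f1 <- write_results(ds, res, dir)
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(lab), n)
  before <- tools::md5sum(file.path(dir, "labels.csv"))
  write_results(ds, res, dir)
  expect_equal(tools::md5sum(file.path(dir, "labels.csv")), before)

  res_bad <- res
  res_bad$final_labels <- res$final_labels[-1]
  expect_error(write_results(ds, res_bad, dir),
               class = "mvc_validation_error")
})

test_that("dataset validation enforces the container invariants", {
  expect_error(st_dataset(matrix(-1, 2, 2), cbind(1:2, 1:2)),
               "non-negative", class = "mvc_validation_error")
  expect_error(st_dataset(matrix(1, 2, 2), cbind(1:3, 1:3)),
               class = "mvc_validation_error")
  expect_error(st_dataset(matrix(1, 2, 2), cbind(1:2, 1:2),
                          spot_ids = c("a", "a")),
               "unique", class = "mvc_validation_error")
  # truth labels canonicalized to 0-based contiguous
  ds <- st_dataset(matrix(1, 3, 2), cbind(1:3, 1:3),
                   truth_labels = c(7, 7, 9))
  expect_equal(ds$truth_labels, c(0L, 0L, 1L))
})
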