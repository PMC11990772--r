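make_test_slice <- function(n = 10, m = 5, seed = 7) {
  set.seed(seed)
  X <- matrix(rpois(n * m, 4), n, m)
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  st_slice(X, coords, spot_ids = paste0("s", seq_len(n)),
           gene_ids = paste0("g", seq_len(m)), slice_id = "fix",
           labels = factor(rep(c("a", "b"), length.out = n)))
}

test_that("slice constructor enforces its invariants", {
  s <- make_test_slice()
  expect_s3_class(s, "st_slice")
  expect_identical(dim(s), c(10L, 5L))
  expect_error(st_slice(matrix(1, 3, 2), matrix(0, 2, 2)), "coords")
  expect_error(st_slice(matrix(1, 2, 2), matrix(0, 2, 2),
                        spot_ids = c("a", "a")), "duplicate-identifier")
  expect_error(st_slice(matrix(c(1, -1, 0, 2), 2, 2), matrix(0, 2, 2)),
               "negative")
  expect_error(st_slice(matrix(NaN, 2, 2), matrix(0, 2, 2)), "finite")
  bad <- make_test_slice(); bad$state <- "mystery"
  expect_error(validate_slice(bad), "state")
})

test_that("h5ad round-trip preserves the slice", {
  s <- make_test_slice()
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_slice_h5ad(s, path)
  r <- load_slice(path, "h5ad", label_key = "label")
  expect_equal(unname(r$X), unname(s$X))
  expect_equal(unname(r$coords), unname(s$coords), tolerance = 1e-12)
  expect_identical(r$spot_ids, s$spot_ids)
  expect_identical(r$gene_ids, s$gene_ids)
  expect_identical(as.character(r$labels), as.character(s$labels))
  expect_identical(r$state, "raw")
  # processing state survives the round trip
  p <- preprocess(s)
  write_slice_h5ad(p, path)
  expect_identical(load_slice(path, "h5ad")$state, "log_normalized")
})

test_that("h5ad files interoperate with python anndata", {
  py <- Sys.which("python")
  s <- make_test_slice()
  path <- withr::local_tempfile(fileext = ".h5ad")
  write_slice_h5ad(s, path)
  out <- withr::local_tempfile(fileext = ".h5ad")
  script <- sprintf(paste0(
    "import anndata as ad, numpy as np, scipy.sparse as sp\n",
    "a = ad.read_h5ad('%s')\n",
    "assert a.shape == (10, 5), a.shape\n",
    "assert a.obsm['spatial'].shape == (10, 2)\n",
    "assert list(a.obs['label'][:2]) == ['a', 'b']\n",
    "a.X = sp.csr_matrix(np.asarray(a.X))\n",
    "a.write_h5ad('%s')\n"), path, out)
  code <- system2(py, c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  status <- attr(code, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(code, collapse = "\n"))
  # read back the python-written CSR variant
  r <- load_slice(out, "h5ad", label_key = "label")
  expect_equal(unname(r$X), unname(s$X))
  expect_identical(r$spot_ids, s$spot_ids)
})

test_that("mtx_dir loading matches the same arrays written as h5ad", {
  s <- make_test_slice()
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(t(s$X), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(s$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(s$spot_ids, file.path(dir, "barcodes.tsv"))
  write.csv(data.frame(spot_id = s$spot_ids, x = s$coords[, 1],
                       y = s$coords[, 2]),
            file.path(dir, "coords.csv"), row.names = FALSE)
  h5 <- withr::local_tempfile(fileext = ".h5ad")
  write_slice_h5ad(s, h5)
  a <- load_slice(h5, "h5ad")
  b <- load_slice(dir, "mtx_dir")
  expect_equal(unname(a$X), unname(b$X))
  expect_identical(a$gene_ids, b$gene_ids)
  expect_identical(a$spot_ids, b$spot_ids)
  expect_equal(unname(a$coords), unname(b$coords), tolerance = 1e-12)
})

test_that("csv loading and error contracts behave", {
  s <- make_test_slice()
  expr <- withr::local_tempfile(fileext = ".csv")
  co <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(s$X)
  rownames(df) <- s$spot_ids
  write.csv(df, expr)
  write.csv(data.frame(spot_id = s$spot_ids, x = s$coords[, 1],
                       y = s$coords[, 2]), co, row.names = FALSE)
  r <- load_slice(expr, "csv", coords_path = co, slice_id = "fix")
  expect_equal(unname(r$X), unname(s$X))
  expect_error(load_slice(expr, "csv"), "coordinate-missing")

  # h5ad without a spatial array errors
  bare <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(bare)
  rhdf5::h5createGroup(bare, "var")
  rhdf5::h5createGroup(bare, "obs")
  rhdf5::h5write(t(s$X), bare, "X")
  rhdf5::h5write(s$gene_ids, bare, "var/_index")
  rhdf5::h5write(s$spot_ids, bare, "obs/_index")
  rhdf5::H5close()
  expect_error(load_slice(bare, "h5ad"), "coordinate-missing")
})
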