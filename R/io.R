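#' Load a spatial transcriptomics slice from disk
#'
#' Reads one slice from an annotated-matrix HDF5 file (h5ad dialect), a
#' MatrixMarket directory, or delimited text, into an [st_slice]. Spot order
#' is preserved as stored in the file.
#'
#' @param path file (h5ad, csv) or directory (mtx_dir) path.
#' @param format one of `"h5ad"`, `"mtx_dir"`, `"csv"`.
#' @param coords_path for `csv` format, path to a coordinate table with
#'   columns `spot_id,x,y`; for `mtx_dir` the default is `coords.csv` inside
#'   the directory.
#' @param slice_id slice name; defaults to the file or directory basename.
#' @param label_key name of an observation column holding per-spot
#'   annotations (h5ad only). `NULL` picks the first categorical column, if
#'   any.
#' @return An [st_slice] in state `"raw"` unless the file declares otherwise.
#' @details
#' For `h5ad`, expression is read from the main matrix slot (dense, CSR or
#' CSC) and coordinates from the observation-level 2-column array named
#' `"spatial"`. For `mtx_dir`, the directory must contain `matrix.mtx[.gz]`
#' (genes x spots, CellRanger orientation), a gene TSV
#' (`genes.tsv`/`features.tsv`), `barcodes.tsv`, and a coordinate CSV.
#' @export
load_slice <- function(path, format = c("h5ad", "mtx_dir", "csv"),
                       coords_path = NULL, slice_id = NULL,
                       label_key = NULL) {
  format <- match.arg(format)
  if (is.null(slice_id))
    slice_id <- sub("\\.(h5ad|csv)$", "", basename(path))
  switch(format,
         h5ad    = load_slice_h5ad(path, slice_id, label_key),
         mtx_dir = load_slice_mtx(path, coords_path, slice_id),
         csv     = load_slice_csv(path, coords_path, slice_id))
}

load_slice_h5ad <- function(path, slice_id, label_key) {
  if (!file.exists(path)) stop("file not found: ", path)
  contents <- rhdf5::h5ls(path)
  entry <- function(group, name) {
    any(contents$group == group & contents$name == name)
  }
  X <- read_h5ad_matrix(path, "X", contents)
  gene_ids <- as.character(rhdf5::h5read(path, "var/_index"))
  spot_ids <- as.character(rhdf5::h5read(path, "obs/_index"))
  if (!entry("/obsm", "spatial"))
    stop("coordinate-missing error: no 'spatial' array under obsm in ", path)
  coords <- t(as.matrix(rhdf5::h5read(path, "obsm/spatial")))

  labels <- NULL
  obs_cols <- contents$name[contents$group == "/obs" & contents$name != "_index"]
  if (is.null(label_key)) {
    cats <- contents$name[contents$group %in% paste0("/obs/", obs_cols) &
                            contents$name == "categories"]
    if (length(cats) > 0) {
      label_key <- sub("^/obs/", "", contents$group[contents$group %in%
                         paste0("/obs/", obs_cols)][1])
    }
  }
  if (!is.null(label_key) && label_key %in% obs_cols) {
    labels <- read_obs_column(path, label_key, contents)
  }
  state <- "raw"
  if (entry("/uns", "processing_state"))
    state <- as.character(rhdf5::h5read(path, "uns/processing_state"))
  st_slice(X, coords, spot_ids = spot_ids, gene_ids = gene_ids,
           slice_id = slice_id, labels = labels, state = state)
}

read_h5ad_matrix <- function(path, name, contents) {
  is_group <- any(contents$group == "/" & contents$name == name &
                    contents$otype == "H5I_GROUP")
  if (!is_group) {
    X <- rhdf5::h5read(path, name)
    if (!is.numeric(X)) stop("parse error: non-numeric expression in ", path)
    return(t(as.matrix(X)))  # HDF5 stores (spots, genes) row-major
  }
  at <- rhdf5::h5readAttributes(path, name)
  enc <- at[["encoding-type"]]
  shape <- as.integer(at[["shape"]])
  data <- as.numeric(rhdf5::h5read(path, paste0(name, "/data")))
  indices <- as.integer(rhdf5::h5read(path, paste0(name, "/indices")))
  indptr <- as.integer(rhdf5::h5read(path, paste0(name, "/indptr")))
  n <- shape[1]; m <- shape[2]
  if (identical(enc, "csr_matrix")) {
    M <- Matrix::sparseMatrix(i = rep(seq_len(n), diff(indptr)),
                              j = indices + 1L, x = data, dims = c(n, m))
  } else if (identical(enc, "csc_matrix")) {
    M <- Matrix::sparseMatrix(j = rep(seq_len(m), diff(indptr)),
                              i = indices + 1L, x = data, dims = c(n, m))
  } else {
    stop("parse error: unsupported matrix encoding '", enc, "'")
  }
  as.matrix(M)
}

read_obs_column <- function(path, key, contents) {
  grp <- paste0("/obs/", key)
  if (any(contents$group == grp & contents$name == "categories")) {
    cats <- as.character(rhdf5::h5read(path, paste0("obs/", key, "/categories")))
    codes <- as.integer(rhdf5::h5read(path, paste0("obs/", key, "/codes")))
    return(factor(cats[codes + 1L], levels = cats))
  }
  as.vector(rhdf5::h5read(path, paste0("obs/", key)))
}

load_slice_mtx <- function(dir, coords_path, slice_id) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  genes <- first_existing(dir, c("genes.tsv", "features.tsv", "genes.tsv.gz",
                                 "features.tsv.gz"))
  barcodes <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(coords_path)) coords_path <- file.path(dir, "coords.csv")
  if (!file.exists(coords_path))
    stop("coordinate-missing error: no coordinate table at ", coords_path)
  M <- Matrix::readMM(mtx)  # genes x spots
  X <- t(as.matrix(M))
  gene_tab <- utils::read.delim(genes, header = FALSE,
                                stringsAsFactors = FALSE)
  gene_ids <- as.character(gene_tab[[1]])
  spot_ids <- as.character(utils::read.delim(barcodes, header = FALSE,
                                             stringsAsFactors = FALSE)[[1]])
  ct <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  coords <- align_coords(ct, spot_ids)
  st_slice(X, coords, spot_ids = spot_ids, gene_ids = gene_ids,
           slice_id = if (is.null(slice_id)) basename(dir) else slice_id)
}

load_slice_csv <- function(path, coords_path, slice_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(coords_path))
    stop("coordinate-missing error: csv format needs a coords_path table")
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("parse error: non-numeric expression values in ", path)
  X <- as.matrix(tab)
  ct <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  coords <- align_coords(ct, rownames(X))
  st_slice(X, coords, spot_ids = rownames(X), gene_ids = colnames(X),
           slice_id = slice_id)
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing file in ", dir, ": expected one of ",
       paste(names, collapse = ", "))
}

align_coords <- function(ct, spot_ids) {
  if (!all(c("spot_id", "x", "y") %in% names(ct)))
    stop("coordinate-missing error: coords table must have spot_id,x,y")
  idx <- match(spot_ids, ct$spot_id)
  if (anyNA(idx))
    stop("coordinate-missing error: coordinates absent for ",
         sum(is.na(idx)), " spots")
  as.matrix(ct[idx, c("x", "y")])
}

#' Write a slice to an annotated-matrix HDF5 file
#'
#' Writes the expression matrix, coordinates, identifiers, labels and the
#' processing state to an h5ad-dialect file readable by the usual Python
#' tooling.
#'
#' @param slice an [st_slice].
#' @param path output path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_slice_h5ad <- function(slice, path) {
  validate_slice(slice)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  set_attr <- function(obj, name, value, scalar = length(value) == 1) {
    if (is.logical(value)) value <- as.integer(value)  # rhdf5 lacks bool attrs
    if (length(value) == 0) {
      # zero-length string array: the attribute is created with an empty
      # dataspace before the (no-op) write step errors — silence it
      value <- as.character(value)
      rhdf5::h5errorHandling(type = "suppress")
      # the attribute is created with an empty dataspace; the no-op write
      # step then errors inside rhdf5, which prints unless captured
      utils::capture.output(
        try(rhdf5::h5writeAttribute(value, obj, name, asScalar = FALSE,
                                    variableLengthString = TRUE,
                                    encoding = "UTF-8"), silent = TRUE),
        type = "message")
      rhdf5::h5errorHandling(type = "normal")
      return(invisible(NULL))
    }
    rhdf5::h5writeAttribute(value, obj, name, asScalar = scalar,
                            variableLengthString = TRUE, encoding = "UTF-8")
  }
  set_attr(h5, "encoding-type", "anndata")
  set_attr(h5, "encoding-version", "0.1.0")

  # X stored dense; R dim (genes, spots) -> HDF5 dataspace (spots, genes)
  rhdf5::h5writeDataset(t(slice$X), h5, "X")
  dX <- rhdf5::H5Dopen(h5, "X")
  set_attr(dX, "encoding-type", "array")
  set_attr(dX, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(dX)

  write_df_group <- function(name, index, columns = list()) {
    rhdf5::h5createGroup(h5, name)
    g <- rhdf5::H5Gopen(h5, name)
    set_attr(g, "encoding-type", "dataframe")
    set_attr(g, "encoding-version", "0.2.0")
    set_attr(g, "_index", "_index")
    set_attr(g, "column-order", as.character(names(columns)), scalar = FALSE)
    write_string_array(h5, paste0(name, "/_index"), index, set_attr)
    for (cn in names(columns)) {
      col <- columns[[cn]]
      cg_name <- paste0(name, "/", cn)
      rhdf5::h5createGroup(h5, cg_name)
      cg <- rhdf5::H5Gopen(h5, cg_name)
      set_attr(cg, "encoding-type", "categorical")
      set_attr(cg, "encoding-version", "0.2.0")
      set_attr(cg, "ordered", FALSE)
      f <- factor(col)
      write_string_array(h5, paste0(cg_name, "/categories"), levels(f),
                         set_attr)
      rhdf5::h5writeDataset(as.integer(f) - 1L, h5, paste0(cg_name, "/codes"))
      cd <- rhdf5::H5Dopen(h5, paste0(cg_name, "/codes"))
      set_attr(cd, "encoding-type", "array")
      set_attr(cd, "encoding-version", "0.2.0")
      rhdf5::H5Dclose(cd)
      rhdf5::H5Gclose(cg)
    }
    rhdf5::H5Gclose(g)
  }
  obs_cols <- list()
  if (!is.null(slice$labels)) obs_cols$label <- slice$labels
  write_df_group("obs", slice$spot_ids, obs_cols)
  write_df_group("var", slice$gene_ids)

  rhdf5::h5createGroup(h5, "obsm")
  gm <- rhdf5::H5Gopen(h5, "obsm")
  set_attr(gm, "encoding-type", "dict")
  set_attr(gm, "encoding-version", "0.1.0")
  rhdf5::H5Gclose(gm)
  rhdf5::h5writeDataset(t(slice$coords), h5, "obsm/spatial")
  ds <- rhdf5::H5Dopen(h5, "obsm/spatial")
  set_attr(ds, "encoding-type", "array")
  set_attr(ds, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(ds)

  rhdf5::h5createGroup(h5, "uns")
  gu <- rhdf5::H5Gopen(h5, "uns")
  set_attr(gu, "encoding-type", "dict")
  set_attr(gu, "encoding-version", "0.1.0")
  rhdf5::H5Gclose(gu)
  write_string_array(h5, "uns/processing_state", slice$state, set_attr,
                     scalar = TRUE)
  write_string_array(h5, "uns/slice_id", slice$slice_id, set_attr,
                     scalar = TRUE)
  invisible(path)
}

write_string_array <- function(h5, name, values, set_attr, scalar = FALSE) {
  rhdf5::h5writeDataset(values, h5, name, variableLengthString = TRUE,
                        encoding = "UTF-8")
  d <- rhdf5::H5Dopen(h5, name)
  set_attr(d, "encoding-type", if (scalar) "string" else "string-array")
  set_attr(d, "encoding-version", "0.2.0")
  rhdf5::H5Dclose(d)
}
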