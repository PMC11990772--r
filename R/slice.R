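#' Construct a spatial transcriptomics slice
#'
#' A slice bundles a spots-by-genes expression matrix with 2-D spot
#' coordinates and identifiers. It is the unit of integration: every
#' downstream step (graph construction, encoding, alignment) operates on one
#' or more slices sharing a gene space.
#'
#' @param X numeric spots x genes matrix (dense or `dgCMatrix`), raw counts
#'   or normalized values.
#' @param coords numeric spots x 2 matrix of spatial coordinates.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   rownames of `X` or `spot_1 ... spot_n`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   colnames of `X` or `gene_1 ... gene_m`.
#' @param slice_id single string naming the slice.
#' @param labels optional per-spot annotation (factor or character).
#' @param state processing state: `"raw"`, `"normalized"` or
#'   `"log_normalized"`.
#' @return An object of class `st_slice`.
#' @export
st_slice <- function(X, coords, spot_ids = NULL, gene_ids = NULL,
                     slice_id = "slice", labels = NULL, state = "raw") {
  if (inherits(X, "sparseMatrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(spot_ids)) {
    spot_ids <- rownames(X)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(X)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(X)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(X)))
  }
  obj <- structure(
    list(X = X, coords = coords, spot_ids = as.character(spot_ids),
         gene_ids = as.character(gene_ids), slice_id = as.character(slice_id),
         labels = labels, state = state),
    class = "st_slice"
  )
  validate_slice(obj)
  rownames(obj$X) <- obj$spot_ids
  colnames(obj$X) <- obj$gene_ids
  rownames(obj$coords) <- obj$spot_ids
  obj
}

#' Validate the internal consistency of a slice
#'
#' Checks the shape and value invariants: matching spot/gene counts across
#' fields, unique identifiers, finite expression, nonnegative values before
#' the log transform, and a recognised processing state.
#'
#' @param slice an `st_slice`.
#' @return `slice`, invisibly; errors if an invariant is violated.
#' @export
validate_slice <- function(slice) {
  stopifnot(inherits(slice, "st_slice"))
  n <- nrow(slice$X)
  if (length(slice$spot_ids) != n)
    stop("slice '", slice$slice_id, "': spot_ids length != nrow(X)")
  if (nrow(slice$coords) != n || ncol(slice$coords) != 2)
    stop("slice '", slice$slice_id, "': coords must be n x 2")
  if (length(slice$gene_ids) != ncol(slice$X))
    stop("slice '", slice$slice_id, "': gene_ids length != ncol(X)")
  if (anyDuplicated(slice$spot_ids))
    stop("duplicate-identifier error: duplicated spot ids in slice '",
         slice$slice_id, "'")
  if (anyDuplicated(slice$gene_ids))
    stop("duplicate-identifier error: duplicated gene ids in slice '",
         slice$slice_id, "'")
  if (!all(is.finite(slice$X)))
    stop("slice '", slice$slice_id, "': non-finite expression values")
  if (!slice$state %in% c("raw", "normalized", "log_normalized"))
    stop("slice '", slice$slice_id, "': unknown processing state '",
         slice$state, "'")
  if (slice$state != "log_normalized" && any(slice$X < 0))
    stop("slice '", slice$slice_id, "': negative expression values before ",
         "log transform")
  if (!is.null(slice$labels) && length(slice$labels) != n)
    stop("slice '", slice$slice_id, "': labels length != number of spots")
  invisible(slice)
}

#' @export
print.st_slice <- function(x, ...) {
  cat("<st_slice> '", x$slice_id, "': ", nrow(x$X), " spots x ", ncol(x$X),
      " genes [", x$state, "]", sep = "")
  if (!is.null(x$labels)) {
    cat(", labels: ", length(unique(x$labels)), " categories", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.st_slice <- function(x) dim(x$X)
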