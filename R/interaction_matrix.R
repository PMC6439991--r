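#' Binary interaction matrix between two node types
#'
#' An `interaction_matrix` is a sparse 0/1 adjacency matrix between two
#' universes of entities (drugs, proteins or diseases), with stable,
#' lexicographically sorted identifier registries on both axes. It is the
#' building block of the heterogeneous drug-protein-disease network: the
#' drug-protein layer, the disease-protein layer and the drug-disease
#' treatment layer are each one `interaction_matrix`.
#'
#' @param values a matrix (dense or `Matrix` sparse) of 0/1 entries with
#'   rownames and colnames set to the entity identifiers.
#' @param row_type,col_type node-type labels, each one of `"Drug"`,
#'   `"Protein"`, `"Disease"`.
#' @return an object of class `interaction_matrix`: a list with elements
#'   `values` (a `dgCMatrix`), `row_ids`, `col_ids`, `row_type`, `col_type`.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("d1", "d2"), c("p1", "p2")))
#' im <- interaction_matrix(m, "Drug", "Protein")
#' n_edges(im)
#' @export
interaction_matrix <- function(values, row_type, col_type) {
  row_type <- match.arg(row_type, c("Drug", "Protein", "Disease"))
  col_type <- match.arg(col_type, c("Drug", "Protein", "Disease"))
  values <- as_dgc(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("interaction_matrix requires row and column identifiers (dimnames)")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate identifiers in registry")
  v <- values@x
  if (length(v) && !all(v %in% c(0, 1)))
    stop("interaction_matrix entries must be 0 or 1")
  values <- Matrix::drop0(values)
  structure(
    list(values = values,
         row_ids = rownames(values), col_ids = colnames(values),
         row_type = row_type, col_type = col_type),
    class = "interaction_matrix")
}

#' @exportS3Method base::print
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %s x %s: %d x %d, %d interactions (density %.4g)\n",
              x$row_type, x$col_type, nrow(x$values), ncol(x$values),
              n_edges(x),
              compute_density(n_edges(x), nrow(x$values), ncol(x$values))))
  invisible(x)
}

#' Number of interactions in a layer
#'
#' @param x an `interaction_matrix`.
#' @return integer count of nonzero (present) interactions.
#' @export
n_edges <- function(x) {
  stopifnot(inherits(x, "interaction_matrix"))
  as.integer(Matrix::nnzero(x$values))
}

#' Read a two-column interaction edge list
#'
#' Parses a tab-separated edge list into a binary [interaction_matrix()].
#' Lines starting with `#` are skipped; an optional single header line can
#' be skipped with `header = TRUE`. Each remaining line must have at least
#' two tab-separated fields (row identifier, column identifier); extra
#' fields are ignored. Duplicate edges collapse to a single interaction.
#' Registries are the sorted unique identifiers seen in the file
#' (byte-wise/radix order, so indices are locale-independent).
#'
#' @param path path to a UTF-8 TSV file.
#' @param row_type,col_type node-type labels for the two columns.
#' @param header if `TRUE`, the first non-comment line is discarded.
#' @return an `interaction_matrix`.
#' @export
read_edge_list <- function(path, row_type, col_type, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (header && length(idx)) idx <- idx[-1L]
  if (!length(idx)) stop("no interaction records in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) sum(nzchar(trimws(f))) < 2L, logical(1)))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields",
                 idx[bad[1L]], path))
  from <- trimws(vapply(fields, `[[`, "", 1L))
  to <- trimws(vapply(fields, `[[`, "", 2L))
  edges_to_matrix(from, to, row_type, col_type)
}

# Coerce any matrix-like input to numeric general column-sparse form.
as_dgc <- function(m) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# Build a deduplicated binary sparse matrix from parallel id vectors.
edges_to_matrix <- function(from, to, row_type, col_type) {
  row_ids <- sort(unique(from), method = "radix")
  col_ids <- sort(unique(to), method = "radix")
  m <- Matrix::sparseMatrix(
    i = match(from, row_ids), j = match(to, col_ids), x = 1,
    dims = c(length(row_ids), length(col_ids)),
    dimnames = list(row_ids, col_ids), use.last.ij = TRUE)
  m@x[] <- 1  # repeated edges may have summed; clamp back to binary
  interaction_matrix(m, row_type, col_type)
}

#' Write an interaction matrix back to a two-column edge list
#'
#' Inverse of [read_edge_list()]: emits one `row_id<TAB>col_id` line per
#' interaction, in (row, column) registry order, so that reloading the file
#' reproduces an identical matrix.
#'
#' @param x an `interaction_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "interaction_matrix"))
  tm <- Matrix::which(x$values != 0, arr.ind = TRUE)
  tm <- tm[order(tm[, 1L], tm[, 2L]), , drop = FALSE]
  writeLines(paste(x$row_ids[tm[, 1L]], x$col_ids[tm[, 2L]], sep = "\t"), path)
  invisible(path)
}

#' Interaction density of a layer
#'
#' Density is the number of known interactions divided by the number of
#' possible pairs between the two universes.
#'
#' @param n_edges number of known interactions.
#' @param n_rows,n_cols sizes of the two universes.
#' @return `n_edges / (n_rows * n_cols)`.
#' @examples
#' compute_density(4642, 1186, 1147) # drug-protein layer, ~0.0034
#' @export
compute_density <- function(n_edges, n_rows, n_cols) {
  if (n_rows <= 0 || n_cols <= 0) stop("universe dimensions must be positive")
  if (n_edges < 0 || n_edges > n_rows * n_cols)
    stop("edge count outside [0, n_rows * n_cols]")
  n_edges / (n_rows * n_cols)
}
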