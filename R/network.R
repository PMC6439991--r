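#' Assemble the heterogeneous drug-protein-disease network
#'
#' Aligns the three interaction layers onto shared identifier registries:
#' the drug registry is the union of drug-protein rows and drug-disease
#' rows, the protein registry the union of the two protein axes, and the
#' disease registry the union of disease-protein rows and drug-disease
#' columns. Entities absent from a layer get all-zero rows/columns, so the
#' three matrices become dimension-compatible for meta-path products. All
#' registries are sorted (radix order) for reproducible indexing.
#'
#' @param A_dp drug x protein [interaction_matrix()].
#' @param A_sp disease x protein `interaction_matrix`.
#' @param A_ds drug x disease `interaction_matrix`.
#' @return an object of class `hetero_network`: a list with the three
#'   aligned `interaction_matrix` layers plus the `drugs`, `proteins`,
#'   `diseases` registries.
#' @export
build_network <- function(A_dp, A_sp, A_ds) {
  stopifnot(inherits(A_dp, "interaction_matrix"),
            inherits(A_sp, "interaction_matrix"),
            inherits(A_ds, "interaction_matrix"))
  want <- function(x, rt, ct) {
    if (x$row_type != rt || x$col_type != ct)
      stop(sprintf("layer typed %s x %s where %s x %s expected",
                   x$row_type, x$col_type, rt, ct))
  }
  want(A_dp, "Drug", "Protein")
  want(A_sp, "Disease", "Protein")
  want(A_ds, "Drug", "Disease")
  drugs    <- sort(union(A_dp$row_ids, A_ds$row_ids), method = "radix")
  proteins <- sort(union(A_dp$col_ids, A_sp$col_ids), method = "radix")
  diseases <- sort(union(A_sp$row_ids, A_ds$col_ids), method = "radix")
  structure(
    list(A_dp = reindex_layer(A_dp, drugs, proteins),
         A_sp = reindex_layer(A_sp, diseases, proteins),
         A_ds = reindex_layer(A_ds, drugs, diseases),
         drugs = drugs, proteins = proteins, diseases = diseases),
    class = "hetero_network")
}

# Embed a layer into enlarged registries, padding absent entities with zeros.
reindex_layer <- function(x, row_ids, col_ids) {
  ij <- Matrix::which(x$values != 0, arr.ind = TRUE)
  ri <- match(x$row_ids, row_ids)
  ci <- match(x$col_ids, col_ids)
  if (anyNA(ri) || anyNA(ci))
    stop("target registries must contain all existing identifiers")
  m <- Matrix::sparseMatrix(
    i = ri[ij[, 1L]], j = ci[ij[, 2L]], x = rep(1, nrow(ij)),
    dims = c(length(row_ids), length(col_ids)),
    dimnames = list(row_ids, col_ids))
  interaction_matrix(m, x$row_type, x$col_type)
}

#' @exportS3Method base::print
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network> %d drugs, %d proteins, %d diseases\n",
              length(x$drugs), length(x$proteins), length(x$diseases)))
  s <- network_summary(x)
  cat(sprintf("  %-18s %6d interactions (density %.4f)\n",
              s$layer, s$interactions, s$density), sep = "")
  invisible(x)
}

#' Descriptive statistics of a heterogeneous network
#'
#' Node counts per type plus, for each interaction layer, the number of
#' known interactions and its density over the full aligned universes.
#'
#' @param network a `hetero_network`.
#' @return a data.frame with one row per layer (`drug-protein`,
#'   `disease-protein`, `drug-disease`) and columns `layer`, `n_rows`,
#'   `n_cols`, `interactions`, `density`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "hetero_network"))
  layer_stats <- function(name, m) {
    data.frame(layer = name, n_rows = nrow(m$values), n_cols = ncol(m$values),
               interactions = n_edges(m),
               density = compute_density(n_edges(m), nrow(m$values), ncol(m$values)))
  }
  rbind(layer_stats("drug-protein", network$A_dp),
        layer_stats("disease-protein", network$A_sp),
        layer_stats("drug-disease", network$A_ds))
}

#' Read a heterogeneous network from three edge-list files
#'
#' Convenience wrapper: [read_edge_list()] on the three layers followed by
#' [build_network()].
#'
#' @param dp_path,sp_path,ds_path paths to the drug-protein,
#'   disease-protein and drug-disease TSV edge lists.
#' @param header passed to [read_edge_list()].
#' @return a `hetero_network`.
#' @export
read_network <- function(dp_path, sp_path, ds_path, header = FALSE) {
  build_network(read_edge_list(dp_path, "Drug", "Protein", header = header),
                read_edge_list(sp_path, "Disease", "Protein", header = header),
                read_edge_list(ds_path, "Drug", "Disease", header = header))
}

#' Write a heterogeneous network as three edge-list files
#'
#' @param network a `hetero_network`.
#' @param dir output directory (created if missing); files are
#'   `drug_protein.tsv`, `disease_protein.tsv`, `drug_disease.tsv`.
#' @return the three file paths, invisibly.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "hetero_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("drug_protein.tsv", "disease_protein.tsv",
                            "drug_disease.tsv"))
  write_edge_list(network$A_dp, paths[1L])
  write_edge_list(network$A_sp, paths[2L])
  write_edge_list(network$A_ds, paths[3L])
  invisible(paths)
}

# Replace the drug-disease layer, e.g. with test-fold edges masked out.
replace_ds_layer <- function(network, values) {
  network$A_ds <- interaction_matrix(values, "Drug", "Disease")
  network
}
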