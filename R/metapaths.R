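#' Meta paths over the drug-protein-disease network
#'
#' Five drug-to-disease meta paths of length at most three are used, each
#' summarising one way a drug can reach a disease through the heterogeneous
#' network:
#'
#' * `MP1` Drug -(treats)-> Disease
#' * `MP2` Drug -(binds to)-> Protein -(causes)-> Disease
#' * `MP3` Drug -(binds to)-> Protein -(binds to)-> Drug -(treats)-> Disease
#' * `MP4` Drug -(treats)-> Disease -(treated by)-> Drug -(treats)-> Disease
#' * `MP5` Drug -(treats)-> Disease -(caused by)-> Protein -(causes)-> Disease
#'
#' @format `METAPATHS` is the character vector `c("MP1", ..., "MP5")`.
#' @export
METAPATHS <- c("MP1", "MP2", "MP3", "MP4", "MP5")

#' @rdname METAPATHS
#' @param metapath a meta-path identifier, one of `METAPATHS`.
#' @return `metapath_definition()` returns the node-type sequence of the
#'   meta path (drug first, disease last).
#' @export
metapath_definition <- function(metapath) {
  switch(match.arg(metapath, METAPATHS),
         MP1 = c("Drug", "Disease"),
         MP2 = c("Drug", "Protein", "Disease"),
         MP3 = c("Drug", "Protein", "Drug", "Disease"),
         MP4 = c("Drug", "Disease", "Drug", "Disease"),
         MP5 = c("Drug", "Disease", "Protein", "Disease"))
}

#' Commuting matrix of a meta path
#'
#' The commuting matrix of a meta path is the product of the adjacency
#' matrices along its node-type sequence; entry (i, j) counts the path
#' instances (walks -- intermediate nodes may repeat) from drug i to
#' disease j that match the template. The five products are
#' `MP1 = A_ds`, `MP2 = A_dp A_sp'`, `MP3 = A_dp A_dp' A_ds`,
#' `MP4 = A_ds A_ds' A_ds`, `MP5 = A_ds A_sp A_sp'`.
#'
#' @param network an aligned [build_network()] result.
#' @param metapath one of `"MP1"`..`"MP5"`.
#' @return an object of class `commuting_matrix`: a list with `values`
#'   (sparse nonnegative integer drug x disease matrix), `metapath`,
#'   `drug_ids`, `disease_ids`.
#' @examples
#' net <- generate_network(synthetic_config(20, 15, 10, seed = 1))$network
#' X2 <- commuting_matrix(net, "MP2")
#' max(X2$values) # most overlapping proteins over any drug-disease pair
#' @export
commuting_matrix <- function(network, metapath) {
  stopifnot(inherits(network, "hetero_network"))
  metapath <- match.arg(metapath, METAPATHS)
  dp <- network$A_dp$values
  sp <- network$A_sp$values
  ds <- network$A_ds$values
  x <- switch(metapath,
              MP1 = ds,
              MP2 = dp %*% Matrix::t(sp),
              MP3 = dp %*% Matrix::t(dp) %*% ds,
              MP4 = ds %*% Matrix::t(ds) %*% ds,
              MP5 = ds %*% sp %*% Matrix::t(sp))
  x <- as_dgc(x)
  dimnames(x) <- list(network$drugs, network$diseases)
  structure(list(values = x, metapath = metapath,
                 drug_ids = network$drugs, disease_ids = network$diseases),
            class = "commuting_matrix")
}

#' @exportS3Method base::print
print.commuting_matrix <- function(x, ...) {
  cat(sprintf("<commuting_matrix> %s: %d drugs x %d diseases, %d nonzero, max count %d\n",
              x$metapath, nrow(x$values), ncol(x$values),
              Matrix::nnzero(x$values),
              if (Matrix::nnzero(x$values)) as.integer(max(x$values)) else 0L))
  invisible(x)
}

#' Enumerate path instances between one drug and one disease
#'
#' Reference implementation of path-instance counting by explicit
#' enumeration of node sequences, independent of the matrix products in
#' [commuting_matrix()]. Every concrete walk whose node types match the
#' meta-path template is counted; nodes may repeat along the walk (the
#' `MP4` walk d -> s -> d -> s is a valid instance). Intended for
#' cross-checking on small networks; cost grows with the product of the
#' intermediate universe sizes.
#'
#' @param network an aligned `hetero_network`.
#' @param metapath one of `"MP1"`..`"MP5"`.
#' @param drug,disease 1-based indices into the drug and disease registries.
#' @return integer path-instance count.
#' @export
count_path_instances <- function(network, metapath, drug, disease) {
  stopifnot(inherits(network, "hetero_network"))
  metapath <- match.arg(metapath, METAPATHS)
  dp <- as.matrix(network$A_dp$values) != 0
  sp <- as.matrix(network$A_sp$values) != 0
  ds <- as.matrix(network$A_ds$values) != 0
  if (drug < 1L || drug > nrow(ds) || disease < 1L || disease > ncol(ds))
    stop("drug or disease index out of range")
  count <- 0L
  switch(metapath,
    MP1 = {
      if (ds[drug, disease]) count <- count + 1L
    },
    MP2 = {  # drug -> p -> disease
      for (p in seq_len(ncol(dp)))
        if (dp[drug, p] && sp[disease, p]) count <- count + 1L
    },
    MP3 = {  # drug -> p -> d2 -> disease
      for (p in seq_len(ncol(dp)))
        for (d2 in seq_len(nrow(dp)))
          if (dp[drug, p] && dp[d2, p] && ds[d2, disease]) count <- count + 1L
    },
    MP4 = {  # drug -> s2 -> d2 -> disease
      for (s2 in seq_len(ncol(ds)))
        for (d2 in seq_len(nrow(ds)))
          if (ds[drug, s2] && ds[d2, s2] && ds[d2, disease]) count <- count + 1L
    },
    MP5 = {  # drug -> s2 -> p -> disease
      for (s2 in seq_len(ncol(ds)))
        for (p in seq_len(ncol(sp)))
          if (ds[drug, s2] && sp[s2, p] && sp[disease, p]) count <- count + 1L
    })
  count
}

#' Export a commuting matrix in MatrixMarket format
#'
#' @param x a `commuting_matrix`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_commuting_matrix <- function(x, path) {
  stopifnot(inherits(x, "commuting_matrix"))
  Matrix::writeMM(x$values, path)
  invisible(path)
}
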