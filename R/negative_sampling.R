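#' Reliable negative drug-disease pairs
#'
#' The treatment layer provides positives only; every other pair is merely
#' unlabeled, and some unlabeled pairs are undiscovered positives. Under
#' the assumption that a drug and a disease with no common interacting
#' protein are unlikely to stand in a treatment relation, the unlabeled
#' pairs whose drug-bound protein set and disease-associated protein set
#' are disjoint are taken as reliable negatives. Disjointness is tested on
#' the full drug-protein and disease-protein layers (those layers are
#' never held out during cross-validation).
#'
#' @param network an aligned `hetero_network`.
#' @return integer matrix with columns `drug`, `disease`: all pairs with
#'   no treat edge and zero protein overlap, ordered by (drug, disease).
#' @export
reliable_negatives <- function(network) {
  stopifnot(inherits(network, "hetero_network"))
  overlap <- network$A_dp$values %*% Matrix::t(network$A_sp$values)
  excluded <- overlap + network$A_ds$values  # nonzero iff treat edge or shared protein
  complement_pairs(excluded, nrow(overlap), ncol(overlap))
}

#' All unlabeled drug-disease pairs
#'
#' The candidate pool of the conventional "random" negative-sampling
#' strategy: every pair without a known treat edge, regardless of protein
#' overlap.
#'
#' @inheritParams reliable_negatives
#' @return integer matrix with columns `drug`, `disease`.
#' @export
unlabeled_pairs <- function(network) {
  stopifnot(inherits(network, "hetero_network"))
  complement_pairs(network$A_ds$values,
                   nrow(network$A_ds$values), ncol(network$A_ds$values))
}

# Pairs (i, j) where the sparse matrix m is zero, as an ordered pair matrix.
# Works on the nonzero pattern only; never materialises a dense m x n logical.
complement_pairs <- function(m, n_rows, n_cols) {
  nz <- Matrix::which(m != 0)
  lin <- setdiff(seq_len(n_rows * n_cols), nz)
  out <- cbind(drug = ((lin - 1L) %% n_rows) + 1L,
               disease = ((lin - 1L) %/% n_rows) + 1L)
  as_pair_matrix(out[order(out[, 1L], out[, 2L]), , drop = FALSE])
}

#' Sample negatives from a candidate pool
#'
#' Uniform sample of pairs without replacement, deterministic given the
#' seed. Used to draw a balanced negative set of the same size as the
#' positives.
#'
#' @param candidates pair matrix (columns drug, disease), e.g. from
#'   [reliable_negatives()] or [unlabeled_pairs()].
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return integer pair matrix with `n` rows.
#' @export
sample_negatives <- function(candidates, n, seed) {
  candidates <- as_pair_matrix(candidates)
  if (n > nrow(candidates))
    stop(sprintf("requested %d negatives but only %d candidates available (short by %d)",
                 n, nrow(candidates), n - nrow(candidates)))
  idx <- with_seed(seed, sample.int(nrow(candidates), n))
  candidates[idx, , drop = FALSE]
}

#' Draw random negatives from the unlabeled pairs
#'
#' The conventional baseline strategy: negatives drawn uniformly from all
#' pairs without a known treat edge.
#'
#' @inheritParams reliable_negatives
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return integer pair matrix with `n` rows.
#' @export
random_unlabeled_negatives <- function(network, n, seed) {
  pool <- unlabeled_pairs(network)
  if (nrow(pool) == 0L) stop("no unlabeled pairs: every pair is a known positive")
  sample_negatives(pool, n, seed)
}

#' Negative candidate pool for a named strategy
#'
#' @inheritParams reliable_negatives
#' @param strategy `"reliable"` (no-common-protein filter) or `"random"`
#'   (all unlabeled pairs).
#' @return integer pair matrix.
#' @export
negative_candidates <- function(network, strategy = c("reliable", "random")) {
  switch(match.arg(strategy),
         reliable = reliable_negatives(network),
         random = unlabeled_pairs(network))
}
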