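#' Truncated SVD of a commuting matrix
#'
#' Factorises a drug x disease commuting matrix X as U S V' and keeps the
#' top `r` singular triplets, where the retained rank is
#' `r = max(1, floor(latent_feature_percent * min(m, n)))`. Rows of the
#' truncated U are the latent drug features, rows of the truncated V the
#' latent disease features. Sign ambiguity is resolved deterministically:
#' each left singular vector is flipped so that its largest-magnitude
#' entry (smallest index on ties) is positive, and the matching right
#' vector is flipped with it, so repeated runs produce bit-identical
#' features.
#'
#' @param X a [commuting_matrix()] or a plain numeric matrix.
#' @param latent_feature_percent fraction of `min(m, n)` retained as the
#'   rank, in (0, 1); the reference setting is 0.03.
#' @return an object of class `latent_features`: list with `U` (m x r),
#'   `d` (r singular values, descending), `V` (n x r), `r`,
#'   `latent_feature_percent`, `metapath`, `drug_ids`, `disease_ids`.
#' @export
truncated_svd <- function(X, latent_feature_percent = 0.03) {
  if (inherits(X, "commuting_matrix")) {
    metapath <- X$metapath
    drug_ids <- X$drug_ids
    disease_ids <- X$disease_ids
    M <- as.matrix(X$values)
  } else {
    metapath <- NA_character_
    M <- as.matrix(X)
    drug_ids <- rownames(M)
    disease_ids <- colnames(M)
  }
  if (!(latent_feature_percent > 0 && latent_feature_percent < 1))
    stop("latent_feature_percent must lie strictly between 0 and 1")
  if (all(M == 0))
    stop("commuting matrix is all zero: this meta path carries no ",
         "information on this network")
  r <- max(1L, as.integer(floor(latent_feature_percent * min(dim(M)))))
  s <- svd(M, nu = r, nv = r)
  U <- s$u
  V <- s$v
  for (k in seq_len(r)) {  # deterministic sign convention
    pivot <- which.max(abs(U[, k]))
    if (U[pivot, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  rownames(U) <- drug_ids
  rownames(V) <- disease_ids
  structure(list(U = U, d = s$d[seq_len(r)], V = V, r = r,
                 latent_feature_percent = latent_feature_percent,
                 metapath = metapath,
                 drug_ids = drug_ids, disease_ids = disease_ids),
            class = "latent_features")
}

#' @exportS3Method base::print
print.latent_features <- function(x, ...) {
  cat(sprintf("<latent_features> %s: rank %d (%.3g%% of min(%d, %d)), top singular value %.4g\n",
              x$metapath, x$r, 100 * x$latent_feature_percent,
              nrow(x$U), nrow(x$V), x$d[1L]))
  invisible(x)
}

#' Latent feature vector of one drug-disease pair
#'
#' Concatenates row `drug` of the truncated U with row `disease` of the
#' truncated V, giving a vector of length `2 * r`. Features are the raw
#' singular-vector rows, not scaled by the singular values.
#'
#' @param latent a [truncated_svd()] result.
#' @param drug,disease 1-based indices into the drug and disease registries.
#' @return numeric vector of length `2 * latent$r`.
#' @export
pair_feature_vector <- function(latent, drug, disease) {
  stopifnot(inherits(latent, "latent_features"))
  if (drug < 1L || drug > nrow(latent$U)) stop("drug index out of range")
  if (disease < 1L || disease > nrow(latent$V)) stop("disease index out of range")
  c(latent$U[drug, ], latent$V[disease, ])
}

#' Latent feature table for a set of drug-disease pairs
#'
#' @param latent a [truncated_svd()] result.
#' @param pairs integer matrix with two columns (drug index, disease index),
#'   one row per pair.
#' @return numeric matrix `nrow(pairs) x 2r`, rows in input order; columns
#'   named `u1..ur, v1..vr`.
#' @export
feature_table <- function(latent, pairs) {
  stopifnot(inherits(latent, "latent_features"))
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) &&
      (max(pairs[, 1L]) > nrow(latent$U) || max(pairs[, 2L]) > nrow(latent$V) ||
       min(pairs) < 1L))
    stop("pair index out of range")
  out <- cbind(latent$U[pairs[, 1L], , drop = FALSE],
               latent$V[pairs[, 2L], , drop = FALSE])
  dimnames(out) <- list(NULL, c(paste0("u", seq_len(latent$r)),
                                paste0("v", seq_len(latent$r))))
  out
}

# Normalise pair input to an integer matrix with columns drug, disease.
as_pair_matrix <- function(pairs) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns (drug, disease)")
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("drug", "disease")
  pairs
}

#' Fraction of singular mass retained by a truncation
#'
#' Diagnostic used when choosing `latent_feature_percent`: the share of the
#' total singular-value sum captured by the retained rank.
#'
#' @param X a commuting matrix (or plain matrix).
#' @param latent_feature_percent truncation fraction.
#' @return fraction in (0, 1].
#' @export
singular_mass_retained <- function(X, latent_feature_percent = 0.03) {
  M <- if (inherits(X, "commuting_matrix")) as.matrix(X$values) else as.matrix(X)
  d <- svd(M, nu = 0, nv = 0)$d
  r <- max(1L, as.integer(floor(latent_feature_percent * min(dim(M)))))
  sum(d[seq_len(r)]) / sum(d)
}
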