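#' Train one meta-path base classifier
#'
#' Fits a 256-tree probability random forest (via \pkg{ranger}) on latent
#' feature vectors. The positive-class score of a pair is the forest's
#' predicted positive probability. Training is single-threaded with a
#' fixed seed, so refitting on identical input reproduces identical
#' scores.
#'
#' @param features numeric matrix, one row per training pair.
#' @param labels 0/1 (or logical) labels, one per row; both classes must
#'   be present.
#' @param seed integer seed for the forest.
#' @param num_trees number of trees (default 256).
#' @param metapath optional meta-path identifier recorded on the model.
#' @return an object of class `base_classifier`.
#' @export
train_base <- function(features, labels, seed, num_trees = 256L,
                       metapath = NA_character_) {
  features <- as.matrix(features)
  labels <- as.integer(as.logical(labels))
  if (nrow(features) != length(labels))
    stop("features rows and labels length differ")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train a base classifier")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- ranger::ranger(x = features,
                        y = factor(labels, levels = c(0L, 1L)),
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, metapath = metapath, seed = seed,
                 num_trees = num_trees,
                 feature_names = colnames(features)),
            class = "base_classifier")
}

#' Positive-class scores from a base classifier
#'
#' @param object a [train_base()] model.
#' @param features numeric matrix of pair feature vectors.
#' @param ... unused.
#' @return numeric vector of positive probabilities in \[0, 1\].
#' @export
predict.base_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  colnames(features) <- object$feature_names
  p <- stats::predict(object$fit, data = features,
                      num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

#' Train the five-path ensemble on a network
#'
#' Builds the five commuting matrices of the (possibly masked) network,
#' extracts truncated-SVD latent features per meta path, and trains one
#' base random forest per path on the given labelled pairs. The ensemble
#' score of a pair is the unweighted mean of the five per-path scores.
#' Per-path forest seeds are derived deterministically from the master
#' seed and the path index.
#'
#' @param network an aligned `hetero_network` (mask held-out treat edges
#'   beforehand if evaluation pairs overlap the treatment layer).
#' @param pairs integer pair matrix (columns drug, disease) of training
#'   pairs.
#' @param labels 0/1 labels for `pairs`.
#' @param latent_feature_percent truncation fraction (default 0.03).
#' @param seed master integer seed.
#' @param num_trees trees per forest (default 256).
#' @return an object of class `ensemble_model`: list with `bases` and
#'   `latents` (both named MP1..MP5), `threshold` (NA until
#'   [calibrate_threshold()] is called), and the settings.
#' @export
train_ensemble <- function(network, pairs, labels,
                           latent_feature_percent = 0.03, seed = 1L,
                           num_trees = 256L) {
  stopifnot(inherits(network, "hetero_network"))
  pairs <- as_pair_matrix(pairs)
  latents <- lapply(METAPATHS, function(mp)
    truncated_svd(commuting_matrix(network, mp), latent_feature_percent))
  names(latents) <- METAPATHS
  bases <- lapply(seq_along(METAPATHS), function(i)
    train_base(feature_table(latents[[i]], pairs), labels,
               seed = derive_seed(seed, 31, i), num_trees = num_trees,
               metapath = METAPATHS[i]))
  names(bases) <- METAPATHS
  structure(list(bases = bases, latents = latents, threshold = NA_real_,
                 settings = list(latent_feature_percent = latent_feature_percent,
                                 seed = seed, num_trees = num_trees),
                 drug_ids = network$drugs, disease_ids = network$diseases),
            class = "ensemble_model")
}

#' @exportS3Method base::print
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> 5 meta-path forests (%d trees each), rank %d features, threshold %s\n",
              x$settings$num_trees, x$latents[[1L]]$r,
              if (is.na(x$threshold)) "unset" else format(x$threshold, digits = 3)))
  invisible(x)
}

# Per-path and ensemble scores for a pair matrix; columns MP1..MP5, ensemble.
predict_scores <- function(model, pairs) {
  stopifnot(inherits(model, "ensemble_model"))
  pairs <- as_pair_matrix(pairs)
  per_path <- vapply(METAPATHS, function(mp)
    predict(model$bases[[mp]], feature_table(model$latents[[mp]], pairs)),
    numeric(nrow(pairs)))
  per_path <- matrix(per_path, nrow = nrow(pairs),
                     dimnames = list(NULL, METAPATHS))
  cbind(per_path, ensemble = rowMeans(per_path))
}

#' Ensemble score of drug-disease pairs
#'
#' The ensemble score is the arithmetic mean of the five meta-path base
#' classifiers' positive probabilities.
#'
#' @param model a trained [train_ensemble()] model.
#' @param pairs integer pair matrix (columns drug, disease).
#' @return numeric vector of ensemble scores in \[0, 1\].
#' @export
ensemble_score <- function(model, pairs) {
  if (!inherits(model, "ensemble_model") || is.null(model$bases))
    stop("model is not a trained ensemble")
  predict_scores(model, pairs)[, "ensemble"]
}

#' F1-maximising decision threshold
#'
#' Scans the candidate thresholds (midpoints of adjacent sorted unique
#' scores, plus one cut below the minimum and one above the maximum) and
#' returns the one maximising the F1-measure of the rule
#' `score > threshold => positive`. Ties are broken toward the smallest
#' threshold. With a single distinct score no cut can separate anything
#' and the below-minimum threshold is returned with a warning.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) true labels.
#' @return list with `threshold` and the achieved `f1`.
#' @export
choose_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical; no threshold separates the classes")
    return(list(threshold = u - 1, f1 = f1_at(scores, labels, u - 1)))
  }
  cands <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  f1s <- vapply(cands, function(t) f1_at(scores, labels, t), numeric(1))
  best <- which.max(f1s)  # which.max takes the first, i.e. smallest, maximiser
  list(threshold = cands[best], f1 = f1s[best])
}

# F1 of the rule score > threshold; 0 when no true positive is recovered.
f1_at <- function(scores, labels, threshold) {
  pred <- scores > threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Calibrate the ensemble decision threshold
#'
#' Scores the given labelled pairs and stores the F1-maximising threshold
#' on the model.
#'
#' @param model a trained `ensemble_model`.
#' @param pairs labelled pair matrix.
#' @param labels 0/1 labels.
#' @return the model with `threshold` set.
#' @export
calibrate_threshold <- function(model, pairs, labels) {
  sc <- ensemble_score(model, pairs)
  model$threshold <- choose_threshold(sc, labels)$threshold
  model
}

#' Rank unlabeled drug-disease pairs by ensemble score
#'
#' Scores every pair without a known treat edge and returns the top of the
#' list, the candidate-repositioning table. Ties are broken by (drug ID,
#' disease ID) in registry order.
#'
#' @param model a trained `ensemble_model`.
#' @param network the `hetero_network` the model was trained on (supplies
#'   the known treat edges to exclude).
#' @param top_n number of candidates to return.
#' @return data.frame with columns `rank`, `drug`, `disease`, `score`,
#'   scores non-increasing.
#' @export
rank_candidates <- function(model, network, top_n = 20L) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(network, "hetero_network"))
  if (top_n <= 0L) stop("top_n must be positive")
  pool <- unlabeled_pairs(network)
  sc <- ensemble_score(model, pool)
  ord <- order(-sc, pool[, 1L], pool[, 2L])
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(keep),
             drug = network$drugs[pool[keep, 1L]],
             disease = network$diseases[pool[keep, 2L]],
             score = sc[keep])
}
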