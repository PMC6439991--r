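#' Confusion counts at a score threshold
#'
#' A pair is predicted positive iff its score is strictly greater than the
#' threshold.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) true labels, same length.
#' @param threshold decision threshold.
#' @return a list of class `confusion_counts` with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) == 0L) stop("empty score vector")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  pred <- scores > threshold
  structure(list(TP = sum(pred & labels == 1L),
                 FP = sum(pred & labels == 0L),
                 TN = sum(!pred & labels == 0L),
                 FN = sum(!pred & labels == 1L)),
            class = "confusion_counts")
}

#' Threshold classification metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/total`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and the
#' F1-measure `2*PRE*REC/(PRE+REC)`. A metric whose denominator is zero is
#' reported as `NA` (undefined), never silently as 0.
#'
#' @param counts a [confusion_counts()] result (or list with TP/FP/TN/FN).
#' @return named list with `PRE`, `REC`, `ACC`, `MCC`, `F1`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  pre <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  acc <- (tp + tn) / total
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
    2 * pre * rec / (pre + rec) else NA_real_
  list(PRE = pre, REC = rec, ACC = acc, MCC = mcc, F1 = f1)
}

#' Areas under the precision-recall and ROC curves
#'
#' AUC is computed by the Mann-Whitney rank statistic with midrank tie
#' correction: the probability that a random positive outranks a random
#' negative, ties counted one half. AUPR is step-wise average precision:
#' the sum over distinct score thresholds (descending) of the recall
#' increment times the precision at that threshold, with no trapezoidal
#' interpolation.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 (or logical) true labels; both classes must occur.
#' @return named list with `AUPR` and `AUC`.
#' @export
aupr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUPR/AUC")
  # AUC: Mann-Whitney with midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # AUPR: average precision over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cut_end <- which(diff(s) != 0)          # last index of each tie block
  cut_end <- c(cut_end, length(s))
  tp <- cumsum(y)[cut_end]
  pred_pos <- cut_end
  precision <- tp / pred_pos
  recall <- tp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  list(AUPR = aupr, AUC = auc)
}

#' Cross-validated evaluation of the meta-path SVD ensemble
#'
#' Runs k-fold cross-validation of the full pipeline on a network.
#' Positives are the known treat edges; a balanced negative set of equal
#' size is drawn once from the chosen strategy's candidate pool and split
#' into the same folds as the positives (seeded shuffles; fold sizes
#' differ by at most one). For each fold, the test fold's positive edges
#' are (by default) zeroed out of the treatment layer before the commuting
#' matrices and SVD features are computed — without this masking the MP1
#' features literally contain the held-out labels — then one 256-tree
#' random forest per meta path is trained on the training folds and the
#' test fold is scored. Test scores are pooled over folds; the ensemble
#' score of a pair is the mean of the five per-path forest scores, and the
#' decision threshold is the F1-maximising cut on the pooled ensemble
#' scores. Per-path base-classifier results use per-path F1-maximising
#' thresholds in the same way.
#'
#' @param network an aligned `hetero_network`.
#' @param latent_feature_percent truncation fraction for [truncated_svd()]
#'   (default 0.03).
#' @param strategy negative-sampling strategy, `"reliable"` or `"random"`.
#' @param seed master integer seed driving negative sampling, fold
#'   assignment and forest training.
#' @param n_folds number of folds (default 5).
#' @param num_trees trees per random forest (default 256).
#' @param mask_test_edges if `TRUE` (default), zero the test fold's
#'   positive edges in the treatment layer before feature construction.
#' @return an object of class `cv_report`: list with `summary` (one row
#'   per classifier MP1..MP5 and `ensemble`: pooled AUPR, AUC, PRE, REC,
#'   ACC, MCC, F1 and the threshold used), `per_fold` (AUPR/AUC per fold
#'   and classifier), `scores` (pooled test scores, one column per
#'   classifier), `labels`, `folds`, `pairs` and the resolved settings.
#' @export
cross_validate <- function(network, latent_feature_percent = 0.03,
                           strategy = c("reliable", "random"),
                           seed = 1L, n_folds = 5L, num_trees = 256L,
                           mask_test_edges = TRUE) {
  stopifnot(inherits(network, "hetero_network"))
  strategy <- match.arg(strategy)
  positives <- as_pair_matrix(
    Matrix::which(network$A_ds$values != 0, arr.ind = TRUE))
  n_pos <- nrow(positives)
  if (n_pos < n_folds)
    stop(sprintf("%d positives cannot fill %d non-empty folds", n_pos, n_folds))
  candidates <- negative_candidates(network, strategy)
  negatives <- sample_negatives(candidates, n_pos, derive_seed(seed, 1))

  fold_of <- function(n, s) with_seed(s, sample(rep_len(seq_len(n_folds), n)))
  pos_fold <- fold_of(n_pos, derive_seed(seed, 2))
  neg_fold <- fold_of(n_pos, derive_seed(seed, 3))

  pairs <- rbind(positives, negatives)
  labels <- rep(c(1L, 0L), each = n_pos)
  folds <- c(pos_fold, neg_fold)

  scores <- matrix(NA_real_, nrow(pairs), length(METAPATHS) + 1L,
                   dimnames = list(NULL, c(METAPATHS, "ensemble")))
  for (k in seq_len(n_folds)) {
    test <- folds == k
    net_k <- if (mask_test_edges)
      mask_positive_edges(network, positives[pos_fold == k, , drop = FALSE])
    else network
    model <- train_ensemble(net_k,
                            pairs = pairs[!test, , drop = FALSE],
                            labels = labels[!test],
                            latent_feature_percent = latent_feature_percent,
                            seed = derive_seed(seed, 4, k),
                            num_trees = num_trees)
    sc <- predict_scores(model, pairs[test, , drop = FALSE])
    scores[test, ] <- sc
  }

  per_fold <- do.call(rbind, lapply(seq_len(n_folds), function(k) {
    do.call(rbind, lapply(colnames(scores), function(cl) {
      pa <- aupr_auc(scores[folds == k, cl], labels[folds == k])
      data.frame(fold = k, classifier = cl, AUPR = pa$AUPR, AUC = pa$AUC)
    }))
  }))

  summary <- do.call(rbind, lapply(colnames(scores), function(cl) {
    pa <- aupr_auc(scores[, cl], labels)
    th <- choose_threshold(scores[, cl], labels)
    m <- classification_metrics(confusion_counts(scores[, cl], labels,
                                                 th$threshold))
    data.frame(classifier = cl, AUPR = pa$AUPR, AUC = pa$AUC,
               PRE = m$PRE, REC = m$REC, ACC = m$ACC, MCC = m$MCC,
               F1 = m$F1, threshold = th$threshold)
  }))

  structure(list(summary = summary, per_fold = per_fold,
                 scores = scores, labels = labels, folds = folds,
                 pairs = pairs,
                 settings = list(latent_feature_percent = latent_feature_percent,
                                 strategy = strategy, seed = seed,
                                 n_folds = n_folds, num_trees = num_trees,
                                 mask_test_edges = mask_test_edges)),
            class = "cv_report")
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<cv_report> %d-fold CV, strategy '%s', latent percent %.3g, seed %d\n",
              s$n_folds, s$strategy, s$latent_feature_percent, s$seed))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

# Zero the given positive (drug, disease) entries out of the treat layer.
mask_positive_edges <- function(network, pairs) {
  pairs <- as_pair_matrix(pairs)
  ds <- network$A_ds$values
  if (nrow(pairs)) {
    ds[cbind(pairs[, 1L], pairs[, 2L])] <- 0
    ds <- Matrix::drop0(ds)
  }
  replace_ds_layer(network, ds)
}

#' Sweep the latent-feature truncation fraction
#'
#' Repeats [cross_validate()] over a grid of `latent_feature_percent`
#' values with the same master seed, so the fold assignment and negative
#' draw are identical across the sweep and only the feature rank varies.
#'
#' @inheritParams cross_validate
#' @param percents vector of truncation fractions (default 1%..20%).
#' @return data.frame with one row per (percent, classifier): pooled AUPR
#'   and AUC.
#' @export
sweep_latent_percent <- function(network, percents = seq(0.01, 0.20, by = 0.01),
                                 strategy = c("reliable", "random"),
                                 seed = 1L, n_folds = 5L, num_trees = 256L,
                                 mask_test_edges = TRUE) {
  strategy <- match.arg(strategy)
  do.call(rbind, lapply(percents, function(p) {
    rep <- cross_validate(network, latent_feature_percent = p,
                          strategy = strategy, seed = seed,
                          n_folds = n_folds, num_trees = num_trees,
                          mask_test_edges = mask_test_edges)
    cbind(percent = p, rep$summary[, c("classifier", "AUPR", "AUC")])
  }))
}
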