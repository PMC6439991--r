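test_that("confusion counts tally the strict-threshold rule", {
  cc <- confusion_counts(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  high <- confusion_counts(c(0.2, 0.4), c(1, 0), 0.9)
  expect_equal(high$TP + high$FP, 0L)
  expect_error(confusion_counts(numeric(0), integer(0), 0.5), "empty")

  set.seed(2)
  s <- runif(50); y <- rbinom(50, 1, 0.5); t <- 0.4
  cc <- confusion_counts(s, y, t)
  expect_equal(cc$TP, sum(s > t & y == 1))
  expect_equal(cc$TN, sum(s <= t & y == 0))
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 50L)
})

test_that("threshold metrics reproduce hand-computed values", {
  m <- classification_metrics(list(TP = 2, FP = 1, TN = 3, FN = 2))
  expect_equal(m$PRE, 2 / 3)
  expect_equal(m$REC, 1 / 2)
  expect_equal(m$ACC, 5 / 8)
  expect_equal(m$F1, 4 / 7)
  expect_equal(m$MCC, 4 / sqrt(240))

  sym <- classification_metrics(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(sym$MCC, 0)

  perfect <- classification_metrics(list(TP = 3, FP = 0, TN = 4, FN = 0))
  expect_equal(unlist(perfect), c(PRE = 1, REC = 1, ACC = 1, MCC = 1, F1 = 1))

  # zero denominators are undefined, not zero
  none_pred <- classification_metrics(list(TP = 0, FP = 0, TN = 3, FN = 2))
  expect_true(is.na(none_pred$PRE))
  expect_true(is.na(none_pred$MCC))
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)))
})

test_that("AUC and AUPR behave on canonical rankings", {
  perfect <- aupr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$AUC, 1)
  expect_equal(perfect$AUPR, 1)
  ties <- aupr_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(ties$AUC, 0.5)
  expect_error(aupr_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force pairwise concordance with ties at one half", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    s <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    expect_equal(aupr_auc(s, y)$AUC, oracle_auc(s, y))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(80); y <- rbinom(80, 1, 0.4)
  expect_equal(aupr_auc(s, y)$AUC,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("AUC and AUPR are invariant under strictly monotone score transforms", {
  set.seed(5)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  a <- aupr_auc(s, y)
  b <- aupr_auc(qlogis(s / 2 + 0.25), y)
  expect_equal(a$AUC, b$AUC)
  expect_equal(a$AUPR, b$AUPR)
})

test_that("cross-validation partitions positives evenly and covers each once", {
  sim <- generate_network(synthetic_config(60, 50, 30, base_treat_rate = 0.02,
                                           seed = 23))
  rep <- cross_validate(sim$network, seed = 5, num_trees = 32)
  n_pos <- nrow(sim$positives)
  pos_folds <- rep$folds[seq_len(n_pos)]
  sizes <- table(pos_folds)
  expect_equal(sum(sizes), n_pos)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(unique(pos_folds)), 1:5)
  # every evaluated pair scored exactly once
  expect_false(anyNA(rep$scores))
  expect_true(all(rep$scores >= 0 & rep$scores <= 1))
})

test_that("the reported F1 at the chosen threshold is self-consistent", {
  set.seed(11)
  s <- runif(60); y <- rbinom(60, 1, 0.5)
  th <- choose_threshold(s, y)
  m <- classification_metrics(confusion_counts(s, y, th$threshold))
  expect_equal(m$F1, th$f1)
})

test_that("cross-validation on a null network stays near chance", {
  sim <- generate_network(synthetic_config(100, 60, 50, base_treat_rate = 0.04,
                                           overlap_boost = 0, seed = 37))
  rep <- cross_validate(sim$network, seed = 3, num_trees = 64)
  auc <- rep$summary$AUC[rep$summary$classifier == "ensemble"]
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("reliable negatives beat random negatives in pooled AUPR over replicates", {
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- generate_network(synthetic_config(100, 80, 50, seed = 500 + s))
    rel <- cross_validate(sim$network, strategy = "reliable", seed = s,
                          num_trees = 64)$summary
    rnd <- cross_validate(sim$network, strategy = "random", seed = s,
                          num_trees = 64)$summary
    if (rel$AUPR[rel$classifier == "ensemble"] >=
        rnd$AUPR[rnd$classifier == "ensemble"]) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("cross-validation is reproducible for a fixed master seed", {
  sim <- generate_network(synthetic_config(50, 40, 25, base_treat_rate = 0.03,
                                           seed = 29))
  a <- cross_validate(sim$network, seed = 8, num_trees = 32)
  b <- cross_validate(sim$network, seed = 8, num_trees = 32)
  expect_identical(a$scores, b$scores)
  expect_identical(a$summary, b$summary)
})
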