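# Small trained model shared across blocks.
make_toy_model <- function(seed = 19, n_trees = 64L) {
  sim <- generate_network(synthetic_config(60, 50, 30, base_treat_rate = 0.02,
                                           seed = seed))
  net <- sim$network
  pos <- sim$positives
  neg <- sample_negatives(reliable_negatives(net), nrow(pos), seed)
  pairs <- rbind(pos, neg)
  labels <- rep(1:0, each = nrow(pos))
  model <- train_ensemble(net, pairs, labels, seed = seed, num_trees = n_trees)
  list(model = model, network = net, pairs = pairs, labels = labels)
}

test_that("a forest memorises linearly separated data and is seed-deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(60, -2), ncol = 2), matrix(rnorm(60, 2), ncol = 2))
  y <- rep(0:1, each = 30)
  clf <- train_base(x, y, seed = 5)
  expect_true(all(predict(clf, x[y == 1, ]) >= 0.5))
  clf2 <- train_base(x, y, seed = 5)
  expect_identical(predict(clf, x), predict(clf2, x))
  expect_error(train_base(x, rep(1, 60), seed = 1), "both classes")
  expect_error(train_base(x, y[-1], seed = 1), "differ")
})

test_that("permuted labels give near-chance held-out discrimination", {
  set.seed(2)
  x <- matrix(rnorm(400 * 4), ncol = 4)
  y <- sample(rep(0:1, each = 200))  # labels independent of features
  half <- seq_len(200)
  clf <- train_base(x[half, ], y[half], seed = 3)
  auc <- aupr_auc(predict(clf, x[-half, ]), y[-half])$AUC
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("the ensemble score is the mean of the five base scores", {
  toy <- make_toy_model()
  set.seed(4)
  pairs <- toy$pairs[sample(nrow(toy$pairs), 25), ]
  sc <- pathrepo:::predict_scores(toy$model, pairs)
  # recomputation oracle: score each path independently and average
  per_path <- sapply(METAPATHS, function(mp)
    predict(toy$model$bases[[mp]],
            feature_table(toy$model$latents[[mp]], pairs)))
  expect_equal(unname(sc[, "ensemble"]), unname(rowMeans(per_path)))
  expect_equal(ensemble_score(toy$model, pairs), unname(sc[, "ensemble"]))
  expect_true(all(sc >= 0 & sc <= 1))
  # the mean lies within the base-score envelope
  expect_true(all(sc[, "ensemble"] >= apply(per_path, 1, min) - 1e-12))
  expect_true(all(sc[, "ensemble"] <= apply(per_path, 1, max) + 1e-12))
  expect_error(ensemble_score(list(), pairs), "not a trained ensemble")
})

test_that("the F1-maximising threshold matches canonical and exhaustive cases", {
  th <- choose_threshold(c(0.1, 0.9), c(0, 1))
  expect_equal(th$threshold, 0.5)
  expect_equal(th$f1, 1)

  allpos <- choose_threshold(c(0.3, 0.6, 0.9), c(1, 1, 1))
  expect_lt(allpos$threshold, 0.3)
  expect_equal(allpos$f1, 1)

  expect_warning(choose_threshold(rep(0.4, 5), c(1, 0, 1, 0, 1)), "identical")

  for (seed in 1:8) {
    set.seed(seed)
    s <- sample(seq(0, 1, 0.05), 20, TRUE)
    y <- c(0, 1, rbinom(18, 1, 0.5))
    th <- choose_threshold(s, y)
    expect_equal(th$f1, oracle_best_f1(s, y), info = paste("seed", seed))
  }
})

test_that("candidate ranking is sorted, deduplicated against positives, and sized", {
  toy <- make_toy_model()
  top <- rank_candidates(toy$model, toy$network, top_n = 15)
  expect_equal(nrow(top), 15L)
  expect_equal(top$rank, 1:15)
  expect_true(all(diff(top$score) <= 0))
  known <- pair_keys(cbind(toy$network$drugs[toy$pairs[toy$labels == 1, 1]],
                           toy$network$diseases[toy$pairs[toy$labels == 1, 2]]))
  expect_length(intersect(paste(top$drug, top$disease, sep = ":"), known), 0)

  one <- rank_candidates(toy$model, toy$network, top_n = 1)
  expect_equal(one$score, top$score[1])
  expect_error(rank_candidates(toy$model, toy$network, top_n = 0), "positive")
})

test_that("threshold calibration stores the F1-optimal cut on the model", {
  toy <- make_toy_model()
  model <- calibrate_threshold(toy$model, toy$pairs, toy$labels)
  sc <- ensemble_score(model, toy$pairs)
  expect_equal(model$threshold, choose_threshold(sc, toy$labels)$threshold)
})
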