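small_cfg <- function(seed = 1, ...) {
  mccv_config(n_outer = 8, n_inner = 6, num_trees = 80, shap_nsim = 5,
              shap_max_explain = 20, seed = seed, ...)
}

test_that("correlation pruning drops the more connected member of each pair", {
  set.seed(11)
  n <- 400
  u <- rnorm(n)
  v <- rnorm(n)
  x <- cbind(
    a = u + 0.5 * v,            # r(a, b) ~ 0.89; r(a, c) ~ 0.4
    b = u,                      # correlated only with a
    c = v + rnorm(n, sd = 0.5),
    d = rnorm(n)
  )
  r <- abs(cor(x))
  expect_gt(r["a", "b"], 0.7)
  expect_lt(r["b", "c"], 0.2)
  kept <- correlation_prune(x, 0.7)
  expect_false("a" %in% kept)   # 'a' has the larger mean |r| to the rest
  expect_true(all(c("b", "c", "d") %in% kept))
  # already-pruned input is unchanged
  set.seed(12)
  y <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("u", "v", "w")))
  expect_identical(correlation_prune(y, 0.7), c("u", "v", "w"))
  # post-condition on random correlated matrices
  for (i in 1:20) {
    set.seed(i)
    f <- matrix(rnorm(50 * 4), 50, 4)
    mat <- f[, c(1, 1, 2, 2, 3, 3, 4, 4)] + matrix(rnorm(50 * 8, sd = 0.6), 50)
    colnames(mat) <- letters[1:8]
    kept_i <- correlation_prune(mat, 0.7)
    if (length(kept_i) > 1) {
      rk <- abs(cor(mat[, kept_i]))
      diag(rk) <- 0
      expect_lte(max(rk), 0.7)
    }
  }
  const <- cbind(k = rep(1, 50), l = rnorm(50))
  expect_warning(kc <- correlation_prune(const, 0.7), "constant")
  expect_identical(kc, "l")
})

test_that("bootstrap rebalancing up-samples the minority class to the target", {
  labels <- rep(c("A", "B", "C"), c(100, 50, 10))
  idx <- bootstrap_rebalance(labels, 0.6, seed = 1)
  expect_equal(sum(labels[idx] == "C"), 60)
  expect_equal(sum(labels[idx] == "A"), 100)   # untouched
  expect_equal(sum(labels[idx] == "B"), 50)
  expect_identical(idx[seq_along(labels)], seq_along(labels))
  # already large enough: unchanged (up-sampling only)
  labels2 <- rep(c("A", "C"), c(10, 8))
  expect_identical(bootstrap_rebalance(labels2, 0.6, seed = 1),
                   seq_along(labels2))
  # appended indices always come from the minority class
  for (s in 1:100) {
    extra <- bootstrap_rebalance(labels, 0.6, seed = s)[-seq_along(labels)]
    expect_true(all(labels[extra] == "C"))
  }
  expect_identical(bootstrap_rebalance(labels, 0.6, seed = 5),
                   bootstrap_rebalance(labels, 0.6, seed = 5))
  expect_error(bootstrap_rebalance(rep("A", 5), minority = "C"), "absent")
})

test_that("imputation medians come from training rows only", {
  # sentinel poisoning: test rows carry absurd values which must never
  # leak into the fitted medians
  x_train <- matrix(c(1, 2, 3, NA, 5, 6), 3, 2,
                    dimnames = list(NULL, c("f1", "f2")))
  x_test <- matrix(c(1e9, 1e9, 1e9, 1e9), 2, 2,
                   dimnames = list(NULL, c("f1", "f2")))
  imp <- impute_train_median(x_train, x_test)
  expect_equal(unname(imp$medians), c(2, 5.5))
  expect_equal(unname(imp$train[1, "f2"]), 5.5)
  expect_true(all(imp$other == 1e9))  # observed test values untouched
  # a missing test cell is filled with the training median even when every
  # other test row carries the sentinel in that column
  x_test2 <- matrix(c(1e9, NA, 1e9, 1e9), 2, 2,
                    dimnames = list(NULL, c("f1", "f2")))
  imp2 <- impute_train_median(x_train, x_test2)
  expect_equal(unname(imp2$other[2, "f1"]), 2)
  # poisoning test rows never changes the fitted medians or training matrix
  imp3 <- impute_train_median(x_train, x_test2 * -5)
  expect_identical(imp3$medians, imp2$medians)
  expect_identical(imp3$train, imp2$train)
})

test_that("Shapley ranking puts a fully informative feature first", {
  ranks_first <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200
    y <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
    x <- cbind(signal = as.numeric(factor(y)) + rnorm(n, sd = 0.05),
               n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
               n4 = rnorm(n), n5 = rnorm(n))
    rownames(x) <- sprintf("r%03d", 1:n)
    rk <- shap_rank_features(x, y, small_cfg(seed = seed))
    rk$median_rank[rk$feature == "signal"]
  }, numeric(1))
  expect_true(all(ranks_first == 1))
})

test_that("Shapley ranking returns a permutation and treats duplicates alike", {
  set.seed(13)
  n <- 150
  y <- rep(c("A", "B", "C"), c(70, 60, 20))
  sig <- as.numeric(factor(y)) + rnorm(n, sd = 0.3)
  x <- cbind(s1 = sig, s2 = sig, n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n), n4 = rnorm(n))
  rownames(x) <- sprintf("r%03d", 1:n)
  rk <- shap_rank_features(x, y, small_cfg(seed = 13))
  expect_setequal(rk$feature, colnames(x))
  half <- ceiling(ncol(x) / 2)
  pos <- match(c("s1", "s2"), rk$feature)
  expect_true(all(pos <= half))
})

test_that("recall curve behaves on separable and shuffled data", {
  sc <- separable_classes()
  cfg <- small_cfg(seed = 3)
  cur <- mccv_recall_curve(sc$x, sc$y, c("f1", "f2"), cfg)
  expect_equal(nrow(cur), 2)
  expect_gte(cur$mean_recall[2], 0.95)
  expect_true(all(cur$mean_recall >= 0 & cur$mean_recall <= 1))
  expect_true(all(cur$sd_recall >= 0))
  # chance level on shuffled balanced labels, pooled over independent
  # shuffles (a single finite dataset retains O(1/sqrt(n)) spurious
  # association that MCCV iterations cannot average away)
  null_recalls <- vapply(1:3, function(ds) {
    set.seed(50 + ds)
    n <- 210
    y0 <- sample(rep(c("A", "B", "C"), each = 70))
    x0 <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("g1", "g2", "g3")))
    cfg0 <- mccv_config(n_outer = 10, n_inner = 2, num_trees = 80, seed = ds)
    mccv_recall_curve(x0, y0, c("g1", "g2", "g3"), cfg0)$mean_recall[3]
  }, numeric(1))
  expect_lt(abs(mean(null_recalls) - 1 / 3), 0.05)
})

test_that("knee detection reproduces the hand-executed Kneedle example", {
  curve <- data.frame(f = 1:5, mean_recall = c(0.5, 0.8, 0.82, 0.83, 0.83))
  expect_equal(knee_select(curve), 2L)
  # strictly linear curve: no knee, full feature count with a warning
  lin <- data.frame(f = 1:6, mean_recall = seq(0.4, 0.9, 0.1))
  expect_warning(k <- knee_select(lin), "no knee")
  expect_equal(k, 6L)
  flat <- data.frame(f = 1:4, mean_recall = rep(0.5, 4))
  expect_warning(kf <- knee_select(flat), "flat|no knee")
  expect_equal(kf, 4L)
  expect_error(knee_select(data.frame(f = 1:2, mean_recall = c(0, 1))),
               "at least 3")
  # knee always inside [1, F]
  set.seed(15)
  for (i in 1:10) {
    y <- sort(runif(7))
    k <- suppressWarnings(knee_select(data.frame(f = 1:7, mean_recall = y)))
    expect_true(k >= 1 && k <= 7)
  }
})

test_that("final evaluation reports per-class metrics and detects overfitting", {
  sc <- separable_classes()
  cfg <- small_cfg(seed = 5)
  rep1 <- evaluate_final(sc$x, sc$y, c("f1", "f2"), cfg)
  expect_true(all(rep1$metrics$test$mean[, "auroc"] >= 0.95))
  expect_output(print(rep1), "AUROC")
  # random labels: chance-level AUROC
  set.seed(16)
  n <- 120
  xr <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("h1", "h2")))
  yr <- rep(c("A", "B", "C"), each = 40)
  repr <- evaluate_final(xr, sample(yr), c("h1", "h2"),
                         mccv_config(n_outer = 12, num_trees = 80, seed = 6))
  expect_lt(abs(mean(repr$metrics$test$mean[, "auroc"]) - 0.5), 0.07)
  # deliberately overfit run: tiny n, pure noise -> train-test gap > 0.1
  set.seed(17)
  no <- 45
  xo <- matrix(rnorm(no * 8), no, 8,
               dimnames = list(NULL, sprintf("z%d", 1:8)))
  yo <- rep(c("A", "B", "C"), each = 15)
  repo <- evaluate_final(xo, yo, colnames(xo),
                         mccv_config(n_outer = 10, num_trees = 150, seed = 7))
  expect_true(repo$overfitting)
  expect_match(repo$notes, "overfitting")
})

test_that("curve endpoint equals final evaluation on identical seeds", {
  sc <- separable_classes()
  cfg <- small_cfg(seed = 8)
  cur <- mccv_recall_curve(sc$x, sc$y, c("f1", "f2"), cfg)
  rep2 <- evaluate_final(sc$x, sc$y, c("f1", "f2"), cfg)
  macro_test <- mean(rep2$metrics$test$mean[, "recall"])
  expect_equal(cur$mean_recall[2], macro_test, tolerance = 1e-9)
})

test_that("the classifier pipeline is deterministic given the seed", {
  sc <- separable_classes()
  cfg <- small_cfg(seed = 9)
  r1 <- shap_rank_features(sc$x, sc$y, cfg)
  r2 <- shap_rank_features(sc$x, sc$y, cfg)
  expect_identical(r1, r2)
  c1 <- mccv_recall_curve(sc$x, sc$y, r1$feature, cfg)
  c2 <- mccv_recall_curve(sc$x, sc$y, r1$feature, cfg)
  expect_identical(c1, c2)
})
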