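test_that("fusion forest memorizes separable training data", {
  tab <- meta_table(sprintf("r%02d", 1:20),
                    data.frame(s = c(seq(0.6, 0.9, length.out = 10),
                                     seq(0.1, 0.4, length.out = 10))),
                    labels = rep(c("AFib", "non-AFib"), each = 10))
  model <- train_fusion(tab, config = fusion_config(n_trees = 100, seed = 1))
  expect_equal(as.character(predict_label(model, tab)),
               as.character(tab$labels))
})

test_that("training is deterministic under the seed", {
  tab <- gen_ensemble(counts = c(non_afib = 150, afib = 40, noisy = 10),
                      seed = 6)
  probe <- gen_ensemble(counts = c(non_afib = 30, afib = 10, noisy = 0),
                        seed = 7)
  m1 <- train_fusion(tab, config = fusion_config(n_trees = 100, seed = 5))
  m2 <- train_fusion(tab, config = fusion_config(n_trees = 100, seed = 5))
  expect_identical(predict_proba(m1, probe), predict_proba(m2, probe))
})

test_that("probabilities are vote ratios on the 1/n_trees grid", {
  tab <- gen_ensemble(counts = c(non_afib = 150, afib = 40, noisy = 10),
                      seed = 6)
  model <- train_fusion(tab, config = fusion_config(n_trees = 500, seed = 2))
  p <- predict_proba(model, tab)
  expect_true(all(abs(p * 500 - round(p * 500)) < 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the 0.5 tie and thresholding go to AFib", {
  tab <- gen_ensemble(counts = c(non_afib = 100, afib = 30, noisy = 0),
                      seed = 9)
  model <- train_fusion(tab, config = fusion_config(n_trees = 100, seed = 3))
  p <- predict_proba(model, tab)
  lab <- predict_label(model, tab)
  expect_equal(as.character(lab),
               unname(ifelse(p >= 0.5, "AFib", "non-AFib")))
  # sweeping the threshold reproduces the ROC staircase
  truth <- afcf:::subset_meta_table(tab)$labels
  roc <- roc_auc(truth, p)
  for (i in seq_len(nrow(roc$points))) {
    t <- roc$points$threshold[i]
    calls <- predict_label(model, tab, threshold = t)
    cm <- confusion(truth, calls)
    m <- metrics(cm)
    if (is.finite(t)) {
      expect_equal(m$sensitivity, roc$points$tpr[i])
      expect_equal(1 - m$specificity, roc$points$fpr[i])
    }
  }
})

test_that("label-independent features give chance-level held-out AUC", {
  set.seed(31)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  tab <- meta_table(sprintf("r%04d", 1:n),
                    data.frame(a = rnorm(n), b = rnorm(n)),
                    labels = ifelse(y == 1, "AFib", "non-AFib"))
  train <- afcf:::subset_meta_table(tab, rows = 1:250)
  test <- afcf:::subset_meta_table(tab, rows = 251:500)
  model <- train_fusion(train, config = fusion_config(n_trees = 200, seed = 8))
  auc <- roc_auc(test$labels, predict_proba(model, test))$auc
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("prediction validates the feature contract", {
  tab <- gen_ensemble(counts = c(non_afib = 80, afib = 20, noisy = 0),
                      seed = 12)
  model <- train_fusion(tab, c("alg1", "kardia_score"),
                        fusion_config(n_trees = 50, seed = 1))
  probe <- afcf:::subset_meta_table(tab, cols = c("alg2", "kardia_score"))
  expect_error(predict_proba(model, probe), "alg1")
  expect_error(train_fusion(
    meta_table(c("a", "b"), data.frame(s = c(0.2, 0.9)),
               labels = c("AFib", "AFib")),
    config = fusion_config(n_trees = 10, seed = 1)), "single class")
})

test_that("select_k honors a singleton grid and prefers parsimony", {
  tab <- gen_ensemble(counts = c(non_afib = 150, afib = 40, noisy = 5),
                      seed = 2)
  r <- permutation_importance(filter_for_ranking(tab), 100, seed = 1)
  s <- select_k(tab, r, k_grid = 7, plan = cv_plan(1, 5, seed = 2),
                config = fusion_config(100, seed = 3))
  expect_equal(s$k, 7)

  # one strong feature plus noise: the one-SD rule picks a small k
  set.seed(44)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  feats <- data.frame(good = y + rnorm(n, 0, 0.2),
                      matrix(rnorm(n * 6), n, 6,
                             dimnames = list(NULL, paste0("z", 1:6))))
  tab2 <- meta_table(sprintf("r%04d", 1:n), feats,
                     labels = ifelse(y == 1, "AFib", "non-AFib"))
  r2 <- permutation_importance(tab2, 150, seed = 5)
  s2 <- select_k(tab2, r2, k_grid = c(1, 3, 5, 7),
                 plan = cv_plan(2, 5, seed = 6),
                 config = fusion_config(150, seed = 7))
  expect_lte(s2$k, 3)
  expect_equal(s2$grid$k, c(1, 3, 5, 7))
})

test_that("models survive the text serialization round trip", {
  tab <- gen_ensemble(counts = c(non_afib = 100, afib = 30, noisy = 5),
                      seed = 15)
  model <- train_fusion(tab, config = fusion_config(n_trees = 60, seed = 4))
  path <- tempfile(fileext = ".json")
  write_fusion_forest(model, path)
  restored <- read_fusion_forest(path)
  expect_identical(predict_proba(model, tab), predict_proba(restored, tab))
  expect_equal(restored$config$n_trees, 60)
  # corrupted header is refused
  bad <- jsonlite::read_json(path)
  bad$format <- "something-else"
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_fusion_forest(path2), "format")
})

test_that("fusion outperforms complementary experts and survives voter loss", {
  f_fusion <- f_best <- f_no_best <- f_only_best <- numeric(10)
  for (seed in 1:10) {
    tab <- gen_complementary_experts(2000, seed = seed)
    set.seed(seed + 900)
    idx <- sample(2000, 1000)
    train <- afcf:::subset_meta_table(tab, rows = idx)
    test <- afcf:::subset_meta_table(tab, rows = setdiff(1:2000, idx))
    voter_f1 <- vapply(names(test$features), function(v)
      afcf:::f1_binary(test$labels, test$features[[v]]), numeric(1))
    best <- names(which.max(voter_f1))
    fit <- function(feats) {
      m <- train_fusion(train, feats, fusion_config(n_trees = 200,
                                                    seed = seed))
      afcf:::f1_binary(test$labels, predict_label(m, test))
    }
    f_fusion[seed] <- fit(names(train$features))
    f_best[seed] <- max(voter_f1)
    f_no_best[seed] <- fit(setdiff(names(train$features), best))
    f_only_best[seed] <- fit(best)
  }
  expect_gt(mean(f_fusion), mean(f_best))
  # dropping the strongest voter hurts less than dropping the other six
  expect_lt(mean(f_fusion) - mean(f_no_best),
            mean(f_fusion) - mean(f_only_best))
})
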