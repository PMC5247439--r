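test_that("AUC ranking matches exhaustive pair counting", {
  fm <- fm_from_matrix(cbind(sep = c(1, 2, 3, 10, 11, 12),
                             flat = rep(1, 6)),
                       groups = rep(c("HA", "LA"), each = 3))
  rk <- auc_rank_features(fm)
  expect_equal(rk$auc[rk$feature == "sep"], 1.0)
  expect_equal(rk$rank[rk$feature == "sep"], 1)
  expect_equal(rk$auc[rk$feature == "flat"], 0.5)

  set.seed(10)
  for (rep in 1:25) {
    n1 <- sample(1:6, 1)
    n0 <- sample(1:6, 1)
    x <- sample(round(rnorm(n1 + n0), 1))                    # duplicates force ties
    y <- sample(rep(c("LA", "HA"), c(n1, n0)))
    fm <- fm_from_matrix(cbind(f = x), y)
    expect_equal(auc_rank_features(fm)$auc, auc_pair_oracle(x, y))
  }
  expect_error(auc_rank_features(fm_from_matrix(cbind(f = 1:4),
                                                rep("LA", 4))),
               "both classes")
})

test_that("confusion metrics follow the printed formulas and flag undefined ratios", {
  perfect <- compute_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$precision, 100)

  m <- compute_metrics(c(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(m$accuracy, 70)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 60)
  expect_equal(m$precision, 100 * 40 / 60, tolerance = 1e-9)

  nopos <- compute_metrics(c(TP = 0, FP = 3, TN = 7, FN = 0))
  expect_true(is.na(nopos$sensitivity))
  expect_true("sensitivity" %in% attr(nopos, "undefined"))
  expect_error(compute_metrics(c(TP = 1, FP = 1)), "TP, FP, TN, FN")
})

test_that("grid search honours degenerate grids and separable data", {
  set.seed(20)
  X <- rbind(matrix(rnorm(40 * 2, 0), ncol = 2),
             matrix(rnorm(40 * 2, 8), ncol = 2))
  y <- rep(c("LA", "HA"), each = 40)
  fm <- fm_from_matrix(X, y)

  one <- tune_svm(fm, svm_config(C_grid = 4, gamma_grid = 0.25, seed = 1))
  expect_equal(one$C, 4)
  expect_equal(one$gamma, 0.25)

  tuned <- tune_svm(fm, svm_config(C_grid = 2^(0:4),
                                   gamma_grid = 2^(-4:0),
                                   tuning_fraction = 0.5, seed = 2))
  model <- wavefi:::fit_svm(X, y, tuned$C, tuned$gamma)
  Xnew <- rbind(matrix(rnorm(20 * 2, 0), ncol = 2),
                matrix(rnorm(20 * 2, 8), ncol = 2))
  pred <- predict(model, Xnew)
  expect_equal(mean(pred == rep(c("LA", "HA"), each = 20)), 1)
})

test_that("cross-validation is deterministic, stratified and size-sane", {
  fm <- tiny_feature_matrix(n_subj = 3, trials = 34, seed = 16)  # 60 trials
  cfg <- fast_svm(seed = 3)
  cv1 <- crossvalidate(fm, k = 5, config = cfg, seed = 4)
  cv2 <- crossvalidate(fm, k = 5, config = cfg, seed = 4)
  expect_identical(cv1, cv2)
  expect_equal(sum(cv1$confusion), nrow(fm))
  expect_equal(nrow(cv1$per_fold), 5)
  expect_true(cv1$accuracy >= 0 && cv1$accuracy <= 100)
  expect_equal(cv1$accuracy, mean(cv1$per_fold$accuracy))

  expect_error(crossvalidate(fm[1:4, ], k = 10, config = cfg), "smaller k")
})

test_that("label permutation drives cross-validation accuracy to chance", {
  fm <- tiny_feature_matrix(n_subj = 3, trials = 34, seed = 17)
  set.seed(30)
  fm$group <- sample(fm$group)
  cv <- crossvalidate(fm, k = 5, config = fast_svm(seed = 5), seed = 6)
  half_width <- 100 * 1.96 * sqrt(0.25 / nrow(fm))
  expect_lt(abs(cv$accuracy - 50), half_width + 10)  # generous single-run band
})

test_that("subject holdout keeps train and test subjects disjoint", {
  fm <- tiny_feature_matrix(n_subj = 5, trials = 34, seed = 18)
  res <- subject_holdout_evaluate(fm, config = fast_svm(seed = 7), seed = 8)
  expect_length(intersect(res$train_subjects, res$test_subjects), 0)
  expect_setequal(c(res$train_subjects, res$test_subjects),
                  unique(fm$subject_id))
  # stratified 70/30: 3 train + 2 test per group of 5
  expect_equal(sum(grepl("^LA", res$train_subjects)), 3)
  expect_equal(sum(grepl("^HA", res$train_subjects)), 3)
  expect_gte(res$accuracy, 90)

  one_per <- fm[!duplicated(fm$subject_id), ]
  res1 <- subject_holdout_evaluate(one_per, config = fast_svm(seed = 9),
                                   seed = 9)
  expect_equal(sum(res1$confusion), sum(!duplicated(fm$subject_id)) -
                 length(res1$train_subjects))

  two <- fm[fm$subject_id %in% unique(fm$subject_id)[1:2], ]
  expect_error(subject_holdout_evaluate(two), "2 subjects per group")
})

test_that("a single-candidate combination search equals plain cross-validation", {
  ep <- simulate_epochs(tiny_params(n_subj = 3, trials = 34, seed = 19))
  ep <- ep[ep$info$stimulus == "target"]
  cfg <- fast_svm(seed = 10)
  cs <- combination_search(ep, band_subsets = list(c("A4", "D4")),
                           k = 5, config = cfg, seed = 11)
  expect_equal(nrow(cs), 1)
  fm <- build_feature_matrix(ep, "swf", bands = c("A4", "D4"),
                             statistics = c("Er", "std"))
  cv <- crossvalidate(fm, k = 5, config = cfg, seed = 11)
  expect_equal(cs$accuracy, cv$accuracy)
  expect_equal(cs$n_features, 12)

  expect_error(combination_search(ep, band_subsets = list("A4", "D4", "D3"),
                                  max_configs = 2, k = 5, config = cfg),
               "exceed")
})
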