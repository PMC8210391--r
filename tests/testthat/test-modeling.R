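# small separable dataset shared across blocks
sep_data <- generate_synthetic(synthetic_config(
  n_pos = 60, n_neg = 60, length_range = c(40, 90), bias_strength = 1,
  signal_mode = "aa_bias", seed = 101))

score_probe <- function(bundle) {
  predict_scores(bundle, sep_data$records[1:20, ])$score
}

test_that("training is deterministic for a fixed seed", {
  feats <- encode_dataset(sep_data$records, "AA")
  m1 <- train_forest(feats, sep_data$records$label, n_trees = 150, seed = 5,
                     scheme = "AA")
  m2 <- train_forest(feats, sep_data$records$label, n_trees = 150, seed = 5,
                     scheme = "AA")
  expect_identical(score_probe(m1), score_probe(m2))
  # on data the forest cannot fit perfectly, the seed visibly matters
  noisy <- generate_synthetic(synthetic_config(
    n_pos = 40, n_neg = 40, length_range = c(40, 60), bias_strength = 0.2,
    signal_mode = "aa_bias", seed = 301))
  nf <- encode_dataset(noisy$records, "AA")
  n1 <- train_forest(nf, noisy$records$label, n_trees = 150, seed = 5,
                     scheme = "AA")
  n3 <- train_forest(nf, noisy$records$label, n_trees = 150, seed = 6,
                     scheme = "AA")
  probe <- noisy$records[1:20, ]
  expect_false(identical(predict_scores(n1, probe)$score,
                         predict_scores(n3, probe)$score))
})

test_that("training rejects degenerate inputs", {
  feats <- encode_dataset(sep_data$records, "AA")
  expect_error(train_forest(feats, rep("positive", nrow(feats)), 50),
               "each class")
  expect_error(train_forest(feats, sep_data$records$label[-1], 50), "length")
})

test_that("a forest separates compositionally disjoint classes", {
  train_idx <- c(1:40, 61:100)
  test_idx <- setdiff(seq_len(120), train_idx)
  feats <- encode_dataset(sep_data$records, "AA")
  m <- train_forest(feats[train_idx, ], sep_data$records$label[train_idx],
                    n_trees = 200, seed = 3, scheme = "AA")
  preds <- predict_scores(m, sep_data$records[test_idx, ])
  truth <- sep_data$records$label[test_idx] == "positive"
  acc <- 100 * mean((preds$score >= 0.5) == truth)
  expect_gte(acc, 95)
})

test_that("scores do not depend on record order and ids must be unique", {
  feats <- encode_dataset(sep_data$records, "AA")
  m <- train_forest(feats, sep_data$records$label, n_trees = 100, seed = 2,
                    scheme = "AA")
  fwd <- predict_scores(m, sep_data$records[1:10, ])
  rev <- predict_scores(m, sep_data$records[10:1, ])
  expect_equal(fwd$score, rev$score[10:1])
  expect_equal(fwd$call, ifelse(fwd$score >= 0.5, "Y", "N"))
  dup <- sep_data$records[c(1, 1), ]
  expect_error(predict_scores(m, dup), "duplicate")
  # an extreme threshold turns every imperfect score into N
  hard <- predict_scores(m, sep_data$records[1:10, ], threshold = 1.0)
  expect_true(all(hard$call[hard$score < 1] == "N"))
})

test_that("cross-validation bookkeeping: cells, partitions, stratification", {
  cfg <- train_config("AA", tree_grid = c(50, 100), n_folds = 5,
                      n_repeats = 2, seed = 77)
  cv <- cross_validate(sep_data$records, cfg)
  # 2 repeats x 5 folds cells per tree value
  cells <- dplyr::count(cv$folds, n_trees)
  expect_equal(cells$n, c(10, 10))
  # each repeat partitions the dataset
  for (r in 1:2) {
    asg <- cv$assignments[cv$assignments$repeat_id == r, ]
    expect_setequal(asg$id, sep_data$records$id)
    expect_equal(nrow(asg), 120)
    # stratified: each fold has 12 pos + 12 neg
    per_fold <- table(asg$fold_id, grepl("^pos", asg$id))
    expect_true(all(abs(per_fold - 12) <= 1))
  }
  # distinct repeats use distinct shuffles
  a1 <- cv$assignments[cv$assignments$repeat_id == 1, "fold_id"]
  a2 <- cv$assignments[cv$assignments$repeat_id == 2, "fold_id"]
  expect_false(identical(a1, a2))
  # separable data: high aggregate accuracy with a dispersion attached
  agg <- tidy(cv)
  expect_true(all(agg$acc_mean >= 95))
  expect_true(all(is.finite(agg$acc_sd)))
})

test_that("cross-validation is reproducible end-to-end for a fixed seed", {
  cfg <- train_config("AA", tree_grid = 60, n_folds = 3, n_repeats = 1,
                      seed = 13)
  cv1 <- cross_validate(sep_data$records, cfg)
  cv2 <- cross_validate(sep_data$records, cfg)
  expect_identical(cv1$aggregate, cv2$aggregate)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("no-leakage: each fold's test ids are absent from training metrics", {
  cfg <- train_config("AA", tree_grid = 60, n_folds = 4, n_repeats = 1,
                      seed = 21)
  cv <- cross_validate(sep_data$records, cfg)
  asg <- cv$assignments
  expect_equal(anyDuplicated(asg$id), 0)
  # fold sizes recorded in metrics match the assignment table
  sizes <- table(asg$fold_id)
  got <- cv$folds[order(cv$folds$fold_id), ]
  expect_equal(got$n_test, as.integer(sizes))
  expect_equal(got$tp + got$fn + got$tn + got$fp, as.integer(sizes))
})

test_that("too-small classes for the fold count fail up front", {
  small <- sep_data$records[c(1:3, 61:70), ]
  expect_error(cross_validate(small, train_config("AA", tree_grid = 50,
                                                  n_folds = 5, n_repeats = 1)),
               "n_folds")
})

test_that("grid selection maximizes the criterion with documented tie-breaks", {
  cv <- structure(list(aggregate = tibble::tibble(
    scheme = c("DP", "AA", "AA", "PCP"),
    n_trees = c(3000L, 500L, 3000L, 100L),
    acc_mean = c(70, 70, 70, 60),
    auc_mean = c(0.7, 0.6, 0.6, 0.8),
    mcc_mean = c(0.4, 0.3, 0.3, 0.1))), class = "exocargo_cv")
  best <- grid_select(cv, "ACC")
  expect_equal(best$n_trees, 500L) # tie broken toward fewer trees
  expect_equal(best$scheme, "AA")
  expect_equal(grid_select(cv, "AUC")$scheme, "PCP")
  single <- structure(list(aggregate = cv$aggregate[1, ]), class = "exocargo_cv")
  expect_equal(grid_select(single, "MCC")$scheme, "DP")
  empty <- structure(list(aggregate = cv$aggregate[0, ]), class = "exocargo_cv")
  expect_error(grid_select(empty), "empty")
})

test_that("a dominant scheme wins the sweep it was constructed to win", {
  # dipeptide-only signal: marginal composition matched across classes
  dp_data <- generate_synthetic(synthetic_config(
    n_pos = 80, n_neg = 80, length_range = c(60, 120), bias_strength = 0.9,
    signal_mode = "dipeptide_bias", seed = 202))
  cfg <- train_config(tree_grid = 150, n_folds = 3, n_repeats = 1, seed = 31)
  cv <- cv_sweep(dp_data$records, schemes = c("AA", "DP"), config = cfg)
  expect_equal(grid_select(cv, "ACC")$scheme, "DP")
})

test_that("model bundles survive a save/load round-trip exactly", {
  feats <- encode_dataset(sep_data$records, "AA")
  m <- train_forest(feats, sep_data$records$label, n_trees = 120, seed = 9,
                    scheme = "AA")
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  probe <- sep_data$records[seq(1, 120, by = 12), ]
  expect_identical(predict_scores(back, probe)$score,
                   predict_scores(m, probe)$score)
  expect_equal(back$scheme, "AA")
  expect_equal(back$n_trees, 120L)
  expect_equal(back$seed, 9L)
})

test_that("corrupted or foreign model files are refused", {
  trunc <- tempfile(fileext = ".rds")
  full <- tempfile(fileext = ".rds")
  feats <- encode_dataset(sep_data$records[c(1:5, 61:65), ], "AA")
  m <- train_forest(feats, rep(c("positive", "negative"), each = 5),
                    n_trees = 30, seed = 1)
  save_model(m, full)
  bytes <- readBin(full, "raw", file.info(full)$size)
  writeBin(bytes[1:20], trunc)
  expect_error(load_model(trunc), "cannot read")
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not an exocargo model")
  expect_error(save_model(list(), tempfile()), "not an exocargo_model")
})

test_that("configuration validation catches bad grids and thresholds", {
  expect_error(train_config(tree_grid = c(100, 100)), "strictly increasing")
  expect_error(train_config(tree_grid = c(-5, 10)), "positive")
  expect_error(train_config(n_folds = 1), "n_folds")
  expect_error(train_config(n_repeats = 0), "n_repeats")
  expect_error(train_config(decision_threshold = 1), "decision_threshold")
  expect_equal(length(default_tree_grid()), 31)
  expect_equal(default_tree_grid()[c(1, 19, 20, 31)],
               c(100L, 1000L, 1500L, 10000L))
})

test_that("tidy and glance summarise models and sweeps", {
  feats <- encode_dataset(sep_data$records, "AA")
  m <- train_forest(feats, sep_data$records$label, n_trees = 80, seed = 4,
                    scheme = "AA")
  td <- tidy(m)
  expect_equal(names(td), c("feature", "importance"))
  expect_equal(nrow(td), 20)
  expect_true(all(diff(td$importance) <= 0))
  gl <- glance(m)
  expect_equal(gl$scheme, "AA")
  expect_equal(gl$n_trees, 80L)

  cfg <- train_config("AA", tree_grid = c(50, 80), n_folds = 3, n_repeats = 1,
                      seed = 55)
  cv <- cross_validate(sep_data$records, cfg)
  expect_s3_class(autoplot(cv), "ggplot")
  gcv <- glance(cv)
  expect_equal(gcv$n_tree_values, 2)
})
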