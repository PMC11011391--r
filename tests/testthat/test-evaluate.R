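test_that("balancing keeps the minority class and subsamples the majority", {
  set.seed(50)
  ids <- sprintf("S%03d", 1:267)
  y <- make_labels(c(rep(1, 89), rep(0, 178)), ids)
  picked <- balance_downsample(ids, y, minority_multiplier = 1,
                               majority_fraction = 0.3)
  expect_equal(sum(y[picked] == "nonsurvivor"), 89L)   # minority kept in full
  expect_equal(sum(y[picked] == "survivor"), 54L)      # ceil(0.3 * 178)
  expect_equal(anyDuplicated(picked), 0L)

  # fraction 1 with multiplier 1 is the identity (as a set)
  all_kept <- balance_downsample(ids, y, 1, 1)
  expect_setequal(all_kept, ids)

  # already balanced input, fraction 1: unchanged
  idsb <- sprintf("B%02d", 1:40)
  yb <- make_labels(rep(c(0, 1), 20), idsb)
  expect_setequal(balance_downsample(idsb, yb, 1, 1), idsb)

  expect_error(balance_downsample(ids, make_labels(rep(1, 267), ids), 1, 0.3),
               "two classes")
})

test_that("pooled AUC matches the pair-counting oracle", {
  expect_equal(pooled_roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  expect_equal(pooled_roc_auc(rep(0.7, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 4-point hand case
  expect_equal(pooled_roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(pooled_roc_auc(c(0.1, 0.9), c(1, 1)), "each class")

  pair_count <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(51)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    s <- round(runif(n), sample(1:3, 1))              # ties likely
    expect_equal(pooled_roc_auc(s, y)$auc, pair_count(s, y))
  }
})

test_that("ROC points are monotone non-decreasing", {
  set.seed(52)
  s <- runif(50); y <- sample(0:1, 50, replace = TRUE, prob = c(0.6, 0.4))
  roc <- pooled_roc_auc(s, y)$roc
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
  expect_equal(c(roc$tpr[nrow(roc)], roc$fpr[nrow(roc)]), c(1, 1))
})

test_that("SHAP has a closed form for a single-feature model", {
  x <- matrix(c(0.2, 0.9, 0.4), 3, 1,
              dimnames = list(c("A", "B", "C"), "f"))
  bg <- matrix(0.5, 1, 1, dimnames = list("bg", "f"))
  f <- function(model, newdata) 2 * newdata[, "f"]
  phi <- shap_values(NULL, x, bg, nsim = 3, predict_fun = f)
  expect_equal(unname(phi[, "f"]), 2 * (x[, "f"] - 0.5), ignore_attr = TRUE)
})

test_that("duplicated features receive equal SHAP under an additive model", {
  set.seed(53)
  x <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("S%d", 1:5), c("a", "b")))
  x[, "b"] <- x[, "a"]
  bg <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  bg[, "b"] <- bg[, "a"]  # symmetry needs identical background columns too
  f <- function(model, newdata) newdata[, "a"] + newdata[, "b"]
  phi <- shap_values(NULL, x, bg, nsim = 20, predict_fun = f)
  expect_equal(phi[, "a"], phi[, "b"], tolerance = 1e-10)
})

test_that("a feature the model ignores gets (near) zero SHAP", {
  set.seed(54)
  n <- 80
  y <- factor(rep(c("survivor", "nonsurvivor"), each = n / 2),
              levels = c("survivor", "nonsurvivor"))
  x <- cbind(signal = as.integer(y == "nonsurvivor") + rnorm(n, sd = 0.1),
             dead = rep(1.5, n))  # constant: the forest can never split on it
  rownames(x) <- sprintf("S%02d", 1:n)
  rf <- randomForest::randomForest(x, y, ntree = 200)
  phi <- shap_values(rf, x[1:10, ], x, nsim = 20)
  expect_lt(mean(abs(phi[, "dead"])), 1e-8)
  expect_gt(mean(abs(phi[, "signal"])), 0.1)
})

test_that("nested CV predicts every sample exactly once per repeat", {
  set.seed(55)
  n <- 60
  y <- c(rep(1, 20), rep(0, 40))
  v <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("f%d", 1:6)))
  v[, 1] <- y * 2 + rnorm(n, sd = 0.5)
  cfg <- nested_cv_config(outer_folds = 5, tune_grid_size = 2, repeats = 2,
                          ntree = 60, seed = 7)
  res <- nested_cv_evaluate(make_fm(v), make_labels(y, rownames(v)), cfg)
  for (r in 1:2) {
    pr <- res$predictions[res$predictions$repeat_id == r, ]
    expect_setequal(pr$sample_id, rownames(v))
    expect_equal(anyDuplicated(pr$sample_id), 0L)
    expect_true(all(!is.na(pr$prob)))
  }
  expect_equal(dim(res$chosen_mtry), c(5L, 2L))
  expect_true(all(res$auc_per_repeat >= 0 & res$auc_per_repeat <= 1))
})

test_that("nested CV separates a planted feature and stays null on noise", {
  set.seed(56)
  n <- 60
  y <- c(rep(1, 20), rep(0, 40))
  ids <- sprintf("S%02d", 1:n)
  sep <- matrix(c(y * 4 + rnorm(n, sd = 0.3), rnorm(n)), n, 2,
                dimnames = list(ids, c("planted", "noise")))
  cfg <- nested_cv_config(outer_folds = 5, tune_grid_size = 2, repeats = 3,
                          ntree = 100, seed = 8)
  strong <- nested_cv_evaluate(make_fm(sep), make_labels(y, ids), cfg)
  expect_gte(strong$mean_auc, 0.95)

  noise <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, sprintf("f%d", 1:5)))
  null <- nested_cv_evaluate(make_fm(noise), make_labels(y, ids), cfg)
  expect_lt(null$mean_auc, strong$mean_auc)
  expect_gt(null$mean_auc, 0.25)
  expect_lt(null$mean_auc, 0.75)
})

test_that("samples with missing features are dropped with a record", {
  set.seed(57)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  ids <- sprintf("S%02d", 1:n)
  v <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, sprintf("f%d", 1:4)))
  v[, 1] <- y * 3 + rnorm(n, sd = 0.5)
  v[c(3, 17), 2] <- NA
  cfg <- nested_cv_config(outer_folds = 4, tune_grid_size = 1, repeats = 1,
                          ntree = 50, seed = 9)
  expect_message(
    res <- nested_cv_evaluate(make_fm(v), make_labels(y, ids), cfg),
    "dropping 2 sample")
  expect_equal(res$n_dropped_samples, 2L)
  expect_false(any(c("S03", "S17") %in% res$predictions$sample_id))
})

test_that("nested CV outputs round-trip through the writers", {
  set.seed(58)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  ids <- sprintf("S%02d", 1:n)
  v <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, sprintf("f%d", 1:3)))
  v[, 1] <- y + rnorm(n, sd = 0.6)
  cfg <- nested_cv_config(outer_folds = 4, tune_grid_size = 1, repeats = 1,
                          ntree = 50, compute_shap = TRUE, shap_nsim = 3,
                          seed = 10)
  res <- nested_cv_evaluate(make_fm(v), make_labels(y, ids), cfg)
  dir <- withr::local_tempdir()
  write_nested_cv(res, dir)
  expect_true(all(file.exists(file.path(dir, c("predictions.tsv", "roc_points.tsv",
                                               "auc_summary.tsv", "shap_matrix.tsv")))))
  shap_back <- t(read_matrix_tsv(file.path(dir, "shap_matrix.tsv")))
  expect_equal(dim(shap_back), dim(res$shap))
})
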