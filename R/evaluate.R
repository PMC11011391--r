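#' Class-balancing down-sampler
#'
#' Rebalances a two-class training set: the minority class is kept in
#' full (multiplier 1) or resampled to \code{multiplier} times its size;
#' the majority class is subsampled without replacement to
#' \code{ceiling(fraction * size)}.  With the defaults (multiplier 1,
#' fraction 0.3) a 178-survivor / 89-nonsurvivor cohort becomes 54
#' survivors + 89 nonsurvivors.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Named factor over (at least) those ids, two classes
#'   present.
#' @param minority_multiplier Minority resampling factor; default 1
#'   (keep as is).
#' @param majority_fraction Fraction of the majority class retained;
#'   default 0.3.
#' @return Character vector of selected sample ids (duplicates possible
#'   only when \code{minority_multiplier > 1}).
#' @export
balance_downsample <- function(sample_ids, labels,
                               minority_multiplier = 1,
                               majority_fraction = 0.3) {
  stopifnot(majority_fraction > 0, majority_fraction <= 1)
  y <- labels[sample_ids]
  tab <- table(factor(y))
  tab <- tab[tab > 0]
  if (length(tab) != 2) stop("balance_downsample needs exactly two classes present", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  min_ids <- sample_ids[y == minority]
  maj_ids <- sample_ids[y == majority]
  n_maj <- ceiling(majority_fraction * length(maj_ids))
  if (n_maj < 1) stop("majority_fraction leaves no majority samples", call. = FALSE)
  keep_min <- if (minority_multiplier == 1) min_ids else
    sample(min_ids, round(minority_multiplier * length(min_ids)),
           replace = minority_multiplier > 1)
  keep_maj <- sample(maj_ids, n_maj)
  c(keep_min, keep_maj)
}

#' Pooled ROC curve and AUC
#'
#' AUC computed from the rank statistic (Mann-Whitney with midranks for
#' ties); the ROC curve is traced over the distinct score thresholds.
#' Scores are probabilities of the positive (nonsurvivor) class.
#'
#' @param scores Numeric prediction scores.
#' @param labels Factor (levels survivor/nonsurvivor) or logical/0-1
#'   vector where TRUE/1 marks the positive class.
#' @return List with \code{roc} (data frame fpr/tpr/threshold, monotone)
#'   and \code{auc}.
#' @export
pooled_roc_auc <- function(scores, labels) {
  pos <- if (is.factor(labels)) labels == "nonsurvivor" else as.logical(labels)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("pooled_roc_auc needs at least one sample of each class", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1)),
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  )
  list(roc = roc, auc = auc)
}

#' Nested cross-validation configuration
#'
#' @param outer_folds Outer stratified folds (default 10).
#' @param tune_grid_size Number of variables-per-split candidates tried
#'   in the inner leave-one-out loop (default 10).
#' @param minority_multiplier,majority_fraction Balancing parameters
#'   (see [balance_downsample()]; defaults 1 and 0.3).
#' @param repeats Number of full nested-CV repetitions (default 100).
#' @param shap_nsim Monte-Carlo coalitions per explained sample for SHAP
#'   (default 10).
#' @param ntree Trees per random forest (default 500).
#' @param compute_shap Whether to compute SHAP attributions.
#' @param seed Master seed; repeat r uses substream seed + r.
#' @return A \code{nested_cv_config} list.
#' @export
nested_cv_config <- function(outer_folds = 10L, tune_grid_size = 10L,
                             minority_multiplier = 1, majority_fraction = 0.3,
                             repeats = 100L, shap_nsim = 10L, ntree = 500L,
                             compute_shap = FALSE, seed = 1L) {
  stopifnot(majority_fraction > 0, majority_fraction <= 1, repeats >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 tune_grid_size = as.integer(tune_grid_size),
                 minority_multiplier = minority_multiplier,
                 majority_fraction = majority_fraction,
                 repeats = as.integer(repeats),
                 shap_nsim = as.integer(shap_nsim),
                 ntree = as.integer(ntree),
                 compute_shap = isTRUE(compute_shap),
                 seed = as.integer(seed)),
            class = "nested_cv_config")
}

# variables-per-split candidates: evenly spaced on the square-root scale
# between 2 and p (so the default random-forest choice sqrt(p) sits near
# the middle of the grid)
.mtry_grid <- function(p, size) {
  if (p <= 2) return(unique(pmin(p, c(1L, 2L)))[seq_len(min(size, 2))])
  g <- unique(pmax(1L, round(seq(sqrt(2), sqrt(p), length.out = size)^2)))
  pmin(g, p)
}

.rf_prob <- function(model, newdata) {
  predict(model, newdata, type = "prob")[, "nonsurvivor"]
}

#' Monte-Carlo SHAP attribution for a probability classifier
#'
#' Approximates Shapley values by sampling feature coalitions: for each
#' explained sample and each of \code{nsim} draws, a random background
#' row and a random feature ordering are taken, and each feature's
#' contribution is the change in predicted positive-class probability
#' when it switches from the background value to the explained sample's
#' value, given that the features preceding it in the ordering already
#' did.  Positive values push the prediction towards the positive
#' (nonsurvivor) class.
#'
#' @param model Fitted classifier accepted by \code{predict_fun}.
#' @param x Samples-by-features matrix of rows to explain.
#' @param background Samples-by-features matrix of background rows.
#' @param nsim Number of Monte-Carlo coalitions per sample.
#' @param predict_fun Function \code{(model, newdata) -> positive-class
#'   probability vector}; defaults to random-forest probability votes.
#' @return Samples-by-features matrix of SHAP values.
#' @export
shap_values <- function(model, x, background, nsim = 10L,
                        predict_fun = .rf_prob) {
  n <- nrow(x); p <- ncol(x)
  phi <- matrix(0, n, p, dimnames = dimnames(x))
  if (p == 0 || n == 0) return(phi)
  for (s in seq_len(nsim)) {
    ord <- sample.int(p)
    bg <- background[sample.int(nrow(background), n, replace = TRUE), , drop = FALSE]
    # chain of p+1 hybrid rows per sample: k-th has the first k features
    # (in `ord`) from x, the rest from the background row
    rows <- matrix(0, n * (p + 1), p, dimnames = list(NULL, colnames(x)))
    for (k in 0:p) {
      hyb <- bg
      if (k > 0) hyb[, ord[seq_len(k)]] <- x[, ord[seq_len(k)], drop = FALSE]
      rows[seq_len(n) + k * n, ] <- hyb
    }
    preds <- predict_fun(model, rows)
    for (k in seq_len(p)) {
      delta <- preds[seq_len(n) + k * n] - preds[seq_len(n) + (k - 1) * n]
      phi[, ord[k]] <- phi[, ord[k]] + delta
    }
  }
  phi / nsim
}

#' Balanced nested cross-validation of a random-forest survival classifier
#'
#' Per repeat: a stratified outer split into \code{outer_folds} folds;
#' within each outer training portion the classes are balanced by
#' down-sampling, an inner leave-one-out loop evaluates each candidate
#' of the variables-per-split grid by pooling all leave-one-out
#' predictions into a single AUC, and the best candidate is refit on the
#' balanced training portion and applied to the untouched outer test
#' fold.  Outer predictions are pooled per repeat into one ROC/AUC.
#' Outer test folds never participate in balancing, tuning or fitting.
#'
#' @param fm A \code{feature_matrix}.
#' @param labels A \code{label_set} or named factor.
#' @param config A [nested_cv_config()].
#' @return Object of class \code{nested_cv_result}: \code{predictions}
#'   (sample, repeat, fold, predicted probability, true label),
#'   \code{auc_per_repeat}, \code{mean_auc}, \code{sd_auc},
#'   \code{chosen_mtry} (folds x repeats), \code{shap}
#'   (samples-by-features, averaged over repeats; NULL unless
#'   \code{compute_shap}), \code{n_dropped_samples} and \code{config}.
#' @export
nested_cv_evaluate <- function(fm, labels, config = nested_cv_config()) {
  al <- .align_labels(fm, labels)
  x <- al$x; y <- al$y
  # samples missing feature values cannot be scored by the forest and
  # are dropped up front (with a record of how many)
  complete <- rowSums(is.na(x)) == 0
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("nested_cv_evaluate: dropping %d sample(s) with missing features",
                    n_dropped))
  x <- x[complete, , drop = FALSE]; y <- y[complete]
  n <- nrow(x); p <- ncol(x)
  if (length(unique(y)) < 2) stop("labels contain a single class", call. = FALSE)

  grid <- .mtry_grid(p, config$tune_grid_size)
  preds_all <- vector("list", config$repeats)
  auc_per_repeat <- numeric(config$repeats)
  chosen <- matrix(NA_integer_, config$outer_folds, config$repeats)
  shap_sum <- if (config$compute_shap)
    matrix(0, n, p, dimnames = dimnames(x)) else NULL

  for (r in seq_len(config$repeats)) {
    set.seed(config$seed + r)
    foldid <- .stratified_folds(y, config$outer_folds)
    prob <- rep(NA_real_, n)
    for (fold in seq_len(config$outer_folds)) {
      test <- which(foldid == fold)
      train <- which(foldid != fold)
      bal_ids <- balance_downsample(rownames(x)[train],
                                    setNames(y, rownames(x))[rownames(x)[train]],
                                    config$minority_multiplier,
                                    config$majority_fraction)
      xb <- x[bal_ids, , drop = FALSE]
      yb <- y[match(bal_ids, rownames(x))]
      if (length(unique(yb)) < 2)
        stop(sprintf("repeat %d fold %d: single class after balancing", r, fold),
             call. = FALSE)
      # inner LOOCV over the mtry grid, pooling all held-out predictions
      best_m <- grid[1]; best_auc <- -Inf
      for (m in grid) {
        loo <- vapply(seq_len(nrow(xb)), function(i) {
          yi <- yb[-i]
          if (length(unique(yi)) < 2) return(NA_real_)
          rf <- randomForest::randomForest(xb[-i, , drop = FALSE], yi,
                                           ntree = config$ntree, mtry = m)
          .rf_prob(rf, xb[i, , drop = FALSE])
        }, numeric(1))
        ok <- !is.na(loo)
        if (length(unique(yb[ok])) < 2) next
        a <- pooled_roc_auc(loo[ok], yb[ok])$auc
        if (a > best_auc) { best_auc <- a; best_m <- m }
      }
      chosen[fold, r] <- best_m
      rf <- randomForest::randomForest(xb, yb, ntree = config$ntree, mtry = best_m)
      prob[test] <- .rf_prob(rf, x[test, , drop = FALSE])
      if (config$compute_shap) {
        shap_sum[test, ] <- shap_sum[test, , drop = FALSE] +
          shap_values(rf, x[test, , drop = FALSE], xb, config$shap_nsim)
      }
    }
    auc_per_repeat[r] <- pooled_roc_auc(prob, y)$auc
    preds_all[[r]] <- data.frame(sample_id = rownames(x), repeat_id = r,
                                 fold = foldid, prob = prob,
                                 label = as.character(y),
                                 stringsAsFactors = FALSE)
  }

  structure(list(
    predictions = do.call(rbind, preds_all),
    auc_per_repeat = auc_per_repeat,
    mean_auc = mean(auc_per_repeat),
    sd_auc = sd(auc_per_repeat),
    chosen_mtry = chosen,
    shap = if (config$compute_shap) shap_sum / config$repeats else NULL,
    n_dropped_samples = n_dropped,
    config = config
  ), class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested_cv_result: %d repeats x %d outer folds; mean AUC %.3f (sd %.3f)\n",
              x$config$repeats, x$config$outer_folds, x$mean_auc,
              ifelse(is.na(x$sd_auc), 0, x$sd_auc)))
  invisible(x)
}

#' Write nested-CV outputs: predictions, ROC points, AUC summary, SHAP
#' @param result A \code{nested_cv_result}.
#' @param dir Output directory (created if needed).
#' @export
write_nested_cv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$predictions, file.path(dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pooled <- pooled_roc_auc(result$predictions$prob,
                           factor(result$predictions$label,
                                  levels = c("survivor", "nonsurvivor")))
  write.table(pooled$roc, file.path(dir, "roc_points.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_df <- data.frame(mean_auc = result$mean_auc, sd_auc = result$sd_auc,
                           pooled_auc = pooled$auc,
                           repeats = result$config$repeats)
  write.table(summary_df, file.path(dir, "auc_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$shap))
    write_matrix_tsv(t(result$shap), file.path(dir, "shap_matrix.tsv"),
                     id_col = "feature_id")
  invisible(dir)
}
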