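#' Remove constant (zero-variance) features
#'
#' @param fm A \code{feature_matrix}.
#' @return A \code{feature_matrix} without columns that take a single
#'   value across all samples.  Idempotent.
#' @export
zero_variance_filter <- function(fm) {
  v <- fm$values
  keep <- apply(v, 2, function(x) length(unique(x[!is.na(x)])) > 1L)
  fm_subset(fm, features = colnames(v)[keep])
}

#' Greedy correlation-based feature filter
#'
#' Removes one member of every feature pair correlated above
#' \code{cutoff}: pairs are processed in order of decreasing |Pearson r|
#' and from each pair the member with the larger mean absolute
#' correlation against all remaining features is dropped (ties broken
#' towards the later column).  The surviving matrix has no pair above
#' the cutoff.  Run [zero_variance_filter()] first: constant columns
#' have undefined correlations.
#'
#' @param fm A \code{feature_matrix} with no constant columns.
#' @param cutoff Absolute correlation threshold in (0, 1); default 0.9.
#' @return List with \code{matrix} (filtered \code{feature_matrix}) and
#'   \code{removed} (character vector of dropped feature ids, in removal
#'   order).
#' @export
correlation_filter <- function(fm, cutoff = 0.9) {
  stopifnot(cutoff > 0, cutoff < 1)
  v <- fm$values
  ids <- colnames(v)
  cm <- abs(cor(v, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(v))
  removed <- character(0)
  repeat {
    sub <- cm
    sub[!alive, ] <- 0; sub[, !alive] <- 0
    top <- max(sub)
    if (top <= cutoff) break
    idx <- which(sub == top, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    mean_i <- mean(cm[i, alive & seq_along(alive) != i])
    mean_j <- mean(cm[j, alive & seq_along(alive) != j])
    drop <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    alive[drop] <- FALSE
    removed <- c(removed, ids[drop])
  }
  list(matrix = fm_subset(fm, features = ids[alive]), removed = removed)
}

.align_labels <- function(fm, labels) {
  lab <- if (inherits(labels, "label_set")) labels$labels else labels
  samples <- intersect(rownames(fm$values), names(lab))
  if (length(samples) == 0) stop("no overlap between matrix samples and labels", call. = FALSE)
  y <- factor(as.character(lab[samples]), levels = c("survivor", "nonsurvivor"))
  if (length(unique(y)) < 2) stop("labels contain a single class", call. = FALSE)
  list(x = fm$values[samples, , drop = FALSE], y = y, samples = samples)
}

.stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Cross-validated AUC along an L1-penalized logistic regression path
#'
#' Fits an L1-penalized (lasso) logistic regression along a decreasing
#' penalty path with standardized predictors, and records for each path
#' point the number of nonzero coefficients on the full data together
#' with the stratified n-fold cross-validated AUC — a profile of how
#' predictive each omics layer is as a function of how many of its
#' features the model is allowed to use.
#'
#' @param fm A \code{feature_matrix} (pre-filtered: no constant columns).
#' @param labels A \code{label_set} or named factor.
#' @param n_folds Cross-validation folds; default 10.
#' @param max_features Largest nonzero-coefficient count reported;
#'   default 100.
#' @param seed Optional integer seed for the fold assignment.
#' @return Object of class \code{lasso_profile}: \code{points} (data
#'   frame with \code{n_nonzero}, \code{mean_cv_auc}, \code{sd_cv_auc},
#'   \code{penalty}) and \code{selected_features} (list of nonzero
#'   feature ids per point).
#' @export
lasso_auc_profile <- function(fm, labels, n_folds = 10L, max_features = 100L,
                              seed = NULL) {
  al <- .align_labels(fm, labels)
  if (!is.null(seed)) set.seed(seed)
  foldid <- .stratified_folds(al$y, n_folds)
  cvfit <- glmnet::cv.glmnet(al$x, al$y, family = "binomial", alpha = 1,
                             standardize = TRUE, type.measure = "auc",
                             foldid = foldid)
  keep <- cvfit$nzero <= max_features
  beta <- cvfit$glmnet.fit$beta
  sel <- lapply(which(keep), function(i) rownames(beta)[beta[, i] != 0])
  structure(list(
    points = data.frame(n_nonzero = as.integer(cvfit$nzero[keep]),
                        mean_cv_auc = cvfit$cvm[keep],
                        sd_cv_auc = cvfit$cvsd[keep],
                        penalty = cvfit$lambda[keep]),
    selected_features = sel
  ), class = "lasso_profile")
}

#' @export
print.lasso_profile <- function(x, ...) {
  cat(sprintf("lasso_profile: %d path points, best mean CV-AUC %.3f at %d features\n",
              nrow(x$points), max(x$points$mean_cv_auc),
              x$points$n_nonzero[which.max(x$points$mean_cv_auc)]))
  invisible(x)
}

#' Write a lasso profile to TSV
#' @param profile A \code{lasso_profile}.
#' @param path Output path.
#' @export
write_lasso_profile <- function(profile, path) {
  write.table(profile$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shadow-feature random-forest selection (Boruta-style)
#'
#' Iteratively compares each feature's random-forest permutation
#' importance (Z-score of the mean decrease in accuracy over trees)
#' against the maximum importance among permuted "shadow" copies.  Each
#' run, every undecided feature receives a freshly permuted shadow; a
#' feature scores a hit when its importance exceeds the best shadow's.
#' After each run a two-sided binomial test (success probability 0.5,
#' Bonferroni-corrected over the currently undecided features at level
#' \code{alpha}) promotes features with significantly many hits to
#' Confirmed and demotes those with significantly few to Rejected;
#' rejected features leave the model.  The loop ends when every feature
#' is decided or after \code{max_runs} runs, features still undecided
#' being reported Tentative.
#'
#' @param fm A \code{feature_matrix}.
#' @param labels A \code{label_set} or named factor.
#' @param max_runs Maximum shadow runs; default 10000.
#' @param alpha Significance level of the binomial decision tests;
#'   default 0.01.
#' @param seed Optional integer seed.
#' @param ntree Trees per random forest; default 500.
#' @return Object of class \code{boruta_result}: \code{decision} (named
#'   factor Confirmed/Tentative/Rejected), \code{hit_counts},
#'   \code{importance_history} (runs-by-features matrix, NA once a
#'   feature has left the model), \code{mean_importance} (run-averaged,
#'   the ranking statistic) and \code{runs_performed}.
#' @export
boruta_rank <- function(fm, labels, max_runs = 10000L, alpha = 0.01,
                        seed = NULL, ntree = 500L) {
  stopifnot(max_runs >= 10 || ncol(fm$values) == 0)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(fm$values)
  ids <- colnames(fm$values)
  if (p == 0L) {
    return(structure(list(
      decision = factor(character(0), levels = c("Confirmed", "Tentative", "Rejected")),
      hit_counts = integer(0),
      importance_history = matrix(numeric(0), 0, 0),
      mean_importance = numeric(0),
      runs_performed = 0L
    ), class = "boruta_result"))
  }
  al <- .align_labels(fm, labels)
  if (min(table(al$y)) < 2) stop("need at least 2 samples per class", call. = FALSE)
  x <- al$x; y <- al$y; n <- nrow(x)

  decision <- rep("Tentative", p)
  hits <- integer(p)
  history <- matrix(NA_real_, max_runs, p, dimnames = list(NULL, ids))
  run <- 0L
  while (run < max_runs) {
    undecided <- which(decision == "Tentative")
    if (length(undecided) == 0L) break
    run <- run + 1L
    active <- which(decision != "Rejected")
    shadows <- apply(x[, undecided, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0(".shadow.", ids[undecided])
    xm <- cbind(x[, active, drop = FALSE], shadows)
    rf <- randomForest::randomForest(xm, y, ntree = ntree, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    real_imp <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    history[run, active] <- real_imp
    names(real_imp) <- NULL
    hit_now <- active[real_imp > shadow_max]
    hits[intersect(hit_now, undecided)] <- hits[intersect(hit_now, undecided)] + 1L
    m <- length(undecided)
    for (f in undecided) {
      p_hi <- pbinom(hits[f] - 1L, run, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[f], run, 0.5)
      if (2 * p_hi < alpha / m) decision[f] <- "Confirmed"
      else if (2 * p_lo < alpha / m) decision[f] <- "Rejected"
    }
  }
  history <- history[seq_len(run), , drop = FALSE]
  dec <- factor(decision, levels = c("Confirmed", "Tentative", "Rejected"))
  names(dec) <- ids
  names(hits) <- ids
  structure(list(
    decision = dec,
    hit_counts = hits,
    importance_history = history,
    mean_importance = colMeans(history, na.rm = TRUE),
    runs_performed = run
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("boruta_result: %d runs; %d Confirmed, %d Tentative, %d Rejected\n",
              x$runs_performed, sum(x$decision == "Confirmed"),
              sum(x$decision == "Tentative"), sum(x$decision == "Rejected")))
  invisible(x)
}

#' Write Boruta decisions (and the importance history) to TSV
#' @param result A \code{boruta_result}.
#' @param path Decision TSV path; the run-by-feature importance history
#'   goes to \code{<path>.history.tsv}.
#' @export
write_boruta <- function(result, path) {
  df <- data.frame(feature_id = names(result$decision),
                   decision = as.character(result$decision),
                   hit_count = result$hit_counts,
                   mean_importance = result$mean_importance,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hist_df <- data.frame(run = seq_len(nrow(result$importance_history)),
                        result$importance_history, check.names = FALSE)
  write.table(hist_df, paste0(path, ".history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
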