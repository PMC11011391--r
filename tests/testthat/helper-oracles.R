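# Independent reference implementations (oracles) shared by the module
# tests and the acceptance suite.

# base-pair-resolution reference implementation of the region partition
bp_oracle <- function(segments, genome_len, neutral = 0, min_support = 2L) {
  samples <- unique(segments$sample_id)
  prof <- matrix(neutral, length(samples), genome_len,
                 dimnames = list(samples, NULL))
  for (k in seq_len(nrow(segments))) {
    prof[segments$sample_id[k], segments$start[k]:segments$end[k]] <-
      segments$segment_mean[k]
  }
  support <- colSums(prof != neutral)
  keep <- support >= min_support
  # maximal runs of adjacent kept positions with identical profiles
  regions <- list()
  j <- 1L
  while (j <= genome_len) {
    if (!keep[j]) { j <- j + 1L; next }
    start <- j
    while (j + 1L <= genome_len && keep[j + 1L] &&
           identical(prof[, j + 1L], prof[, start])) j <- j + 1L
    regions[[length(regions) + 1L]] <-
      list(start = start, end = j, values = prof[, start])
    j <- j + 1L
  }
  regions
}

# data whose empirical correlation matrix is exactly R
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  x <- matrix(rnorm(n * p), n, p)
  xc <- scale(x, center = TRUE, scale = FALSE)
  w <- xc %*% solve(chol(cov(xc)))       # whitened: unit sample covariance
  y <- w %*% chol(R)
  dimnames(y) <- list(sprintf("S%02d", 1:n), sprintf("f%d", 1:p))
  y
}

# exhaustive implementation of the greedy correlation filter
greedy_oracle <- function(v, cutoff) {
  ids <- colnames(v)
  cm <- abs(cor(v)); diag(cm) <- 0
  alive <- setNames(rep(TRUE, ncol(v)), ids)
  removed <- character(0)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (nrow(sub) < 2 || max(sub) <= cutoff) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- rownames(sub)[idx]
    means <- vapply(pair, function(f)
      mean(cm[f, setdiff(names(alive)[alive], f)]), numeric(1))
    drop <- if (means[1] > means[2]) pair[1]
            else if (means[2] > means[1]) pair[2]
            else pair[which.max(match(pair, ids))]
    alive[drop] <- FALSE
    removed <- c(removed, drop)
  }
  list(kept = ids[alive], removed = removed)
}

# pair-counting AUC oracle (Mann-Whitney with half-credit for ties)
pair_count_auc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
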