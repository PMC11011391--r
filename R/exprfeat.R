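#' Remove features below a minimum read count in every sample
#'
#' A feature is retained iff at least one sample reaches
#' \code{min_reads}; with the default of 10 this removes features
#' showing fewer than 10 reads in all samples.  Idempotent.
#'
#' @param counts Features-by-samples non-negative integer matrix.
#' @param min_reads Minimum count; default 10.
#' @return Filtered count matrix.
#' @export
filter_min_count <- function(counts, min_reads = 10L) {
  stopifnot(min_reads >= 0)
  keep <- apply(counts, 1, max) >= min_reads
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size-factor normalization
#'
#' The standard bulk RNA-seq between-sample normalization: per-feature
#' geometric means are computed over features with no zero count; each
#' sample's size factor is the median of its count-to-geometric-mean
#' ratios over those features; normalized values are counts divided by
#' the size factor.  Scale-equivariant: multiplying one sample's counts
#' by c multiplies its factor by c and leaves its normalized profile
#' unchanged.
#'
#' @param counts Features-by-samples non-negative count matrix.
#' @return List with \code{normalized} (same shape as \code{counts}) and
#'   \code{size_factors} (named per-sample positive reals).
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  positive <- rowSums(counts == 0) == 0
  if (!any(positive))
    stop("no feature has positive counts in every sample; cannot compute size factors",
         call. = FALSE)
  log_geomean <- rowMeans(log(counts[positive, , drop = FALSE]))
  ratios <- counts[positive, , drop = FALSE] / exp(log_geomean)
  size_factors <- apply(ratios, 2, median)
  names(size_factors) <- colnames(counts)
  list(normalized = sweep(counts, 2, size_factors, "/"),
       size_factors = size_factors)
}

#' Principal-component feature extraction
#'
#' Condenses a feature matrix to its first \code{k} principal-component
#' scores, components ordered by decreasing explained variance.  Sign
#' convention: each component is flipped so that its largest-magnitude
#' loading is positive, making scores deterministic across eigensolvers.
#'
#' @param fm A \code{feature_matrix} with no missing values.
#' @param k Number of components; must not exceed
#'   \code{min(n_samples - 1, n_features)}.
#' @return List with \code{scores} (a \code{feature_matrix}, method
#'   \code{pca}) and \code{model} (class \code{pca_model}: loadings,
#'   per-feature centers, explained-variance fractions).
#' @export
pca_features <- function(fm, k) {
  v <- fm$values
  if (anyNA(v)) stop("PCA requires a complete matrix (no missing values)", call. = FALSE)
  kmax <- min(nrow(v) - 1L, ncol(v))
  if (k < 1 || k > kmax)
    stop(sprintf("k must be in 1..%d for a %d x %d matrix", kmax, nrow(v), ncol(v)),
         call. = FALSE)
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  omics <- unique(fm$provenance$omics)[1]
  colnames(scores) <- sprintf("%s_PC%d", omics, seq_len(k))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  model <- structure(list(loadings = rot, centers = pc$center,
                          explained_variance = ev[seq_len(k)]),
                     class = "pca_model")
  list(scores = feature_matrix(scores, omics = omics, method = "pca"),
       model = model)
}

#' Write a PCA model (loadings and centers) to TSV
#' @param model A \code{pca_model}.
#' @param path Output path.
#' @export
write_pca_model <- function(model, path) {
  df <- data.frame(feature_id = rownames(model$loadings),
                   center = model$centers, model$loadings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
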