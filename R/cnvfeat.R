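#' Partition copy-number segments into shared regions across samples
#'
#' Multi-sample region-overlap aggregation: per chromosome, all segment
#' breakpoints define elementary intervals; each sample's segment mean
#' (log2(CN/2) scale, 0 = neutral diploid) is painted onto the intervals
#' it covers; intervals altered (non-neutral) in fewer than
#' \code{min_support} samples are dropped; finally, genomically adjacent
#' retained intervals are merged when the fraction of samples whose
#' values agree exactly across the pair is at least \code{frac_overlap},
#' the merged value being the per-sample length-weighted mean.  With
#' \code{frac_overlap = 1} merging only ever joins intervals with
#' identical per-sample profiles.
#'
#' @param segments Segment data frame (see [read_seg()]).
#' @param frac_overlap Agreement fraction required to merge adjacent
#'   intervals, in (0, 1]; default 0.9.
#' @param neutral_value Value for unaltered positions; default 0
#'   (diploid on the log2(CN/2) scale).
#' @param min_support Minimum number of samples with a non-neutral value
#'   for an interval to be retained; default 2.
#' @param samples Optional sample set/ordering.
#' @return Object of class \code{region_partition}: \code{regions}
#'   (data frame chrom/start/end), \code{values} (samples-by-regions
#'   matrix), \code{support} (non-neutral sample count per region) and
#'   \code{neutral_value}.  Regions are non-overlapping and sorted.
#' @export
partition_segments <- function(segments, frac_overlap = 0.9,
                               neutral_value = 0, min_support = 2L,
                               samples = NULL) {
  stopifnot(frac_overlap > 0, frac_overlap <= 1)
  if (is.null(samples)) samples <- unique(segments$sample_id)
  n <- length(samples)

  region_chrom <- character(0)
  region_start <- integer(0)
  region_end <- integer(0)
  value_cols <- list()

  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(seg$start, seg$end + 1L)))
    if (length(bounds) < 2) next
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1L
    covered <- vapply(seq_along(starts), function(i) {
      any(seg$start <= starts[i] & seg$end >= ends[i])
    }, logical(1))
    starts <- starts[covered]; ends <- ends[covered]
    if (length(starts) == 0) next

    vals <- matrix(neutral_value, n, length(starts),
                   dimnames = list(samples, NULL))
    for (k in seq_len(nrow(seg))) {
      if (!seg$sample_id[k] %in% samples) next
      hit <- seg$start[k] <= starts & seg$end[k] >= ends
      vals[seg$sample_id[k], hit] <- seg$segment_mean[k]
    }
    support <- colSums(vals != neutral_value)
    keep <- support >= min_support
    if (!any(keep)) next
    starts <- starts[keep]; ends <- ends[keep]
    vals <- vals[, keep, drop = FALSE]

    # merge adjacent intervals with near-identical per-sample profiles
    m_start <- starts[1]; m_end <- ends[1]
    m_val <- vals[, 1] * (ends[1] - starts[1] + 1)
    m_len <- ends[1] - starts[1] + 1
    prev_col <- vals[, 1]
    flush <- function() {
      region_chrom <<- c(region_chrom, ch)
      region_start <<- c(region_start, m_start)
      region_end <<- c(region_end, m_end)
      value_cols[[length(value_cols) + 1L]] <<- m_val / m_len
    }
    for (j in seq_along(starts)[-1]) {
      adjacent <- starts[j] == m_end + 1L
      agree <- mean(vals[, j] == prev_col)
      len_j <- ends[j] - starts[j] + 1
      if (adjacent && agree >= frac_overlap) {
        m_end <- ends[j]
        m_val <- m_val + vals[, j] * len_j
        m_len <- m_len + len_j
      } else {
        flush()
        m_start <- starts[j]; m_end <- ends[j]
        m_val <- vals[, j] * len_j; m_len <- len_j
      }
      prev_col <- vals[, j]
    }
    flush()
  }

  values <- if (length(value_cols)) do.call(cbind, value_cols) else
    matrix(numeric(0), n, 0, dimnames = list(samples, NULL))
  regions <- data.frame(chrom = region_chrom, start = region_start,
                        end = region_end, stringsAsFactors = FALSE)
  if (nrow(regions)) {
    ord <- order(regions$chrom, regions$start)
    regions <- regions[ord, , drop = FALSE]
    values <- values[, ord, drop = FALSE]
    rownames(regions) <- NULL
  }
  colnames(values) <- if (nrow(regions))
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end) else character(0)
  rownames(values) <- samples
  structure(list(regions = regions, values = values,
                 support = colSums(values != neutral_value),
                 neutral_value = neutral_value),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: %d regions x %d samples\n",
              nrow(x$regions), nrow(x$values)))
  invisible(x)
}

#' Region-overlap CNV feature matrix from a partition
#' @param partition A \code{region_partition}.
#' @return A \code{feature_matrix} (omics \code{cnv}, method
#'   \code{region_overlap}) of per-region segment means.
#' @export
region_cn_matrix <- function(partition) {
  feature_matrix(partition$values, omics = "cnv", method = "region_overlap")
}

#' Gene-level copy-number matrix
#'
#' Assigns each gene the segment mean of the altered region it overlaps —
#' even when the region covers only part of the gene.  When several
#' altered regions overlap a gene, the one with the largest overlap
#' length wins; genes overlapping no altered region get the neutral
#' value.  Accepts either a \code{region_partition} (shared altered
#' regions; assignment is the same region for every sample) or a raw
#' segment data frame (per-sample assignment).
#'
#' @param x A \code{region_partition} or segment data frame.
#' @param gene_models Gene model data frame (see [read_bed()]).
#' @param neutral_value Used when \code{x} is a segment data frame;
#'   otherwise taken from the partition.
#' @param samples Sample set when \code{x} is a segment data frame.
#' @return A \code{feature_matrix} (omics \code{cnv}, method
#'   \code{gene}).
#' @export
gene_cn_matrix <- function(x, gene_models, neutral_value = 0, samples = NULL) {
  genes <- gene_models$gene
  if (inherits(x, "region_partition")) {
    neutral_value <- x$neutral_value
    samples <- rownames(x$values)
    m <- matrix(neutral_value, length(samples), length(genes),
                dimnames = list(samples, genes))
    for (g in seq_along(genes)) {
      gm <- gene_models[g, ]
      same <- which(x$regions$chrom == gm$chrom &
                      x$regions$start <= gm$end & x$regions$end >= gm$start)
      if (length(same) == 0) next
      ov <- pmin(x$regions$end[same], gm$end) - pmax(x$regions$start[same], gm$start) + 1L
      best <- same[which.max(ov)]
      m[, genes[g]] <- x$values[, best]
    }
  } else {
    segments <- x
    if (is.null(samples)) samples <- unique(segments$sample_id)
    m <- matrix(neutral_value, length(samples), length(genes),
                dimnames = list(samples, genes))
    for (g in seq_along(genes)) {
      gm <- gene_models[g, ]
      hits <- segments[segments$chrom == gm$chrom &
                         segments$start <= gm$end & segments$end >= gm$start, ,
                       drop = FALSE]
      if (nrow(hits) == 0) next
      ov <- pmin(hits$end, gm$end) - pmax(hits$start, gm$start) + 1L
      for (s in unique(hits$sample_id)) {
        rows <- which(hits$sample_id == s)
        m[s, genes[g]] <- hits$segment_mean[rows[which.max(ov[rows])]]
      }
    }
  }
  feature_matrix(m, omics = "cnv", method = "gene")
}

#' Write a region partition: values TSV plus a BED of region coordinates
#' @param partition A \code{region_partition}.
#' @param path Values TSV path; the BED goes to \code{<path>.bed}.
#' @export
write_region_partition <- function(partition, path) {
  write_matrix_tsv(t(partition$values), path, id_col = "region")
  lines <- sprintf("%s\t%d\t%d\t%s", partition$regions$chrom,
                   partition$regions$start - 1L, partition$regions$end,
                   colnames(partition$values))
  writeLines(lines, paste0(path, ".bed"))
  invisible(path)
}
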