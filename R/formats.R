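#' @importFrom stats median prcomp rnorm rbinom rnbinom rbeta runif sd var
#'   quantile setNames pbinom chisq.test cor predict rgamma rpois
#' @importFrom utils read.delim write.table head
NULL

# MAF Variant_Classification values counted as protein-altering.  The
# gene-level mutation matrix marks a gene as mutated only for these classes
# (configurable via protein_altering_only = FALSE to count every class).
PROTEIN_ALTERING_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Nonstop_Mutation", "Translation_Start_Site"
)

SYNONYMOUS_CLASSES <- c("Silent", "Synonymous")

.fmt_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

.find_column <- function(header, aliases, label, path, required = TRUE) {
  hit <- which(tolower(header) %in% tolower(aliases))
  if (length(hit) == 0) {
    if (required) {
      stop(sprintf("%s: missing mandatory column '%s' (accepted names: %s)",
                   path, label, paste(aliases, collapse = ", ")),
           call. = FALSE)
    }
    return(NA_integer_)
  }
  hit[1]
}

.is_dna <- function(x) grepl("^[ACGT]+$", x)

#' Read somatic variants from a MAF-like tab-separated file
#'
#' Parses a tab-separated file with one somatic variant per row.  Column
#' names are matched case-insensitively against the common MAF names
#' (\code{Tumor_Sample_Barcode}, \code{Chromosome}, \code{Start_Position},
#' \code{Reference_Allele}, \code{Tumor_Seq_Allele2}, \code{Hugo_Symbol},
#' \code{Variant_Classification}) and plain aliases (\code{sample},
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene}).
#' Coordinates are 1-based; insertions and deletions are represented
#' VCF-style with a shared anchor base (e.g. ref \code{"TA"}, alt \code{"T"}
#' for a 1-bp deletion), so that every allele is a non-empty ACGT string.
#'
#' @param path Path to the file.
#' @return A data frame of variant records with columns \code{sample_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene} and
#'   \code{effect} (one of \code{protein_altering}, \code{synonymous},
#'   \code{other}).  \code{effect} is inferred from the
#'   variant-classification column when present, otherwise \code{"other"}.
#' @export
read_maf <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  hdr <- names(df)
  i_sample <- .find_column(hdr, c("Tumor_Sample_Barcode", "sample", "sample_id"), "sample", path)
  i_chrom  <- .find_column(hdr, c("Chromosome", "chrom", "chr"), "chromosome", path)
  i_pos    <- .find_column(hdr, c("Start_Position", "pos", "position"), "position", path)
  i_ref    <- .find_column(hdr, c("Reference_Allele", "ref"), "ref", path)
  i_alt    <- .find_column(hdr, c("Tumor_Seq_Allele2", "alt"), "alt", path)
  i_gene   <- .find_column(hdr, c("Hugo_Symbol", "gene"), "gene", path, required = FALSE)
  i_class  <- .find_column(hdr, c("Variant_Classification", "effect", "classification"),
                           "variant classification", path, required = FALSE)

  n <- nrow(df)
  ref <- toupper(df[[i_ref]])
  alt <- toupper(df[[i_alt]])
  pos <- suppressWarnings(as.integer(df[[i_pos]]))
  for (i in seq_len(n)) {
    line <- i + 1L  # header occupies line 1
    if (is.na(pos[i]) || pos[i] < 1L)
      .fmt_error(path, line, sprintf("invalid position '%s'", df[[i_pos]][i]))
    if (!.is_dna(ref[i]))
      .fmt_error(path, line, sprintf("non-ACGT reference allele '%s'", ref[i]))
    if (!.is_dna(alt[i]))
      .fmt_error(path, line, sprintf("non-ACGT alternate allele '%s'", alt[i]))
    if (ref[i] == alt[i])
      .fmt_error(path, line, sprintf("ref equals alt ('%s')", ref[i]))
  }

  effect <- rep("other", n)
  if (!is.na(i_class)) {
    cls <- df[[i_class]]
    effect[cls %in% PROTEIN_ALTERING_CLASSES | cls == "protein_altering"] <- "protein_altering"
    effect[cls %in% SYNONYMOUS_CLASSES | cls == "synonymous"] <- "synonymous"
  }

  data.frame(
    sample_id = df[[i_sample]],
    chrom = df[[i_chrom]],
    pos = pos,
    ref = ref,
    alt = alt,
    gene = if (!is.na(i_gene)) df[[i_gene]] else rep("", n),
    effect = effect,
    stringsAsFactors = FALSE
  )
}

#' Write variant records to a MAF-like tab-separated file
#'
#' Inverse of [read_maf()]; `read_maf(write_maf(x, p))` preserves all
#' fields.  The effect enumeration is written verbatim into the
#' \code{Variant_Classification} column.
#'
#' @param variants Data frame as returned by [read_maf()].
#' @param path Output path.
#' @export
write_maf <- function(variants, path) {
  out <- data.frame(
    Tumor_Sample_Barcode = variants$sample_id,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Hugo_Symbol = variants$gene,
    Variant_Classification = variants$effect,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments from a SEG file
#'
#' @param path Tab-separated file with sample / chromosome / start / end /
#'   segment-mean columns (1-based inclusive coordinates; segment mean on
#'   the log2(CN/2) scale, 0 = diploid neutral).
#' @return Data frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{segment_mean}.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  hdr <- names(df)
  i_sample <- .find_column(hdr, c("ID", "Sample", "sample_id"), "sample", path)
  i_chrom  <- .find_column(hdr, c("chrom", "chromosome", "chr"), "chromosome", path)
  i_start  <- .find_column(hdr, c("loc.start", "start"), "start", path)
  i_end    <- .find_column(hdr, c("loc.end", "end"), "end", path)
  i_mean   <- .find_column(hdr, c("seg.mean", "segment_mean", "seg_mean"), "segment mean", path)

  n <- nrow(df)
  start <- suppressWarnings(as.integer(df[[i_start]]))
  end <- suppressWarnings(as.integer(df[[i_end]]))
  segmean <- suppressWarnings(as.numeric(df[[i_mean]]))
  for (i in seq_len(n)) {
    line <- i + 1L
    if (is.na(start[i]) || is.na(end[i]))
      .fmt_error(path, line, "non-integer segment coordinates")
    if (start[i] > end[i])
      .fmt_error(path, line, sprintf("segment start %d > end %d", start[i], end[i]))
    if (is.na(segmean[i]) || !is.finite(segmean[i]))
      .fmt_error(path, line, sprintf("non-numeric segment mean '%s'", df[[i_mean]][i]))
  }

  data.frame(
    sample_id = df[[i_sample]],
    chrom = df[[i_chrom]],
    start = start,
    end = end,
    segment_mean = segmean,
    stringsAsFactors = FALSE
  )
}

#' Write copy-number segments to a SEG file
#' @param segments Data frame as returned by [read_seg()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(
    ID = segments$sample_id,
    chrom = segments$chrom,
    loc.start = segments$start,
    loc.end = segments$end,
    seg.mean = segments$segment_mean,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description (discarded) and one or more
#' member gene symbols, tab-separated — the MSigDB distribution format.
#' Duplicate genes within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list mapping set name to a character vector of gene
#'   symbols, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      .fmt_error(path, i, sprintf("expected >= 3 tab-separated fields, got %d", length(fields)))
    name <- fields[1]
    if (name %in% names(sets))
      .fmt_error(path, i, sprintf("duplicate gene set name '%s'", name))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      .fmt_error(path, i, sprintf("gene set '%s' has no members", name))
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' internal 1-based inclusive convention on read.
#'
#' @param path BED file with at least chrom / start / end / name columns.
#' @return Data frame with columns \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 4)
      .fmt_error(path, i, "expected >= 4 BED fields (chrom, start, end, name)")
  }
  df <- data.frame(
    gene = vapply(rows, `[`, character(1), 4),
    chrom = vapply(rows, `[`, character(1), 1),
    start = as.integer(vapply(rows, `[`, character(1), 2)) + 1L,
    end = as.integer(vapply(rows, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene))
    stop(sprintf("%s: duplicate gene name(s): %s", path,
                 paste(unique(df$gene[duplicated(df$gene)]), collapse = ", ")),
         call. = FALSE)
  if (any(df$start > df$end))
    stop(sprintf("%s: gene model with start > end", path), call. = FALSE)
  df
}

#' Write gene models to a BED file (1-based inclusive converted back to BED)
#' @param gene_models Data frame as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(gene_models, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", gene_models$chrom,
                   gene_models$start - 1L, gene_models$end, gene_models$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Read a features-by-samples numeric matrix from TSV
#'
#' First column holds feature ids, header holds sample ids.
#'
#' @param path Input path.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric matrix entries", path), call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a features-by-samples numeric matrix to TSV
#' @param m Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param path Output path.
#' @param id_col Name of the first (feature id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path Tab-separated file with columns \code{sample_id},
#'   \code{days_to_last_contact_or_death}, \code{vital_status}
#'   (\code{alive}/\code{dead}) and optionally
#'   \code{cause_of_death_cancer} (TRUE/FALSE, may be NA).
#' @return Data frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  hdr <- names(df)
  i_sample <- .find_column(hdr, c("sample_id", "sample"), "sample", path)
  i_days <- .find_column(hdr, c("days_to_last_contact_or_death", "days", "days_to_event"),
                         "days", path)
  i_status <- .find_column(hdr, c("vital_status", "status"), "vital status", path)
  i_cause <- .find_column(hdr, c("cause_of_death_cancer",  "cancer_death"),
                          "cause of death", path, required = FALSE)
  days <- suppressWarnings(as.integer(df[[i_days]]))
  status <- tolower(df[[i_status]])
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    if (is.na(days[i]) || days[i] < 0)
      .fmt_error(path, line, sprintf("invalid day count '%s'", df[[i_days]][i]))
    if (!status[i] %in% c("alive", "dead"))
      .fmt_error(path, line, sprintf("vital status must be alive/dead, got '%s'", df[[i_status]][i]))
  }
  cause <- if (!is.na(i_cause)) as.logical(df[[i_cause]]) else rep(NA, nrow(df))
  data.frame(
    sample_id = df[[i_sample]],
    days_to_last_contact_or_death = days,
    vital_status = status,
    cause_of_death_cancer = cause,
    stringsAsFactors = FALSE
  )
}

#' Write a clinical table
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FeatureMatrix container

#' Construct a feature matrix
#'
#' The package's central container: a samples-by-features numeric matrix
#' plus per-feature provenance recording which omics layer and extraction
#' method produced each column.  Missing values are encoded as \code{NA}
#' and propagated, never silently imputed.
#'
#' @param values Numeric matrix, samples in rows, features in columns,
#'   both with dimnames.
#' @param omics Per-feature omics layer, one of \code{mutation},
#'   \code{cnv}, \code{mrna}, \code{mirna}, \code{methylation}; recycled.
#' @param method Per-feature extraction method, one of
#'   \code{region_overlap}, \code{gene}, \code{gene_set},
#'   \code{mut_stats}, \code{signature}, \code{pca}, \code{raw}; recycled.
#' @return An object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(values, omics, method) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  p <- ncol(values)
  omics <- rep_len(omics, p)
  method <- rep_len(method, p)
  ok_omics <- c("mutation", "cnv", "mrna", "mirna", "methylation")
  ok_method <- c("region_overlap", "gene", "gene_set", "mut_stats", "signature", "pca", "raw")
  if (!all(omics %in% ok_omics)) stop("unknown omics layer", call. = FALSE)
  if (!all(method %in% ok_method)) stop("unknown extraction method", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in feature matrix", call. = FALSE)
  structure(
    list(values = values,
         provenance = data.frame(feature_id = colnames(values), omics = omics,
                                 method = method, stringsAsFactors = FALSE)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$provenance$omics, x$provenance$method)
  print(tab)
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Combine feature matrices over the same samples
#'
#' Columns are concatenated; all inputs must share an identical sample
#' ordering and feature ids must stay unique after the merge.
#'
#' @param ... \code{feature_matrix} objects.
#' @return A combined \code{feature_matrix}.
#' @export
fm_cbind <- function(...) {
  fms <- list(...)
  stopifnot(length(fms) >= 1)
  samples <- rownames(fms[[1]]$values)
  for (fm in fms) {
    if (!identical(rownames(fm$values), samples))
      stop("feature matrices have different sample orderings", call. = FALSE)
  }
  values <- do.call(cbind, lapply(fms, function(fm) fm$values))
  prov <- do.call(rbind, lapply(fms, function(fm) fm$provenance))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids after combining", call. = FALSE)
  structure(list(values = values, provenance = prov), class = "feature_matrix")
}

#' Subset a feature matrix by sample ids and/or feature ids
#' @param fm A \code{feature_matrix}.
#' @param samples Optional character vector of sample ids to keep (order kept).
#' @param features Optional character vector of feature ids to keep.
#' @return A \code{feature_matrix}.
#' @export
fm_subset <- function(fm, samples = NULL, features = NULL) {
  v <- fm$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  prov <- fm$provenance[match(colnames(v), fm$provenance$feature_id), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(values = v, provenance = prov), class = "feature_matrix")
}

#' Write a feature matrix to TSV with a provenance sidecar
#'
#' Values go to \code{path} in the features-by-samples TSV layout;
#' provenance (feature_id, omics, method) to \code{<path>.provenance.tsv}.
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  write_matrix_tsv(t(fm$values), path)
  write.table(fm$provenance, paste0(path, ".provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Path of the values TSV.
#' @return A \code{feature_matrix}.
#' @export
read_feature_matrix <- function(path) {
  m <- t(read_matrix_tsv(path))
  prov <- read.delim(paste0(path, ".provenance.tsv"), stringsAsFactors = FALSE)
  if (!identical(prov$feature_id, colnames(m)))
    stop(sprintf("%s: provenance sidecar does not match matrix columns", path), call. = FALSE)
  feature_matrix(m, prov$omics, prov$method)
}
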