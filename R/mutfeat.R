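#' Mutation catalogue category schemes
#'
#' Fixed, ordered category enumerations for the three small-variant
#' catalogue schemes: single-base substitutions in trinucleotide context
#' (96 categories), doublet-base substitutions (78) and small
#' insertions/deletions stratified by length, repeat context and
#' microhomology (83).  The full scheme is always enumerated regardless
#' of which categories are observed in a cohort.
#'
#' @return Character vector of category ids.
#' @name catalogue_schemes
NULL

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname catalogue_schemes
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    r <- substr(s, 1, 1)
    for (five in .BASES) for (three in .BASES) {
      out <- c(out, sprintf("%s[%s]%s", five, s, three))
    }
  }
  out
}

# Canonical (pyrimidine-at-first-differing-position) reference doublets.
.DBS_CANONICAL_REFS <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
.DBS_PALINDROMES <- c("AT", "CG", "GC", "TA")

#' @rdname catalogue_schemes
#' @export
dbs78_categories <- function() {
  out <- character(0)
  for (ref in .DBS_CANONICAL_REFS) {
    r1 <- substr(ref, 1, 1); r2 <- substr(ref, 2, 2)
    alts <- as.vector(outer(setdiff(.BASES, r1), setdiff(.BASES, r2), paste0))
    if (ref %in% .DBS_PALINDROMES) {
      alts <- unique(pmin(alts, .revcomp(alts)))
    }
    out <- c(out, sprintf("%s>%s", ref, sort(alts)))
  }
  out
}

#' @rdname catalogue_schemes
#' @export
id83_categories <- function() {
  out <- character(0)
  # 1-bp deletions / insertions by homopolymer run length
  for (b in c("C", "T")) out <- c(out, sprintf("1:Del:%s:%s", b, c(1:5, "6+")))
  for (b in c("C", "T")) out <- c(out, sprintf("1:Ins:%s:%s", b, c(0:4, "5+")))
  # >=2-bp deletions at repeats: length x repeat-unit count (incl. deleted copy)
  for (l in c("2", "3", "4", "5+")) out <- c(out, sprintf("%s:Del:R:%s", l, c(1:5, "6+")))
  # >=2-bp insertions at repeats: length x adjacent-copy count
  for (l in c("2", "3", "4", "5+")) out <- c(out, sprintf("%s:Ins:R:%s", l, c(0:4, "5+")))
  # deletions with flanking microhomology
  out <- c(out, "2:Del:M:1",
           sprintf("3:Del:M:%d", 1:2),
           sprintf("4:Del:M:%d", 1:3),
           sprintf("5+:Del:M:%s", c(1:4, "5+")))
  out
}

#' Classify a single-base substitution into its SBS96 category
#'
#' Substitutions are reported with a pyrimidine (C or T) reference base;
#' purine-reference variants are reverse-complemented (variant and
#' context) before classification, so a variant and its reverse
#' complement always land in the same category.
#'
#' @param ref,alt Single reference / alternate bases.
#' @param context 3-nucleotide uppercase reference context centred on the
#'   variant position (\code{substr(context, 2, 2)} must equal
#'   \code{ref}).
#' @return Category id of the form \code{"X[R>A]Y"}, or
#'   \code{NA_character_} when the input is not a classifiable SBS
#'   (indel/multi-nucleotide input, \code{ref == alt}, or non-ACGT
#'   context).
#' @export
classify_sbs96 <- function(ref, alt, context) {
  if (nchar(ref) != 1 || nchar(alt) != 1 || ref == alt) return(NA_character_)
  if (!.is_dna(ref) || !.is_dna(alt) || nchar(context) != 3 || !.is_dna(context))
    return(NA_character_)
  if (substr(context, 2, 2) != ref) return(NA_character_)
  if (ref %in% c("A", "G")) {
    ref <- .COMPLEMENT[[ref]]
    alt <- .COMPLEMENT[[alt]]
    context <- .revcomp(context)
  }
  sprintf("%s[%s>%s]%s", substr(context, 1, 1), ref, alt, substr(context, 3, 3))
}

#' Classify a doublet-base substitution into its DBS78 category
#'
#' The reference doublet is mapped to its canonical strand representative
#' among \code{AC, AT, CC, CG, CT, GC, TA, TC, TG, TT}; for the four
#' palindromic references the alternate doublet is additionally collapsed
#' with its reverse complement.  Doublets whose alternate matches the
#' reference at one of the two positions are single-base substitutions in
#' disguise and are not classifiable here.
#'
#' @param ref,alt Two-base reference / alternate strings.
#' @return One of the 78 category ids (\code{"REF>ALT"}), or
#'   \code{NA_character_} for non-classifiable input.
#' @export
classify_dbs78 <- function(ref, alt) {
  if (nchar(ref) != 2 || nchar(alt) != 2) return(NA_character_)
  if (!.is_dna(ref) || !.is_dna(alt)) return(NA_character_)
  if (substr(ref, 1, 1) == substr(alt, 1, 1) ||
      substr(ref, 2, 2) == substr(alt, 2, 2)) return(NA_character_)
  if (!ref %in% .DBS_CANONICAL_REFS) {
    ref <- .revcomp(ref)
    alt <- .revcomp(alt)
  }
  if (ref %in% .DBS_PALINDROMES) {
    alt <- min(alt, .revcomp(alt))
  }
  sprintf("%s>%s", ref, alt)
}

# Count adjacent whole copies of `unit` in `s` starting at `from` going
# right (dir = 1) or ending at `from` going left (dir = -1).
.count_adjacent_copies <- function(s, unit, from, dir) {
  L <- nchar(unit)
  n <- 0L
  pos <- from
  repeat {
    if (dir > 0) {
      if (pos + L - 1 > nchar(s)) break
      piece <- substr(s, pos, pos + L - 1)
      if (piece != unit) break
      n <- n + 1L; pos <- pos + L
    } else {
      if (pos - L + 1 < 1) break
      piece <- substr(s, pos - L + 1, pos)
      if (piece != unit) break
      n <- n + 1L; pos <- pos - L
    }
  }
  n
}

# Longest length k < nchar(unit) such that the first k bases of `unit`
# match s[from .. from+k-1] (dir = 1) or the last k bases match
# s[from-k+1 .. from] (dir = -1).
.microhomology_len <- function(s, unit, from, dir) {
  L <- nchar(unit)
  best <- 0L
  for (k in seq_len(L - 1)) {
    if (dir > 0) {
      if (from + k - 1 > nchar(s)) break
      if (substr(unit, 1, k) == substr(s, from, from + k - 1)) best <- k else break
    } else {
      if (from - k + 1 < 1) break
      if (substr(unit, L - k + 1, L) == substr(s, from - k + 1, from)) best <- k else break
    }
  }
  best
}

#' Classify a small insertion or deletion into its ID83 category
#'
#' Indels are anchored VCF-style: one allele must be a prefix of the
#' other (e.g. ref \code{"TAC"}, alt \code{"T"} deletes \code{"AC"}).
#' 1-bp indels are binned by the affected base (normalized to the
#' pyrimidine C/T) and the homopolymer run length at the site; longer
#' indels by length (2, 3, 4, 5+) and the number of adjacent whole copies
#' of the indel sequence in the reference; deletions with no adjacent
#' copy but partial sequence identity at the breakpoint fall into the
#' microhomology categories.
#'
#' @param ref,alt Anchored reference / alternate alleles (one a strict
#'   prefix of the other).
#' @param flank Uppercase reference sequence window containing the
#'   variant and enough context to count repeats up to the 6+ bin.
#' @param offset 1-based position of the variant's reference coordinate
#'   (the anchor base) inside \code{flank}.
#' @return One of the 83 category ids, or \code{NA_character_} when the
#'   input is not an anchored indel or the flank is inconsistent or too
#'   short to classify.
#' @export
classify_id83 <- function(ref, alt, flank, offset) {
  if (!.is_dna(ref) || !.is_dna(alt)) return(NA_character_)
  if (nchar(ref) == nchar(alt)) return(NA_character_)
  if (!.is_dna(flank)) return(NA_character_)
  is_del <- nchar(ref) > nchar(alt)
  long <- if (is_del) ref else alt
  short <- if (is_del) alt else ref
  if (substr(long, 1, nchar(short)) != short) return(NA_character_)
  s <- substr(long, nchar(short) + 1, nchar(long))  # the indel sequence
  L <- nchar(s)

  if (is_del) {
    # deleted bases occupy flank positions del_start .. del_end
    del_start <- offset + nchar(short)
    del_end <- offset + nchar(long) - 1L
    if (del_end > nchar(flank) || del_start < 1) return(NA_character_)
    if (substr(flank, del_start, del_end) != s) return(NA_character_)
    if (L == 1L) {
      b <- s
      run <- 1L +
        .count_adjacent_copies(flank, b, del_end + 1L, 1L) +
        .count_adjacent_copies(flank, b, del_start - 1L, -1L)
      if (b %in% c("A", "G")) b <- .COMPLEMENT[[b]]
      return(sprintf("1:Del:%s:%s", b, if (run >= 6) "6+" else run))
    }
    units <- 1L +
      .count_adjacent_copies(flank, s, del_end + 1L, 1L) +
      .count_adjacent_copies(flank, s, del_start - 1L, -1L)
    lenbin <- if (L >= 5) "5+" else as.character(L)
    if (units >= 2L)
      return(sprintf("%s:Del:R:%s", lenbin, if (units >= 6) "6+" else units))
    mh <- max(.microhomology_len(flank, s, del_end + 1L, 1L),
              .microhomology_len(flank, s, del_start - 1L, -1L))
    if (mh >= 1L) {
      mhbin <- if (L >= 5 && mh >= 5) "5+" else as.character(mh)
      return(sprintf("%s:Del:M:%s", lenbin, mhbin))
    }
    return(sprintf("%s:Del:R:1", lenbin))
  }

  # insertion between flank positions ins_left and ins_left + 1
  ins_left <- offset + nchar(short) - 1L
  if (ins_left < 1 || ins_left >= nchar(flank)) return(NA_character_)
  if (L == 1L) {
    b <- s
    run <- .count_adjacent_copies(flank, b, ins_left + 1L, 1L) +
      .count_adjacent_copies(flank, b, ins_left, -1L)
    if (b %in% c("A", "G")) b <- .COMPLEMENT[[b]]
    return(sprintf("1:Ins:%s:%s", b, if (run >= 5) "5+" else run))
  }
  units <- .count_adjacent_copies(flank, s, ins_left + 1L, 1L) +
    .count_adjacent_copies(flank, s, ins_left, -1L)
  lenbin <- if (L >= 5) "5+" else as.character(L)
  sprintf("%s:Ins:R:%s", lenbin, if (units >= 5) "5+" else units)
}

#' Build SBS96, DBS78 and ID83 mutation catalogues for a cohort
#'
#' Each variant contributes to exactly one scheme (single-base
#' substitutions to SBS96, doublets to DBS78, anchored indels to ID83) or
#' to none; per-sample catalogue totals therefore conserve the number of
#' classifiable variants.  Trinucleotide context and indel flanks are
#' looked up in the reference sequence.
#'
#' @param variants Variant data frame (see [read_maf()]).
#' @param reference Path to a FASTA file or a
#'   \code{Biostrings::DNAStringSet} with one entry per chromosome.
#' @param samples Optional character vector fixing the sample set and
#'   ordering (samples without variants get all-zero rows).
#' @param flank_width Half-width of the reference window used for indel
#'   repeat counting.
#' @return List with elements \code{sbs96}, \code{dbs78}, \code{id83}
#'   (each of class \code{mutation_catalogue}: scheme, category ids and a
#'   samples-by-categories count matrix) and \code{n_unclassified}.
#' @export
build_catalogues <- function(variants, reference, samples = NULL,
                             flank_width = 60L) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  # FASTA headers may carry descriptions after the id
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (is.null(samples)) samples <- unique(variants$sample_id)

  schemes <- list(sbs96 = sbs96_categories(),
                  dbs78 = dbs78_categories(),
                  id83 = id83_categories())
  counts <- lapply(schemes, function(cats) {
    m <- matrix(0L, nrow = length(samples), ncol = length(cats),
                dimnames = list(samples, cats))
    m
  })
  n_unclassified <- 0L

  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$sample_id %in% samples) next
    if (!v$chrom %in% names(reference)) {
      stop(sprintf("variant %d: chromosome '%s' absent from reference", i, v$chrom),
           call. = FALSE)
    }
    chrom_seq <- reference[[v$chrom]]
    chrom_len <- length(chrom_seq)
    if (v$pos + nchar(v$ref) - 1 > chrom_len)
      stop(sprintf("variant %d: coordinates outside reference", i), call. = FALSE)
    cat_id <- NA_character_
    scheme <- NA_character_
    if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
      if (v$pos >= 2 && v$pos + 1 <= chrom_len) {
        context <- as.character(Biostrings::subseq(chrom_seq, v$pos - 1, v$pos + 1))
        cat_id <- classify_sbs96(v$ref, v$alt, context)
      }
      scheme <- "sbs96"
    } else if (nchar(v$ref) == 2 && nchar(v$alt) == 2) {
      cat_id <- classify_dbs78(v$ref, v$alt)
      scheme <- "dbs78"
    } else if (nchar(v$ref) != nchar(v$alt)) {
      lo <- max(1L, v$pos - flank_width)
      hi <- min(chrom_len, v$pos + nchar(v$ref) - 1L + flank_width)
      flank <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
      cat_id <- classify_id83(v$ref, v$alt, flank, v$pos - lo + 1L)
      scheme <- "id83"
    }
    if (is.na(cat_id)) {
      n_unclassified <- n_unclassified + 1L
    } else {
      counts[[scheme]][v$sample_id, cat_id] <- counts[[scheme]][v$sample_id, cat_id] + 1L
    }
  }

  out <- lapply(names(schemes), function(sc) {
    structure(list(scheme = toupper(sc), categories = schemes[[sc]],
                   counts = counts[[sc]]),
              class = "mutation_catalogue")
  })
  names(out) <- names(schemes)
  out$n_unclassified <- n_unclassified
  out
}

#' @export
print.mutation_catalogue <- function(x, ...) {
  cat(sprintf("mutation_catalogue %s: %d samples x %d categories, %d variants\n",
              x$scheme, nrow(x$counts), length(x$categories), sum(x$counts)))
  invisible(x)
}

#' Write a mutation catalogue to TSV (categories x samples)
#' @param catalogue A \code{mutation_catalogue}.
#' @param path Output path.
#' @export
write_catalogue <- function(catalogue, path) {
  write_matrix_tsv(t(catalogue$counts), path, id_col = "category")
  invisible(path)
}

#' Fit reference mutational signatures to a catalogue
#'
#' Attributes each sample's catalogue to a supplied reference-signature
#' matrix by non-negative least squares: per sample, exposures minimize
#' the Euclidean reconstruction error subject to non-negativity.  A row
#' lying in the non-negative cone of the signatures is reconstructed
#' exactly.
#'
#' @param catalogue A \code{mutation_catalogue}.
#' @param reference_signatures Categories-by-signatures matrix of
#'   probability columns (each summing to 1), with rownames in the same
#'   category ordering as the catalogue.
#' @return Object of class \code{signature_exposure}: signature ids,
#'   samples-by-signatures exposure matrix and per-sample Euclidean
#'   reconstruction error.
#' @export
fit_signatures <- function(catalogue, reference_signatures) {
  S <- as.matrix(reference_signatures)
  if (is.null(rownames(S)) || !identical(rownames(S), catalogue$categories))
    stop("reference signature categories do not match the catalogue scheme",
         call. = FALSE)
  n <- nrow(catalogue$counts)
  k <- ncol(S)
  exposures <- matrix(0, n, k, dimnames = list(rownames(catalogue$counts), colnames(S)))
  err <- numeric(n)
  for (i in seq_len(n)) {
    d <- as.numeric(catalogue$counts[i, ])
    if (all(d == 0)) { err[i] <- 0; next }
    fit <- pracma::lsqnonneg(S, d)
    exposures[i, ] <- fit$x
    err[i] <- sqrt(sum((d - S %*% fit$x)^2))
  }
  structure(list(signature_ids = colnames(S), exposures = exposures,
                 reconstruction_error = err),
            class = "signature_exposure")
}

#' Binary gene-level mutation matrix
#'
#' Marks a gene 1 for a sample if it carries at least one (by default
#' protein-altering) mutation, 0 otherwise.  Variants with a gene
#' annotation use it directly; variants with an empty gene field fall
#' back to coordinate overlap with the gene models.  Variants mapping to
#' no known gene are counted in the \code{n_unmapped} attribute, not
#' errors.
#'
#' @param variants Variant data frame (see [read_maf()]).
#' @param gene_models Gene model data frame (see [read_bed()]); its gene
#'   list defines the feature columns.
#' @param protein_altering_only If TRUE (default) only variants with
#'   \code{effect == "protein_altering"} count; if FALSE every variant
#'   class counts.
#' @param samples Optional sample set/ordering.
#' @return A \code{feature_matrix} (omics \code{mutation}, method
#'   \code{gene}) of 0/1 values.
#' @export
gene_mutation_matrix <- function(variants, gene_models,
                                 protein_altering_only = TRUE,
                                 samples = NULL) {
  if (is.null(samples)) samples <- unique(variants$sample_id)
  variants <- variants[variants$sample_id %in% samples, , drop = FALSE]
  genes <- gene_models$gene
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  n_unmapped <- 0L
  if (nrow(variants) > 0) {
    use <- if (protein_altering_only) variants$effect == "protein_altering" else
      rep(TRUE, nrow(variants))
    for (i in which(use)) {
      v <- variants[i, ]
      g <- v$gene
      if (!nzchar(g)) {
        hit <- which(gene_models$chrom == v$chrom &
                       gene_models$start <= v$pos &
                       gene_models$end >= v$pos)
        g <- if (length(hit)) gene_models$gene[hit[1]] else ""
      }
      if (nzchar(g) && g %in% genes && v$sample_id %in% samples) {
        m[v$sample_id, g] <- 1
      } else {
        n_unmapped <- n_unmapped + 1L
      }
    }
  }
  fm <- feature_matrix(m, omics = "mutation", method = "gene")
  attr(fm, "n_unmapped") <- n_unmapped
  fm
}

#' Aggregate gene-level features over gene sets
#'
#' Collapses per-gene columns into one column per gene set: \code{sum}
#' for mutation matrices (number of mutated member genes), \code{mean}
#' for copy-number matrices (average signed segment mean over members).
#' Genes absent from the matrix are skipped; sets with no resolvable
#' member are dropped with a warning.
#'
#' @param fm A \code{feature_matrix} whose feature ids are gene symbols.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param mode Aggregation mode, \code{"sum"} or \code{"mean"}.
#' @return A \code{feature_matrix} (method \code{gene_set}) with one
#'   column per retained set.
#' @export
geneset_aggregate <- function(fm, sets, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  v <- fm$values
  keep <- vapply(sets, function(g) any(g %in% colnames(v)), logical(1))
  if (any(!keep))
    warning(sprintf("dropping %d gene set(s) with no resolvable genes: %s",
                    sum(!keep), paste(head(names(sets)[!keep], 5), collapse = ", ")))
  sets <- sets[keep]
  if (length(sets) == 0)
    stop("no gene set has resolvable genes in the matrix", call. = FALSE)
  agg <- vapply(sets, function(g) {
    cols <- intersect(g, colnames(v))
    sub <- v[, cols, drop = FALSE]
    if (mode == "sum") rowSums(sub) else rowMeans(sub)
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(v), names(sets)))
  omics <- unique(fm$provenance$omics)
  feature_matrix(agg, omics = omics[1], method = "gene_set")
}
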