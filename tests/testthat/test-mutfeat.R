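BASES <- c("A", "C", "G", "T")
rc1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
rcs <- function(s) paste(rev(vapply(strsplit(s, "")[[1]], rc1, "")), collapse = "")

test_that("catalogue schemes enumerate exactly 96, 78 and 83 unique categories", {
  expect_equal(length(sbs96_categories()), 96L)
  expect_equal(anyDuplicated(sbs96_categories()), 0L)
  expect_equal(length(dbs78_categories()), 78L)
  expect_equal(anyDuplicated(dbs78_categories()), 0L)
  expect_equal(length(id83_categories()), 83L)
  expect_equal(anyDuplicated(id83_categories()), 0L)
})

test_that("SBS96 classification handles the pyrimidine convention", {
  expect_equal(classify_sbs96("T", "C", "GTT"), "G[T>C]T")
  # purine reference: reverse-complement variant and context first
  expect_equal(classify_sbs96("A", "G", "CAT"), "A[T>C]G")
  expect_true(is.na(classify_sbs96("C", "C", "ACA")))
  expect_true(is.na(classify_sbs96("CC", "TT", "ACC")))
  expect_true(is.na(classify_sbs96("C", "T", "ANA")))
})

test_that("SBS96 classification is strand-involution invariant", {
  set.seed(10)
  for (i in 1:200) {
    ctx <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
    ref <- substr(ctx, 2, 2)
    alt <- sample(setdiff(BASES, ref), 1)
    a <- classify_sbs96(ref, alt, ctx)
    b <- classify_sbs96(rc1(ref), rc1(alt), rcs(ctx))
    expect_equal(a, b)
    expect_true(a %in% sbs96_categories())
  }
})

test_that("DBS78 canonicalization matches a brute-force oracle over all doublets", {
  expect_equal(classify_dbs78("AC", "GA"), "AC>GA")
  expect_equal(classify_dbs78("GT", "TC"), "AC>GA")  # reverse complement

  # brute force: all 16 refs x 9 both-position-changed alts
  refs <- as.vector(outer(BASES, BASES, paste0))
  seen <- character(0)
  for (ref in refs) {
    alts <- as.vector(outer(setdiff(BASES, substr(ref, 1, 1)),
                            setdiff(BASES, substr(ref, 2, 2)), paste0))
    for (alt in alts) {
      id <- classify_dbs78(ref, alt)
      expect_true(id %in% dbs78_categories())
      # involution: the reverse-complement doublet maps to the same id
      expect_equal(classify_dbs78(rcs(ref), rcs(alt)), id)
      seen <- c(seen, id)
    }
  }
  expect_equal(sort(unique(seen)), sort(dbs78_categories()))
  # partial doublets (one position unchanged) are not DBS
  expect_true(is.na(classify_dbs78("AC", "AT")))
  expect_true(is.na(classify_dbs78("A", "T")))
})

test_that("ID83 classifies homopolymer, repeat and microhomology indels", {
  # deletion of one T from the run TTTT (flank GCTTTTGA, anchor C at 2)
  expect_equal(classify_id83("CT", "C", "GCTTTTGA", 2L), "1:Del:T:4")
  # deleted base normalized to pyrimidine: one A from AAA run
  expect_equal(classify_id83("CA", "C", "GCAAAG", 2L), "1:Del:T:3")
  # 1-bp insertion of G next to a G (run length 1 in reference)
  expect_equal(classify_id83("A", "AG", "TAGT", 2L), "1:Ins:C:1")
  # 4-bp deletion with 2-bp flanking microhomology, no full repeat
  expect_equal(classify_id83("TACGT", "T", "GTACGTACTT", 2L), "4:Del:M:2")
  # tandem-repeat deletion: remove one AC unit from (AC)x3
  expect_equal(classify_id83("GAC", "G", "TGACACACTT", 2L), "2:Del:R:3")
  # repeat insertion: add one AC unit next to (AC)x2
  expect_equal(classify_id83("G", "GAC", "TGACACTT", 2L), "2:Ins:R:2")
  # substitutions are not indels
  expect_true(is.na(classify_id83("A", "T", "CAT", 2L)))
  # non-anchored (complex) indel is unclassifiable
  expect_true(is.na(classify_id83("AT", "GCC", "CATG", 2L)))
})

test_that("ID83 homopolymer and microhomology agree with literal string oracles", {
  set.seed(11)
  # oracle 1: 1-bp deletion run length by scanning the literal flank
  for (i in 1:100) {
    flank <- paste(sample(BASES, 30, replace = TRUE), collapse = "")
    off <- sample(5:20, 1)
    del_base <- substr(flank, off + 1L, off + 1L)
    ref <- paste0(substr(flank, off, off), del_base)
    got <- classify_id83(ref, substr(flank, off, off), flank, off)
    # brute-force run length around the deleted base
    run <- 1L
    k <- off + 2L
    while (k <= nchar(flank) && substr(flank, k, k) == del_base) { run <- run + 1L; k <- k + 1L }
    k <- off
    while (k >= 1 && substr(flank, k, k) == del_base) { run <- run + 1L; k <- k - 1L }
    base_norm <- if (del_base %in% c("A", "G")) rc1(del_base) else del_base
    expect_equal(got, sprintf("1:Del:%s:%s", base_norm, if (run >= 6) "6+" else run))
  }
  # oracle 2: microhomology by scanning deleted-sequence prefixes/suffixes
  for (i in 1:100) {
    L <- sample(2:6, 1)
    s <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    left <- paste(sample(BASES, 8, replace = TRUE), collapse = "")
    right <- paste(sample(BASES, 8, replace = TRUE), collapse = "")
    flank <- paste0(left, s, right)
    off <- nchar(left)          # anchor just before the deletion
    ref <- paste0(substr(flank, off, off), s)
    got <- classify_id83(ref, substr(flank, off, off), flank, off)
    # brute-force unit count and microhomology
    count_side <- function(str, from, dir) {
      n <- 0L
      repeat {
        lo <- if (dir > 0) from + n * L else from - (n + 1L) * L + 1L
        hi <- lo + L - 1L
        if (lo < 1 || hi > nchar(str) || substr(str, lo, hi) != s) break
        n <- n + 1L
      }
      n
    }
    units <- 1L + count_side(flank, off + L + 1L, 1L) + count_side(flank, off, -1L)
    mh <- 0L
    for (k in seq_len(L - 1)) {
      if (substr(s, 1, k) == substr(flank, off + L + 1L, off + L + k)) mh <- max(mh, k)
      if (substr(s, L - k + 1L, L) == substr(flank, off - k + 1L, off)) mh <- max(mh, k)
    }
    lenbin <- if (L >= 5) "5+" else as.character(L)
    want <- if (units >= 2) sprintf("%s:Del:R:%s", lenbin, if (units >= 6) "6+" else units)
            else if (mh >= 1) sprintf("%s:Del:M:%s", lenbin,
                                      if (L >= 5 && mh >= 5) "5+" else mh)
            else sprintf("%s:Del:R:1", lenbin)
    expect_equal(got, want)
  }
})

test_that("catalogues conserve classifiable variant counts per sample", {
  dir <- withr::local_tempdir()
  genome <- paste(rep("TACG", 50), collapse = "")  # ACG context at many spots
  fa <- file.path(dir, "ref.fa")
  writeLines(c(">chr1", genome), fa)
  # three identical C>T at an A|C|G context (positions 4k+2 hold C in TACG runs)
  v <- data.frame(sample_id = "S1", chrom = "chr1", pos = c(3, 7, 11),
                  ref = "C", alt = "T", gene = "", effect = "other",
                  stringsAsFactors = FALSE)
  cats <- build_catalogues(v, fa)
  expect_equal(unname(cats$sbs96$counts["S1", "A[C>T]G"]), 3L)
  expect_equal(sum(cats$sbs96$counts), 3L)
  expect_equal(sum(cats$id83$counts), 0L)   # no indels in the cohort
  expect_equal(sum(cats$dbs78$counts), 0L)
})

test_that("catalogues of signature-drawn variants recover the signature profile", {
  set.seed(12)
  # one synthetic signature concentrated on a few categories
  cats96 <- sbs96_categories()
  sig <- setNames(rep(0, 96), cats96)
  sig[c("A[C>T]G", "T[C>A]A", "G[T>C]T", "C[T>G]C")] <- c(0.4, 0.3, 0.2, 0.1)
  # build a genome hosting each needed trinucleotide context, then draw
  contexts <- c("ACG", "TCA", "GTT", "CTC")
  alts <- c("T", "A", "C", "G")
  genome <- paste0(paste(rep("N", 0), collapse = ""),
                   paste(vapply(contexts, function(cx) paste0(cx, "AAAA"), ""),
                         collapse = ""))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", genome), fa)
  pos_of <- 7 * (seq_along(contexts) - 1) + 2  # middle base of each context
  n_draw <- 2000
  draw <- sample(seq_along(contexts), n_draw, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  v <- data.frame(sample_id = "S1", chrom = "chr1", pos = pos_of[draw],
                  ref = substr(contexts[draw], 2, 2), alt = alts[draw],
                  gene = "", effect = "other", stringsAsFactors = FALSE)
  cats <- build_catalogues(v, fa)
  freq <- cats$sbs96$counts["S1", ] / n_draw
  expect_equal(sum(cats$sbs96$counts), n_draw)
  expect_lt(max(abs(freq - sig)), 0.03)  # multinomial error at n = 2000
})

test_that("NNLS signature fitting reconstructs cone members exactly", {
  cats96 <- sbs96_categories()
  S <- matrix(0, 96, 2, dimnames = list(cats96, c("sigA", "sigB")))
  S[1:10, 1] <- 0.1          # disjoint supports
  S[11:20, 2] <- 0.1
  counts <- matrix(0L, 2, 96, dimnames = list(c("S1", "S2"), cats96))
  counts[1, ] <- as.integer(round(100 * S[, 1]))          # pure signature A
  counts[2, ] <- as.integer(round(60 * S[, 1] + 40 * S[, 2]))
  cat_obj <- structure(list(scheme = "SBS96", categories = cats96, counts = counts),
                       class = "mutation_catalogue")
  fit <- fit_signatures(cat_obj, S)
  expect_equal(unname(fit$exposures["S1", ]), c(100, 0), tolerance = 1e-8)
  expect_equal(unname(fit$exposures["S2", ]), c(60, 40), tolerance = 1e-8)
  expect_equal(fit$reconstruction_error, c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)

  # grid-search oracle agrees on the mixture weights
  grid <- seq(0, 120, by = 0.5)
  err <- outer(grid, grid, Vectorize(function(a, b) {
    sum((counts[2, ] - a * S[, 1] - b * S[, 2])^2)
  }))
  best <- which(err == min(err), arr.ind = TRUE)[1, ]
  expect_equal(c(grid[best[1]], grid[best[2]]), c(60, 40))

  # all-zero row fits with zero exposure and zero error
  counts0 <- counts; counts0[1, ] <- 0L
  cat0 <- structure(list(scheme = "SBS96", categories = cats96, counts = counts0),
                    class = "mutation_catalogue")
  fit0 <- fit_signatures(cat0, S)
  expect_equal(unname(fit0$exposures["S1", ]), c(0, 0))

  expect_error(fit_signatures(cat_obj, S[96:1, ]), "categories do not match")
})

test_that("gene mutation matrix applies the protein-altering rule", {
  gm <- data.frame(gene = c("EGFR", "KRAS"), chrom = "chr1",
                   start = c(100L, 500L), end = c(200L, 600L),
                   stringsAsFactors = FALSE)
  v <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3"),
    chrom = "chr1", pos = c(110L, 150L, 120L, 550L),
    ref = "C", alt = "T",
    gene = c("EGFR", "EGFR", "EGFR", ""),
    effect = c("protein_altering", "protein_altering", "synonymous",
               "protein_altering"),
    stringsAsFactors = FALSE
  )
  fm <- gene_mutation_matrix(v, gm, samples = c("S1", "S2", "S3"))
  expect_equal(unname(fm$values["S1", "EGFR"]), 1)   # two hits still 1
  expect_equal(unname(fm$values["S2", "EGFR"]), 0)   # synonymous only
  expect_equal(unname(fm$values["S3", "KRAS"]), 1)   # coordinate fallback
  fm_all <- gene_mutation_matrix(v, gm, protein_altering_only = FALSE,
                                 samples = c("S1", "S2", "S3"))
  expect_equal(unname(fm_all$values["S2", "EGFR"]), 1)

  empty <- gene_mutation_matrix(v[0, ], gm, samples = c("S1", "S2"))
  expect_true(all(empty$values == 0))
})

test_that("gene-set aggregation sums member indicators and matches brute force", {
  set.seed(13)
  m <- matrix(rbinom(60, 1, 0.4), 10, 6,
              dimnames = list(sprintf("S%02d", 1:10),
                              c("EGFR", "KRAS", "TP53", "BRAF", "ALK", "MET")))
  fm <- feature_matrix(m, "mutation", "gene")
  sets <- list(PATH = c("EGFR", "KRAS"), ONE = "TP53",
               MIX = c("BRAF", "ALK", "NOTPRESENT"))
  agg <- geneset_aggregate(fm, sets, mode = "sum")
  # sample mutated in KRAS only scores 1 on the pathway
  expect_equal(unname(agg$values[, "PATH"]),
               unname(m[, "EGFR"] + m[, "KRAS"]))
  # singleton set equals the gene column under either mode
  expect_equal(unname(agg$values[, "ONE"]), unname(m[, "TP53"]))
  aggm <- geneset_aggregate(fm, sets, mode = "mean")
  expect_equal(unname(aggm$values[, "ONE"]), unname(m[, "TP53"]))
  # brute-force recomputation oracle
  for (nm in names(sets)) {
    cols <- intersect(sets[[nm]], colnames(m))
    expect_equal(unname(agg$values[, nm]), unname(rowSums(m[, cols, drop = FALSE])))
  }
  # unresolvable set dropped with a warning
  expect_warning(geneset_aggregate(fm, c(sets, list(BAD = "NOPE")), "sum"),
                 "no resolvable genes")
})
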