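test_that("read_maf parses MAF-named columns and infers effects", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    paste("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", "Hugo_Symbol",
          "Variant_Classification", sep = "\t"),
    paste("S1", "chr1", "100", "C", "T", "EGFR", "Missense_Mutation", sep = "\t"),
    paste("S2", "chr2", "55", "G", "A", "KRAS", "Silent", sep = "\t")
  ), path)
  v <- read_maf(path)
  expect_equal(nrow(v), 2)
  expect_equal(v$effect, c("protein_altering", "synonymous"))
  expect_equal(v$pos, c(100L, 55L))
})

test_that("read_maf rejects malformed rows with the 1-based line number", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "sample\tchrom\tpos\tref\talt",
    "S1\tchr1\t10\tN\tA"
  ), path)
  expect_error(read_maf(path), "line 2.*non-ACGT")

  path2 <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("sample\tchrom\tpos\tref\talt", "S1\tchr1\t10\tC\tC"), path2)
  expect_error(read_maf(path2), "line 2.*ref equals alt")

  path3 <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("sample\tchrom\tpos\talt", "S1\tchr1\t10\tA"), path3)
  expect_error(read_maf(path3), "missing mandatory column 'ref'")
})

test_that("variant write/read round-trip preserves all fields", {
  set.seed(1)
  n <- 40
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  v <- data.frame(
    sample_id = sample(sprintf("S%d", 1:5), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = ref, alt = alt,
    gene = sample(c("EGFR", "KRAS", ""), n, replace = TRUE),
    effect = sample(c("protein_altering", "synonymous", "other"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(v, path)
  expect_equal(read_maf(path), v)
})

test_that("read_seg validates coordinates and segment means", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t100\t200\t0.5"), path)
  s <- read_seg(path)
  expect_equal(s$start, 100L)
  expect_equal(s$segment_mean, 0.5)

  bad <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t300\t200\t0.5"), bad)
  expect_error(read_seg(bad), "line 2.*start 300 > end 200")

  nonnum <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t100\t200\tx"), nonnum)
  expect_error(read_seg(nonnum), "line 2.*non-numeric segment mean")
})

test_that("segment write/read round-trip is the identity", {
  set.seed(2)
  n <- 30
  start <- sample.int(1e5, n)
  seg <- data.frame(sample_id = sample(sprintf("S%d", 1:4), n, replace = TRUE),
                    chrom = "chr1", start = start,
                    end = start + sample.int(1e4, n),
                    segment_mean = round(rnorm(n), 4),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(seg, path)
  expect_equal(read_seg(path), seg)
})

test_that("read_gmt parses sets, discards descriptions, dedups genes", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tEGFR\tKRAS",
               "SETB\tdesc\tTP53\tTP53\tBRAF"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("SETA", "SETB"))
  expect_equal(sets$SETA, c("EGFR", "KRAS"))
  expect_equal(sets$SETB, c("TP53", "BRAF"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("SETA\tdesc", bad)
  expect_error(read_gmt(bad), "line 1.*>= 3")
})

test_that("BED gene models convert 0-based half-open to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tG1", path)
  gm <- read_bed(path)
  expect_equal(gm$start, 100L)
  expect_equal(gm$end, 200L)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(gm, out)
  expect_equal(readLines(out), "chr1\t99\t200\tG1")
})

test_that("matrix TSV round-trips with feature ids and sample headers", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("S1", "S2", "S3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, m)
})

test_that("clinical reader validates days and vital status", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tdays_to_last_contact_or_death\tvital_status",
               "S1\t500\tdead", "S2\t-3\talive"), path)
  expect_error(read_clinical(path), "line 3.*invalid day count")
})

test_that("feature_matrix enforces unique ids and consistent combination", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  fm <- feature_matrix(m, "mrna", "raw")
  expect_equal(dim(fm), c(2L, 3L))
  expect_error(feature_matrix(m, "mrna", "bogus"), "unknown extraction method")
  m2 <- m; colnames(m2) <- c("a", "a", "c")
  expect_error(feature_matrix(m2, "mrna", "raw"), "duplicate feature ids")

  fm2 <- feature_matrix(matrix(1, 2, 1, dimnames = list(c("S1", "S2"), "d")),
                        "cnv", "gene")
  comb <- fm_cbind(fm, fm2)
  expect_equal(colnames(comb$values), c("a", "b", "c", "d"))
  expect_equal(comb$provenance$omics, c("mrna", "mrna", "mrna", "cnv"))
  expect_error(fm_cbind(fm, fm), "duplicate feature ids")
})

test_that("feature matrix TSV + provenance sidecar round-trips", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("S1", "S2"), sprintf("f%d", 1:4)))
  fm <- feature_matrix(m, c("mrna", "mrna", "cnv", "methylation"),
                       c("raw", "raw", "gene", "raw"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values)
  expect_equal(back$provenance, fm$provenance)
})
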