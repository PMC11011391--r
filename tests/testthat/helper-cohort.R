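# Session-level cache of generated cohorts so multiple test files can
# share the same bundle without regenerating it.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed, ...) {
  args <- list(...)
  key <- paste0("s", seed, "_", paste(names(args), unlist(args), collapse = "_"))
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  spec <- do.call(cohort_spec, c(list(seed = seed), args))
  dir <- file.path(tempdir(), "survomics_cohorts", key)
  bundle <- generate_cohort(spec, dir)
  labels <- dichotomize_survival(read_clinical(bundle$paths$clinical))
  out <- list(spec = spec, bundle = bundle, labels = labels)
  .cohort_cache[[key]] <- out
  out
}

# feature matrix helper for hand-built tests
make_fm <- function(values, omics = "mrna", method = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  feature_matrix(values, omics, method)
}

# labels helper: named factor wrapped as a label_set-like factor input
make_labels <- function(y, samples = sprintf("S%02d", seq_along(y))) {
  lab <- factor(ifelse(y == 1, "nonsurvivor", "survivor"),
                levels = c("survivor", "nonsurvivor"))
  names(lab) <- samples
  lab
}
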