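#' Build all feature matrices for a cohort file bundle
#'
#' Runs every feature-extraction method on the files of a cohort bundle
#' and returns the per-layer matrices plus their column-wise combination
#' over the labeled samples.  Feature ids are prefixed by layer and
#' method (\code{mut.gene:}, \code{mut.set:}, \code{sig:},
#' \code{cnv.region:}, \code{cnv.gene:}, \code{cnv.set:}, \code{mrna:},
#' \code{mirna:}, \code{meth:}) so the combined matrix stays unique.
#'
#' @param paths Named list of input paths (as produced by
#'   [generate_cohort()]): \code{mutations}, \code{genome}, \code{genes},
#'   \code{gene_sets}, \code{signatures}, \code{cnv}, \code{mrna},
#'   \code{mirna}, \code{methylation}.
#' @param labels A \code{label_set}; featurization is restricted to its
#'   labeled samples, in order.
#' @param min_reads Count filter threshold (default 10).
#' @param frac_overlap Region-merge agreement fraction (default 0.9).
#' @param protein_altering_only Gene mutation matrix restriction
#'   (default TRUE).
#' @param include Character vector choosing which feature groups to
#'   build (any of \code{mut_gene}, \code{mut_set}, \code{signature},
#'   \code{cnv_region}, \code{cnv_gene}, \code{cnv_set}, \code{mrna},
#'   \code{mirna}, \code{meth}); default all.
#' @return List with one \code{feature_matrix} per built group and
#'   \code{combined}.
#' @export
featurize_cohort <- function(paths, labels, min_reads = 10L,
                             frac_overlap = 0.9,
                             protein_altering_only = TRUE,
                             include = c("mut_gene", "mut_set", "signature",
                                         "cnv_region", "cnv_gene", "cnv_set",
                                         "mrna", "mirna", "meth")) {
  samples <- names(labels$labels)
  out <- list()
  prefix <- function(fm, pre) {
    colnames(fm$values) <- paste0(pre, colnames(fm$values))
    fm$provenance$feature_id <- colnames(fm$values)
    fm
  }
  restrict <- function(fm) {
    missing <- setdiff(samples, rownames(fm$values))
    if (length(missing)) {
      pad <- matrix(NA_real_, length(missing), ncol(fm$values),
                    dimnames = list(missing, colnames(fm$values)))
      fm$values <- rbind(fm$values, pad)
    }
    fm_subset(fm, samples = samples)
  }

  need_mut <- any(c("mut_gene", "mut_set", "signature") %in% include)
  if (need_mut) {
    variants <- read_maf(paths$mutations)
    gm <- read_bed(paths$genes)
    gene_fm <- gene_mutation_matrix(variants, gm,
                                    protein_altering_only = protein_altering_only,
                                    samples = samples)
    if ("mut_gene" %in% include) out$mut_gene <- prefix(restrict(gene_fm), "mut.gene:")
    if ("mut_set" %in% include) {
      sets <- read_gmt(paths$gene_sets)
      out$mut_set <- prefix(restrict(geneset_aggregate(gene_fm, sets, "sum")), "mut.set:")
    }
    if ("signature" %in% include) {
      cats <- build_catalogues(variants, paths$genome, samples = samples)
      sigs <- read_matrix_tsv(paths$signatures)
      expo <- fit_signatures(cats$sbs96, sigs)
      fm <- feature_matrix(expo$exposures, omics = "mutation", method = "signature")
      out$signature <- prefix(restrict(fm), "sig:")
    }
  }

  if (any(c("cnv_region", "cnv_gene", "cnv_set") %in% include)) {
    segments <- read_seg(paths$cnv)
    part <- partition_segments(segments, frac_overlap = frac_overlap,
                               samples = samples)
    if ("cnv_region" %in% include)
      out$cnv_region <- prefix(restrict(region_cn_matrix(part)), "cnv.region:")
    if (any(c("cnv_gene", "cnv_set") %in% include)) {
      gm <- read_bed(paths$genes)
      cg <- gene_cn_matrix(part, gm)
      if ("cnv_gene" %in% include) out$cnv_gene <- prefix(restrict(cg), "cnv.gene:")
      if ("cnv_set" %in% include) {
        sets <- read_gmt(paths$gene_sets)
        out$cnv_set <- prefix(restrict(geneset_aggregate(cg, sets, "mean")), "cnv.set:")
      }
    }
  }

  norm_counts <- function(path) {
    counts <- filter_min_count(read_matrix_tsv(path), min_reads)
    t(size_factor_normalize(counts)$normalized)
  }
  if ("mrna" %in% include) {
    m <- norm_counts(paths$mrna)
    out$mrna <- prefix(restrict(feature_matrix(m, "mrna", "raw")), "mrna:")
  }
  if ("mirna" %in% include) {
    m <- norm_counts(paths$mirna)
    out$mirna <- prefix(restrict(feature_matrix(m, "mirna", "raw")), "mirna:")
  }
  if ("meth" %in% include) {
    m <- t(read_matrix_tsv(paths$methylation))
    out$meth <- prefix(restrict(feature_matrix(m, "methylation", "raw")), "meth:")
  }

  out$combined <- do.call(fm_cbind, unname(out))
  out
}

.stage_hash <- function(inputs, params) {
  files <- as.character(unlist(inputs))
  files <- files[file.exists(files)]
  hashes <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  paste(c(hashes, vapply(params, function(p) paste(deparse(p), collapse = ""),
                         character(1))), collapse = "|")
}

#' Run the end-to-end analysis pipeline from a configuration
#'
#' Stages run in order: \code{simulate} (optional; otherwise input paths
#' must point at existing files), \code{labels}, \code{featurize},
#' \code{select} (zero-variance + correlation filters, per-omics lasso
#' AUC profiles, Boruta ranking on the combined matrix) and
#' \code{evaluate} (balanced nested CV of a random forest on the
#' Boruta-confirmed features, with optional SHAP attribution).  Each
#' stage records an input hash in \code{manifest.yaml}; rerunning with
#' unchanged inputs and parameters skips stages whose outputs are
#' already up to date.
#'
#' @param config A named list or path to a YAML file.  Recognized
#'   blocks: \code{output_dir}, \code{seed}, \code{simulate} (cohort
#'   spec overrides or \code{enabled: false}), \code{inputs} (paths when
#'   not simulating), \code{labels}, \code{featurize}, \code{select},
#'   \code{evaluate}.
#' @param stages Which stages to run; default all.
#' @return Invisibly, a list with the stage outputs (\code{labels},
#'   \code{features}, \code{filter}, \code{profiles}, \code{boruta},
#'   \code{cv}) and the output manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "labels", "featurize",
                                    "select", "evaluate")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config requires output_dir", call. = FALSE)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else list()
  log_msg <- function(...) message(sprintf("[survomics] %s", sprintf(...)))

  sim_cfg <- config$simulate
  simulate_enabled <- is.null(sim_cfg$enabled) || isTRUE(sim_cfg$enabled)
  if (simulate_enabled) {
    sim_cfg$enabled <- NULL
    spec <- do.call(cohort_spec, c(sim_cfg, list(seed = seed)))
    paths <- list()  # filled by the simulate stage
  } else {
    paths <- config$inputs
    need <- c("mutations", "genome", "genes", "gene_sets", "signatures",
              "cnv", "mrna", "mirna", "methylation", "clinical")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop(sprintf("config inputs missing: %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    absent <- !file.exists(unlist(paths[need]))
    if (any(absent))
      stop(sprintf("input file(s) not found: %s",
                   paste(unlist(paths[need])[absent], collapse = ", ")),
           call. = FALSE)
  }

  run_stage <- function(name, inputs, params, outputs, fun) {
    hash <- .stage_hash(inputs, params)
    up_to_date <- identical(manifest[[name]]$hash, hash) &&
      all(file.exists(unlist(outputs)))
    if (up_to_date) {
      log_msg("stage %s: up to date, skipping", name)
      return(invisible(NULL))
    }
    log_msg("stage %s: running", name)
    ok <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest[[name]] <<- list(hash = hash, outputs = unlist(outputs))
    yaml::write_yaml(manifest, manifest_path)
    invisible(ok)
  }

  result <- list()

  if (simulate_enabled) {
    sim_dir <- file.path(out_dir, "cohort")
    paths <- list(genome = file.path(sim_dir, "genome.fa"),
                  genes = file.path(sim_dir, "genes.bed"),
                  gene_sets = file.path(sim_dir, "gene_sets.gmt"),
                  signatures = file.path(sim_dir, "signatures_synthetic.tsv"),
                  mutations = file.path(sim_dir, "mutations.maf"),
                  cnv = file.path(sim_dir, "cnv.seg"),
                  mrna = file.path(sim_dir, "mrna_counts.tsv"),
                  mirna = file.path(sim_dir, "mirna_counts.tsv"),
                  methylation = file.path(sim_dir, "methylation.tsv"),
                  clinical = file.path(sim_dir, "clinical.tsv"))
    if ("simulate" %in% stages) {
      run_stage("simulate", inputs = list(), params = spec,
                outputs = paths, fun = function() generate_cohort(spec, sim_dir))
    }
  }

  lab_cfg <- config$labels
  horizon <- if (is.null(lab_cfg$horizon_days)) 730L else as.integer(lab_cfg$horizon_days)
  labels_path <- file.path(out_dir, "labels.tsv")
  if ("labels" %in% stages) {
    run_stage("labels", inputs = list(paths$clinical),
              params = lab_cfg,
              outputs = list(labels_path), fun = function() {
                clin <- read_clinical(paths$clinical)
                lab <- dichotomize_survival(
                  clin, horizon_days = horizon,
                  exclude_non_cancer_death = isTRUE(lab_cfg$exclude_non_cancer_death))
                write_labels(lab, labels_path)
              })
  }
  labels <- read_labels(labels_path, horizon_days = horizon)
  result$labels <- labels

  feat_cfg <- config$featurize
  combined_path <- file.path(out_dir, "features_combined.tsv")
  if ("featurize" %in% stages) {
    run_stage("featurize",
              inputs = c(unname(paths[c("mutations", "genome", "genes", "gene_sets",
                                        "signatures", "cnv", "mrna", "mirna",
                                        "methylation")]), labels_path),
              params = feat_cfg,
              outputs = list(combined_path), fun = function() {
                args <- list(paths = paths, labels = labels)
                for (nm in c("min_reads", "frac_overlap", "protein_altering_only",
                             "include")) {
                  if (!is.null(feat_cfg[[nm]])) args[[nm]] <- feat_cfg[[nm]]
                }
                feats <- do.call(featurize_cohort, args)
                write_feature_matrix(feats$combined, combined_path)
              })
  }
  features <- read_feature_matrix(combined_path)
  result$features <- features

  sel_cfg <- config$select
  boruta_path <- file.path(out_dir, "boruta_decisions.tsv")
  profile_dir <- file.path(out_dir, "lasso_profiles")
  if ("select" %in% stages) {
    cutoff <- if (is.null(sel_cfg$correlation_cutoff)) 0.9 else sel_cfg$correlation_cutoff
    run_stage("select", inputs = list(combined_path), params = sel_cfg,
              outputs = list(boruta_path), fun = function() {
                filt <- correlation_filter(zero_variance_filter(features), cutoff)
                dir.create(profile_dir, showWarnings = FALSE)
                for (om in unique(filt$matrix$provenance$omics)) {
                  ids <- filt$matrix$provenance$feature_id[
                    filt$matrix$provenance$omics == om]
                  sub <- fm_subset(filt$matrix, features = ids)
                  if (ncol(sub$values) < 2) next
                  prof <- lasso_auc_profile(
                    sub, labels,
                    n_folds = if (is.null(sel_cfg$lasso_folds)) 10L else sel_cfg$lasso_folds,
                    max_features = if (is.null(sel_cfg$max_features)) 100L else
                      sel_cfg$max_features,
                    seed = seed)
                  write_lasso_profile(prof, file.path(profile_dir,
                                                      sprintf("lasso_%s.tsv", om)))
                }
                bor <- boruta_rank(
                  filt$matrix, labels,
                  max_runs = if (is.null(sel_cfg$boruta_max_runs)) 10000L else
                    sel_cfg$boruta_max_runs,
                  alpha = if (is.null(sel_cfg$boruta_alpha)) 0.01 else
                    sel_cfg$boruta_alpha,
                  seed = seed,
                  ntree = if (is.null(sel_cfg$boruta_ntree)) 500L else
                    sel_cfg$boruta_ntree)
                write_boruta(bor, boruta_path)
              })
  }

  eval_cfg <- config$evaluate
  eval_dir <- file.path(out_dir, "evaluation")
  if ("evaluate" %in% stages) {
    run_stage("evaluate", inputs = list(combined_path, boruta_path),
              params = eval_cfg, outputs = list(file.path(eval_dir, "auc_summary.tsv")),
              fun = function() {
                dec <- read.delim(boruta_path, stringsAsFactors = FALSE)
                confirmed <- dec$feature_id[dec$decision == "Confirmed"]
                if (length(confirmed) < 2) {
                  log_msg("fewer than 2 confirmed features; using top 10 by importance")
                  confirmed <- dec$feature_id[order(-dec$mean_importance)][1:10]
                }
                sub <- fm_subset(features, features = confirmed)
                cfg <- nested_cv_config(
                  outer_folds = if (is.null(eval_cfg$outer_folds)) 10L else eval_cfg$outer_folds,
                  tune_grid_size = if (is.null(eval_cfg$tune_grid_size)) 10L else
                    eval_cfg$tune_grid_size,
                  minority_multiplier = if (is.null(eval_cfg$minority_multiplier)) 1 else
                    eval_cfg$minority_multiplier,
                  majority_fraction = if (is.null(eval_cfg$majority_fraction)) 0.3 else
                    eval_cfg$majority_fraction,
                  repeats = if (is.null(eval_cfg$repeats)) 100L else eval_cfg$repeats,
                  shap_nsim = if (is.null(eval_cfg$shap_nsim)) 10L else eval_cfg$shap_nsim,
                  ntree = if (is.null(eval_cfg$ntree)) 500L else eval_cfg$ntree,
                  compute_shap = isTRUE(eval_cfg$compute_shap),
                  seed = seed)
                cv <- nested_cv_evaluate(sub, labels, cfg)
                write_nested_cv(cv, eval_dir)
              })
  }

  result$manifest <- manifest
  result$output_dir <- out_dir
  invisible(result)
}
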