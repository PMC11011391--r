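#' Synthetic multiomics cohort specification
#'
#' Parameters of the synthetic lung-adenocarcinoma-like cohort generator.
#' The default shape mirrors the cohort the pipeline is designed for:
#' 267 cases with a 2:1 survivor/nonsurvivor imbalance (89 nonsurvivors),
#' a mutually exclusive planted driver pathway, negative-binomial
#' expression counts with planted differential genes, beta-distributed
#' methylation with planted mean shifts, piecewise-constant copy-number
#' segments with a class-biased amplified region, and dichotomized
#' survival with injected early-censored cases.
#'
#' @param n_samples Labeled cohort size (default 267).
#' @param fraction_nonsurvivor Fraction dying before the horizon
#'   (default 1/3, i.e. 89 of 267).
#' @param n_genes Genes in the genome model (default 60).
#' @param n_gene_sets,genes_per_set Gene-set collection shape (defaults
#'   12 sets of 5).
#' @param n_probes Methylation probes (default 60).
#' @param n_mirna miRNA features (default 20).
#' @param planted_pathway_size Genes in the mutually exclusive driver
#'   pathway (default 4).
#' @param mutual_exclusivity If TRUE (default) at most one pathway gene
#'   is mutated per sample.
#' @param mutation_rate_background Per-gene background mutation
#'   probability (default 0.05).
#' @param pathway_mutation_prob_by_class Probability that a sample
#'   carries a pathway mutation, by class
#'   (nonsurvivor, survivor); default c(0.55, 0.28).
#' @param de_gene_count,de_log2_fold_change Planted differentially
#'   expressed genes and their effect (defaults 5 and 1.5).
#' @param nb_dispersion Negative-binomial dispersion, var = mu + mu^2 *
#'   disp (default 0.2).
#' @param methyl_diff_probe_count,methyl_beta_shift Planted
#'   differential probes and their beta-mean shift (defaults 5, 0.2).
#' @param cnv_segments_per_sample Random copy-number segments per sample
#'   (default 8).
#' @param cnv_gain_prob_by_class Probability of the planted amplified
#'   region, by class (nonsurvivor, survivor); default c(0.5, 0.2).
#' @param n_signatures Synthetic reference SBS signatures (default 5).
#' @param censor_fraction Extra early-censored cases injected, as a
#'   fraction of \code{n_samples} (default 0.08).
#' @param seed Master seed for every random draw.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_samples = 267L, fraction_nonsurvivor = 1 / 3,
                        n_genes = 60L, n_gene_sets = 12L, genes_per_set = 5L,
                        n_probes = 60L, n_mirna = 20L,
                        planted_pathway_size = 4L, mutual_exclusivity = TRUE,
                        mutation_rate_background = 0.05,
                        pathway_mutation_prob_by_class = c(0.55, 0.28),
                        de_gene_count = 5L, de_log2_fold_change = 1.5,
                        nb_dispersion = 0.2,
                        methyl_diff_probe_count = 5L, methyl_beta_shift = 0.2,
                        cnv_segments_per_sample = 8L,
                        cnv_gain_prob_by_class = c(0.5, 0.2),
                        n_signatures = 5L,
                        censor_fraction = 0.08, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               fraction_nonsurvivor = fraction_nonsurvivor,
               n_genes = as.integer(n_genes),
               n_gene_sets = as.integer(n_gene_sets),
               genes_per_set = as.integer(genes_per_set),
               n_probes = as.integer(n_probes), n_mirna = as.integer(n_mirna),
               planted_pathway_size = as.integer(planted_pathway_size),
               mutual_exclusivity = isTRUE(mutual_exclusivity),
               mutation_rate_background = mutation_rate_background,
               pathway_mutation_prob_by_class = pathway_mutation_prob_by_class,
               de_gene_count = as.integer(de_gene_count),
               de_log2_fold_change = de_log2_fold_change,
               nb_dispersion = nb_dispersion,
               methyl_diff_probe_count = as.integer(methyl_diff_probe_count),
               methyl_beta_shift = methyl_beta_shift,
               cnv_segments_per_sample = as.integer(cnv_segments_per_sample),
               cnv_gain_prob_by_class = cnv_gain_prob_by_class,
               n_signatures = as.integer(n_signatures),
               censor_fraction = censor_fraction,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_samples > 0, fraction_nonsurvivor > 0, fraction_nonsurvivor < 1,
              n_genes > 0, n_gene_sets > 0, genes_per_set > 0,
              planted_pathway_size >= 1, planted_pathway_size <= n_genes,
              mutation_rate_background >= 0, mutation_rate_background <= 1,
              all(pathway_mutation_prob_by_class >= 0),
              all(pathway_mutation_prob_by_class <= 1),
              de_gene_count >= 0, de_gene_count <= n_genes,
              nb_dispersion >= 0,
              methyl_diff_probe_count >= 0, methyl_diff_probe_count <= n_probes,
              all(cnv_gain_prob_by_class >= 0), all(cnv_gain_prob_by_class <= 1),
              censor_fraction >= 0)
  })
  structure(spec, class = "cohort_spec")
}

#' Null version of a cohort spec: all planted effects removed
#'
#' Sets pathway mutation and copy-number-gain probabilities equal
#' between classes, the expression fold change to 0 and the methylation
#' shift to 0, yielding label-independent data.
#'
#' @param spec A \code{cohort_spec}.
#' @return The modified \code{cohort_spec}.
#' @export
cohort_spec_null <- function(spec) {
  spec$pathway_mutation_prob_by_class <-
    rep(mean(spec$pathway_mutation_prob_by_class), 2)
  spec$cnv_gain_prob_by_class <- rep(mean(spec$cnv_gain_prob_by_class), 2)
  spec$de_log2_fold_change <- 0
  spec$methyl_beta_shift <- 0
  spec
}

.GENE_LEN <- 200L
.GENE_GAP <- 100L
.GENOME_FLANK <- 100L

#' Generate the fixed fixtures of a synthetic cohort
#'
#' Produces the reference sequence (long enough to hold every gene model
#' with flanks), the gene models, the gene-set collection (the planted
#' pathway set first, then random sets over the remaining genes) and a
#' synthetic reference SBS96 signature matrix whose columns are
#' probability vectors.  Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with \code{genome} (named character, one chromosome),
#'   \code{gene_models}, \code{gene_sets}, \code{signatures} and
#'   \code{truth_fixtures} (planted pathway gene/set names).
#' @export
generate_fixtures <- function(spec) {
  set.seed(spec$seed)
  genome_len <- .GENOME_FLANK * 2L +
    spec$n_genes * (.GENE_LEN + .GENE_GAP)
  genome <- paste(sample(.BASES, genome_len, replace = TRUE), collapse = "")
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  starts <- .GENOME_FLANK + (seq_len(spec$n_genes) - 1L) * (.GENE_LEN + .GENE_GAP) + 1L
  gene_models <- data.frame(gene = genes, chrom = "chr1",
                            start = starts, end = starts + .GENE_LEN - 1L,
                            stringsAsFactors = FALSE)
  if (max(gene_models$end) + .GENOME_FLANK > genome_len)
    stop("gene models do not fit the reference sequence", call. = FALSE)

  pathway_genes <- genes[seq_len(spec$planted_pathway_size)]
  other <- setdiff(genes, pathway_genes)
  sets <- list(GS_PATHWAY = pathway_genes)
  for (i in seq_len(spec$n_gene_sets - 1L)) {
    sets[[sprintf("GS%02d", i)]] <-
      sample(other, min(spec$genes_per_set, length(other)))
  }

  sigs <- matrix(rgamma(96 * spec$n_signatures, shape = 0.5), 96,
                 dimnames = list(sbs96_categories(),
                                 sprintf("SYNSIG%d", seq_len(spec$n_signatures))))
  sigs <- sweep(sigs, 2, colSums(sigs), "/")

  list(genome = c(chr1 = genome), gene_models = gene_models,
       gene_sets = sets, signatures = sigs,
       truth_fixtures = list(planted_gene_set = "GS_PATHWAY",
                             planted_genes = pathway_genes))
}

#' @importFrom stats rgamma rpois
.rand_other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(.BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

# class-dependent copy-number gain probability lookup
.class_prob <- function(classes, probs) {
  ifelse(classes == "nonsurvivor", probs[1], probs[2])
}

#' Generate a complete synthetic multiomics cohort
#'
#' Emits all five omics layers plus the clinical table and genome
#' fixtures to \code{dir}, in exactly the formats the package readers
#' consume, together with a manifest (\code{manifest.yaml}) listing the
#' emitted paths and the planted truth.  Nonsurvivors die uniformly on
#' days 30-729; survivors have follow-up of at least 730 days; an extra
#' \code{censor_fraction} of early-censored (alive, < 730 days) cases is
#' appended to exercise the label exclusion logic.  Byte-identical
#' output for identical spec (including seed).
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, a list with \code{paths} (named file paths),
#'   \code{truth} (planted signal description and true class labels) and
#'   \code{fixtures}.
#' @export
generate_cohort <- function(spec, dir) {
  fx <- generate_fixtures(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 101L)

  n <- spec$n_samples
  n_non <- round(spec$fraction_nonsurvivor * n)
  n_cens <- round(spec$censor_fraction * n)
  n_total <- n + n_cens
  samples <- sprintf("S%04d", seq_len(n_total))
  classes <- c(rep("nonsurvivor", n_non), rep("survivor", n - n_non),
               rep("survivor", n_cens))  # censored cases drawn as baseline
  labeled <- seq_len(n)

  genome <- fx$genome[["chr1"]]
  gm <- fx$gene_models
  pathway <- fx$truth_fixtures$planted_genes
  bg_genes <- setdiff(gm$gene, pathway)

  # --- somatic mutations -------------------------------------------------
  set.seed(spec$seed + 202L)
  rows <- list()
  add_snv <- function(s, gene_row, effect) {
    pos <- sample(seq(gm$start[gene_row], gm$end[gene_row]), 1)
    ref <- substr(genome, pos, pos)
    data.frame(sample_id = s, chrom = "chr1", pos = pos, ref = ref,
               alt = .rand_other_base(ref), gene = gm$gene[gene_row],
               effect = effect, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_total)) {
    s <- samples[i]
    # background mutations (never in the planted pathway, preserving
    # mutual exclusivity there by construction)
    mut_bg <- bg_genes[runif(length(bg_genes)) < spec$mutation_rate_background]
    for (g in mut_bg) rows[[length(rows) + 1L]] <-
      add_snv(s, which(gm$gene == g), "protein_altering")
    # planted pathway signal
    p_path <- .class_prob(classes[i], spec$pathway_mutation_prob_by_class)
    if (spec$mutual_exclusivity) {
      if (runif(1) < p_path) {
        g <- sample(pathway, 1)
        rows[[length(rows) + 1L]] <- add_snv(s, which(gm$gene == g), "protein_altering")
      }
    } else {
      for (g in pathway[runif(length(pathway)) < p_path / length(pathway)]) {
        rows[[length(rows) + 1L]] <- add_snv(s, which(gm$gene == g), "protein_altering")
      }
    }
    # effect-free passenger variants so all three catalogues are exercised
    n_extra <- rpois(1, 12)
    for (k in seq_len(n_extra)) {
      pos <- sample(seq(2L, nchar(genome) - 10L), 1)
      kind <- sample(c("sbs", "sbs", "sbs", "dbs", "ins", "del"), 1)
      ref <- switch(kind,
                    sbs = substr(genome, pos, pos),
                    dbs = substr(genome, pos, pos + 1L),
                    ins = substr(genome, pos, pos),
                    del = substr(genome, pos, pos + sample(1:3, 1)))
      alt <- switch(kind,
                    sbs = .rand_other_base(ref),
                    dbs = paste0(.rand_other_base(substr(ref, 1, 1)),
                                 .rand_other_base(substr(ref, 2, 2))),
                    ins = paste0(ref, paste(sample(.BASES, sample(1:3, 1),
                                                   replace = TRUE), collapse = "")),
                    del = substr(ref, 1, 1))
      hit <- which(gm$start <= pos & gm$end >= pos)
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = s, chrom = "chr1", pos = pos, ref = ref, alt = alt,
                   gene = if (length(hit)) gm$gene[hit[1]] else "",
                   effect = "synonymous", stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)

  # --- copy-number segments ---------------------------------------------
  set.seed(spec$seed + 303L)
  glen <- nchar(genome)
  planted_region <- c(start = gm$start[spec$n_genes - 2L], end = gm$end[spec$n_genes])
  seg_rows <- list()
  snap <- function(x) pmax(1L, pmin(glen, as.integer(round(x / 100) * 100 + 1L)))
  for (i in seq_len(n_total)) {
    s <- samples[i]
    for (k in seq_len(spec$cnv_segments_per_sample)) {
      start <- snap(runif(1, 1, glen - 400))
      end <- min(glen, start + as.integer(round(runif(1, 200, 2000) / 100) * 100) - 1L)
      cn <- sample(c(0, 1, 3, 4), 1)
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(sample_id = s, chrom = "chr1", start = start, end = end,
                   segment_mean = log2(max(cn, 0.25) / 2), stringsAsFactors = FALSE)
    }
    if (runif(1) < .class_prob(classes[i], spec$cnv_gain_prob_by_class)) {
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(sample_id = s, chrom = "chr1",
                   start = planted_region[["start"]], end = planted_region[["end"]],
                   segment_mean = log2(4 / 2), stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)

  # --- expression counts (mRNA, miRNA) -----------------------------------
  set.seed(spec$seed + 404L)
  de_genes <- sample(bg_genes, spec$de_gene_count)
  base_mu <- exp(rnorm(spec$n_genes, log(200), 1))
  names(base_mu) <- gm$gene
  size <- if (spec$nb_dispersion > 0) 1 / spec$nb_dispersion else Inf
  rcounts <- function(k, mu) {
    if (is.finite(size)) rnbinom(k, mu = mu, size = size) else rpois(k, mu)
  }
  mrna <- matrix(0L, spec$n_genes, n_total, dimnames = list(gm$gene, samples))
  for (i in seq_len(n_total)) {
    mu <- base_mu
    if (classes[i] == "nonsurvivor")
      mu[de_genes] <- mu[de_genes] * 2^spec$de_log2_fold_change
    mrna[, i] <- rcounts(spec$n_genes, mu)
  }
  mirna_ids <- sprintf("MIR%03d", seq_len(spec$n_mirna))
  mirna_mu <- exp(rnorm(spec$n_mirna, log(100), 1))
  mirna <- matrix(rcounts(spec$n_mirna * n_total, mirna_mu),
                  spec$n_mirna, n_total, dimnames = list(mirna_ids, samples))

  # --- methylation betas --------------------------------------------------
  set.seed(spec$seed + 505L)
  probes <- sprintf("cg%05d", seq_len(spec$n_probes))
  diff_probes <- probes[seq_len(spec$methyl_diff_probe_count)]
  probe_mean <- runif(spec$n_probes, 0.2, 0.8)
  names(probe_mean) <- probes
  conc <- 30
  meth <- matrix(0, spec$n_probes, n_total, dimnames = list(probes, samples))
  for (i in seq_len(n_total)) {
    m <- probe_mean
    if (classes[i] == "nonsurvivor") {
      m[diff_probes] <- pmin(0.95, pmax(0.05, m[diff_probes] + spec$methyl_beta_shift))
    }
    meth[, i] <- rbeta(spec$n_probes, m * conc, (1 - m) * conc)
  }

  # --- clinical ------------------------------------------------------------
  set.seed(spec$seed + 606L)
  days <- integer(n_total)
  status <- character(n_total)
  for (i in seq_len(n_total)) {
    if (i > n) {                      # injected early-censored case
      days[i] <- sample(30:729, 1); status[i] <- "alive"
    } else if (classes[i] == "nonsurvivor") {
      days[i] <- sample(30:729, 1); status[i] <- "dead"
    } else {
      days[i] <- sample(730:2000, 1)
      status[i] <- sample(c("alive", "dead"), 1, prob = c(0.75, 0.25))
    }
  }
  clinical <- data.frame(sample_id = samples,
                         days_to_last_contact_or_death = days,
                         vital_status = status,
                         cause_of_death_cancer = ifelse(status == "dead", TRUE, NA),
                         stringsAsFactors = FALSE)

  # --- write bundle --------------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    signatures = file.path(dir, "signatures_synthetic.tsv"),
    mutations = file.path(dir, "mutations.maf"),
    cnv = file.path(dir, "cnv.seg"),
    mrna = file.path(dir, "mrna_counts.tsv"),
    mirna = file.path(dir, "mirna_counts.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  dna <- Biostrings::DNAStringSet(fx$genome)
  Biostrings::writeXStringSet(dna, paths$genome, width = 80L)
  write_bed(fx$gene_models, paths$genes)
  write_gmt(fx$gene_sets, paths$gene_sets)
  write_matrix_tsv(fx$signatures, paths$signatures, id_col = "category")
  write_maf(variants, paths$mutations)
  write_seg(segments, paths$cnv)
  write_matrix_tsv(mrna, paths$mrna, id_col = "gene_id")
  write_matrix_tsv(mirna, paths$mirna, id_col = "mirna_id")
  write_matrix_tsv(round(meth, 6), paths$methylation, id_col = "probe_id")
  write_clinical(clinical, paths$clinical)

  truth <- list(
    planted_gene_set = fx$truth_fixtures$planted_gene_set,
    planted_genes = pathway,
    planted_de_genes = de_genes,
    planted_probes = diff_probes,
    planted_cnv_region = list(chrom = "chr1",
                              start = unname(planted_region[["start"]]),
                              end = unname(planted_region[["end"]])),
    class_labels = setNames(classes[labeled], samples[labeled]),
    censored_samples = samples[setdiff(seq_len(n_total), labeled)]
  )
  yaml::write_yaml(list(paths = lapply(paths, normalizePath, mustWork = FALSE),
                        truth = truth), paths$manifest)
  invisible(list(paths = paths, truth = truth, fixtures = fx))
}
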