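#' Dichotomize survival at a fixed horizon
#'
#' Assigns each clinical case a binary label — \code{nonsurvivor} if the
#' patient died before the horizon, \code{survivor} otherwise — and
#' excludes cases whose 2-year status cannot be ascertained: patients
#' alive at last contact but followed for less than the horizon
#' (\code{censored_before_horizon}) and, optionally, deaths from causes
#' other than cancer (\code{non_cancer_death}).  Death exactly on the
#' horizon day counts as survival by default ("died within" read
#' strictly); set \code{death_at_horizon_survives = FALSE} for the other
#' boundary convention.
#'
#' @param clinical Data frame of clinical records (see [read_clinical()]).
#' @param horizon_days Positive integer horizon, default 730 (2 years).
#' @param exclude_non_cancer_death If TRUE, deaths with
#'   \code{cause_of_death_cancer == FALSE} are excluded instead of
#'   labelled.
#' @param death_at_horizon_survives Boundary convention for a death on
#'   exactly the horizon day.
#' @return An object of class \code{label_set}: list with
#'   \code{horizon_days}, \code{labels} (named factor with levels
#'   \code{survivor}, \code{nonsurvivor}) and \code{excluded} (named
#'   character vector of exclusion reasons).  Every input sample appears
#'   exactly once across the two.
#' @export
dichotomize_survival <- function(clinical, horizon_days = 730L,
                                 exclude_non_cancer_death = FALSE,
                                 death_at_horizon_survives = TRUE) {
  stopifnot(horizon_days > 0)
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table", call. = FALSE)
  if (any(is.na(clinical$days_to_last_contact_or_death)))
    stop("missing day counts in clinical table", call. = FALSE)

  days <- clinical$days_to_last_contact_or_death
  dead <- clinical$vital_status == "dead"
  died_within <- if (death_at_horizon_survives) days < horizon_days else days <= horizon_days

  labels <- character(nrow(clinical))
  excluded <- character(nrow(clinical))
  labels[dead & died_within] <- "nonsurvivor"
  labels[dead & !died_within] <- "survivor"
  labels[!dead & days >= horizon_days] <- "survivor"
  excluded[!dead & days < horizon_days] <- "censored_before_horizon"
  if (exclude_non_cancer_death) {
    non_cancer <- dead & !is.na(clinical$cause_of_death_cancer) &
      !clinical$cause_of_death_cancer
    labels[non_cancer] <- ""
    excluded[non_cancer] <- "non_cancer_death"
  }

  keep <- nzchar(labels)
  lab <- factor(labels[keep], levels = c("survivor", "nonsurvivor"))
  names(lab) <- clinical$sample_id[keep]
  exc <- excluded[nzchar(excluded)]
  names(exc) <- clinical$sample_id[nzchar(excluded)]
  structure(list(horizon_days = as.integer(horizon_days),
                 labels = lab, excluded = exc),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: horizon %d days; %d survivors, %d nonsurvivors, %d excluded\n",
              x$horizon_days, sum(x$labels == "survivor"),
              sum(x$labels == "nonsurvivor"), length(x$excluded)))
  invisible(x)
}

#' Write a label set to TSV (sample, label, excluded_reason)
#' @param labels A \code{label_set}.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  df <- rbind(
    data.frame(sample_id = names(labels$labels),
               label = as.character(labels$labels),
               excluded_reason = "", stringsAsFactors = FALSE),
    data.frame(sample_id = names(labels$excluded),
               label = "",
               excluded_reason = unname(labels$excluded), stringsAsFactors = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a label set written by [write_labels()]
#' @param path Input path.
#' @param horizon_days Horizon recorded in the returned object.
#' @return A \code{label_set}.
#' @export
read_labels <- function(path, horizon_days = 730L) {
  df <- read.delim(path, colClasses = "character")
  lab_rows <- nzchar(df$label)
  lab <- factor(df$label[lab_rows], levels = c("survivor", "nonsurvivor"))
  names(lab) <- df$sample_id[lab_rows]
  exc <- df$excluded_reason[!lab_rows]
  names(exc) <- df$sample_id[!lab_rows]
  structure(list(horizon_days = as.integer(horizon_days),
                 labels = lab, excluded = exc),
            class = "label_set")
}
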