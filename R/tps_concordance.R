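#' Cell-type counts for one slide
#'
#' @param n_tcpos,n_tcneg,n_oc nonnegative integer counts of PD-L1
#'   positive tumor cells, PD-L1 negative tumor cells and other cells.
#' @return object of class `cell_counts`.
#' @export
cell_counts <- function(n_tcpos, n_tcneg, n_oc = 0L) {
  if (any(c(n_tcpos, n_tcneg, n_oc) < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  structure(list(n_tcpos = n_tcpos, n_tcneg = n_tcneg, n_oc = n_oc),
            class = "cell_counts")
}

#' Tumor proportion score (TPS)
#'
#' TPS is the percentage of PD-L1 positive tumor cells among all tumor
#' cells: `100 * TC+ / (TC+ + TC-)`. Other cells never enter the score.
#' When no tumor cells were counted the score is undefined and an
#' explicit `NA` is returned (never 0): a failed tumor detection must not
#' silently read as "PD-L1 negative".
#'
#' @param counts a [cell_counts()] object, or the TC+ count when `n_tcneg`
#'   is given.
#' @param n_tcneg optional TC- count for the two-argument form.
#' @return TPS percentage in `[0, 100]`, or `NA_real_` when undefined.
#' @export
compute_tps <- function(counts, n_tcneg = NULL) {
  if (!is.null(n_tcneg)) counts <- cell_counts(counts, n_tcneg)
  if (!inherits(counts, "cell_counts")) {
    counts <- do.call(cell_counts, as.list(counts))
  }
  denom <- counts$n_tcpos + counts$n_tcneg
  if (denom <= 0) return(NA_real_)
  100 * counts$n_tcpos / denom
}

#' Concordance configuration
#'
#' @param delta_pp discrepancy (percentage points) strictly above which an
#'   assessment is flagged for re-evaluation (default 10).
#' @param cutoff_percent clinical TPS cutoff used for binarized
#'   concordance (default 20; `>= cutoff` counts as positive).
#' @param correlation `"pearson"` or `"spearman"`.
#' @param patient_aggregation `"mean"`, `"max"` or `"per_slide"` for
#'   multi-slide patients.
#' @return object of class `concordance_config`.
#' @export
concordance_config <- function(delta_pp = 10,
                               cutoff_percent = 20,
                               correlation = c("pearson", "spearman"),
                               patient_aggregation = c("mean", "max", "per_slide")) {
  stopifnot(delta_pp > 0, cutoff_percent > 0, cutoff_percent < 100)
  structure(
    list(delta_pp = delta_pp, cutoff_percent = cutoff_percent,
         correlation = match.arg(correlation),
         patient_aggregation = match.arg(patient_aggregation)),
    class = "concordance_config"
  )
}

#' Aggregate per-slide TPS to a patient-level TPS
#'
#' Multi-slide patients get the arithmetic mean of their defined slide
#' scores by default (`"max"` is available); undefined slides are
#' dropped, and the result is undefined only when every slide is.
#' Per-slide values should always be retained alongside the aggregate.
#'
#' @param slide_tps numeric vector of slide TPS percentages (may contain
#'   `NA` for undefined slides).
#' @param method `"mean"` or `"max"`.
#' @return patient TPS percentage or `NA_real_`.
#' @export
aggregate_patient <- function(slide_tps, method = c("mean", "max")) {
  stopifnot(length(slide_tps) >= 1)
  method <- match.arg(method)
  ok <- !is.na(slide_tps)
  if (!any(ok)) return(NA_real_)
  switch(method,
         mean = mean(slide_tps[ok]),
         max = max(slide_tps[ok]))
}

#' Flag AI-vs-pathologist discrepancies
#'
#' An assessment is flagged when it differs from the AI score by strictly
#' more than `delta_pp` percentage points; a difference of exactly
#' `delta_pp` is not flagged.
#'
#' @param ai AI TPS percentage.
#' @param raters numeric vector of pathologist TPS percentages.
#' @param delta_pp flag threshold in percentage points (default 10).
#' @return logical vector, one flag per rater.
#' @export
flag_discrepancies <- function(ai, raters, delta_pp = 10) {
  abs(ai - raters) > delta_pp
}

#' Binarized (cutoff) concordance between AI and one rater
#'
#' Both score lists are binarized at the clinical cutoff (`>= cutoff` is
#' positive); accuracy is the percentage of cases on the same side.
#'
#' @param ai,rater numeric vectors of equal length (TPS percentages).
#' @param cutoff_percent TPS cutoff (default 20).
#' @return list with `accuracy` (percent), `discordant` (count) and `n`.
#' @export
cutoff_concordance <- function(ai, rater, cutoff_percent = 20) {
  if (length(ai) != length(rater)) {
    stop("score lists have different lengths", call. = FALSE)
  }
  stopifnot(length(ai) >= 1)
  a <- ai >= cutoff_percent
  r <- rater >= cutoff_percent
  disc <- sum(a != r)
  list(accuracy = 100 * (length(ai) - disc) / length(ai),
       discordant = disc, n = length(ai))
}

#' Correlation between AI and rater scores
#'
#' Pearson product-moment correlation by default (Spearman available).
#' Requires at least three pairs and nonzero variance in both vectors;
#' otherwise `NA` is returned with a warning.
#'
#' @param ai,rater numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
concordance_correlation <- function(ai, rater,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(ai) != length(rater) || length(ai) < 3) {
    stop("need at least 3 paired scores", call. = FALSE)
  }
  if (stats::sd(ai) == 0 || stats::sd(rater) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(ai, rater, method = method)
}

#' Summarize the reassessment bookkeeping
#'
#' Counts flagged patients and assessments over all patient-by-rater
#' pairs, and how many flagged assessments led to a revised score.
#'
#' @param records data frame with one row per patient-rater assessment and
#'   columns `patient_id`, `rater_id`, `flagged` (logical) and optionally
#'   `changed` (logical; whether a flagged assessment was revised).
#' @return list with `n_patients_flagged`, `n_assessments_flagged`,
#'   `pct_assessments` (percentage of all assessments flagged),
#'   `n_changed` and `n_unchanged`.
#' @export
reassessment_summary <- function(records) {
  stopifnot(all(c("patient_id", "rater_id", "flagged") %in% names(records)))
  n_total <- nrow(records)
  flagged <- records$flagged
  n_flagged <- sum(flagged)
  pats <- unique(records$patient_id[flagged])
  changed <- if ("changed" %in% names(records)) records$changed else
    rep(NA, n_total)
  n_changed <- sum(flagged & changed %in% TRUE)
  n_unchanged <- sum(flagged & changed %in% FALSE)
  list(
    n_patients_flagged = length(pats),
    n_assessments_flagged = n_flagged,
    pct_assessments = if (n_total > 0) 100 * n_flagged / n_total else 0,
    n_changed = n_changed,
    n_unchanged = n_unchanged
  )
}

#' Full AI-vs-pathologist concordance report
#'
#' Joins AI slide scores (aggregated per patient) with pathologist scores,
#' flags discrepancies, binarizes at the clinical cutoff, and summarizes
#' per-rater correlation and cutoff accuracy.
#'
#' @param ai_scores data frame with columns `patient_id`, `slide_id`,
#'   `tps` (AI per-slide TPS percentages).
#' @param pathologist_scores data frame with columns `patient_id`,
#'   `rater_id`, `tps`.
#' @param cfg a [concordance_config()].
#' @return list with `table` (one row per assessment: `patient_id`,
#'   `ai_tps`, `rater_id`, `rater_tps`, `abs_diff`, `flagged`,
#'   `ai_cutoff`, `rater_cutoff`, `concordant`) and `summary` (per-rater
#'   correlations and cutoff accuracies, their means, and the
#'   reassessment counts).
#' @export
concordance_report <- function(ai_scores, pathologist_scores,
                               cfg = concordance_config()) {
  agg_method <- if (cfg$patient_aggregation == "per_slide") "mean" else
    cfg$patient_aggregation
  ai_pat <- stats::aggregate(tps ~ patient_id, data = ai_scores,
                             FUN = function(x) aggregate_patient(x, agg_method))
  names(ai_pat)[2] <- "ai_tps"
  tab <- merge(pathologist_scores, ai_pat, by = "patient_id")
  tab$abs_diff <- abs(tab$ai_tps - tab$tps)
  tab$flagged <- flag_discrepancies(tab$ai_tps, tab$tps, cfg$delta_pp)
  tab$ai_cutoff <- tab$ai_tps >= cfg$cutoff_percent
  tab$rater_cutoff <- tab$tps >= cfg$cutoff_percent
  tab$concordant <- tab$ai_cutoff == tab$rater_cutoff
  names(tab)[names(tab) == "tps"] <- "rater_tps"
  tab <- tab[order(tab$rater_id, tab$patient_id),
             c("patient_id", "ai_tps", "rater_id", "rater_tps", "abs_diff",
               "flagged", "ai_cutoff", "rater_cutoff", "concordant")]
  rownames(tab) <- NULL

  raters <- unique(tab$rater_id)
  per_rater <- lapply(raters, function(r) {
    sub <- tab[tab$rater_id == r, ]
    cc <- cutoff_concordance(sub$ai_tps, sub$rater_tps, cfg$cutoff_percent)
    list(
      rater_id = r,
      # correlation needs >= 3 cases and nonzero variance; NA otherwise
      correlation = if (nrow(sub) >= 3 && stats::sd(sub$ai_tps) > 0 &&
                          stats::sd(sub$rater_tps) > 0) {
        concordance_correlation(sub$ai_tps, sub$rater_tps, cfg$correlation)
      } else {
        NA_real_
      },
      accuracy = cc$accuracy,
      discordant = cc$discordant,
      n = cc$n
    )
  })
  reass <- reassessment_summary(data.frame(
    patient_id = tab$patient_id, rater_id = tab$rater_id,
    flagged = tab$flagged
  ))
  list(
    table = tab,
    summary = list(
      per_rater = per_rater,
      mean_correlation = mean(vapply(per_rater, `[[`, numeric(1),
                                     "correlation"), na.rm = TRUE),
      mean_accuracy = mean(vapply(per_rater, `[[`, numeric(1), "accuracy")),
      reassessment = reass
    )
  )
}
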