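#' Sensitivity of an HRD cutoff for BRCA-deficient samples
#'
#' Fraction of BRCA-deficient samples whose HRD score reaches the cutoff:
#' `#(deficient & score >= t) / #deficient`.
#'
#' @param scores Integer HRD scores, one per sample.
#' @param deficient_flags Logical vector marking BRCA-deficient samples.
#' @param t Integer cutoff.
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity_at_cutoff <- function(scores, deficient_flags, t) {
  stopifnot(length(scores) == length(deficient_flags))
  n_def <- sum(deficient_flags)
  if (n_def == 0L) stop("no BRCA-deficient samples; sensitivity undefined")
  sum(scores[deficient_flags] >= t) / n_def
}

#' Candidate HRD-positive cutoffs at a sensitivity floor
#'
#' Integer cutoffs whose sensitivity for BRCA-deficient samples is at least
#' `min_sensitivity`. Because sensitivity is non-increasing in the cutoff,
#' every cutoff below a qualifying one also qualifies; with the default
#' `search_range = NULL` the function therefore returns only the top
#' qualifying plateau — the cutoffs achieving the *smallest* sensitivity
#' still at or above the floor. With discontinuous score distributions this
#' plateau is exactly the interval of interchangeable thresholds (the
#' "candidate" cutoffs) from which the final threshold is picked by
#' [select_cutoff()]. Supplying an explicit `search_range` instead returns
#' every qualifying integer in that range.
#'
#' @inheritParams sensitivity_at_cutoff
#' @param min_sensitivity Sensitivity floor; default 0.95.
#' @param search_range `NULL` (plateau over `0:max(scores)`), or an integer
#'   vector of cutoffs to scan (e.g. `36:120`).
#' @return Sorted integer vector (possibly empty).
#' @export
candidate_cutoffs <- function(scores, deficient_flags,
                              min_sensitivity = 0.95, search_range = NULL) {
  stopifnot(length(scores) == length(deficient_flags))
  plateau <- is.null(search_range)
  if (plateau) search_range <- 0:max(scores)
  search_range <- sort(unique(as.integer(search_range)))
  sens <- vapply(search_range, function(t) {
    sensitivity_at_cutoff(scores, deficient_flags, t)
  }, numeric(1))
  keep <- sens >= min_sensitivity
  if (!any(keep)) return(integer(0))
  if (plateau) keep <- keep & sens == min(sens[keep])
  search_range[keep]
}

#' Select the HRD threshold from candidate cutoffs
#'
#' The threshold is the median candidate; for even-sized candidate sets the
#' lower median is used, so the selected threshold is always itself a
#' candidate (e.g. candidates 36..41 select 38).
#'
#' @param candidates Non-empty integer vector of candidate cutoffs.
#' @param rule Only `"lower_median"` is implemented.
#' @return Integer threshold.
#' @export
select_cutoff <- function(candidates, rule = "lower_median") {
  rule <- match.arg(rule, "lower_median")
  if (length(candidates) == 0L) stop("no candidate cutoffs to select from")
  sorted <- sort(as.integer(candidates))
  sorted[ceiling(length(sorted) / 2)]
}

#' Cox proportional-hazards cutoff scan
#'
#' For each candidate cutoff `t`, fits a univariate Cox model of
#' progression-free survival on the binary indicator `score >= t` (Efron
#' tie handling) and reports the hazard ratio of positive vs negative, its
#' 95% confidence interval, and the Wald p-value. Cutoffs leaving fewer
#' than two samples in either arm are skipped with a warning. The cutoff
#' with the smallest p-value is flagged as the scan optimum.
#'
#' @param scores Integer HRD scores.
#' @param pfs_days Progression-free survival times (days).
#' @param event_flags Logical/0-1 event indicators (1 = progression).
#' @param t_range Integer cutoffs to scan; default `35:45`.
#' @return List with `scan`, a `data.frame` (`cutoff`, `n_positive`,
#'   `n_negative`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`), and
#'   `best_cutoff`, the cutoff minimising the p-value.
#' @export
cox_cutoff_scan <- function(scores, pfs_days, event_flags, t_range = 35:45) {
  stopifnot(length(scores) == length(pfs_days),
            length(scores) == length(event_flags))
  event_flags <- as.integer(event_flags)
  rows <- lapply(as.integer(t_range), function(t) {
    pos <- scores >= t
    if (sum(pos) < 2L || sum(!pos) < 2L) {
      warning("cutoff ", t, " skipped: fewer than 2 samples in one arm")
      return(NULL)
    }
    fit <- survival::coxph(
      survival::Surv(pfs_days, event_flags) ~ pos, ties = "efron")
    s <- summary(fit)
    data.frame(cutoff = t, n_positive = sum(pos), n_negative = sum(!pos),
               hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
               ci_low = unname(s$conf.int[1, "lower .95"]),
               ci_high = unname(s$conf.int[1, "upper .95"]),
               p_value = unname(s$coefficients[1, "Pr(>|z|)"]))
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0L) {
    stop("all cutoffs in the scan range are degenerate")
  }
  rownames(scan) <- NULL
  list(scan = scan, best_cutoff = scan$cutoff[which.min(scan$p_value)])
}
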