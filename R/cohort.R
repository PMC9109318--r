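#' Compare score distributions between two groups
#'
#' Two-sided Wilcoxon rank-sum test with group medians, the standard
#' comparison for continuous scores between clinical groups (e.g. HRD score
#' by platinum response).
#'
#' @param scores_a,scores_b Numeric score vectors for the two groups.
#' @return List with `median_a`, `median_b`, `p_value`.
#' @export
compare_scores <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("both groups must be non-empty")
  }
  p <- stats::wilcox.test(scores_a, scores_b,
                          alternative = "two.sided")$p.value
  list(median_a = stats::median(scores_a),
       median_b = stats::median(scores_b),
       p_value = p)
}

# build a Surv object from a cohort table, with basic checks
cohort_surv <- function(cohort) {
  stopifnot(all(c("pfs_days", "pfs_event") %in% names(cohort)))
  if (any(cohort$pfs_days < 0)) stop("pfs_days must be non-negative")
  survival::Surv(cohort$pfs_days, as.integer(cohort$pfs_event))
}

#' Kaplan-Meier medians and log-rank test
#'
#' Estimates the Kaplan-Meier median progression-free survival per group
#' and tests the group difference with the log-rank test. A group whose
#' curve never crosses 0.5 has its median reported as `NA` ("not reached").
#'
#' @param cohort `data.frame` with columns `pfs_days`, `pfs_event` and the
#'   grouping column.
#' @param group_by Name of the grouping column (e.g. `"hrd_positive"` or
#'   `"brca_status"`).
#' @return List with `medians` (named numeric, `NA` = not reached),
#'   `n` (group sizes), `p_value` (log-rank).
#' @export
km_logrank <- function(cohort, group_by = "hrd_positive") {
  stopifnot(group_by %in% names(cohort))
  grp <- factor(cohort[[group_by]])
  if (nlevels(grp) < 2L) stop("need at least two groups for a log-rank test")
  if (sum(cohort$pfs_event) == 0L) {
    stop("no events in the cohort; survival comparison is degenerate")
  }
  surv <- cohort_surv(cohort)
  fit <- survival::survfit(surv ~ grp)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  medians <- stats::setNames(tab[, "median"],
                             sub("^grp=", "", rownames(tab)))
  sd <- survival::survdiff(surv ~ grp)
  p <- stats::pchisq(sd$chisq, df = nlevels(grp) - 1L, lower.tail = FALSE)
  list(medians = medians,
       n = stats::setNames(as.vector(table(grp)), levels(grp)),
       p_value = p)
}

#' Multivariate Cox model of progression-free survival
#'
#' Fits a multivariable Cox proportional-hazards model (Efron ties) of PFS
#' on HRD status and clinical covariates. Reference levels: HRD-negative,
#' stage III, residual tumor R0.
#'
#' @param cohort `data.frame` with `pfs_days`, `pfs_event` and the
#'   covariate columns.
#' @param covariates Covariate column names; default
#'   `c("hrd_positive", "stage", "residual")`.
#' @return `data.frame` with one row per model term: `term`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
cox_multivariate <- function(cohort,
                             covariates = c("hrd_positive", "stage",
                                            "residual")) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop("cohort table is missing covariate(s): ",
         paste(missing_cov, collapse = ", "))
  }
  dat <- cohort[c("pfs_days", "pfs_event", covariates)]
  if ("hrd_positive" %in% covariates) {
    dat$hrd_positive <- factor(ifelse(as.logical(dat$hrd_positive),
                                      "positive", "negative"),
                               levels = c("negative", "positive"))
  }
  if ("stage" %in% covariates) {
    dat$stage <- factor(dat$stage,
                        levels = intersect(c("III", "IV", "other"),
                                           unique(as.character(dat$stage))))
  }
  if ("residual" %in% covariates) {
    dat$residual <- factor(dat$residual,
                           levels = intersect(c("R0", "R1", "R2"),
                                              unique(as.character(dat$residual))))
  }
  for (cv in covariates) {
    if (length(unique(dat[[cv]])) < 2L) {
      stop("covariate '", cv, "' is constant; drop it from the model")
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(pfs_days, as.integer(pfs_event)) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$conf.int),
                    hazard_ratio = unname(s$conf.int[, "exp(coef)"]),
                    ci_low = unname(s$conf.int[, "lower .95"]),
                    ci_high = unname(s$conf.int[, "upper .95"]),
                    p_value = unname(s$coefficients[, "Pr(>|z|)"]))
  rownames(out) <- NULL
  out
}

#' Concurrent-alteration enrichment scan
#'
#' For every alteration column with overall frequency above `min_freq`,
#' tests enrichment between HRD-positive and HRD-negative samples
#' (two-sided Fisher's exact test by default) and returns the alterations
#' with `p <= alpha` together with group frequencies and the direction of
#' enrichment. The full scan is attached as attribute `"scan"`.
#'
#' @param matrix Binary samples-by-alterations matrix (or data.frame);
#'   mutation, copy-loss and amplification of one gene are distinct
#'   columns.
#' @param hrd_flags Logical vector aligned to the matrix rows.
#' @param min_freq Minimum overall alteration frequency (exclusive);
#'   default 0.05.
#' @param alpha Significance cutoff on the (optionally adjusted) p-value.
#' @param test `"fisher"` (default) or `"chisq"`.
#' @param p_adjust `"none"` (default, raw p-values as in the original
#'   analyses) or `"BH"` for Benjamini-Hochberg.
#' @return `data.frame` with `alteration`, `n_pos`, `n_neg`, `freq_pos`,
#'   `freq_neg`, `p_value`, `direction` (`"positive"`/`"negative"`),
#'   sorted by p-value.
#' @export
enrichment_scan <- function(matrix, hrd_flags, min_freq = 0.05,
                            alpha = 0.05, test = c("fisher", "chisq"),
                            p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  mat <- as.matrix(matrix)
  if (nrow(mat) != length(hrd_flags)) {
    stop("alteration matrix rows and hrd_flags are misaligned (",
         nrow(mat), " vs ", length(hrd_flags), ")")
  }
  if (!all(mat %in% c(0, 1))) stop("alteration matrix must be binary")
  hrd_flags <- as.logical(hrd_flags)
  n_pos <- sum(hrd_flags)
  n_neg <- sum(!hrd_flags)
  keep <- colMeans(mat) > min_freq
  rows <- lapply(colnames(mat)[keep], function(alt) {
    a <- sum(mat[hrd_flags, alt])   # altered, HRD-positive
    c_ <- sum(mat[!hrd_flags, alt]) # altered, HRD-negative
    tab <- rbind(c(a, n_pos - a), c(c_, n_neg - c_))
    p <- if (test == "fisher") {
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    } else {
      stats::chisq.test(tab)$p.value
    }
    data.frame(alteration = alt, n_pos = a, n_neg = c_,
               freq_pos = a / n_pos, freq_neg = c_ / n_neg, p_value = p,
               direction = if (a / n_pos >= c_ / n_neg) "positive" else "negative")
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan)) {
    scan <- data.frame(alteration = character(), n_pos = integer(),
                       n_neg = integer(), freq_pos = numeric(),
                       freq_neg = numeric(), p_value = numeric(),
                       direction = character())
  }
  if (p_adjust == "BH") scan$p_value <- stats::p.adjust(scan$p_value, "BH")
  scan <- scan[order(scan$p_value), , drop = FALSE]
  rownames(scan) <- NULL
  out <- scan[scan$p_value <= alpha & scan$freq_pos != scan$freq_neg, ,
              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scan") <- scan
  out
}

#' Pearson concordance of two score vectors
#'
#' @param scores_a,scores_b Paired, equal-length numeric vectors (e.g. HRD
#'   scores from two scoring models).
#' @return Pearson correlation coefficient.
#' @export
concordance <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors differ in length")
  }
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    stop("zero variance; Pearson correlation undefined")
  }
  stats::cor(scores_a, scores_b, method = "pearson")
}

#' Cohen's kappa for paired status calls
#'
#' Unweighted Cohen's kappa quantifying agreement of two categorical call
#' vectors (e.g. HRD-positive/negative by two pipelines) beyond chance.
#'
#' @param calls_a,calls_b Paired, equal-length call vectors.
#' @return List with `kappa` and the `contingency` table.
#' @export
status_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length")
  }
  levels_all <- sort(unique(c(as.character(calls_a), as.character(calls_b))))
  a <- factor(as.character(calls_a), levels = levels_all)
  b <- factor(as.character(calls_b), levels = levels_all)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, contingency = tab)
}
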