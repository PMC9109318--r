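#' Parameters for simulating a cohort
#'
#' Study-level generative parameters for [simulate_cohort()]. The defaults
#' emulate an 85-patient high-grade serous ovarian cancer cohort treated
#' with platinum chemotherapy: 27% BRCA-deficient samples, 95% of which are
#' HRD-high; exponential progression-free survival with a 343-day median in
#' HRD-negative patients and a hazard ratio of 0.47 for HRD-positive ones;
#' and a platinum-sensitivity probability linked to HRD status.
#'
#' @param n_samples Number of samples (>= 2).
#' @param frac_brca_deficient Fraction of BRCA-deficient samples.
#' @param frac_monoallelic Fraction with a single pathogenic BRCA allele
#'   and no second hit.
#' @param p_high_given_deficient Probability a BRCA-deficient sample is
#'   HRD-high.
#' @param p_high_given_nondeficient Probability a non-deficient sample is
#'   HRD-high.
#' @param threshold Generative HRD threshold the phenotypes straddle.
#' @param margin Half-width of the unambiguous band: HRD-high totals are
#'   at least `threshold + margin`, HRD-low at most `threshold - margin`.
#' @param hr_hrd Hazard ratio of progression for HRD-positive vs negative.
#' @param baseline_median_days Median PFS (days) of HRD-negative samples.
#' @param censor_rate Target fraction of censored observations
#'   (independent uniform censoring).
#' @param pfi_link Named probabilities of platinum sensitivity given HRD
#'   status, `c(positive = , negative = )`.
#' @param p_hrr_deficient Named probabilities that a BRCA-intact sample
#'   carries a biallelic non-BRCA HRR-gene hit, by HRD status.
#' @param background_noise_rate Noise rate forwarded to the profile
#'   simulator.
#' @param with_profiles Build full segment profiles (`TRUE`) or only the
#'   cohort-level tables (`FALSE`, much faster for survival studies).
#' @param seed Optional integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 85L,
                          frac_brca_deficient = 0.271,
                          frac_monoallelic = 0.058,
                          p_high_given_deficient = 0.95,
                          p_high_given_nondeficient = 0.37,
                          threshold = 38L,
                          margin = 10L,
                          hr_hrd = 0.47,
                          baseline_median_days = 343,
                          censor_rate = 0.2,
                          pfi_link = c(positive = 0.82, negative = 0.63),
                          p_hrr_deficient = c(positive = 0.11,
                                              negative = 0.04),
                          background_noise_rate = 0,
                          with_profiles = TRUE,
                          seed = NULL) {
  stopifnot(n_samples >= 2, hr_hrd > 0, baseline_median_days > 0,
            frac_brca_deficient >= 0, frac_brca_deficient <= 1,
            frac_monoallelic >= 0,
            frac_brca_deficient + frac_monoallelic <= 1,
            censor_rate >= 0, censor_rate < 1,
            all(c(p_high_given_deficient, p_high_given_nondeficient,
                  pfi_link, p_hrr_deficient) >= 0),
            all(c(p_high_given_deficient, p_high_given_nondeficient,
                  pfi_link, p_hrr_deficient) <= 1),
            margin >= 0, threshold > margin)
  structure(as.list(environment()), class = "cohort_params")
}

# split a target HRD total into (loh, tai, lst) planted counts
split_total <- function(total, max_tai = 40L) {
  parts <- as.vector(stats::rmultinom(1L, total, c(0.45, 0.25, 0.30)))
  if (parts[2] > max_tai) {   # at most one TAI per autosomal chromosome end
    parts[1] <- parts[1] + parts[2] - max_tai
    parts[2] <- max_tai
  }
  parts
}

# uniform-censoring horizon giving the target overall censoring fraction
censor_horizon <- function(rates, weights, target) {
  if (target <= 0) return(Inf)
  p_cens <- function(m) {
    sum(weights * (1 - exp(-rates * m)) / (rates * m))
  }
  stats::uniroot(function(m) p_cens(m) - target,
                 lower = 1, upper = 1e7, tol = 1)$root
}

#' Simulate a cohort with HRD-linked survival and alterations
#'
#' Generates per-sample BRCA status, HRD phenotype (high/low, straddling
#' the generative threshold by an unambiguous margin), planted scar counts
#' (and optionally full segment profiles realising them), exponential
#' progression-free survival whose hazard is multiplied by `hr_hrd` for
#' HRD-positive samples with independent uniform censoring, a platinum
#' sensitivity flag linked to HRD status, BRCA1/2 and HRR-gene variant and
#' copy-number evidence consistent with the assigned status, and a binary
#' concurrent-alteration matrix with planted enrichments (one alteration
#' enriched in HRD-positive samples, one in HRD-negative, one exclusive to
#' positives, plus neutral columns).
#'
#' @param params A [cohort_params].
#' @param build A [genome_build]; default [hg19_build()].
#' @return List with:
#' \describe{
#'   \item{cohort}{`data.frame`: `sample_id`, `hrd_total`, `hrd_positive`,
#'     `brca_status`, `cancer_type`, `pt_response`, `pfs_days`,
#'     `pfs_event`, `stage`, `residual`, `hrr_deficient`.}
#'   \item{profiles}{Named list of [segment_profile] (or `NULL`).}
#'   \item{alterations}{Binary samples-by-alterations matrix.}
#'   \item{variants, gene_cnas}{Long-format evidence tables for
#'     [classify_brca_status()] / [hrr_deficiency()].}
#'   \item{truth}{Generative values: per-sample planted counts, phenotype,
#'     the threshold, and `hr_hrd`.}
#' }
#' @export
simulate_cohort <- function(params, build = hg19_build()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_samples
  ids <- sprintf("S%03d", seq_len(n))

  # BRCA status and HRD phenotype -------------------------------------
  status <- sample(c("deficient", "monoallelic_pathogenic", "intact"), n,
                   replace = TRUE,
                   prob = c(params$frac_brca_deficient,
                            params$frac_monoallelic,
                            1 - params$frac_brca_deficient -
                              params$frac_monoallelic))
  p_high <- ifelse(status == "deficient", params$p_high_given_deficient,
                   params$p_high_given_nondeficient)
  hrd_high <- stats::runif(n) < p_high
  lo_max <- params$threshold - params$margin
  hi_min <- params$threshold + params$margin
  total <- integer(n)
  total[hrd_high] <- pmin(107L, pmax(hi_min, round(stats::rnorm(
    sum(hrd_high), mean = 63, sd = 12))))
  total[!hrd_high] <- pmin(lo_max, pmax(0L, round(stats::rnorm(
    sum(!hrd_high), mean = 26, sd = 9))))
  # BRCA-deficient samples that fall below the threshold are near-misses:
  # their scar burden is genuinely elevated, so they land just under the
  # margin band rather than anywhere in the low range
  low_def <- !hrd_high & status == "deficient"
  total[low_def] <- sample(seq(max(0L, lo_max - 6L), lo_max),
                           sum(low_def), replace = TRUE)

  planted <- t(vapply(total, split_total, integer(3)))
  colnames(planted) <- c("loh", "tai", "lst")

  profiles <- NULL
  if (params$with_profiles) {
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- sim_params(planted[i, "loh"], planted[i, "tai"],
                       planted[i, "lst"],
                       background_noise_rate = params$background_noise_rate)
      sim <- simulate_profile(sp, build)
      sim$profile$sample_id <- ids[i]
      profiles[[i]] <- sim$profile
    }
    names(profiles) <- ids
  }

  # survival: exponential PFS, uniform censoring ----------------------
  lambda0 <- log(2) / params$baseline_median_days
  rate <- lambda0 * ifelse(hrd_high, params$hr_hrd, 1)
  t_event <- stats::rexp(n, rate)
  w_pos <- mean(hrd_high)
  horizon <- censor_horizon(c(lambda0 * params$hr_hrd, lambda0),
                            c(w_pos, 1 - w_pos), params$censor_rate)
  t_cens <- if (is.finite(horizon)) stats::runif(n, 0, horizon) else
    rep(Inf, n)
  pfs <- pmax(1, round(pmin(t_event, t_cens)))
  event <- as.integer(t_event <= t_cens)

  # platinum response via the PFI link ---------------------------------
  p_sens <- ifelse(hrd_high, params$pfi_link[["positive"]],
                   params$pfi_link[["negative"]])
  pt_response <- ifelse(stats::runif(n) < p_sens, "sensitive", "resistant")

  stage <- sample(c("III", "IV"), n, TRUE, prob = c(0.896, 0.104))
  residual <- sample(c("R0", "R1", "R2"), n, TRUE,
                     prob = c(0.494, 0.435, 0.071))

  # BRCA / HRR evidence tables -----------------------------------------
  hrr_pool <- setdiff(hrr_genes(), c("BRCA1", "BRCA2"))
  p_hrr <- ifelse(status == "intact",
                  ifelse(hrd_high, params$p_hrr_deficient[["positive"]],
                         params$p_hrr_deficient[["negative"]]), 0)
  hrr_def <- stats::runif(n) < p_hrr
  var_rows <- list()
  cna_rows <- list()
  add_var <- function(sample, gene, effect, cls, origin, allele) {
    var_rows[[length(var_rows) + 1L]] <<- data.frame(
      sample = sample, gene = gene, effect = effect, clinical_class = cls,
      origin = origin, allele_id = allele)
  }
  for (i in seq_len(n)) {
    gene <- if (stats::runif(1) < 0.76) "BRCA1" else "BRCA2"
    if (status[i] == "deficient") {
      mech <- sample(c("biallelic", "var_plus_del", "homdel"), 1L,
                     prob = c(0.6, 0.3, 0.1))
      if (mech == "biallelic") {
        add_var(ids[i], gene, "frameshift", "pathogenic", "germline",
                paste0(gene, ":a1"))
        add_var(ids[i], gene, "nonsense", "likely_pathogenic", "somatic",
                paste0(gene, ":a2"))
      } else if (mech == "var_plus_del") {
        add_var(ids[i], gene, "nonsense", "pathogenic", "somatic",
                paste0(gene, ":a1"))
        cna_rows[[length(cna_rows) + 1L]] <- data.frame(
          sample = ids[i], gene = gene, log2_ratio = -1.5)
      } else {
        cna_rows[[length(cna_rows) + 1L]] <- data.frame(
          sample = ids[i], gene = gene, log2_ratio = -2.5)
      }
    } else if (status[i] == "monoallelic_pathogenic") {
      add_var(ids[i], gene, "missense", "pathogenic",
              if (stats::runif(1) < 0.5) "germline" else "somatic",
              paste0(gene, ":a1"))
    } else if (stats::runif(1) < 0.10) {
      add_var(ids[i], gene, "missense", "vus", "somatic",
              paste0(gene, ":v1"))
    }
    if (hrr_def[i]) {
      g <- sample(hrr_pool, 1L)
      add_var(ids[i], g, "nonsense", "pathogenic", "somatic",
              paste0(g, ":a1"))
      add_var(ids[i], g, "frameshift", "unknown", "somatic",
              paste0(g, ":a2"))
    }
  }
  variants <- do.call(rbind, var_rows)
  if (is.null(variants)) {
    variants <- data.frame(sample = character(), gene = character(),
                           effect = character(), clinical_class = character(),
                           origin = character(), allele_id = character())
  }
  gene_cnas <- do.call(rbind, cna_rows)
  if (is.null(gene_cnas)) {
    gene_cnas <- data.frame(sample = character(), gene = character(),
                            log2_ratio = numeric())
  }

  # concurrent-alteration matrix with planted enrichments --------------
  p_alt <- function(p_pos, p_neg) {
    as.integer(stats::runif(n) < ifelse(hrd_high, p_pos, p_neg))
  }
  alterations <- cbind(
    TP53_mutation = p_alt(0.983, 0.815),   # enriched in HRD-positive
    NCOR1_copy_loss = p_alt(0.35, 0.08),   # enriched in HRD-positive
    PTK2_amplification = p_alt(0.25, 0.0), # exclusive to HRD-positive
    KRAS_mutation = p_alt(0.05, 0.30),     # enriched in HRD-negative
    ARID1A_mutation = p_alt(0.08, 0.25),   # enriched in HRD-negative
    MUC16_mutation = p_alt(0.15, 0.15),    # neutral
    TTN_mutation = p_alt(0.20, 0.20))      # neutral
  rownames(alterations) <- ids

  cohort <- data.frame(
    sample_id = ids, hrd_total = total, hrd_positive = hrd_high,
    brca_status = status, cancer_type = "ovarian",
    pt_response = pt_response, pfs_days = pfs, pfs_event = event,
    stage = stage, residual = residual, hrr_deficient = hrr_def)

  list(cohort = cohort, profiles = profiles, alterations = alterations,
       variants = variants, gene_cnas = gene_cnas,
       truth = list(planted = planted, hrd_high = hrd_high,
                    threshold = params$threshold, hr_hrd = params$hr_hrd,
                    brca_status = status, hrr_deficient = hrr_def))
}
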