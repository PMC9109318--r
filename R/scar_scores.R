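#' Configuration for the genomic-scar scores
#'
#' Bundles the tunable parameters of the three scar components. The
#' defaults follow the published panel pipeline: LOH segments must be at
#' least 15 Mb, LST breakpoints join segments of at least 10 Mb separated
#' by at most 3 Mb, and short (< 3 Mb) slivers are smoothed away before
#' breakpoints are counted.
#'
#' @param loh_min_len_bp Minimum LOH segment length (bp); default 15 Mb.
#' @param lst_min_seg_bp Minimum length (bp) of both flanking segments of
#'   an LST breakpoint; default 10 Mb.
#' @param lst_max_gap_bp Maximum inter-segment gap (bp) for an LST
#'   breakpoint, and the gap bridged when equal states are merged;
#'   default 3 Mb.
#' @param lst_smooth_bp Segments shorter than this are iteratively removed
#'   (with re-merging of newly adjacent equal states) before breakpoints
#'   are counted; default 3 Mb; `0` disables smoothing.
#' @param lst_per_arm Count LST breakpoints within chromosome arms only;
#'   pairs straddling the centromere are never counted when `TRUE` (default).
#' @param tai_exclude_centromere_crossing Exclude centromere-spanning
#'   segments from the TAI count (default `TRUE`).
#' @param tai_min_len_bp Minimum TAI segment length (bp); default 0.
#' @param autosomes_only Restrict all three components to autosomes
#'   (default `TRUE`); allele-specific copy number on X/Y is sex-dependent.
#' @param whole_chrom_fraction A segment covering at least this fraction of
#'   its chromosome counts as whole-chromosome and is excluded from LOH;
#'   default 0.90.
#'
#' @return A list of class `scar_config`.
#' @export
scar_config <- function(loh_min_len_bp = 15e6,
                        lst_min_seg_bp = 10e6,
                        lst_max_gap_bp = 3e6,
                        lst_smooth_bp = 3e6,
                        lst_per_arm = TRUE,
                        tai_exclude_centromere_crossing = TRUE,
                        tai_min_len_bp = 0,
                        autosomes_only = TRUE,
                        whole_chrom_fraction = 0.90) {
  cfg <- list(loh_min_len_bp = loh_min_len_bp,
              lst_min_seg_bp = lst_min_seg_bp,
              lst_max_gap_bp = lst_max_gap_bp,
              lst_smooth_bp = lst_smooth_bp,
              lst_per_arm = isTRUE(lst_per_arm),
              tai_exclude_centromere_crossing =
                isTRUE(tai_exclude_centromere_crossing),
              tai_min_len_bp = tai_min_len_bp,
              autosomes_only = isTRUE(autosomes_only),
              whole_chrom_fraction = whole_chrom_fraction)
  lens <- c("loh_min_len_bp", "lst_min_seg_bp", "lst_max_gap_bp",
            "lst_smooth_bp", "tai_min_len_bp")
  if (any(unlist(cfg[lens]) < 0)) stop("scar_config lengths must be >= 0")
  if (!(cfg$whole_chrom_fraction > 0 && cfg$whole_chrom_fraction <= 1)) {
    stop("whole_chrom_fraction must be in (0, 1]")
  }
  structure(cfg, class = "scar_config")
}

# canonical scoring substrate: autosome filter + abutting equal-state merge
scoring_segments <- function(profile, config) {
  seg <- merge_equal_state_df(profile$segments, 0)
  if (config$autosomes_only) {
    autos <- profile$build$chrom[profile$build$is_autosome]
    seg <- seg[seg$chrom %in% autos, , drop = FALSE]
  }
  seg
}

#' LOH scar score
#'
#' Counts loss-of-heterozygosity segments: `mCN == 0`, `tCN > 0`, length at
#' least `loh_min_len_bp`, and not covering the whole chromosome (a segment
#' covering at least `whole_chrom_fraction` of the chromosome length is
#' treated as whole-chromosome and excluded).
#'
#' @param profile A [segment_profile].
#' @param config A [scar_config].
#' @return Non-negative integer count.
#' @export
loh_score <- function(profile, config = scar_config()) {
  seg <- scoring_segments(profile, config)
  if (nrow(seg) == 0L) return(0L)
  len <- seg$end - seg$start + 1
  chrom_len <- profile$build$length[match(seg$chrom, profile$build$chrom)]
  hit <- seg$mCN == 0 & seg$tCN > 0 & len >= config$loh_min_len_bp &
    len < config$whole_chrom_fraction * chrom_len
  sum(hit)
}

#' TAI scar score
#'
#' Counts telomeric allelic-imbalance segments: segments with
#' `mCN != tCN - mCN` that extend to a telomeric end of their chromosome.
#' A segment reaches the p (q) telomere iff it is the first (last) segment
#' of its chromosome in the profile — panel-covered territory never reaches
#' the telomere repeats themselves, so the terminal segment is the standard
#' proxy. Centromere-spanning segments are excluded by default.
#'
#' @inheritParams loh_score
#' @return Non-negative integer count.
#' @export
tai_score <- function(profile, config = scar_config()) {
  seg <- scoring_segments(profile, config)
  if (nrow(seg) == 0L) return(0L)
  n <- nrow(seg)
  new_chrom <- c(TRUE, seg$chrom[-1L] != seg$chrom[-n])
  terminal <- new_chrom | c(new_chrom[-1L], TRUE)
  len <- seg$end - seg$start + 1
  hit <- terminal & (seg$mCN != seg$tCN - seg$mCN) &
    len >= config$tai_min_len_bp
  if (config$tai_exclude_centromere_crossing && any(hit)) {
    hit[hit] <- arm_of(seg[hit, , drop = FALSE], profile$build) !=
      "spans_centromere"
  }
  sum(hit)
}

# iterative smoothing for LST: drop sub-threshold slivers, re-merge equal
# states that become adjacent, repeat to fixpoint
lst_smooth <- function(seg, config) {
  repeat {
    seg <- merge_equal_state_df(seg, config$lst_max_gap_bp)
    short <- (seg$end - seg$start + 1) < config$lst_smooth_bp
    if (!any(short)) return(seg)
    seg <- seg[!short, , drop = FALSE]
  }
}

#' LST scar score
#'
#' Counts large-scale state transitions: copy-number breakpoints between
#' adjacent segments that are both at least `lst_min_seg_bp` long, separated
#' by a gap of at most `lst_max_gap_bp`, and differ in `(tCN, mCN)`.
#' Equal-state neighbours are merged first (a transition between identical
#' states is not a break), segments shorter than `lst_smooth_bp` are
#' smoothed away, and with `lst_per_arm` breakpoints are only counted
#' between segments on the same chromosome arm.
#'
#' @inheritParams loh_score
#' @param build A [genome_build]; defaults to the profile's own build.
#' @return Non-negative integer count.
#' @export
lst_score <- function(profile, build = profile$build,
                      config = scar_config()) {
  seg <- profile$segments
  if (config$autosomes_only) {
    autos <- build$chrom[build$is_autosome]
    seg <- seg[seg$chrom %in% autos, , drop = FALSE]
  }
  if (nrow(seg) < 2L) return(0L)
  if (config$lst_smooth_bp > 0) {
    seg <- lst_smooth(seg, config)
  } else {
    seg <- merge_equal_state_df(seg, config$lst_max_gap_bp)
  }
  n <- nrow(seg)
  if (n < 2L) return(0L)
  a <- seq_len(n - 1L)
  b <- a + 1L
  len <- seg$end - seg$start + 1
  ok <- seg$chrom[a] == seg$chrom[b] &
    len[a] >= config$lst_min_seg_bp & len[b] >= config$lst_min_seg_bp &
    (seg$start[b] - seg$end[a] - 1) <= config$lst_max_gap_bp &
    (seg$tCN[a] != seg$tCN[b] | seg$mCN[a] != seg$mCN[b])
  if (config$lst_per_arm && any(ok)) {
    arm <- arm_of(seg, build)
    ok <- ok & arm[a] == arm[b] & arm[a] != "spans_centromere"
  }
  sum(ok)
}

#' HRD score
#'
#' The composite homologous-recombination-deficiency score: the sum of the
#' LOH, TAI and LST scar counts. A sample is HRD-positive when the total
#' reaches the threshold (inclusive); 38 is the calibrated panel default.
#'
#' @inheritParams lst_score
#' @param threshold HRD-positive threshold; `total >= threshold` is positive.
#' @return An object of class `hrd_result`: list with `sample_id`, `loh`,
#'   `tai`, `lst`, `total`, `hrd_positive`, `threshold`.
#' @examples
#' build <- hg19_build()
#' prof <- segment_profile("S1", data.frame(
#'   chrom = "chr2", start = c(1, 30e6 + 1), end = c(30e6, 243199373),
#'   tCN = c(1, 2), mCN = c(0, 1)), build)
#' hrd_score(prof)
#' @export
hrd_score <- function(profile, build = profile$build,
                      config = scar_config(), threshold = 38L) {
  loh <- loh_score(profile, config)
  tai <- tai_score(profile, config)
  lst <- lst_score(profile, build, config)
  total <- loh + tai + lst
  structure(list(sample_id = profile$sample_id, loh = loh, tai = tai,
                 lst = lst, total = total,
                 hrd_positive = total >= threshold,
                 threshold = as.integer(threshold)),
            class = "hrd_result")
}

#' @export
print.hrd_result <- function(x, ...) {
  cat(sprintf("HRD result '%s': LOH %d + TAI %d + LST %d = %d (%s at >= %d)\n",
              x$sample_id, x$loh, x$tai, x$lst, x$total,
              if (x$hrd_positive) "HRD-positive" else "HRD-negative",
              x$threshold))
  invisible(x)
}

#' Score a collection of profiles
#'
#' Applies [hrd_score()] to each profile and stacks the results into a
#' table, one row per sample.
#'
#' @param profiles List of [segment_profile] objects.
#' @inheritParams hrd_score
#' @return `data.frame` with columns `sample`, `loh`, `tai`, `lst`,
#'   `hrd_score`, `hrd_status` (`"positive"`/`"negative"`).
#' @export
hrd_score_table <- function(profiles, config = scar_config(),
                            threshold = 38L) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    r <- hrd_score(p, p$build, config, threshold)
    data.frame(sample = r$sample_id, loh = r$loh, tai = r$tai, lst = r$lst,
               hrd_score = r$total,
               hrd_status = if (r$hrd_positive) "positive" else "negative")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(), loh = integer(),
                      tai = integer(), lst = integer(),
                      hrd_score = integer(), hrd_status = character())
  }
  rownames(out) <- NULL
  out
}
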