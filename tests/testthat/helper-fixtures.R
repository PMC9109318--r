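# Shared fixtures: a small toy genome, a random-profile generator, and
# independent brute-force oracles for the three scar scores. The oracles are
# written as literal per-segment loops so they share no code with the
# package implementation.

toy_build <- function() {
  genome_build("toy", data.frame(
    chrom = c("chr1", "chr2", "chr3", "chrX"),
    length = c(200e6, 150e6, 100e6, 120e6),
    cen_start = c(100e6, 60e6, 40e6, 50e6),
    cen_end = c(105e6, 65e6, 45e6, 55e6)))
}

# one balanced 2/1 segment per chromosome
balanced_profile <- function(build, sample_id = "BAL") {
  segment_profile(sample_id, data.frame(
    chrom = build$chrom, start = 1, end = build$length,
    tCN = 2, mCN = 1), build)
}

# random valid profile: per chromosome a random partition into segments
# with random states (adjacent states always differ) and random gaps
random_profile <- function(build, sample_id = "RND") {
  states <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(3, 0), c(3, 1),
                  c(4, 1), c(4, 2), c(5, 2))
  rows <- lapply(seq_len(nrow(build)), function(ci) {
    L <- build$length[ci]
    k <- sample(1:8, 1)
    cuts <- sort(sample.int(L - 1, k - 1))
    start <- c(1, cuts + 1)
    end <- c(cuts, L)
    # random right-shrink opens gaps between segments
    shrink <- floor(runif(k, 0, 0.2) * (end - start))
    end <- end - shrink
    si <- integer(k)
    si[1] <- sample.int(nrow(states), 1)
    for (j in seq_len(k - 1)) {
      si[j + 1] <- sample(setdiff(seq_len(nrow(states)), si[j]), 1)
    }
    data.frame(chrom = build$chrom[ci], start = start, end = end,
               tCN = states[si, 1], mCN = states[si, 2])
  })
  segment_profile(sample_id, do.call(rbind, rows), build)
}

chrom_info <- function(build, chrom) {
  build[match(chrom, build$chrom), ]
}

spans_cen <- function(build, chrom, start, end) {
  info <- chrom_info(build, chrom)
  !(end <= info$cen_start || start >= info$cen_end)
}

# ---- brute-force oracles -------------------------------------------------

oracle_loh <- function(profile, min_len = 15e6, whole_frac = 0.90) {
  build <- profile$build
  seg <- profile$segments
  count <- 0L
  for (i in seq_len(nrow(seg))) {
    info <- chrom_info(build, seg$chrom[i])
    if (!info$is_autosome) next
    len <- seg$end[i] - seg$start[i] + 1
    if (seg$mCN[i] == 0 && seg$tCN[i] > 0 && len >= min_len &&
        len < whole_frac * info$length) {
      count <- count + 1L
    }
  }
  count
}

oracle_tai <- function(profile, exclude_cen = TRUE, min_len = 0) {
  build <- profile$build
  seg <- profile$segments
  count <- 0L
  for (chrom in unique(seg$chrom)) {
    info <- chrom_info(build, chrom)
    if (!info$is_autosome) next
    sub <- seg[seg$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    for (i in unique(c(1L, nrow(sub)))) {
      imbalanced <- sub$mCN[i] != sub$tCN[i] - sub$mCN[i]
      long_enough <- (sub$end[i] - sub$start[i] + 1) >= min_len
      crosses <- spans_cen(build, chrom, sub$start[i], sub$end[i])
      if (imbalanced && long_enough && !(exclude_cen && crosses)) {
        count <- count + 1L
      }
    }
  }
  count
}

# naive merge/smooth/count re-implementation with explicit loops
oracle_lst <- function(profile, min_seg = 10e6, max_gap = 3e6,
                       smooth = 3e6, per_arm = TRUE) {
  build <- profile$build
  seg <- profile$segments
  seg <- seg[build$is_autosome[match(seg$chrom, build$chrom)], , drop = FALSE]
  seg <- seg[order(match(seg$chrom, build$chrom), seg$start), , drop = FALSE]
  merge_once <- function(s) {
    i <- 1L
    while (i < nrow(s)) {
      gap <- s$start[i + 1] - s$end[i] - 1
      if (s$chrom[i] == s$chrom[i + 1] && s$tCN[i] == s$tCN[i + 1] &&
          s$mCN[i] == s$mCN[i + 1] && gap <= max_gap) {
        s$end[i] <- s$end[i + 1]
        s <- s[-(i + 1), , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    s
  }
  if (nrow(seg) >= 2L) {
    repeat {
      seg <- merge_once(seg)
      if (smooth <= 0) break
      short <- which(seg$end - seg$start + 1 < smooth)
      if (length(short) == 0L) break
      seg <- seg[-short, , drop = FALSE]
      if (nrow(seg) == 0L) break
    }
  }
  arm_name <- function(i) {
    info <- chrom_info(build, seg$chrom[i])
    if (seg$end[i] <= info$cen_start) "p"
    else if (seg$start[i] >= info$cen_end) "q"
    else "cen"
  }
  count <- 0L
  for (i in seq_len(max(0L, nrow(seg) - 1L))) {
    j <- i + 1L
    if (seg$chrom[i] != seg$chrom[j]) next
    if (seg$end[i] - seg$start[i] + 1 < min_seg) next
    if (seg$end[j] - seg$start[j] + 1 < min_seg) next
    if (seg$start[j] - seg$end[i] - 1 > max_gap) next
    if (seg$tCN[i] == seg$tCN[j] && seg$mCN[i] == seg$mCN[j]) next
    if (per_arm) {
      ai <- arm_name(i); aj <- arm_name(j)
      if (ai == "cen" || aj == "cen" || ai != aj) next
    }
    count <- count + 1L
  }
  count
}

# two-sided Fisher p by direct hypergeometric enumeration:
# sum of P(X = x) over all x with P(X = x) <= P(observed) (+ tolerance,
# matching the conventional handling of floating-point ties)
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # margin: row 1
  n2 <- c_ + d        # margin: row 2
  k <- a + c_         # margin: column 1
  x <- max(0L, k - n2):min(k, m)
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
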