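make_profile <- function(build, ...) {
  segment_profile("T1", data.frame(...), build)
}

test_that("LOH counts long interstitial mCN=0 segments only", {
  build <- toy_build()
  expect_equal(loh_score(balanced_profile(build)), 0L)

  # 30 Mb mCN=0 segment qualifies: long enough, tCN>0, not whole-chromosome
  p <- make_profile(build,
                    chrom = "chr2", start = c(1, 30e6 + 1),
                    end = c(30e6, 150e6), tCN = c(1, 2), mCN = c(0, 1))
  expect_equal(loh_score(p), 1L)

  # each exclusion clause on its own
  whole <- make_profile(build, chrom = "chr2", start = 1, end = 150e6,
                        tCN = 1, mCN = 0)
  expect_equal(loh_score(whole), 0L)
  zero_tcn <- make_profile(build, chrom = "chr2", start = 1, end = 30e6,
                           tCN = 0, mCN = 0)
  expect_equal(loh_score(zero_tcn), 0L)
  short <- make_profile(build, chrom = "chr2", start = 1, end = 14e6,
                        tCN = 1, mCN = 0)
  expect_equal(loh_score(short), 0L)

  # whole-chromosome is a fraction, not literal full coverage
  almost <- make_profile(build, chrom = "chr2", start = 1,
                         end = ceiling(0.95 * 150e6), tCN = 1, mCN = 0)
  expect_equal(loh_score(almost), 0L)
  below <- make_profile(build, chrom = "chr2", start = 1,
                        end = floor(0.85 * 150e6), tCN = 1, mCN = 0)
  expect_equal(loh_score(below), 1L)

  # sex chromosomes excluded by default, included on request
  x_loh <- make_profile(build, chrom = "chrX", start = 1, end = 30e6,
                        tCN = 1, mCN = 0)
  expect_equal(loh_score(x_loh), 0L)
  expect_equal(loh_score(x_loh, scar_config(autosomes_only = FALSE)), 1L)
})

test_that("TAI counts imbalanced telomere-reaching segments", {
  build <- toy_build()
  bal <- balanced_profile(build)$segments
  # replace the terminal chr3 q segment with an imbalanced one
  seg <- rbind(bal[bal$chrom != "chr3", ],
               data.frame(chrom = "chr3", start = c(1, 80e6 + 1),
                          end = c(80e6, 100e6), tCN = c(2, 3), mCN = c(1, 1)))
  p <- segment_profile("T1", seg, build)
  expect_equal(tai_score(p), 1L)

  # interior imbalance flanked by balanced terminal segments: not telomeric
  p_int <- make_profile(build,
                        chrom = "chr3", start = c(1, 20e6 + 1, 60e6 + 1),
                        end = c(20e6, 60e6, 100e6),
                        tCN = c(2, 3, 2), mCN = c(1, 1, 1))
  expect_equal(tai_score(p_int), 0L)

  # terminal but balanced: no imbalance
  p_bal <- make_profile(build, chrom = "chr3", start = c(1, 50e6 + 1),
                        end = c(50e6, 100e6), tCN = c(2, 2), mCN = c(1, 1))
  expect_equal(tai_score(p_bal), 0L)

  # centromere-spanning terminal segment: excluded by default, counted
  # when the exclusion is disabled
  p_cen <- make_profile(build, chrom = "chr3", start = c(1, 70e6 + 1),
                        end = c(70e6, 100e6), tCN = c(3, 2), mCN = c(1, 1))
  expect_equal(tai_score(p_cen), 0L)
  expect_equal(
    tai_score(p_cen, scar_config(tai_exclude_centromere_crossing = FALSE)),
    1L)

  # minimum-length option
  expect_equal(tai_score(p, scar_config(tai_min_len_bp = 30e6)), 0L)
})

test_that("LST counts breaks between large close segments", {
  build <- toy_build()
  # two 12 Mb segments, different states, abutting, on chr1 p: one break
  p <- make_profile(build, chrom = "chr1", start = c(1, 12e6 + 1),
                    end = c(12e6, 24e6), tCN = c(2, 3), mCN = c(1, 1))
  expect_equal(lst_score(p), 1L)

  # short flank fails; wide gap fails
  p_short <- make_profile(build, chrom = "chr1", start = c(1, 12e6 + 1),
                          end = c(12e6, 20e6), tCN = c(2, 3), mCN = c(1, 1))
  expect_equal(lst_score(p_short), 0L)
  p_gap <- make_profile(build, chrom = "chr1", start = c(1, 16e6 + 1),
                        end = c(12e6, 28e6), tCN = c(2, 3), mCN = c(1, 1))
  expect_equal(lst_score(p_gap), 0L)

  # k alternating-state 11 Mb segments in one arm: k - 1 breaks
  k <- 7
  starts <- 1 + (0:(k - 1)) * 11e6
  p_run <- make_profile(build, chrom = "chr1", start = starts,
                        end = starts + 11e6 - 1,
                        tCN = rep(c(2, 3), length.out = k),
                        mCN = rep(1, k))
  expect_equal(lst_score(p_run), k - 1L)

  # equal-state adjacency is not a break
  p_same <- make_profile(build, chrom = "chr1", start = c(1, 12e6 + 1),
                         end = c(12e6, 24e6), tCN = c(2, 2), mCN = c(1, 1))
  expect_equal(lst_score(p_same), 0L)

  # per-arm: a pair straddling the centromere is not counted by default
  p_cross <- make_profile(build, chrom = "chr1", start = c(80e6, 103e6),
                          end = c(102e6, 120e6), tCN = c(2, 3), mCN = c(1, 1))
  expect_equal(lst_score(p_cross), 0L)
  expect_equal(lst_score(p_cross, config = scar_config(lst_per_arm = FALSE)),
               1L)
})

test_that("LST smoothing removes slivers before counting breaks", {
  build <- toy_build()
  # 2 Mb sliver between equal 15 Mb flanks: flanks merge, no break
  p_same <- make_profile(build, chrom = "chr1",
                         start = c(1, 15e6 + 1, 17e6 + 1),
                         end = c(15e6, 17e6, 32e6),
                         tCN = c(2, 1, 2), mCN = c(1, 0, 1))
  expect_equal(lst_score(p_same), 0L)
  expect_equal(lst_score(p_same, config = scar_config(lst_smooth_bp = 0)), 0L)

  # 2 Mb third-state sliver between distinct >= 10 Mb states: the sliver
  # hides the break without smoothing and exposes it with smoothing
  p_diff <- make_profile(build, chrom = "chr1",
                         start = c(1, 15e6 + 1, 17e6 + 1),
                         end = c(15e6, 17e6, 32e6),
                         tCN = c(2, 1, 3), mCN = c(1, 0, 1))
  expect_equal(lst_score(p_diff), 1L)
  expect_equal(lst_score(p_diff, config = scar_config(lst_smooth_bp = 0)), 0L)
})

test_that("hrd_score composes the three components with an inclusive threshold", {
  build <- toy_build()
  empty <- segment_profile("E", data.frame(chrom = character(),
                                           start = numeric(),
                                           end = numeric(), tCN = numeric(),
                                           mCN = numeric()), build)
  r0 <- hrd_score(empty)
  expect_equal(c(r0$loh, r0$tai, r0$lst, r0$total), c(0L, 0L, 0L, 0L))
  expect_false(r0$hrd_positive)

  withr::local_seed(7)
  for (i in 1:10) {
    p <- random_profile(build)
    r <- hrd_score(p)
    expect_identical(r$total, loh_score(p) + tai_score(p) + lst_score(p))
    expect_identical(r$hrd_positive, r$total >= r$threshold)
  }
  # threshold comparison is >= (this profile scores LOH 1 + TAI 1 = 2)
  p1 <- make_profile(build, chrom = "chr2", start = c(1, 30e6 + 1),
                     end = c(30e6, 150e6), tCN = c(1, 2), mCN = c(0, 1))
  expect_equal(hrd_score(p1)$total, 2L)
  expect_true(hrd_score(p1, threshold = 2L)$hrd_positive)
  expect_false(hrd_score(p1, threshold = 3L)$hrd_positive)
})

test_that("scores are invariant to row order and to equal-state splits", {
  build <- toy_build()
  withr::local_seed(11)
  for (i in 1:25) {
    p <- random_profile(build)
    scores <- c(loh_score(p), tai_score(p), lst_score(p))

    # split a random segment into two abutting equal-state pieces
    seg <- p$segments
    long <- which(seg$end - seg$start > 1)
    j <- long[sample.int(length(long), 1)]
    mid <- floor((seg$start[j] + seg$end[j]) / 2)
    split_seg <- rbind(
      seg[-j, ],
      data.frame(chrom = seg$chrom[j], start = c(seg$start[j], mid + 1),
                 end = c(mid, seg$end[j]), tCN = seg$tCN[j],
                 mCN = seg$mCN[j]))
    # shuffled rows exercise order invariance at the same time
    p2 <- segment_profile(p$sample_id,
                          split_seg[sample.int(nrow(split_seg)), ], build)
    expect_equal(c(loh_score(p2), tai_score(p2), lst_score(p2)), scores)
  }
})

test_that("scar components match brute-force oracles on random profiles", {
  build <- toy_build()
  withr::local_seed(13)
  cfg <- scar_config()
  for (i in 1:60) {
    p <- random_profile(build)
    expect_identical(loh_score(p, cfg), oracle_loh(p))
    expect_identical(tai_score(p, cfg), oracle_tai(p))
    expect_identical(lst_score(p, config = cfg), oracle_lst(p))
  }
})

test_that("hrd_score_table stacks per-sample results", {
  build <- toy_build()
  tab <- hrd_score_table(list(balanced_profile(build, "A"),
                              balanced_profile(build, "B")))
  expect_equal(tab$sample, c("A", "B"))
  expect_equal(tab$hrd_score, c(0L, 0L))
  expect_equal(tab$hrd_status, c("negative", "negative"))
  empty <- hrd_score_table(list())
  expect_equal(nrow(empty), 0L)
})
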