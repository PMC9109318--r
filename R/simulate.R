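#' Parameters for simulating one segment profile
#'
#' Planted scar counts and a background-noise rate for
#' [simulate_profile()]. Noise events are sub-threshold by construction
#' (short LOH, interior allelic imbalance, short-flank transitions), so
#' they never alter any scar score under the default [scar_config()].
#'
#' @param n_loh_events Planted interstitial LOH segments (each 15-20 Mb,
#'   state 1/0).
#' @param n_tai_events Planted terminal allelic-imbalance segments (each
#'   5-14 Mb, state 3/1 or 2/0, never centromere-spanning).
#' @param n_lst_breaks Planted copy-number breakpoints between adjacent
#'   10 Mb segments within single arms.
#' @param background_noise_rate Sub-threshold noise events per Gb of
#'   autosomal genome (Poisson).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_loh_events = 0L, n_tai_events = 0L,
                       n_lst_breaks = 0L, background_noise_rate = 0,
                       seed = NULL) {
  stopifnot(n_loh_events >= 0, n_tai_events >= 0, n_lst_breaks >= 0,
            background_noise_rate >= 0)
  structure(list(n_loh_events = as.integer(n_loh_events),
                 n_tai_events = as.integer(n_tai_events),
                 n_lst_breaks = as.integer(n_lst_breaks),
                 background_noise_rate = background_noise_rate,
                 seed = seed),
            class = "sim_params")
}

# geometry constants for event placement (bp)
.sim_gap <- 3.5e6      # gap isolating every planted event (> lst_max_gap)
.sim_tel_reserve <- 18e6  # telomeric territory reserved for TAI events
.sim_cen_buffer <- 1e6
.sim_lst_seg <- 10e6   # length of each segment in a planted LST run

# interior placement windows, one per arm, for one build
sim_arm_windows <- function(build) {
  autos <- build[build$is_autosome, , drop = FALSE]
  p <- data.frame(chrom = autos$chrom, arm = "p",
                  lo = 1 + .sim_tel_reserve,
                  hi = autos$cen_start - 1 - .sim_cen_buffer)
  q <- data.frame(chrom = autos$chrom, arm = "q",
                  lo = autos$cen_end + 1 + .sim_cen_buffer,
                  hi = autos$length - .sim_tel_reserve)
  out <- rbind(p, q)
  out[out$hi - out$lo + 1 > 0, , drop = FALSE]
}

# first-fit placement of interior event contents (widths in bp) into arm
# windows; returns data.frame(chrom, start, end) of content intervals
sim_place_interior <- function(widths, windows, label = "event") {
  if (length(widths) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  # contents only need > lst_max_gap separation from each other; the
  # profile assembly pads every event with a .sim_gap uncovered flank
  # against the background, so consecutive contents in an arm are placed
  # one .sim_gap apart
  cursor <- windows$lo
  out <- vector("list", length(widths))
  ord <- order(widths, decreasing = TRUE)  # pack large events first
  for (k in seq_along(ord)) {
    i <- ord[k]
    w <- widths[i]
    fits <- which(cursor + w - 1 <= windows$hi)
    if (length(fits) == 0L) {
      stop("placement infeasible: autosomal arm territory exhausted while ",
           "placing ", label, " of ", round(w / 1e6, 1), " Mb (",
           length(widths) - k + 1L, " event(s) unplaced)")
    }
    # best-fit decreasing: tightest arm that still takes the event
    a <- fits[which.min(windows$hi[fits] - cursor[fits])]
    out[[i]] <- data.frame(chrom = windows$chrom[a], start = cursor[a],
                           end = cursor[a] + w - 1)
    cursor[a] <- cursor[a] + w + .sim_gap + stats::runif(1, 1, 0.5e6)
  }
  list(placed = do.call(rbind, out), cursor = cursor)
}

#' Simulate one allele-specific segment profile with planted scars
#'
#' Starts from a balanced diploid genome (one 2/1 segment per autosome,
#' plus 2/1 sex chromosomes) and plants exactly the requested numbers of
#' LOH segments, TAI segments and LST breakpoints, placed non-overlapping
#' and isolated by >3 Mb uncovered gaps so the events cannot interact:
#' with zero noise the scored components equal the planted counts exactly.
#' Optional noise adds sub-threshold segments that leave all scores
#' unchanged.
#'
#' @param params A [sim_params].
#' @param build A [genome_build]; default [hg19_build()].
#' @return List with `profile` (a [segment_profile]) and `truth`
#'   (`loh`, `tai`, `lst` planted counts).
#' @export
simulate_profile <- function(params, build = hg19_build()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  autos <- build[build$is_autosome, , drop = FALSE]
  windows <- sim_arm_windows(build)
  events <- list()  # list of data.frame(chrom, start, end, tCN, mCN)

  # --- TAI: terminal imbalance segments at sampled chromosome ends ------
  ends <- data.frame(chrom = rep(autos$chrom, 2L),
                     side = rep(c("p", "q"), each = nrow(autos)),
                     cen_start = rep(autos$cen_start, 2L),
                     length = rep(autos$length, 2L))
  if (params$n_tai_events > nrow(ends)) {
    stop("placement infeasible: ", params$n_tai_events,
         " TAI events exceed the ", nrow(ends), " autosomal chromosome ends")
  }
  if (params$n_tai_events > 0L) {
    pick <- ends[sample.int(nrow(ends), params$n_tai_events), , drop = FALSE]
    pick$cen_end <- autos$cen_end[match(pick$chrom, autos$chrom)]
    for (i in seq_len(nrow(pick))) {
      # stay on the arm: a centromere-spanning segment would not count
      arm_max <- if (pick$side[i] == "p") pick$cen_start[i] else
        pick$length[i] - pick$cen_end[i]
      len <- stats::runif(1, 5e6, min(14e6, arm_max))
      state <- if (stats::runif(1) < 0.5) c(3, 1) else c(2, 0)
      if (pick$side[i] == "p") {
        ev <- data.frame(chrom = pick$chrom[i], start = 1,
                         end = floor(len))
      } else {
        ev <- data.frame(chrom = pick$chrom[i],
                         start = pick$length[i] - floor(len) + 1,
                         end = pick$length[i])
      }
      ev$tCN <- state[1]; ev$mCN <- state[2]
      events[[length(events) + 1L]] <- ev
    }
  }

  # --- interior events: LOH segments and LST runs -----------------------
  loh_len <- if (params$n_loh_events > 0L) {
    floor(stats::runif(params$n_loh_events, 15e6, 20e6))
  } else numeric(0)
  # group planted breaks into alternating-state runs of <= 8 breaks each
  lst_runs <- integer(0)
  left <- params$n_lst_breaks
  while (left > 0L) {
    k <- min(left, 8L)
    lst_runs <- c(lst_runs, k)
    left <- left - k
  }
  run_widths <- (lst_runs + 1L) * .sim_lst_seg
  # noise widths drawn now so placement covers them too
  n_noise <- if (params$background_noise_rate > 0) {
    gb <- sum(autos$length) / 1e9
    stats::rpois(1L, params$background_noise_rate * gb)
  } else 0L
  noise_type <- if (n_noise > 0L) {
    sample(c("short_loh", "interior_ai", "short_flank_break"), n_noise,
           replace = TRUE)
  } else character(0)
  noise_widths <- vapply(noise_type, function(tp) {
    if (tp == "short_flank_break") 2 * 8e6 else floor(stats::runif(1, 3e6, 10e6))
  }, numeric(1))

  widths <- c(loh_len, run_widths, noise_widths)
  labels <- rep(c("LOH segment", "LST run", "noise"),
                c(length(loh_len), length(run_widths), length(noise_widths)))
  placed <- sim_place_interior(widths, windows,
                               label = "interior scar/noise event")$placed
  idx <- 0L
  for (i in seq_along(loh_len)) {
    idx <- idx + 1L
    events[[length(events) + 1L]] <- data.frame(
      chrom = placed$chrom[idx], start = placed$start[idx],
      end = placed$end[idx], tCN = 1, mCN = 0)
  }
  for (k in lst_runs) {
    idx <- idx + 1L
    starts <- placed$start[idx] + (0:k) * .sim_lst_seg
    states <- if (stats::runif(1) < 0.5) {
      rbind(c(2, 1), c(3, 1))
    } else {
      rbind(c(3, 1), c(2, 1))
    }
    events[[length(events) + 1L]] <- data.frame(
      chrom = placed$chrom[idx], start = starts,
      end = starts + .sim_lst_seg - 1,
      tCN = states[(0:k) %% 2 + 1, 1], mCN = states[(0:k) %% 2 + 1, 2])
  }
  for (i in seq_along(noise_type)) {
    idx <- idx + 1L
    tp <- noise_type[i]
    if (tp == "short_loh") {
      ev <- data.frame(chrom = placed$chrom[idx], start = placed$start[idx],
                       end = placed$end[idx], tCN = 1, mCN = 0)
    } else if (tp == "interior_ai") {
      ev <- data.frame(chrom = placed$chrom[idx], start = placed$start[idx],
                       end = placed$end[idx], tCN = 3, mCN = 1)
    } else {
      s <- placed$start[idx]
      ev <- data.frame(chrom = placed$chrom[idx],
                       start = c(s, s + 8e6),
                       end = c(s + 8e6 - 1, s + 16e6 - 1),
                       tCN = c(3, 4), mCN = c(1, 1))
    }
    events[[length(events) + 1L]] <- ev
  }

  # --- assemble: background 2/1 fills the complement, minus gaps --------
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               tCN = numeric(), mCN = numeric())
  seg_list <- lapply(seq_len(nrow(build)), function(ci) {
    chrom <- build$chrom[ci]
    len <- build$length[ci]
    e <- ev[ev$chrom == chrom, , drop = FALSE]
    if (!build$is_autosome[ci]) e <- e[0, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    # blocked intervals = events padded with the isolation gap
    blk_start <- pmax(1, e$start - .sim_gap)
    blk_end <- pmin(len, e$end + .sim_gap)
    bg_start <- c(1, blk_end + 1)
    bg_end <- c(blk_start - 1, len)
    keep <- which(bg_start <= bg_end)
    bg <- data.frame(chrom = rep(chrom, length(keep)),
                     start = bg_start[keep], end = bg_end[keep],
                     tCN = rep(2, length(keep)), mCN = rep(1, length(keep)))
    rbind(e, bg)
  })
  seg <- do.call(rbind, seg_list)
  profile <- segment_profile(paste0("SIM_", paste0(
    sample(c(LETTERS, 0:9), 8, replace = TRUE), collapse = "")),
    seg, build)
  list(profile = profile,
       truth = list(loh = params$n_loh_events, tai = params$n_tai_events,
                    lst = params$n_lst_breaks))
}
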