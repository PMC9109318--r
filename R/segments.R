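#' Construct an allele-specific segment profile
#'
#' A segment profile is one sample's genome-wide allele-specific copy-number
#' state: per segment the total copy number (tCN) and the minor-allele copy
#' number (mCN), on 1-based inclusive coordinates. It is the substrate for
#' all scar scores. Segments are sorted by chromosome and start, and the
#' profile is validated against its genome build.
#'
#' @param sample_id Sample identifier.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `tCN`, `mCN` (1-based inclusive coordinates).
#' @param build A [genome_build] the coordinates refer to.
#'
#' @return An object of class `segment_profile`: a list with elements
#'   `sample_id`, `segments` (canonically sorted) and `build`.
#'
#' @details Invariants enforced: `start <= end`; `0 <= mCN <= tCN - mCN`
#'   (the minor allele is the smaller copy count); every chromosome exists
#'   in the build with `end` within the chromosome length; segments on one
#'   chromosome are pairwise non-overlapping. Gaps between segments are
#'   allowed: panel-derived profiles cover only assayed territory.
#' @export
segment_profile <- function(sample_id, segments, build) {
  stopifnot(length(sample_id) == 1L, inherits(build, "genome_build"))
  seg <- as.data.frame(segments)
  req <- c("chrom", "start", "end", "tCN", "mCN")
  missing_cols <- setdiff(req, names(seg))
  if (length(missing_cols)) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  seg <- seg[req]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "tCN", "mCN")) seg[[col]] <- as.numeric(seg[[col]])
  if (anyNA(seg)) stop("segment table contains missing values")
  validate_segments(seg, build, sample_id = sample_id)
  ord <- order(match(seg$chrom, build$chrom), seg$start)
  seg <- seg[ord, , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(sample_id = as.character(sample_id), segments = seg,
                 build = build),
            class = "segment_profile")
}

validate_segments <- function(seg, build, sample_id = "?") {
  where <- function(i) {
    paste0("sample ", sample_id, ", row ", paste(i, collapse = ","))
  }
  bad <- which(seg$start > seg$end | seg$start < 1)
  if (length(bad)) {
    stop("invalid segment coordinates (need 1 <= start <= end) at ",
         where(bad))
  }
  bad <- which(seg$tCN < 0 | seg$mCN < 0 |
                 seg$tCN != round(seg$tCN) | seg$mCN != round(seg$mCN))
  if (length(bad)) {
    stop("tCN/mCN must be non-negative integers at ", where(bad))
  }
  bad <- which(seg$mCN > seg$tCN - seg$mCN)
  if (length(bad)) {
    stop("mCN exceeds tCN - mCN (minor allele must be the smaller copy ",
         "count) at ", where(bad))
  }
  idx <- match(seg$chrom, build$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s) not in build '", attr(build, "name"), "': ",
         paste(unique(seg$chrom[is.na(idx)]), collapse = ", "),
         " (", where(which(is.na(idx))), ")")
  }
  bad <- which(seg$end > build$length[idx])
  if (length(bad)) {
    stop("segment end exceeds chromosome length at ", where(bad))
  }
  ord <- order(idx, seg$start)
  same_chrom <- diff(idx[ord]) == 0
  overlap <- same_chrom & (seg$start[ord][-1] <= seg$end[ord][-length(ord)])
  if (any(overlap)) {
    i <- which(overlap)[1L]
    stop("overlapping segments on ", seg$chrom[ord][i], " at rows ",
         ord[i], " and ", ord[i + 1L], " (sample ", sample_id, ")")
  }
  invisible(TRUE)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("Segment profile '", x$sample_id, "' (build ",
      attr(x$build, "name"), "): ", nrow(x$segments), " segments on ",
      length(unique(x$segments$chrom)), " chromosomes\n", sep = "")
  print.data.frame(utils::head(x$segments, 8L))
  if (nrow(x$segments) > 8L) cat("... and", nrow(x$segments) - 8L, "more\n")
  invisible(x)
}

#' @method all.equal segment_profile
#' @export
all.equal.segment_profile <- function(target, current, ...) {
  all.equal(list(target$sample_id, target$segments),
            list(current$sample_id, current$segments), ...)
}

#' Read allele-specific segment tables
#'
#' Reads a SEG-like tab-separated table with one row per segment and returns
#' one [segment_profile] per sample. Column names are remappable through
#' `dialect`, and 0-based half-open input coordinates are converted to the
#' internal 1-based inclusive convention.
#'
#' @param path Path to a TSV file (or a connection). Lines starting with
#'   `#` are treated as comments.
#' @param build A [genome_build].
#' @param dialect Named character vector mapping the canonical names
#'   `sample`, `chrom`, `start`, `end`, `tCN`, `mCN` to the column names
#'   used in the file. Defaults to the identity mapping.
#' @param zero_based Logical; `TRUE` when the input uses 0-based half-open
#'   coordinates (starts are shifted by +1).
#'
#' @return Named list of [segment_profile] objects, one per sample, in
#'   order of first appearance.
#' @seealso [write_segment_table()]
#' @export
read_segment_table <- function(path, build, dialect = NULL,
                               zero_based = FALSE) {
  canonical <- c("sample", "chrom", "start", "end", "tCN", "mCN")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  missing_cols <- setdiff(unname(map), names(tab))
  if (length(missing_cols)) {
    stop("segment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- stats::setNames(tab[unname(map)], canonical)
  if (zero_based) tab$start <- tab$start + 1
  samples <- unique(tab$sample)
  profiles <- lapply(samples, function(s) {
    segment_profile(s, tab[tab$sample == s, canonical[-1L]], build)
  })
  stats::setNames(profiles, samples)
}

#' Write segment profiles as a TSV table
#'
#' Inverse of [read_segment_table()]: the written table round-trips to an
#' equal collection of profiles.
#'
#' @param profiles A [segment_profile] or list of them.
#' @param path Output file path (or connection).
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    cbind(sample = p$sample_id, p$segments)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      tCN = numeric(), mCN = numeric())
  }
  utils::write.table(format(tab, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge adjacent equal-state segments
#'
#' Fuses same-chromosome neighbours with identical `(tCN, mCN)` whose
#' inter-segment gap is at most `max_gap_bp`. This canonicalisation
#' guarantees that transitions between adjacent segments are true
#' copy-number changes, so splitting a segment into abutting equal-state
#' pieces never alters any scar score. Idempotent.
#'
#' @param profile A [segment_profile].
#' @param max_gap_bp Maximum gap (bp) bridged by a merge; `0` fuses only
#'   abutting segments.
#' @return A merged [segment_profile].
#' @export
merge_equal_state <- function(profile, max_gap_bp = 0) {
  stopifnot(inherits(profile, "segment_profile"), max_gap_bp >= 0)
  seg <- profile$segments
  if (nrow(seg) >= 2L) {
    seg <- merge_equal_state_df(seg, max_gap_bp)
    profile$segments <- seg
  }
  profile
}

# core merge on a sorted segments data.frame (no revalidation)
merge_equal_state_df <- function(seg, max_gap_bp) {
  n <- nrow(seg)
  if (n < 2L) return(seg)
  same <- seg$chrom[-1L] == seg$chrom[-n] &
    seg$tCN[-1L] == seg$tCN[-n] & seg$mCN[-1L] == seg$mCN[-n] &
    (seg$start[-1L] - seg$end[-n] - 1) <= max_gap_bp
  grp <- cumsum(c(TRUE, !same))
  if (max(grp) == n) return(seg)
  first <- !duplicated(grp)
  last <- c(grp[-1L] != grp[-n], TRUE)
  out <- data.frame(
    chrom = seg$chrom[first],
    start = seg$start[first],
    end   = seg$end[last],
    tCN   = seg$tCN[first],
    mCN   = seg$mCN[first]
  )
  rownames(out) <- NULL
  out
}
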