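#' Construct a genome build
#'
#' A genome build holds, for every chromosome, its length and the centromere
#' interval, which together define the p and q arms and the telomeric ends
#' needed by the TAI and LST scar scores.
#'
#' @param name Build identifier, e.g. `"hg19"`.
#' @param chromosomes A `data.frame` with columns `chrom`, `length`,
#'   `cen_start`, `cen_end` and optionally `is_autosome`. When
#'   `is_autosome` is absent it is inferred from the chromosome name
#'   (anything matching X, Y or M/MT, with or without a `chr` prefix, is
#'   treated as non-autosomal).
#'
#' @return An object of class `genome_build`: the validated chromosome
#'   table with the build name attached as an attribute.
#'
#' @examples
#' toy <- genome_build("toy", data.frame(
#'   chrom = c("chr1", "chr2"), length = c(200e6, 150e6),
#'   cen_start = c(90e6, 60e6), cen_end = c(95e6, 65e6)))
#' toy
#' @export
genome_build <- function(name, chromosomes) {
  stopifnot(is.character(name), length(name) == 1L)
  req <- c("chrom", "length", "cen_start", "cen_end")
  missing_cols <- setdiff(req, names(chromosomes))
  if (length(missing_cols)) {
    stop("genome build table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  chr <- as.data.frame(chromosomes)
  chr$chrom <- as.character(chr$chrom)
  for (col in c("length", "cen_start", "cen_end")) {
    chr[[col]] <- as.numeric(chr[[col]])
  }
  if (anyDuplicated(chr$chrom)) {
    stop("duplicate chromosome names in genome build: ",
         paste(unique(chr$chrom[duplicated(chr$chrom)]), collapse = ", "))
  }
  if (any(chr$length <= 0)) stop("chromosome lengths must be positive")
  bad <- !(chr$cen_start > 0 & chr$cen_start < chr$cen_end &
             chr$cen_end < chr$length)
  if (any(bad)) {
    stop("invalid centromere interval (need 0 < cen_start < cen_end < length) ",
         "for: ", paste(chr$chrom[bad], collapse = ", "))
  }
  if (is.null(chr$is_autosome)) {
    core <- sub("^chr", "", chr$chrom, ignore.case = TRUE)
    chr$is_autosome <- !toupper(core) %in% c("X", "Y", "M", "MT")
  } else {
    chr$is_autosome <- as.logical(chr$is_autosome)
  }
  rownames(chr) <- NULL
  structure(chr, name = name, class = c("genome_build", "data.frame"))
}

#' @export
print.genome_build <- function(x, ...) {
  cat("Genome build '", attr(x, "name"), "': ", nrow(x), " chromosomes (",
      sum(x$is_autosome), " autosomes)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a genome build from a TSV file
#'
#' Expects tab-separated columns `chrom`, `length`, `cen_start`, `cen_end`
#' (and optionally `is_autosome`).
#'
#' @param path File path.
#' @param name Build identifier; defaults to the file name without extension.
#' @return A [genome_build] object.
#' @export
read_genome_build <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  genome_build(name, tab)
}

#' Bundled hg19 genome build
#'
#' Chromosome lengths and centromere intervals for the 24 hg19 chromosomes
#' (UCSC gap-track centromere coordinates). Any other assembly can be used
#' by constructing a [genome_build] from its own table.
#'
#' @return A [genome_build] object named `"hg19"`.
#' @export
hg19_build <- function() {
  path <- system.file("extdata", "hg19_build.tsv", package = "hrdscar",
                      mustWork = TRUE)
  read_genome_build(path, name = "hg19")
}

#' Chromosome-arm assignment of segments
#'
#' Classifies genomic intervals relative to the centromere: `"p"` when the
#' interval ends at or before the centromere start, `"q"` when it starts at
#' or after the centromere end, and `"spans_centromere"` otherwise.
#'
#' @param segments A `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. the `segments` component of a
#'   [segment_profile].
#' @param build A [genome_build].
#' @return Character vector, one of `"p"`, `"q"`, `"spans_centromere"` per row.
#' @export
arm_of <- function(segments, build) {
  idx <- match(segments$chrom, build$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome(s) for build '", attr(build, "name"), "': ",
         paste(unique(segments$chrom[is.na(idx)]), collapse = ", "))
  }
  out <- rep("spans_centromere", nrow(segments))
  out[segments$end <= build$cen_start[idx]] <- "p"
  out[segments$start >= build$cen_end[idx]] <- "q"
  out
}
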