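variant_effects <- c("nonsense", "frameshift", "missense", "splice",
                     "inframe_indel", "synonymous", "other")
clinical_classes <- c("pathogenic", "likely_pathogenic", "vus",
                      "likely_benign", "benign", "unknown")

#' Pathogenicity of a variant call
#'
#' A variant is pathogenic when its effect is nonsense or frameshift, or
#' when its curated clinical classification is pathogenic / likely
#' pathogenic. Both rule sets apply this same operational rule; they differ
#' only in the curation source the `clinical_class` field is expected to
#' come from (`acmg_brca`: ACMG-classified BRCA1/2 calls; `clinvar_hrr`:
#' ClinVar-classified HRR-panel calls).
#'
#' @param variants `data.frame` of variant calls with columns `effect`
#'   (one of nonsense, frameshift, missense, splice, inframe_indel,
#'   synonymous, other) and `clinical_class` (one of pathogenic,
#'   likely_pathogenic, vus, likely_benign, benign, unknown).
#' @param rule_set `"acmg_brca"` or `"clinvar_hrr"`.
#' @return Logical vector, one flag per row.
#' @export
is_pathogenic <- function(variants, rule_set = c("acmg_brca", "clinvar_hrr")) {
  rule_set <- match.arg(rule_set)
  effect <- as.character(variants$effect)
  cls <- as.character(variants$clinical_class)
  bad <- setdiff(unique(effect), variant_effects)
  if (length(bad)) stop("unknown variant effect(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(cls), clinical_classes)
  if (length(bad)) stop("unknown clinical class(es): ", paste(bad, collapse = ", "))
  effect %in% c("nonsense", "frameshift") |
    cls %in% c("pathogenic", "likely_pathogenic")
}

#' Gene-level copy-number call from a log2 ratio
#'
#' Applies the panel cutoffs: log2 ratio at or above +1 is an
#' amplification, at or below -1 a deletion, and at or below
#' `homdel_threshold` (default -2) a homozygous deletion.
#'
#' @param log2_ratio Numeric vector of gene-level log2 copy-number ratios.
#' @param homdel_threshold Log2 ratio at or below which a deletion is
#'   called homozygous.
#' @return Character vector: `"amplification"`, `"deletion"`,
#'   `"homozygous_deletion"` or `"neutral"`.
#' @export
gene_cna_call <- function(log2_ratio, homdel_threshold = -2) {
  if (any(!is.finite(log2_ratio))) stop("log2_ratio must be finite")
  out <- rep("neutral", length(log2_ratio))
  out[log2_ratio >= 1] <- "amplification"
  out[log2_ratio <= -1] <- "deletion"
  out[log2_ratio <= homdel_threshold] <- "homozygous_deletion"
  out
}

# shared per-gene "deficient" logic: two distinct pathogenic alleles, one
# pathogenic allele plus a deletion call, a homozygous deletion, or a
# rearrangement flag
gene_deficiency_evidence <- function(gene, variants, cnas, rearrangements,
                                     rule_set) {
  v <- variants[variants$gene == gene, , drop = FALSE]
  path <- v[is_pathogenic(v, rule_set), , drop = FALSE]
  n_alleles <- length(unique(path$allele_id))
  calls <- character(0)
  if (!is.null(cnas) && nrow(cnas)) {
    calls <- cnas$call[cnas$gene == gene]
  }
  rearranged <- !is.null(rearrangements) && nrow(rearrangements) > 0 &&
    gene %in% rearrangements$gene
  deficient <- n_alleles >= 2L ||
    (n_alleles == 1L && any(calls %in% c("deletion", "homozygous_deletion"))) ||
    any(calls == "homozygous_deletion") ||
    rearranged
  list(gene = gene, n_pathogenic_alleles = n_alleles,
       pathogenic_variants = path,
       cna_calls = calls, rearranged = rearranged, deficient = deficient)
}

# normalize an input CNA table: derive the call column from log2_ratio
# when absent
prepare_cnas <- function(cnas, homdel_threshold = -2) {
  if (is.null(cnas) || nrow(cnas) == 0L) return(cnas)
  if (is.null(cnas$call)) {
    if (is.null(cnas$log2_ratio)) {
      stop("CNA table needs a 'call' or 'log2_ratio' column")
    }
    cnas$call <- gene_cna_call(cnas$log2_ratio, homdel_threshold)
  }
  cnas
}

#' Classify BRCA1/2 status of one sample
#'
#' Three-way classification from variant, gene-level copy-number and
#' rearrangement evidence restricted to BRCA1/BRCA2:
#' \describe{
#'   \item{deficient}{two distinct pathogenic alleles in the same gene
#'     (assumed biallelic; panel data carry no phase), one pathogenic
#'     allele accompanied by a deletion call in that gene, a homozygous
#'     deletion, or a large-rearrangement flag.}
#'   \item{monoallelic_pathogenic}{pathogenic alteration present but no
#'     second hit in any gene.}
#'   \item{intact}{no pathogenic BRCA1/2 alteration at all.}
#' }
#' Deficient vs the union of the other two is the "BRCA non-deficient"
#' contrast used in cohort analyses.
#'
#' @param variants Variant calls for this sample (columns `gene`, `effect`,
#'   `clinical_class`, `allele_id`; BRCA1/BRCA2 rows only). A germline and
#'   a somatic record of the same `allele_id` count once.
#' @param cnas Gene-level copy-number calls for this sample (columns
#'   `gene` and `call`, or `gene` and `log2_ratio` from which calls are
#'   derived via [gene_cna_call()]). May be `NULL`.
#' @param rearrangements Optional table flagging large genome
#'   rearrangements (column `gene`). May be `NULL`.
#' @param sample_id Sample identifier recorded in the result.
#' @param homdel_threshold Passed to [gene_cna_call()] when calls are
#'   derived from log2 ratios.
#' @return Object of class `brca_status`: list with `sample_id`, `status`
#'   and `evidence` (per-gene detail of the triggering calls).
#' @export
classify_brca_status <- function(variants, cnas = NULL,
                                 rearrangements = NULL, sample_id,
                                 homdel_threshold = -2) {
  brca <- c("BRCA1", "BRCA2")
  check_genes <- function(tab, what) {
    if (!is.null(tab) && nrow(tab)) {
      extra <- setdiff(unique(tab$gene), brca)
      if (length(extra)) {
        stop(what, " table contains non-BRCA gene(s): ",
             paste(extra, collapse = ", "), "; pre-filter to BRCA1/2")
      }
    }
  }
  if (is.null(variants)) {
    variants <- data.frame(gene = character(), effect = character(),
                           clinical_class = character(),
                           allele_id = character())
  }
  check_genes(variants, "variant")
  check_genes(cnas, "CNA")
  check_genes(rearrangements, "rearrangement")
  cnas <- prepare_cnas(cnas, homdel_threshold)
  evidence <- lapply(brca, gene_deficiency_evidence, variants = variants,
                     cnas = cnas, rearrangements = rearrangements,
                     rule_set = "acmg_brca")
  names(evidence) <- brca
  n_path <- sum(vapply(evidence, `[[`, 0L, "n_pathogenic_alleles"))
  status <- if (any(vapply(evidence, `[[`, FALSE, "deficient"))) {
    "deficient"
  } else if (n_path >= 1L) {
    "monoallelic_pathogenic"
  } else {
    "intact"
  }
  structure(list(sample_id = as.character(sample_id), status = status,
                 evidence = evidence),
            class = "brca_status")
}

#' @export
print.brca_status <- function(x, ...) {
  cat("BRCA status '", x$sample_id, "': ", x$status, "\n", sep = "")
  for (g in names(x$evidence)) {
    e <- x$evidence[[g]]
    cat(sprintf("  %s: %d pathogenic allele(s)%s%s\n", g,
                e$n_pathogenic_alleles,
                if (length(e$cna_calls))
                  paste0("; CNA ", paste(e$cna_calls, collapse = ",")) else "",
                if (e$rearranged) "; rearranged" else ""))
  }
  invisible(x)
}

#' Default HRR gene panel
#'
#' Reads the bundled provisional 25-gene homologous-recombination-repair
#' list, or a user-supplied one-symbol-per-line file.
#'
#' @param path Optional path to a gene-list file (lines starting with `#`
#'   are ignored).
#' @return Character vector of gene symbols.
#' @export
hrr_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hrr_genes_default.txt",
                        package = "hrdscar", mustWork = TRUE)
  }
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' HRR-pathway gene deficiency of one sample
#'
#' Applies the same deficiency logic as [classify_brca_status()] to every
#' non-BRCA gene of an HRR panel under ClinVar-based pathogenicity: a
#' sample is HRR-deficient when any such gene carries two distinct
#' pathogenic alleles, one pathogenic allele plus a deletion, or a
#' homozygous deletion. A single pathogenic allele alone (monoallelic)
#' does not qualify.
#'
#' @param variants Variant calls for this sample (any genes; rows outside
#'   `genes` are ignored).
#' @param cnas Gene-level copy-number table for this sample (may be `NULL`).
#' @param sample_id Sample identifier.
#' @param genes HRR gene symbols; defaults to [hrr_genes()]. BRCA1/2 are
#'   excluded from the scan.
#' @param homdel_threshold Passed to [gene_cna_call()].
#' @return List with `sample_id`, `deficient` flag, and `detail`, a
#'   per-gene `data.frame` (`gene`, `n_pathogenic_alleles`, `has_deletion`,
#'   `has_homdel`, `deficient`) for genes with any evidence.
#' @export
hrr_deficiency <- function(variants, cnas = NULL, sample_id,
                           genes = hrr_genes(), homdel_threshold = -2) {
  if (length(genes) == 0L) stop("HRR gene list is empty")
  genes <- setdiff(genes, c("BRCA1", "BRCA2"))
  cnas <- prepare_cnas(cnas, homdel_threshold)
  if (is.null(variants)) {
    variants <- data.frame(gene = character(), effect = character(),
                           clinical_class = character(),
                           allele_id = character())
  }
  active <- union(intersect(unique(variants$gene), genes),
                  if (!is.null(cnas) && nrow(cnas))
                    intersect(unique(cnas$gene), genes) else character(0))
  rows <- lapply(active, function(g) {
    e <- gene_deficiency_evidence(g, variants, cnas, NULL, "clinvar_hrr")
    data.frame(gene = g, n_pathogenic_alleles = e$n_pathogenic_alleles,
               has_deletion = any(e$cna_calls == "deletion"),
               has_homdel = any(e$cna_calls == "homozygous_deletion"),
               deficient = e$deficient)
  })
  detail <- do.call(rbind, rows)
  if (is.null(detail)) {
    detail <- data.frame(gene = character(), n_pathogenic_alleles = integer(),
                         has_deletion = logical(), has_homdel = logical(),
                         deficient = logical())
  }
  list(sample_id = as.character(sample_id),
       deficient = any(detail$deficient), detail = detail)
}

#' Read a variant-call table
#'
#' TSV with columns `sample, gene, effect, clinical_class, origin,
#' allele_id`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample", "gene", "effect", "clinical_class", "allele_id")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Read a gene-level copy-number table
#'
#' TSV with columns `sample, gene, log2_ratio` (or a pre-made `call`
#' column).
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_cna_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample", "gene")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) || (is.null(tab$log2_ratio) && is.null(tab$call))) {
    stop("CNA table needs columns sample, gene and log2_ratio (or call)")
  }
  tab
}
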