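vc <- function(gene, effect, cls, allele, origin = "somatic") {
  data.frame(gene = gene, effect = effect, clinical_class = cls,
             origin = origin, allele_id = allele)
}

test_that("is_pathogenic applies the truncating-or-curated rule", {
  v <- rbind(vc("BRCA1", "frameshift", "unknown", "a1"),
             vc("BRCA2", "missense", "likely_pathogenic", "a2"),
             vc("BRCA1", "missense", "vus", "a3"),
             vc("BRCA2", "nonsense", "benign", "a4"),
             vc("BRCA1", "synonymous", "unknown", "a5"))
  expect_equal(is_pathogenic(v, "acmg_brca"),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(is_pathogenic(v, "clinvar_hrr"),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(is_pathogenic(v, "bogus"))
  expect_error(is_pathogenic(vc("BRCA1", "weird", "vus", "a")), "effect")
  expect_error(is_pathogenic(vc("BRCA1", "missense", "odd", "a")), "class")
})

test_that("gene_cna_call applies the log2 cutoffs", {
  expect_equal(gene_cna_call(c(1.2, -1.5, 0, 1, -1, -2, -2.5)),
               c("amplification", "deletion", "neutral", "amplification",
                 "deletion", "homozygous_deletion", "homozygous_deletion"))
  expect_equal(gene_cna_call(-1.8, homdel_threshold = -1.5),
               "homozygous_deletion")
  expect_error(gene_cna_call(NaN), "finite")
  expect_error(gene_cna_call(c(0, Inf)), "finite")
})

test_that("classify_brca_status covers the deficient mechanisms", {
  # biallelic: germline + somatic hits with distinct allele ids
  bi <- rbind(vc("BRCA1", "frameshift", "unknown", "g1", "germline"),
              vc("BRCA1", "nonsense", "unknown", "s1", "somatic"))
  expect_equal(classify_brca_status(bi, sample_id = "S")$status, "deficient")

  # one pathogenic allele only: monoallelic
  mono <- vc("BRCA2", "missense", "pathogenic", "g1", "germline")
  expect_equal(classify_brca_status(mono, sample_id = "S")$status,
               "monoallelic_pathogenic")

  # VUS only: intact
  vus <- vc("BRCA1", "missense", "vus", "v1")
  expect_equal(classify_brca_status(vus, sample_id = "S")$status, "intact")
  expect_equal(classify_brca_status(NULL, sample_id = "S")$status, "intact")

  # pathogenic allele + heterozygous deletion in the same gene
  del <- data.frame(gene = "BRCA2", log2_ratio = -1.3)
  one <- vc("BRCA2", "nonsense", "unknown", "s1")
  expect_equal(classify_brca_status(one, del, sample_id = "S")$status,
               "deficient")
  # ... but a deletion in the *other* gene does not make it deficient
  del1 <- data.frame(gene = "BRCA1", log2_ratio = -1.3)
  expect_equal(classify_brca_status(one, del1, sample_id = "S")$status,
               "monoallelic_pathogenic")

  # homozygous deletion alone suffices
  homdel <- data.frame(gene = "BRCA1", log2_ratio = -2.4)
  expect_equal(classify_brca_status(NULL, homdel, sample_id = "S")$status,
               "deficient")

  # large rearrangement flag alone suffices
  rearr <- data.frame(gene = "BRCA2", description = "LGR")
  expect_equal(
    classify_brca_status(NULL, NULL, rearr, sample_id = "S")$status,
    "deficient")

  # the same allele re-detected in tumor and blood counts once
  dup <- rbind(vc("BRCA1", "frameshift", "pathogenic", "a1", "germline"),
               vc("BRCA1", "frameshift", "pathogenic", "a1", "somatic"))
  expect_equal(classify_brca_status(dup, sample_id = "S")$status,
               "monoallelic_pathogenic")

  # evidence outside BRCA1/2 is the caller's bug, not silently dropped
  expect_error(classify_brca_status(vc("ATM", "nonsense", "unknown", "a1"),
                                    sample_id = "S"),
               "non-BRCA")
})

test_that("classification partitions samples and is order/monotone sound", {
  withr::local_seed(5)
  effects <- c("nonsense", "frameshift", "missense", "splice", "synonymous")
  classes <- c("pathogenic", "likely_pathogenic", "vus", "benign", "unknown")
  for (i in 1:40) {
    n <- sample(0:4, 1)
    v <- if (n > 0) {
      data.frame(gene = sample(c("BRCA1", "BRCA2"), n, TRUE),
                 effect = sample(effects, n, TRUE),
                 clinical_class = sample(classes, n, TRUE),
                 origin = sample(c("somatic", "germline"), n, TRUE),
                 allele_id = paste0("a", sample(1:3, n, TRUE)))
    } else NULL
    cn <- if (runif(1) < 0.4) {
      data.frame(gene = sample(c("BRCA1", "BRCA2"), 1),
                 log2_ratio = runif(1, -3, 2))
    } else NULL
    res <- classify_brca_status(v, cn, sample_id = "S")
    expect_true(res$status %in% c("deficient", "intact",
                                  "monoallelic_pathogenic"))
    # intact iff no pathogenic alteration among the evidence
    any_path <- (!is.null(v) && any(is_pathogenic(v))) ||
      (!is.null(cn) && any(gene_cna_call(cn$log2_ratio) ==
                             "homozygous_deletion"))
    expect_identical(res$status == "intact", !any_path)
    # order determinism
    if (!is.null(v) && nrow(v) > 1) {
      res2 <- classify_brca_status(v[rev(seq_len(nrow(v))), ], cn,
                                   sample_id = "S")
      expect_identical(res2$status, res$status)
    }
    # monotonicity: a second pathogenic hit never yields intact
    if (res$status == "monoallelic_pathogenic") {
      g <- v$gene[is_pathogenic(v)][1]
      v2 <- rbind(v, vc(g, "nonsense", "pathogenic", "extra_allele"))
      expect_equal(classify_brca_status(v2, cn, sample_id = "S")$status,
                   "deficient")
    }
  }
})

test_that("hrr_deficiency applies the deficient logic to non-BRCA genes", {
  # biallelic RAD51C truncations
  bi <- rbind(vc("RAD51C", "nonsense", "unknown", "a1"),
              vc("RAD51C", "nonsense", "unknown", "a2"))
  expect_true(hrr_deficiency(bi, sample_id = "S")$deficient)

  # single pathogenic ATM allele is monoallelic, not deficient
  one <- vc("ATM", "missense", "pathogenic", "a1")
  res <- hrr_deficiency(one, sample_id = "S")
  expect_false(res$deficient)
  expect_equal(res$detail$n_pathogenic_alleles, 1L)

  # no HRR evidence at all
  expect_false(hrr_deficiency(NULL, sample_id = "S")$deficient)

  # BRCA hits do not leak into the HRR scan; gene list is overridable
  brca_only <- rbind(vc("BRCA1", "nonsense", "unknown", "a1"),
                     vc("BRCA1", "nonsense", "unknown", "a2"))
  expect_false(hrr_deficiency(brca_only, sample_id = "S")$deficient)
  expect_false(hrr_deficiency(bi, sample_id = "S",
                              genes = c("ATM", "PALB2"))$deficient)
  expect_error(hrr_deficiency(bi, sample_id = "S", genes = character(0)),
               "empty")

  # pathogenic variant + gene deletion
  cn <- data.frame(gene = "PALB2", log2_ratio = -1.2)
  v <- vc("PALB2", "frameshift", "unknown", "a1")
  expect_true(hrr_deficiency(v, cn, sample_id = "S")$deficient)
})

test_that("the bundled HRR panel has 25 unique symbols including core genes", {
  genes <- hrr_genes()
  expect_length(genes, 25L)
  expect_false(anyDuplicated(genes) > 0)
  expect_true(all(c("ATM", "PALB2", "RAD51C", "BRCA1", "BRCA2") %in% genes))
})
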