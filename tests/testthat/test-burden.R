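# Rarity filtering, gene collapsing, the burden scan, and reconstruction of
# published odds ratios from printed summary statistics.

# hand-built cohort: gene-level aggregates with known counts
manual_calls <- function(n_individuals, carriers) {
  # carriers: tibble(variant_id, chrom, pos, ref, alt, gene, consequence,
  #                  indiv, gt)
  variants <- carriers |>
    dplyr::distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$gene, .data$consequence) |>
    dplyr::mutate(class = classify_consequence(.data$consequence),
                  filter = "PASS")
  genotypes <- carriers |>
    dplyr::transmute(.data$variant_id, .data$indiv, gt = .data$gt,
                     ab = 0.5, gq = 99, dp = 40)
  rvburden:::new_cohort_calls(genotypes, variants, n_individuals)
}

tlr9_like_calls <- function() {
  # 7 missense variants totalling 8 alt alleles in a 371-individual cohort
  carriers <- tibble::tibble(
    variant_id = paste0("3:", 100 + c(1:7, 1), ":G:C")[1:8],
    chrom = "3", pos = 100 + c(1:7, 1), ref = "G", alt = "C",
    gene = "TLR9", consequence = "missense_variant",
    indiv = sprintf("S%03d", 1:8), gt = 1)
  manual_calls(371, carriers)
}

test_that("gene collapsing reproduces printed-style aggregate MAFs", {
  calls <- tlr9_like_calls()
  coll <- collapse_gene(calls, "TLR9")
  expect_equal(coll$n_variants, 7)
  expect_equal(coll$ac, 8)
  expect_equal(coll$allele_number, 742)
  expect_equal(round(coll$case_maf, 3), 0.011)   # 8/742
  # two variants totalling 7 alleles: 7/742 prints as 0.009
  carriers <- tibble::tibble(
    variant_id = rep(c("10:1:G:A", "10:2:C:T"), c(4, 3)),
    chrom = "10", pos = rep(c(1, 2), c(4, 3)), ref = rep(c("G", "C"), c(4, 3)),
    alt = rep(c("A", "T"), c(4, 3)), gene = "FAS",
    consequence = "missense_variant", indiv = sprintf("S%03d", 1:7), gt = 1)
  coll <- collapse_gene(manual_calls(371, carriers), "FAS")
  expect_equal(coll$ac, 7)
  expect_equal(round(coll$case_maf, 3), 0.009)
  # absent gene collapses to zero
  coll <- collapse_gene(calls, "NFKB1")
  expect_equal(coll$ac, 0); expect_equal(coll$n_variants, 0)
})

test_that("rarity filter drops strictly above the CSVS cutoff", {
  carriers <- tibble::tibble(
    variant_id = c("1:1:A:T", "1:2:A:T", "1:3:A:T"),
    chrom = "1", pos = 1:3, ref = "A", alt = "T", gene = "TLR9",
    consequence = "missense_variant", indiv = "S001", gt = 1)
  calls <- manual_calls(10, carriers)
  panel <- read_panel(tibble::tibble(
    CHROM = "1", POS = 1:2, REF = "A", ALT = "T", GENE = "TLR9",
    CONSEQUENCE = "missense_variant", POP = "CSVS",
    AC = NA, AN = NA, AF = c(0.06, 0.05)))
  filt <- suppressMessages(rarity_filter(calls, panel))
  # AF 0.06 dropped; AF exactly 0.05 retained; absent retained and novel
  expect_setequal(filt$variants$variant_id, c("1:2:A:T", "1:3:A:T"))
  expect_true(filt$variants$novel[filt$variants$variant_id == "1:3:A:T"])
  expect_false(filt$variants$novel[filt$variants$variant_id == "1:2:A:T"])
  expect_equal(attr(filt, "dropped_common"), 1)
})

test_that("burden scan reproduces a known contingency end to end", {
  calls <- tlr9_like_calls()
  # panel: the 7 qualifying variants sum to 5 NFE alt alleles
  v <- calls$variants
  panel <- read_panel(tibble::tibble(
    CHROM = v$chrom, POS = v$pos, REF = v$ref, ALT = v$alt, GENE = v$gene,
    CONSEQUENCE = v$consequence, POP = "NFE",
    AC = c(2, 1, 1, 1, 0, 0, 0), AN = 68058, AF = NA))
  scan <- suppressWarnings(burden_scan(calls, panel, gene_list = c("TLR9", "NFKB1"),
                      populations = "NFE", primary = "NFE",
                      default_an = c(NFE = 68058)))
  row <- tidy(scan) |>
    dplyr::filter(.data$gene == "TLR9", .data$class == "functional")
  expect_equal(row$ac, 8)
  expect_equal(row$control_ac, 5)
  expect_equal(row$control_an, 68058)
  manual_or <- odds_ratio(8, 742 - 8, 5, 68058 - 5)
  expect_equal(row$odds_ratio, manual_or)
  expect_equal(row$p, fisher_exact_p(8, 734, 5, 68053))
  # the family is both genes even though one is empty
  expect_equal(attr(scan, "family_size"), 2)
  expect_equal(row$p_bonferroni, min(1, 2 * row$p))
  # BH q is never below the raw p
  expect_true(all(tidy(scan)$q_fdr >= tidy(scan)$p))
  # empty gene flagged non-significant with zero counts
  empty <- tidy(scan) |> dplyr::filter(.data$gene == "NFKB1",
                                       .data$class == "functional")
  expect_equal(empty$ac, 0)
  expect_false(empty$significant)
})

test_that("per-variant allele counts sum to the gene aggregate", {
  cfg <- tiny_config(seed = 41)
  sim <- suppressMessages(simulate_cohort(cfg))
  calls <- qc_cohort(sim$calls)
  ac_var <- variant_allele_counts(calls)
  for (g in unique(calls$variants$gene)) {
    ids <- calls$variants$variant_id[calls$variants$gene == g &
                                       calls$variants$class %in%
                                       c("missense", "lof")]
    coll <- collapse_gene(calls, g)
    expect_equal(coll$ac, sum(ac_var$ac[ac_var$variant_id %in% ids]))
  }
})

test_that("an empty cohort yields all-zero, non-significant results", {
  calls <- rvburden:::new_cohort_calls(
    genotypes = tibble::tibble(variant_id = character(), indiv = character(),
                               gt = numeric(), ab = numeric(), gq = numeric(),
                               dp = numeric()),
    variants = tibble::tibble(variant_id = character(), chrom = character(),
                              pos = integer(), ref = character(),
                              alt = character(), gene = character(),
                              consequence = character(), class = character(),
                              filter = character()),
    n_individuals = 371)
  panel <- read_panel(tibble::tibble(
    CHROM = "1", POS = 1L, REF = "A", ALT = "T", GENE = "TLR9",
    CONSEQUENCE = "missense_variant", POP = "NFE", AC = 5, AN = 1000,
    AF = NA))
  scan <- suppressWarnings(burden_scan(calls, panel, gene_list = c("TLR9", "FAS"),
                                       populations = "NFE",
                                       default_an = c(NFE = 1000)))
  d <- tidy(scan)
  expect_true(all(d$ac == 0))
  expect_true(all(!d$significant))
})

test_that("reconstructed odds ratios track the printed values", {
  rec <- reconstruct_published_or()
  finite <- rec[is.finite(rec$printed_or), ]
  rel <- abs(finite$reconstructed_or - finite$printed_or) / finite$printed_or
  # printed MAFs carry 3 significant figures; 1% covers their rounding
  expect_true(all(rel < 0.01))
  # the zero-control-MAF row reconstructs as infinite
  expect_identical(rec$reconstructed_or[rec$printed_or == Inf], Inf)
})

test_that("tidy, glance and autoplot work on a scan object", {
  calls <- tlr9_like_calls()
  panel <- read_panel(tibble::tibble(
    CHROM = "3", POS = 101L, REF = "G", ALT = "C", GENE = "TLR9",
    CONSEQUENCE = "missense_variant", POP = "NFE", AC = 2, AN = 68058,
    AF = NA))
  scan <- suppressWarnings(burden_scan(calls, panel, gene_list = "TLR9",
                                       populations = "NFE",
                                       default_an = c(NFE = 68058)))
  expect_s3_class(tidy(scan), "tbl_df")
  g <- glance(scan)
  expect_equal(g$n_genes, 1)
  expect_s3_class(autoplot(scan), "ggplot")
})
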