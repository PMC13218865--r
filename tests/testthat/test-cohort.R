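# Genotype QC rules, VCF parsing edge cases, gene restriction, consequence
# classes, and the QC invariants.

test_that("genotype QC applies the thresholds with inclusive boundaries", {
  # het just below the AB window fails on AB even with perfect GQ/DP
  r <- apply_genotype_qc(1, ab = 0.19, gq = 99, dp = 30)
  expect_false(r$pass); expect_identical(r$reason, "AB")
  # inclusive boundaries all pass
  expect_true(apply_genotype_qc(1, ab = 0.20, gq = 20, dp = 10)$pass)
  expect_true(apply_genotype_qc(1, ab = 0.80, gq = 20, dp = 10)$pass)
  # hom-alt: AB not assessed, GQ below threshold fails on GQ
  r <- apply_genotype_qc(2, ab = NA, gq = 19, dp = 30)
  expect_false(r$pass); expect_identical(r$reason, "GQ")
  r <- apply_genotype_qc(0, ab = NA, gq = 50, dp = 9)
  expect_false(r$pass); expect_identical(r$reason, "DP")
  # haploid depth threshold
  expect_true(apply_genotype_qc(1, ab = 0.5, gq = 50, dp = 6, ploidy = 1L)$pass)
  expect_false(apply_genotype_qc(1, ab = 0.5, gq = 50, dp = 6)$pass)
})

test_that("a missing required field fails as MISSING_FIELD, never passes", {
  r <- apply_genotype_qc(1, ab = NA, gq = 99, dp = 30)   # het without AB
  expect_false(r$pass); expect_identical(r$reason, "MISSING_FIELD")
  r <- apply_genotype_qc(2, ab = NA, gq = NA, dp = 30)
  expect_false(r$pass); expect_identical(r$reason, "MISSING_FIELD")
  # uncalled genotypes pass through without a reason
  r <- apply_genotype_qc(NA, ab = NA, gq = NA, dp = NA)
  expect_true(r$pass); expect_true(is.na(r$reason))
})

test_that("consequence terms map to burden classes", {
  expect_identical(
    classify_consequence(c("stop_gained", "frameshift_variant",
                           "splice_acceptor_variant", "splice_donor_variant",
                           "start_lost")),
    rep("lof", 5))
  expect_identical(classify_consequence("missense_variant"), "missense")
  expect_identical(classify_consequence("synonymous_variant"), "synonymous")
  expect_identical(classify_consequence(c("intron_variant", "5_prime_UTR_variant")),
                   c("other", "other"))
})

test_that("QC audit on a synthetic VCF matches the injected failure count", {
  cfg <- tiny_config(seed = 23, qc_fail_rate = 0.05)
  sim <- suppressMessages(simulate_cohort(cfg))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  calls <- read_cohort_vcf(paths[["vcf"]], paths[["annotation"]])
  expect_equal(nrow(calls$audit), nrow(sim$truth$qc_injected))
  aud <- dplyr::arrange(calls$audit, variant_id, indiv)
  tru <- dplyr::arrange(sim$truth$qc_injected, variant_id, indiv)
  expect_identical(aud$variant_id, tru$variant_id)
  expect_identical(aud$indiv, tru$indiv)
  expect_identical(aud$reason, tru$field)
})

test_that("an empty VCF body yields an empty table with the header cohort", {
  path <- write_mini_vcf(character(0), samples = c("A", "B", "C"))
  calls <- read_cohort_vcf(path, mini_annotation(character(0), integer(0),
                                                 character(0), character(0),
                                                 character(0), character(0)))
  expect_equal(nrow(calls$variants), 0)
  expect_equal(calls$n_individuals, 3)
})

test_that("a 1/1 genotype contributes two alt alleles", {
  path <- write_mini_vcf(
    "1\t100\t.\tG\tC\t.\tPASS\t.\tGT:AB:GQ:DP\t1/1:.:99:40\t0/0:.:99:40")
  ann <- mini_annotation("1", 100L, "G", "C", "TLR9", "missense_variant")
  calls <- read_cohort_vcf(path, ann)
  expect_equal(variant_allele_counts(calls)$ac, 2)
})

test_that("multi-allelic records are decomposed into biallelic rows", {
  path <- write_mini_vcf(
    "1\t100\t.\tG\tC,T\t.\tPASS\t.\tGT:AB:GQ:DP\t1/2:0.5:99:40\t0/1:0.5:99:40")
  ann <- dplyr::bind_rows(
    mini_annotation("1", 100L, "G", "C", "TLR9", "missense_variant"),
    mini_annotation("1", 100L, "G", "T", "TLR9", "synonymous_variant"))
  calls <- read_cohort_vcf(path, ann)
  expect_equal(nrow(calls$variants), 2)
  ac <- variant_allele_counts(calls)
  expect_equal(sort(ac$ac), c(1, 2))   # C: one in S1 + one in S2; T: one in S1
})

test_that("sites outside the pass tranche are excluded with reason TRANCHE", {
  path <- write_mini_vcf(c(
    "1\t100\t.\tG\tC\t.\tPASS\t.\tGT:AB:GQ:DP\t0/1:0.5:99:40\t0/0:.:99:40",
    "1\t200\t.\tA\tT\t.\tVQSRTrancheSNP99.00to100.00\t.\tGT:AB:GQ:DP\t0/1:0.5:99:40\t0/1:0.5:99:40"))
  ann <- dplyr::bind_rows(
    mini_annotation("1", 100L, "G", "C", "TLR9", "missense_variant"),
    mini_annotation("1", 200L, "A", "T", "TLR9", "missense_variant"))
  calls <- read_cohort_vcf(path, ann)
  expect_equal(calls$variants$pos, 100)
  expect_true(all(calls$audit$reason[calls$audit$variant_id == "1:200:A:T"] ==
                    "TRANCHE"))
})

test_that("QC is idempotent and never increases allele counts", {
  cfg <- tiny_config(seed = 31, qc_fail_rate = 0.1)
  sim <- suppressMessages(simulate_cohort(cfg))
  raw <- sim$calls
  once <- qc_cohort(raw)
  twice <- qc_cohort(once)
  expect_identical(once$genotypes, twice$genotypes)
  ac_raw <- variant_allele_counts(raw)
  ac_qc <- variant_allele_counts(once)
  joined <- dplyr::inner_join(ac_raw, ac_qc, by = "variant_id",
                              suffix = c("_raw", "_qc"))
  expect_true(all(joined$ac_qc <= joined$ac_raw))
})

test_that("writing then reading reproduces genotype and annotation fields", {
  cfg <- tiny_config(seed = 37, qc_fail_rate = 0)
  sim <- suppressMessages(simulate_cohort(cfg))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_cohort_vcf(paths[["vcf"]], paths[["annotation"]])
  orig <- dplyr::arrange(sim$calls$genotypes, variant_id, indiv)
  got <- dplyr::arrange(back$genotypes, variant_id, indiv)
  expect_equal(got$gt, orig$gt)
  expect_equal(got$ab, orig$ab, tolerance = 1e-9)
  expect_equal(got$gq, orig$gq)
  expect_equal(got$dp, orig$dp)
  v1 <- dplyr::arrange(sim$calls$variants, variant_id)
  v2 <- dplyr::arrange(back$variants, variant_id)
  expect_identical(v1$gene, v2$gene)
  expect_identical(v1$consequence, v2$consequence)
  expect_identical(v1$class, v2$class)
})

test_that("phased and unphased genotype notation give identical dosages", {
  body_unphased <- "1\t100\t.\tG\tC\t.\tPASS\t.\tGT:AB:GQ:DP\t0/1:0.5:99:40\t1/1:.:99:40"
  body_phased <- "1\t100\t.\tG\tC\t.\tPASS\t.\tGT:AB:GQ:DP\t0|1:0.5:99:40\t1|1:.:99:40"
  ann <- mini_annotation("1", 100L, "G", "C", "TLR9", "missense_variant")
  c1 <- read_cohort_vcf(write_mini_vcf(body_unphased), ann)
  c2 <- read_cohort_vcf(write_mini_vcf(body_phased), ann)
  expect_equal(c1$genotypes$gt, c2$genotypes$gt)
})

test_that("gene restriction is exact, case-sensitive, and logged", {
  path <- write_mini_vcf(c(
    "1\t100\t.\tG\tC\t.\tPASS\t.\tGT:AB:GQ:DP\t0/1:0.5:99:40\t0/0:.:99:40",
    "1\t200\t.\tA\tT\t.\tPASS\t.\tGT:AB:GQ:DP\t0/1:0.5:99:40\t0/0:.:99:40"))
  ann <- dplyr::bind_rows(
    mini_annotation("1", 100L, "G", "C", "TLR9", "missense_variant"),
    mini_annotation("1", 200L, "A", "T", "tlr9", "missense_variant"))
  calls <- read_cohort_vcf(path, ann)
  expect_message(kept <- restrict_to_genes(calls, c("TLR9", "FAS")), "dropped")
  expect_equal(kept$variants$gene, "TLR9")   # case-mismatched symbol dropped
  expect_warning(expect_message(
    none <- restrict_to_genes(calls, "NFKB1")), "no variants")
  expect_equal(nrow(none$variants), 0)
  expect_error(restrict_to_genes(calls, character(0)), "nonempty")
})
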