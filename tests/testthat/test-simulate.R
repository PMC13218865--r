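# Simulator contracts: determinism, panel arithmetic, genotype model,
# planting, QC injection, and splice-region planting.

test_that("identical configs give byte-identical artifact files", {
  cfg <- tiny_config(seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages({
    p1 <- write_simulation(simulate_cohort(cfg), d1)
    p2 <- write_simulation(simulate_cohort(cfg), d2)
  })
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("panel allele counts are round-half-even of q * AN", {
  cfg <- tiny_config(seed = 3)
  panel <- suppressMessages(simulate_panel(cfg))
  vt <- attr(panel, "variants")
  for (pop in c("NFE", "CSVS")) {
    sub <- panel[panel$POP == pop, ]
    qq <- vt[[paste0("q_", pop)]][match(sub$variant_id, vt$variant_id)]
    expect_equal(sub$AC, round(qq * cfg$panel_an[[pop]]))
    expect_equal(sub$AF, sub$AC / sub$AN)
  }
})

test_that("absent populations emit no rows and q = 0 means no row", {
  cfg <- tiny_config(seed = 5)
  cfg$absent_prob <- c(NFE = 0, CSVS = 1)
  panel <- suppressMessages(simulate_panel(cfg))
  expect_false("CSVS" %in% panel$POP)
  expect_true(all(panel$POP == "NFE"))
})

test_that("lambda = 0 yields an all-homozygous-reference cohort", {
  cfg <- tiny_config(seed = 8, qc_fail_rate = 0,
                     enrichment = setNames(rep(0, 3), tiny_gene_spec()$gene))
  sim <- suppressMessages(simulate_cohort(cfg))
  expect_true(all(sim$calls$genotypes$gt == 0))
})

test_that("lambda * q above 0.5 is clamped with a warning", {
  cfg <- tiny_config(seed = 2, maf_range = c(4e-3, 5e-3),
                     enrichment = c(G01 = 1000))
  expect_warning(panel <- simulate_panel(cfg), "clamping")
  vt <- attr(panel, "variants")
  expect_true(all(vt$p_case <= 0.5))
})

test_that("aggregate case allele count matches its binomial expectation", {
  # 500 replicate cohorts; total AC should sit within 3 SE of sum(2 n q)
  total <- 0; expected <- 0; var_sum <- 0
  n <- 20
  genes <- tibble::tibble(gene = "G01", cds_length = 900L, n_variants = 3L)
  for (s in 1:500) {
    cfg <- sim_config(n_cases = n, genes = genes,
                      panel_an = c(NFE = 10000), absent_prob = c(NFE = 0),
                      maf_range = c(5e-3, 2e-2), qc_fail_rate = 0, seed = s)
    sim <- suppressMessages(simulate_cohort(cfg))
    q <- sim$truth$variants$q
    total <- total + sum(sim$calls$genotypes$gt)
    expected <- expected + 2 * n * sum(q)
    var_sum <- var_sum + sum(2 * n * q * (1 - q))
  }
  expect_lt(abs(total - expected), 3 * sqrt(var_sum))
})

test_that("planted pairs put exactly the requested multi-carriers in place", {
  cfg <- tiny_config(seed = 13, qc_fail_rate = 0,
                     maf_range = c(1e-6, 1e-5),   # background carriers ~ none
                     planted_pairs = c(G02 = 1))
  sim <- suppressMessages(simulate_cohort(cfg))
  calls <- qc_cohort(sim$calls)
  mc <- find_multicarriers(calls, classes = NULL)
  expect_equal(nrow(mc[mc$gene == "G02", ]), 1)
  expect_identical(mc$indiv[mc$gene == "G02"],
                   unique(sim$truth$planted$indiv))
})

test_that("every planted entity is recoverable from the emitted files", {
  cfg <- tiny_config(seed = 17, qc_fail_rate = 0.02,
                     planted_pairs = c(G01 = 1), planted_syn_mis = c(G03 = 1))
  sim <- suppressMessages(simulate_cohort(cfg))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  calls <- read_cohort_vcf(paths[["vcf"]], paths[["annotation"]])
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  # planted carrier genotypes are present in the re-read VCF
  for (i in seq_len(nrow(truth$planted))) {
    g <- calls$genotypes
    hit <- g[g$indiv == truth$planted$indiv[i] &
               g$variant_id == truth$planted$variant_id[i], ]
    expect_true(nrow(hit) == 1 && !is.na(hit$gt) && hit$gt >= 1)
  }
  # every simulated variant appears in the VCF and the panel keys match
  expect_setequal(calls$variants$variant_id, truth$variants$variant_id)
})

test_that("splice-region planting hits the requested score band", {
  m <- default_splice_matrices()$donor
  # degenerate bands map to the consensus / anti-consensus k-mers
  top <- simulate_splice_region(m, c(100, 100), seed = 1)
  expect_identical(substr(top$alt_seq, top$site_start, top$site_start + m$k - 1),
                   consensus_kmer(m))
  bottom <- simulate_splice_region(m, c(0, 0), seed = 1)
  expect_identical(substr(bottom$alt_seq, bottom$site_start,
                          bottom$site_start + m$k - 1),
                   anticonsensus_kmer(m))
  # arbitrary bands verified by rescoring the planted k-mer
  for (band in list(c(30, 40), c(55, 65), c(80, 95))) {
    for (s in 1:3) {
      reg <- simulate_splice_region(m, band, seed = s)
      kmer <- substr(reg$alt_seq, reg$site_start, reg$site_start + m$k - 1)
      sc <- score_site(kmer, m)
      expect_gte(sc, band[1]); expect_lte(sc, band[2])
      # single-base ref/alt difference
      expect_equal(sum(strsplit(reg$ref_seq, "")[[1]] !=
                         strsplit(reg$alt_seq, "")[[1]]), 1)
    }
  }
  acc <- default_splice_matrices()$acceptor
  reg <- simulate_splice_region(acc, c(70, 90), seed = 4)
  kmer <- substr(reg$alt_seq, reg$site_start, reg$site_start + acc$k - 1)
  expect_true(score_site(kmer, acc) >= 70 && score_site(kmer, acc) <= 90)
})

test_that("an unreachable score band fails explicitly", {
  m <- default_splice_matrices()$donor
  # no k-mer scores strictly between the best non-consensus score and 100
  expect_error(simulate_splice_region(m, c(99.95, 99.99), seed = 1,
                                      max_tries = 25),
               "reachable|budget")
})
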