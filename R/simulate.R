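# Seeded synthetic cohorts, reference panels, and splice-region sequence
# pairs with planted structure, for end-to-end validation of the burden
# pipeline without restricted patient data.
#
# Genotype model: per variant, each individual's alt dosage is Binomial(2, p)
# with p = min(lambda_gene * q, 0.5) — independent sites, no linkage
# disequilibrium (irrelevant to allele-count collapsing at these
# frequencies). Panel allele counts are round-half-to-even of q * AN so that
# published-style rounded frequencies regenerate integer counts
# deterministically.

#' Simulation configuration
#'
#' @param n_cases Number of diploid case individuals.
#' @param genes Gene specification tibble with columns `gene`, `cds_length`,
#'   `n_variants`; defaults to the packaged 63-gene NF-kB pathway list with 5
#'   rare variants per gene.
#' @param panel_an Named vector of control allele numbers per population.
#' @param maf_range Panel frequency law: each variant's base frequency `q` is
#'   log-uniform over this interval.
#' @param enrichment Named vector of per-gene multiplicative factors `lambda`
#'   on the case allele frequency (unnamed genes default to 1, the null).
#' @param planted_pairs Named integer vector: number of individuals per gene
#'   forced to carry two distinct qualifying variants.
#' @param planted_syn_mis Named integer vector: number of individuals per
#'   gene forced to carry one synonymous plus one missense variant.
#' @param qc_fail_rate Fraction of genotype calls emitted with one QC field
#'   just outside its threshold, to exercise the genotype filter.
#' @param consequence_probs Sampling weights over consequence classes.
#' @param absent_prob Named per-population probability that a variant is
#'   absent from that panel (novelty; no row emitted).
#' @param pop_jitter_sd Log-normal SD of the non-NFE population frequency
#'   around the base `q` (cases are NFE-like, so the NFE panel frequency is
#'   `q` itself).
#' @param tranche_fail_rate Fraction of sites emitted with a non-pass FILTER.
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 371,
                       genes = default_gene_spec(),
                       panel_an = c(NFE = 68058, Global = 152312, CSVS = 4074),
                       maf_range = c(1e-6, 5e-2),
                       enrichment = NULL,
                       planted_pairs = NULL,
                       planted_syn_mis = NULL,
                       qc_fail_rate = 0.02,
                       consequence_probs = c(missense_variant = 0.7,
                                             synonymous_variant = 0.2,
                                             stop_gained = 0.1),
                       absent_prob = c(NFE = 0, Global = 0.05, CSVS = 0.2),
                       pop_jitter_sd = 0.3,
                       tranche_fail_rate = 0,
                       seed = 1L) {
  stopifnot(n_cases >= 1, is.data.frame(genes),
            all(c("gene", "cds_length", "n_variants") %in% names(genes)),
            all(maf_range > 0), maf_range[1] <= maf_range[2],
            maf_range[2] <= 0.5, all(panel_an > 0), !is.null(names(panel_an)),
            qc_fail_rate >= 0, qc_fail_rate < 1,
            tranche_fail_rate >= 0, tranche_fail_rate < 1,
            is.numeric(seed), length(seed) == 1)
  if (!is.null(enrichment)) {
    stopifnot(all(enrichment >= 0), all(names(enrichment) %in% genes$gene))
  }
  for (pl in list(planted_pairs, planted_syn_mis)) {
    if (!is.null(pl)) stopifnot(all(pl >= 1), all(names(pl) %in% genes$gene))
  }
  structure(list(n_cases = as.integer(n_cases), genes = tibble::as_tibble(genes),
                 panel_an = panel_an, maf_range = maf_range,
                 enrichment = enrichment, planted_pairs = planted_pairs,
                 planted_syn_mis = planted_syn_mis,
                 qc_fail_rate = qc_fail_rate,
                 consequence_probs = consequence_probs,
                 absent_prob = absent_prob, pop_jitter_sd = pop_jitter_sd,
                 tranche_fail_rate = tranche_fail_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default gene specification: the packaged NF-kB pathway gene list
#'
#' @param n_variants Rare variants per gene.
#' @return Tibble `gene`, `cds_length`, `n_variants`. CDS lengths are
#'   assigned deterministically in a realistic 1.2-4.2 kb range.
#' @export
default_gene_spec <- function(n_variants = 5) {
  genes <- read_gene_list(system.file("extdata", "nfkb_genes.txt",
                                      package = "rvburden", mustWork = TRUE))
  i <- seq_along(genes)
  tibble::tibble(gene = genes,
                 cds_length = 1200L + ((i * 7L) %% 17L) * 180L,
                 n_variants = as.integer(n_variants))
}

# Deterministic variant set shared by panel and cohort generation. Everything
# here is a function of config$seed only.
.sim_variant_set <- function(config) {
  set.seed(config$seed)
  g <- config$genes
  gi <- rep(seq_len(nrow(g)), g$n_variants)
  n_var <- length(gi)
  cds_pos <- unlist(purrr::map(seq_len(nrow(g)), function(i) {
    sort(sample.int(g$cds_length[i], g$n_variants[i]) - 1L)
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  q <- exp(runif(n_var, log(config$maf_range[1]), log(config$maf_range[2])))
  consequence <- sample(names(config$consequence_probs), n_var, replace = TRUE,
                        prob = config$consequence_probs)

  vt <- tibble::tibble(
    gene = g$gene[gi],
    chrom = as.character((gi - 1L) %% 22L + 1L),
    pos = gi * 1000000L + cds_pos,
    cds_pos = cds_pos,
    cds_length = g$cds_length[gi],
    ref = unname(ref), alt = unname(alt),
    consequence = consequence,
    q = q
  )

  # planted syn+mis co-carriers need one variant of each class in the gene
  if (!is.null(config$planted_syn_mis)) {
    for (gene in names(config$planted_syn_mis)) {
      idx <- which(vt$gene == gene)
      stopifnot(length(idx) >= 2)
      vt$consequence[idx[1]] <- "synonymous_variant"
      vt$consequence[idx[2]] <- "missense_variant"
    }
  }

  lambda <- setNames(rep(1, nrow(g)), g$gene)
  if (!is.null(config$enrichment))
    lambda[names(config$enrichment)] <- config$enrichment
  vt$lambda <- unname(lambda[vt$gene])
  if (any(vt$lambda * vt$q > 0.5))
    warning("enrichment pushes lambda*q above 0.5; clamping case frequency")
  vt$p_case <- pmin(vt$lambda * vt$q, 0.5)

  # per-population panel frequency: NFE tracks q, others jittered; absence
  # by population-specific probability
  pops <- names(config$panel_an)
  for (p in pops) {
    qp <- if (p == "NFE") vt$q else
      pmin(vt$q * exp(stats::rnorm(nrow(vt), 0, config$pop_jitter_sd)), 0.5)
    ab_pr <- if (p %in% names(config$absent_prob)) config$absent_prob[[p]] else 0
    qp[runif(nrow(vt)) < ab_pr] <- 0
    vt[[paste0("q_", p)]] <- qp
  }

  vt$filter <- ifelse(runif(nrow(vt)) < config$tranche_fail_rate,
                      "VQSRTrancheSNP99.00to100.00", "PASS")
  vt$variant_id <- .variant_id(vt$chrom, vt$pos, vt$ref, vt$alt)
  vt
}

#' Generate a reference-panel frequency table
#'
#' One row per variant per population with `AC = round(q * AN)`
#' (round-half-to-even), `AF = AC/AN`. Variants absent from a population emit
#' no row there. Variants whose true `q > 0` rounds to `AC = 0` are kept
#' (frequency zero with known AN) and logged in the `"novel_in_panel"`
#' attribute.
#'
#' @param config A [sim_config()].
#' @return A `panel_table` tibble with the simulated variant truth attached
#'   as attribute `"variants"`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vt <- .sim_variant_set(config)
  pops <- names(config$panel_an)
  rows <- purrr::map(pops, function(p) {
    qp <- vt[[paste0("q_", p)]]
    keep <- qp > 0
    an <- config$panel_an[[p]]
    ac <- round(qp[keep] * an)
    tibble::tibble(CHROM = vt$chrom[keep], POS = vt$pos[keep],
                   REF = vt$ref[keep], ALT = vt$alt[keep],
                   GENE = vt$gene[keep], CONSEQUENCE = vt$consequence[keep],
                   POP = p, AC = ac, AN = an, AF = ac / an)
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$POP, .data$CHROM, .data$POS, .data$ALT)
  novel_in_panel <- tab[tab$AC == 0, c("CHROM", "POS", "REF", "ALT", "POP")]
  if (nrow(novel_in_panel) > 0)
    message(nrow(novel_in_panel),
            " panel row(s) with q > 0 rounded to AC = 0 (novel-in-panel edge)")
  out <- read_panel(tab)
  attr(out, "variants") <- vt
  attr(out, "novel_in_panel") <- novel_in_panel
  out
}

#' Generate a synthetic case cohort
#'
#' Draws per-individual genotypes at the configured variant set, plants
#' multi-variant carriers, injects QC-failing field values at the configured
#' rate, and returns the raw (pre-QC) cohort calls together with the full
#' generating truth.
#'
#' @param config A [sim_config()].
#' @param panel Panel generated from the same config (defaults to
#'   regenerating it); its attached variant truth defines the variant set.
#' @return An `rv_sim` list: `calls` (raw `cohort_calls`), `truth` (variant
#'   truth, planted carriers, injected QC failures), `config`, `panel`.
#' @export
simulate_cohort <- function(config, panel = simulate_panel(config)) {
  stopifnot(inherits(config, "sim_config"))
  vt <- attr(panel, "variants")
  if (is.null(vt)) stop("panel lacks simulated variant truth; generate it with simulate_panel()")
  n <- config$n_cases
  V <- nrow(vt)
  indiv <- sprintf("S%04d", seq_len(n))

  set.seed(config$seed + 1L)
  # variant-major long layout: rows vary individual fastest within variant
  gt <- rbinom(n * V, 2L, rep(vt$p_case, each = n))

  planted <- tibble::tibble(indiv = character(), gene = character(),
                            variant_id = character(), kind = character())
  planted_cells <- integer(0)
  plant <- function(spec, kind) {
    for (gene in names(spec)) {
      vidx <- which(vt$gene == gene)
      if (kind == "syn_mis") {
        cls <- classify_consequence(vt$consequence[vidx])
        pick <- c(vidx[which(cls == "synonymous")[1]],
                  vidx[which(cls == "missense")[1]])
      } else {
        pick <- vidx[seq_len(2)]
      }
      stopifnot(length(pick) == 2, !anyNA(pick))
      carriers <- sample.int(n, spec[[gene]])
      for (ind in carriers) {
        cells <- (pick - 1L) * n + ind
        gt[cells] <<- pmax(gt[cells], 1L)
        planted_cells <<- c(planted_cells, cells)
        planted <<- dplyr::bind_rows(planted, tibble::tibble(
          indiv = indiv[ind], gene = gene, variant_id = vt$variant_id[pick],
          kind = kind))
      }
    }
  }
  if (!is.null(config$planted_pairs)) plant(config$planted_pairs, "pair")
  if (!is.null(config$planted_syn_mis)) plant(config$planted_syn_mis, "syn_mis")

  ncell <- n * V
  ab <- ifelse(gt == 1L, round(runif(ncell, 0.25, 0.75), 3), NA_real_)
  gq <- sample(30:99, ncell, replace = TRUE)
  dp <- sample(15:60, ncell, replace = TRUE)

  # QC-fail injection: one field pushed just outside its threshold. Planted
  # genotypes are exempt so the planting contract survives downstream QC.
  inject <- setdiff(which(runif(ncell) < config$qc_fail_rate), planted_cells)
  fields <- vapply(inject, function(i) {
    if (gt[i] == 1L) sample(c("AB", "GQ", "DP"), 1) else sample(c("GQ", "DP"), 1)
  }, character(1))
  for (k in seq_along(inject)) {
    i <- inject[k]
    switch(fields[k],
           AB = { ab[i] <- round(sample(c(runif(1, 0.02, 0.19),
                                          runif(1, 0.81, 0.98)), 1), 3) },
           GQ = { gq[i] <- sample(0:19, 1) },
           DP = { dp[i] <- sample(0:9, 1) })
  }

  genotypes <- tibble::tibble(
    variant_id = rep(vt$variant_id, each = n),
    indiv = rep(indiv, V),
    gt = as.numeric(gt), ab = ab, gq = as.numeric(gq), dp = as.numeric(dp)
  )
  variants <- tibble::tibble(
    variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
    ref = vt$ref, alt = vt$alt, gene = vt$gene,
    consequence = vt$consequence,
    class = classify_consequence(vt$consequence), filter = vt$filter
  )
  calls <- new_cohort_calls(genotypes, variants, n)

  truth <- list(
    variants = vt,
    planted = planted,
    qc_injected = tibble::tibble(
      variant_id = vt$variant_id[(inject - 1L) %/% n + 1L],
      indiv = indiv[(inject - 1L) %% n + 1L],
      field = fields)
  )
  structure(list(calls = calls, truth = truth, config = config, panel = panel),
            class = "rv_sim")
}

#' @export
print.rv_sim <- function(x, ...) {
  cat("<rv_sim> ", x$config$n_cases, " cases, ", nrow(x$truth$variants),
      " variants, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort calls object as VCF v4.2
#'
#' Emits `GT:AB:GQ:DP` genotypes with fixed numeric formatting so identical
#' objects produce byte-identical files.
#'
#' @param calls A `cohort_calls` object (normally raw, pre-QC).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "cohort_calls"))
  v <- calls$variants |> dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  indiv <- sort(unique(calls$genotypes$indiv))
  gtab <- calls$genotypes |>
    dplyr::mutate(gt_str = dplyr::case_when(
      is.na(.data$gt) ~ "./.",
      .data$gt == 0 ~ "0/0", .data$gt == 1 ~ "0/1", TRUE ~ "1/1"),
      ab_str = ifelse(is.na(.data$ab), ".", sprintf("%.3f", .data$ab)),
      cell = paste0(.data$gt_str, ":", .data$ab_str, ":",
                    ifelse(is.na(.data$gq), ".", sprintf("%d", as.integer(.data$gq))), ":",
                    ifelse(is.na(.data$dp), ".", sprintf("%d", as.integer(.data$dp)))))
  wide <- gtab |>
    dplyr::select("variant_id", "indiv", "cell") |>
    tidyr::pivot_wider(names_from = "indiv", values_from = "cell")
  wide <- wide[match(v$variant_id, wide$variant_id), c("variant_id", indiv)]

  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=rvburden-", as.character(packageVersion("rvburden"))),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=VQSRTrancheSNP99.00to100.00,Description=\"Outside the first VQSR tranche\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance (alt depth over total depth), heterozygous calls\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", indiv), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter, ".",
                "GT:AB:GQ:DP",
                apply(as.matrix(wide[, indiv, drop = FALSE]), 1, paste,
                      collapse = "\t"),
                sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Write all simulation artifacts to a directory
#'
#' Emits `cohort.vcf`, `panel.tsv`, `annotation.tsv`, `genes.txt`,
#' `truth.json` and `config.json`. All files are plain text and byte-stable
#' for a fixed config.
#'
#' @param sim An `rv_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rv_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             panel = file.path(dir, "panel.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             genes = file.path(dir, "genes.txt"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.json"))
  write_cohort_vcf(sim$calls, paths[["vcf"]])

  panel_out <- sim$panel |>
    dplyr::select("CHROM", "POS", "REF", "ALT", "GENE", "CONSEQUENCE",
                  "POP", "AC", "AN", "AF") |>
    dplyr::mutate(AF = sprintf("%.6g", .data$AF))
  readr::write_tsv(panel_out, paths[["panel"]])

  sim$calls$variants |>
    dplyr::select(CHROM = "chrom", POS = "pos", REF = "ref", ALT = "alt",
                  GENE = "gene", CONSEQUENCE = "consequence") |>
    readr::write_tsv(paths[["annotation"]])

  readr::write_lines(sim$config$genes$gene, paths[["genes"]])

  jsonlite::write_json(list(variants = sim$truth$variants,
                            planted = sim$truth$planted,
                            qc_injected = sim$truth$qc_injected),
                       paths[["truth"]], digits = NA, auto_unbox = TRUE)
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(paths)
}

#' Generate a ref/alt sequence pair with a planted splice site
#'
#' Searches for a k-mer whose score under `matrix` falls inside
#' `target_band`, then derives the reference sequence by mutating one base of
#' that k-mer (choosing the single-base change that moves the score furthest
#' down, so the variant creates the site). Both k-mers are embedded at the
#' same position in random flanking sequence.
#'
#' @param matrix A [splice_matrix()].
#' @param target_band Numeric `c(lo, hi)` band for the planted alt-site
#'   score on the 0-100 scale.
#' @param seed Integer seed.
#' @param flank Flanking bases on each side.
#' @param max_tries Bounded search effort before failing.
#' @return List with `ref_seq`, `alt_seq`, `site_start` (1-based position of
#'   the planted k-mer), `variant_pos` (1-based changed base), `alt_score`.
#' @export
simulate_splice_region <- function(matrix, target_band, seed = 1L,
                                   flank = 20L, max_tries = 5000L) {
  stopifnot(inherits(matrix, "splice_matrix"), length(target_band) == 2,
            target_band[1] <= target_band[2])
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  k <- matrix$k
  in_band <- function(s) s >= target_band[1] && s <= target_band[2]

  # hill-climb single-base moves toward the band, random restarts
  kmer <- NULL
  for (try in seq_len(max_tries)) {
    cand <- if (try == 1 && target_band[1] >= 100) consensus_kmer(matrix)
            else if (try == 1 && target_band[2] <= 0) anticonsensus_kmer(matrix)
            else paste(sample(bases, k, replace = TRUE), collapse = "")
    for (step in seq_len(4L * k)) {
      s <- score_site(cand, matrix)
      if (in_band(s)) { kmer <- cand; break }
      moves <- .one_base_neighbours(cand)
      ms <- score_site(moves, matrix)
      target <- if (s < target_band[1]) which.max(ms) else which.min(ms)
      if ((s < target_band[1] && max(ms) <= s) ||
          (s > target_band[2] && min(ms) >= s)) break
      cand <- moves[target]
    }
    if (!is.null(kmer)) break
  }
  if (is.null(kmer))
    stop("no k-mer with score in [", target_band[1], ", ", target_band[2],
         "] reachable within the search budget")

  # reference k-mer: the single-base change that lowers the score most
  neigh <- .one_base_neighbours(kmer)
  ref_kmer <- neigh[which.min(score_site(neigh, matrix))]
  mut_at <- which(strsplit(ref_kmer, "")[[1]] != strsplit(kmer, "")[[1]])

  fl_l <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  fl_r <- paste(sample(bases, flank, replace = TRUE), collapse = "")
  list(ref_seq = paste0(fl_l, ref_kmer, fl_r),
       alt_seq = paste0(fl_l, kmer, fl_r),
       site_start = flank + 1L,
       variant_pos = flank + mut_at,
       alt_score = score_site(kmer, matrix))
}

.one_base_neighbours <- function(kmer) {
  ch <- strsplit(kmer, "")[[1]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(bases, ch[i])) {
      x <- ch; x[i] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}
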