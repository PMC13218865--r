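# Case-cohort variant table: VCF input, genotype-level QC, consequence
# annotation, gene restriction.

#' Genotype-level quality-control thresholds
#'
#' Defaults follow standard short-read germline practice: allele balance in
#' \[0.2, 0.8\] for heterozygous genotypes, genotype quality >= 20, depth
#' >= 10 for diploid (>= 5 for haploid) calls, and a site-level VQSR tranche
#' filter requiring the pass label. All boundaries are inclusive.
#'
#' @param ab_range Allele-balance bounds (alt depth / total depth), het calls only.
#' @param gq_min Minimum genotype quality (phred).
#' @param dp_min Minimum read depth, diploid calls.
#' @param dp_min_haploid Minimum read depth, haploid calls.
#' @param tranche_pass Site FILTER value accepted as passing.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(ab_range = c(0.2, 0.8), gq_min = 20, dp_min = 10,
                          dp_min_haploid = 5, tranche_pass = "PASS") {
  stopifnot(length(ab_range) == 2, ab_range[1] >= 0, ab_range[1] < ab_range[2],
            ab_range[2] <= 1, gq_min >= 0, dp_min >= 0, dp_min_haploid >= 0,
            is.character(tranche_pass), length(tranche_pass) == 1)
  structure(list(ab_range = as.numeric(ab_range), gq_min = gq_min,
                 dp_min = dp_min, dp_min_haploid = dp_min_haploid,
                 tranche_pass = tranche_pass),
            class = "qc_thresholds")
}

#' Apply genotype-level QC
#'
#' Vectorised pass/fail decision for called genotypes. A genotype fails with
#' the first applicable reason among `MISSING_FIELD` (a required field is
#' absent), `AB` (heterozygous allele balance outside the inclusive range),
#' `GQ`, and `DP`. Allele balance is only assessed for heterozygous calls.
#' Uncalled genotypes (`gt` is `NA`) pass through unchanged with no reason.
#'
#' @param gt Alt-allele dosage per call: 0, 1, 2 or `NA` (uncalled).
#' @param ab Allele balance (alt depth / total depth); may be `NA` for
#'   non-heterozygous calls without penalty.
#' @param gq Genotype quality.
#' @param dp Read depth.
#' @param thresholds A [qc_thresholds()] object.
#' @param ploidy 2 (default) or 1; selects the depth threshold.
#' @return A tibble with logical `pass` and character `reason`
#'   (`NA` when passing).
#' @examples
#' apply_genotype_qc(1, ab = 0.19, gq = 99, dp = 30)  # fails AB
#' apply_genotype_qc(1, ab = 0.20, gq = 20, dp = 10)  # inclusive boundaries pass
#' @export
apply_genotype_qc <- function(gt, ab = NA_real_, gq = NA_real_, dp = NA_real_,
                              thresholds = qc_thresholds(), ploidy = 2L) {
  stopifnot(inherits(thresholds, "qc_thresholds"), ploidy %in% c(1L, 2L))
  n <- length(gt)
  ab <- rep_len(ab, n); gq <- rep_len(gq, n); dp <- rep_len(dp, n)
  het <- !is.na(gt) & gt == 1
  called <- !is.na(gt)
  dp_min <- if (ploidy == 2L) thresholds$dp_min else thresholds$dp_min_haploid

  reason <- rep(NA_character_, n)
  miss <- called & (is.na(gq) | is.na(dp) | (het & is.na(ab)))
  reason[miss] <- "MISSING_FIELD"
  fail_ab <- called & is.na(reason) & het &
    (ab < thresholds$ab_range[1] | ab > thresholds$ab_range[2])
  reason[fail_ab] <- "AB"
  fail_gq <- called & is.na(reason) & gq < thresholds$gq_min
  reason[fail_gq] <- "GQ"
  fail_dp <- called & is.na(reason) & dp < dp_min
  reason[fail_dp] <- "DP"

  tibble::tibble(pass = is.na(reason), reason = reason)
}

#' Sequence-Ontology consequence to burden class
#'
#' Loss-of-function covers stop-gained, frameshift, splice donor/acceptor and
#' start-lost terms; missense and synonymous map to their own classes and
#' everything else is `other`.
#'
#' @param term Character vector of Sequence-Ontology-style consequence terms.
#' @return Character vector over `missense`, `lof`, `synonymous`, `other`.
#' @examples
#' classify_consequence(c("stop_gained", "missense_variant", "intron_variant"))
#' @export
classify_consequence <- function(term) {
  lof_terms <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
                 "splice_donor_variant", "start_lost")
  dplyr::case_when(
    term %in% lof_terms ~ "lof",
    term == "missense_variant" ~ "missense",
    term == "synonymous_variant" ~ "synonymous",
    TRUE ~ "other"
  )
}

.variant_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Assemble a cohort calls object
#'
#' Internal constructor shared by [read_cohort_vcf()] and the simulator. The
#' genotype table is long: one row per variant per individual.
#'
#' @param genotypes Tibble with columns `variant_id`, `indiv`, `gt`, `ab`,
#'   `gq`, `dp`.
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `class`, `filter`.
#' @param n_individuals Cohort size.
#' @param thresholds QC thresholds already applied.
#' @param audit QC audit tibble (one row per genotype set to missing, plus
#'   site-level tranche exclusions).
#' @return A `cohort_calls` object.
#' @keywords internal
new_cohort_calls <- function(genotypes, variants, n_individuals,
                             thresholds = qc_thresholds(),
                             audit = tibble::tibble()) {
  structure(list(genotypes = genotypes, variants = variants,
                 n_individuals = n_individuals, thresholds = thresholds,
                 audit = audit),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat("<cohort_calls> ", nrow(x$variants), " variants x ", x$n_individuals,
      " individuals; ", nrow(x$audit), " QC-failed genotypes\n", sep = "")
  invisible(x)
}

.parse_gt_string <- function(gt) {
  # phase-agnostic alt dosage from GT strings; any non-ref allele index counts
  gt <- sub("\\|", "/", gt)
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0", "0")] <- 0
  out[gt %in% c("0/1", "1/0")] <- 1
  out[gt %in% c("1/1", "1")] <- 2
  out
}

#' Read a case-cohort VCF with genotype QC
#'
#' Reads a VCF v4.2 with per-genotype `GT:AB:GQ:DP` fields, splits
#' multi-allelic records into biallelic rows, applies the site-level tranche
#' filter and genotype-level QC, and joins consequence annotations. Failed
#' genotypes are set to missing and logged in the audit table.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param annotation Annotation tibble or TSV path with columns
#'   `CHROM, POS, REF, ALT, GENE, CONSEQUENCE`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A `cohort_calls` object.
#' @export
read_cohort_vcf <- function(path, annotation, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_mat <- vcf@gt
  samples <- colnames(gt_mat)[-1]
  n_indiv <- length(samples)

  if (nrow(fix) == 0) {
    return(new_cohort_calls(
      genotypes = tibble::tibble(variant_id = character(), indiv = character(),
                                 gt = numeric(), ab = numeric(), gq = numeric(),
                                 dp = numeric()),
      variants = tibble::tibble(variant_id = character(), chrom = character(),
                                pos = integer(), ref = character(),
                                alt = character(), gene = character(),
                                consequence = character(), class = character(),
                                filter = character()),
      n_individuals = n_indiv, thresholds = thresholds))
  }

  fmt <- unique(gt_mat[, "FORMAT"])
  if (!all(vapply(strsplit(fmt, ":"), function(f)
    all(c("GT", "AB", "GQ", "DP") %in% f), logical(1)))) {
    stop("unsupported FORMAT layout; need GT, AB, GQ and DP fields")
  }

  field <- function(el) {
    m <- vcfR::extract.gt(vcf, element = el, as.numeric = el != "GT")
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(fix))
    m
  }
  gt_raw <- field("GT"); ab_m <- field("AB"); gq_m <- field("GQ"); dp_m <- field("DP")

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(sub("\\|", "/", gt_raw[i, ]), "/", fixed = TRUE)
    purrr::map(seq_along(alts), function(k) {
      dose <- unname(vapply(alleles, function(al) {
        if (length(al) == 0 || any(al == ".") || any(is.na(al))) return(NA_real_)
        sum(al == as.character(k))
      }, numeric(1)))
      tibble::tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        filter = fix$FILTER[i] %||% "PASS",
        indiv = samples, gt = dose,
        ab = unname(ab_m[i, ]), gq = unname(gq_m[i, ]), dp = unname(dp_m[i, ])
      )
    })
  })
  long <- dplyr::bind_rows(purrr::flatten(rows))
  if (any(is.na(long$pos))) stop("malformed VCF record: non-integer POS")
  if (any(long$ref == long$alt)) stop("malformed VCF record: REF equals ALT")
  long$variant_id <- .variant_id(long$chrom, long$pos, long$ref, long$alt)

  variants <- long |>
    dplyr::distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$filter)
  ann <- annotation |>
    dplyr::mutate(variant_id = .variant_id(.data$CHROM, .data$POS, .data$REF,
                                           .data$ALT)) |>
    dplyr::select("variant_id", gene = "GENE", consequence = "CONSEQUENCE")
  variants <- variants |>
    dplyr::left_join(ann, by = "variant_id") |>
    dplyr::mutate(class = classify_consequence(.data$consequence)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)

  genotypes <- long |>
    dplyr::select("variant_id", "indiv", "gt", "ab", "gq", "dp")

  qc_cohort(new_cohort_calls(genotypes, variants, n_indiv, thresholds))
}

#' Apply genotype and site QC to a cohort calls object
#'
#' Runs [apply_genotype_qc()] over every call, applies the site-level
#' tranche filter (sites whose FILTER is not the configured pass label are
#' excluded wholesale, their called genotypes logged with reason `TRANCHE`),
#' sets failed genotypes to missing and records the audit table. Applying QC
#' twice is a no-op: already-missing genotypes pass through.
#'
#' @param calls A `cohort_calls` object (raw or already QC'd).
#' @param thresholds A [qc_thresholds()] object; defaults to the thresholds
#'   stored on the object.
#' @return The QC'd `cohort_calls`.
#' @export
qc_cohort <- function(calls, thresholds = NULL) {
  stopifnot(inherits(calls, "cohort_calls"))
  thresholds <- thresholds %||% calls$thresholds
  g <- calls$genotypes
  site_fail <- calls$variants$variant_id[calls$variants$filter !=
                                           thresholds$tranche_pass]
  qc <- apply_genotype_qc(g$gt, g$ab, g$gq, g$dp, thresholds)
  tranche <- g$variant_id %in% site_fail & !is.na(g$gt)
  qc$reason[tranche] <- "TRANCHE"
  qc$pass[tranche] <- FALSE

  new_audit <- tibble::tibble(variant_id = g$variant_id, indiv = g$indiv,
                              reason = qc$reason)[!qc$pass & !is.na(g$gt), ]
  g$gt[!qc$pass] <- NA_real_
  calls$genotypes <- g
  calls$variants <- calls$variants[!calls$variants$variant_id %in% site_fail, ]
  calls$genotypes <- dplyr::semi_join(calls$genotypes, calls$variants,
                                      by = "variant_id")
  calls$thresholds <- thresholds
  calls$audit <- dplyr::bind_rows(calls$audit, new_audit)
  calls
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `CHROM, POS, REF, ALT, GENE, CONSEQUENCE`.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(CHROM = "c", POS = "i",
                                                 REF = "c", ALT = "c",
                                                 GENE = "c", CONSEQUENCE = "c"))
  need <- c("CHROM", "POS", "REF", "ALT", "GENE", "CONSEQUENCE")
  if (!all(need %in% names(ann))) stop("annotation table missing columns: ",
                                       paste(setdiff(need, names(ann)), collapse = ", "))
  ann
}

#' Restrict a cohort to a curated gene set
#'
#' Gene symbols match exactly and case-sensitively; records outside the list
#' are dropped and the drop count is recorded in the audit attribute and
#' reported as a message.
#'
#' @param calls A `cohort_calls` object.
#' @param gene_list Character vector of gene symbols (or path to a
#'   one-symbol-per-line file).
#' @return A filtered `cohort_calls` object.
#' @export
restrict_to_genes <- function(calls, gene_list) {
  stopifnot(inherits(calls, "cohort_calls"))
  if (length(gene_list) == 1 && file.exists(gene_list))
    gene_list <- read_gene_list(gene_list)
  if (length(gene_list) == 0) stop("gene_list must be nonempty")
  keep <- calls$variants$gene %in% gene_list
  dropped <- sum(!keep)
  if (all(!keep)) warning("no variants fall in the supplied gene list")
  message(dropped, " variant record(s) outside the gene list dropped")
  calls$variants <- calls$variants[keep, ]
  calls$genotypes <- dplyr::semi_join(calls$genotypes, calls$variants,
                                      by = "variant_id")
  attr(calls, "dropped_off_target") <- dropped
  calls
}

#' Read a one-symbol-per-line gene list
#' @param path Text file, one gene symbol per line; blank lines and `#`
#'   comments ignored.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Per-variant alt-allele counts across the cohort
#'
#' @param calls A `cohort_calls` object.
#' @return Tibble `variant_id`, `ac` (alt alleles), `n_called` (individuals
#'   with a non-missing genotype).
#' @export
variant_allele_counts <- function(calls) {
  stopifnot(inherits(calls, "cohort_calls"))
  calls$genotypes |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(ac = sum(.data$gt, na.rm = TRUE),
                     n_called = sum(!is.na(.data$gt)), .groups = "drop")
}
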