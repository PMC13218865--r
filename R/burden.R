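# Gene-level burden scan: rarity filtering, collapsing, exact 2x2
# statistics, multiple-testing over the gene family, and prioritisation.
#
# Collapsing aggregates alt-allele counts across a gene's qualifying
# variants before testing (frequencies are aggregated, not per-variant
# tables): case alt count a out of A = 2N alleles versus control alt count
# b (summed panel AC) out of B = the median per-variant panel AN. The cohort
# N is fixed; per-variant missing genotypes reduce only that variant's
# contribution.

#' Prioritisation criteria for significant burden
#'
#' A gene is prioritised when its FDR-adjusted p-value falls below `fdr_max`
#' and its odds ratio exceeds `or_min` in the primary panel; upstream, the
#' rarity filter excludes variants above `csvs_af_max` in the Spanish
#' reference panel.
#'
#' @param or_min Minimum odds ratio (default 5).
#' @param fdr_max Maximum BH-adjusted p (default 0.05).
#' @param csvs_af_max Maximum CSVS allele frequency for a qualifying variant
#'   (default 0.05, strict inequality: exactly 0.05 is retained).
#' @return A `prioritisation_criteria` list.
#' @export
prioritisation_criteria <- function(or_min = 5, fdr_max = 0.05,
                                    csvs_af_max = 0.05) {
  stopifnot(or_min > 0, fdr_max > 0, fdr_max <= 1, csvs_af_max >= 0)
  structure(list(or_min = or_min, fdr_max = fdr_max,
                 csvs_af_max = csvs_af_max),
            class = "prioritisation_criteria")
}

#' Drop variants common in the Spanish reference panel
#'
#' Removes cohort variants whose allele frequency in the rarity population
#' (CSVS by default) strictly exceeds the cutoff; variants absent from that
#' panel are retained as novelty candidates. Survivors are annotated with
#' per-population frequencies and the novelty flag.
#'
#' @param calls A QC'd `cohort_calls` object.
#' @param panel A `panel_table`.
#' @param criteria A [prioritisation_criteria()].
#' @param population Panel population used for the rarity cut.
#' @param populations Populations annotated onto survivors.
#' @return The filtered `cohort_calls`; per-variant panel annotation is
#'   attached to `$variants` (columns `af_<pop>` and `novel`), and the drop
#'   count to attribute `"dropped_common"`.
#' @export
rarity_filter <- function(calls, panel, criteria = prioritisation_criteria(),
                          population = "CSVS",
                          populations = c("NFE", "Global", "CSVS")) {
  stopifnot(inherits(calls, "cohort_calls"), inherits(panel, "panel_table"))
  look <- panel_lookup(panel, calls$variants$variant_id, populations)
  wide <- look |>
    dplyr::select("variant_id", "population", "AF") |>
    tidyr::pivot_wider(names_from = "population", values_from = "AF",
                       names_prefix = "af_")
  novelty <- attr(look, "novelty")
  v <- calls$variants |>
    dplyr::left_join(wide, by = "variant_id") |>
    dplyr::left_join(novelty, by = "variant_id")
  rar_col <- paste0("af_", population)
  common <- !is.na(v[[rar_col]]) & v[[rar_col]] > criteria$csvs_af_max
  dropped <- sum(common)
  if (dropped > 0)
    message(dropped, " variant(s) above AF ", criteria$csvs_af_max, " in ",
            population, " dropped")
  calls$variants <- v[!common, ]
  calls$genotypes <- dplyr::semi_join(calls$genotypes, calls$variants,
                                      by = "variant_id")
  attr(calls, "dropped_common") <- dropped
  calls
}

#' Collapse one gene's qualifying variants to an aggregate allele count
#'
#' @param calls A QC'd (and typically rarity-filtered) `cohort_calls`.
#' @param gene Gene symbol.
#' @param classes Qualifying variant classes.
#' @return List: `ac` (aggregate case alt alleles), `allele_number` (2N,
#'   constant across genes), `case_maf`, `n_variants`, `variant_ids`.
#' @examples
#' # a TLR9-like gene with 7 variants totalling 8 alt alleles in 371 cases
#' # has case MAF 8/742 = 0.0108
#' @export
collapse_gene <- function(calls, gene, classes = c("missense", "lof")) {
  stopifnot(inherits(calls, "cohort_calls"))
  v <- calls$variants[calls$variants$gene %in% gene &
                        calls$variants$class %in% classes, ]
  A <- 2 * calls$n_individuals
  if (nrow(v) == 0)
    return(list(ac = 0, allele_number = A, case_maf = 0, n_variants = 0,
                variant_ids = character(0)))
  acs <- calls$genotypes |>
    dplyr::filter(.data$variant_id %in% v$variant_id) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(ac = sum(.data$gt, na.rm = TRUE), .groups = "drop")
  ac <- sum(acs$ac)
  list(ac = ac, allele_number = A, case_maf = ac / A, n_variants = nrow(v),
       variant_ids = v$variant_id)
}

#' Gene-burden scan against reference panels
#'
#' Runs the full per-gene collapsing test for every gene in the family, per
#' variant class and per panel population: aggregate case and control allele
#' counts, sample (or conditional-MLE) odds ratio, exact conditional 95% CI,
#' two-sided Fisher exact p, and Bonferroni and BH adjustment over the gene
#' family (all genes in `gene_list`, adjusted separately per population and
#' class). The significance flag requires FDR < `fdr_max` and OR >
#' `or_min` in the primary panel.
#'
#' @param calls A QC'd, rarity-filtered `cohort_calls`.
#' @param panel A `panel_table`.
#' @param gene_list Gene family tested (drives the correction burden `m`).
#' @param populations Panel populations tested.
#' @param primary Population whose FDR/OR drive the significance flag.
#' @param classes Named list of variant-class groupings; the default tests
#'   the functional (missense + lof) burden with a synonymous control track.
#' @param criteria A [prioritisation_criteria()].
#' @param default_an Named fallback allele numbers per population for
#'   frequency-only or absent panel entries.
#' @param or_method `"sample"` or `"cmle"` (see [odds_ratio()]).
#' @param ci Compute exact CIs (disable to speed up large simulation scans).
#' @return An `rv_burden` object: a tibble with one row per gene x class x
#'   population plus scan metadata attributes.
#' @export
burden_scan <- function(calls, panel, gene_list,
                        populations = c("NFE", "Global", "CSVS"),
                        primary = "NFE",
                        classes = list(functional = c("missense", "lof"),
                                       synonymous = "synonymous"),
                        criteria = prioritisation_criteria(),
                        default_an = c(NFE = 68058, Global = 152312,
                                       CSVS = 4074),
                        or_method = "sample", ci = TRUE) {
  stopifnot(inherits(calls, "cohort_calls"), inherits(panel, "panel_table"),
            length(gene_list) > 0, primary %in% populations)
  A <- 2 * calls$n_individuals
  m <- length(gene_list)

  # per-variant case allele counts and control counts, computed once
  vtab <- calls$variants |>
    dplyr::left_join(variant_allele_counts(calls), by = "variant_id") |>
    dplyr::mutate(ac = dplyr::coalesce(.data$ac, 0))
  if (!"novel" %in% names(vtab)) vtab$novel <- NA
  look <- panel_lookup(panel, vtab$variant_id, populations)
  ctrl <- look |>
    dplyr::group_by(.data$population) |>
    dplyr::group_modify(function(d, key) {
      cc <- control_counts(af = d$AF, ac = d$AC, an = d$AN,
                           default_an = default_an[[key$population]])
      tibble::tibble(variant_id = d$variant_id, b = cc$b, B = cc$B)
    }) |>
    dplyr::ungroup()

  grid <- tidyr::expand_grid(gene = gene_list,
                             class = names(classes),
                             population = populations)
  rows <- purrr::imap(classes, function(cls, cls_name) {
    sub <- vtab[vtab$class %in% cls & vtab$gene %in% gene_list, ]
    case_side <- sub |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_variants = dplyr::n(), ac = sum(.data$ac),
                       n_novel = sum(.data$novel), .groups = "drop")
    ctrl_side <- sub |>
      dplyr::select("variant_id", "gene") |>
      dplyr::inner_join(ctrl, by = "variant_id",
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$gene, .data$population) |>
      dplyr::summarise(control_ac = sum(.data$b), control_an = median(.data$B),
                       .groups = "drop")
    grid[grid$class == cls_name, ] |>
      dplyr::left_join(case_side, by = "gene") |>
      dplyr::left_join(ctrl_side, by = c("gene", "population"))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      n_variants = dplyr::coalesce(.data$n_variants, 0L),
      ac = dplyr::coalesce(.data$ac, 0),
      case_maf = .data$ac / A,
      control_an = dplyr::coalesce(.data$control_an,
                                   unname(default_an[.data$population])),
      control_ac = dplyr::coalesce(.data$control_ac, 0),
      control_maf = .data$control_ac / .data$control_an)
  if (any(rows$control_ac > rows$control_an))
    stop("aggregate control alt count exceeds the panel allele number")

  a <- rows$ac; b <- rows$control_ac
  cc <- A - a; dd <- rows$control_an - b
  rows$odds_ratio <- odds_ratio(a, cc, b, dd, method = or_method)
  rows$p <- fisher_exact_p(a, cc, b, dd)
  if (ci) {
    cis <- exact_ci(a, cc, b, dd)
    rows$ci_lo <- cis$ci_lo; rows$ci_hi <- cis$ci_hi
  } else {
    rows$ci_lo <- NA_real_; rows$ci_hi <- NA_real_
  }

  rows <- rows |>
    dplyr::group_by(.data$class, .data$population) |>
    dplyr::mutate(p_bonferroni = adjust_multiple(.data$p, "bonferroni",
                                                 family_size = m),
                  q_fdr = adjust_multiple(.data$p, "bh", family_size = m)) |>
    dplyr::ungroup()

  prim <- rows |>
    dplyr::filter(.data$population == primary) |>
    dplyr::mutate(significant = .data$q_fdr < criteria$fdr_max &
                    .data$odds_ratio > criteria$or_min) |>
    dplyr::select("gene", "class", "significant")
  rows <- dplyr::left_join(rows, prim, by = c("gene", "class"))

  structure(rows, class = c("rv_burden", class(rows)),
            n_cases = calls$n_individuals, family_size = m,
            primary = primary, criteria = criteria, or_method = or_method)
}

#' @export
tidy.rv_burden <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
glance.rv_burden <- function(x, ...) {
  prim <- x[x$population == attr(x, "primary"), ]
  func <- prim[prim$class == "functional", ]
  if (nrow(func) == 0) func <- prim
  tibble::tibble(
    n_genes = attr(x, "family_size"),
    n_cases = attr(x, "n_cases"),
    primary_panel = attr(x, "primary"),
    n_significant = sum(func$significant, na.rm = TRUE),
    median_or = median(func$odds_ratio[is.finite(func$odds_ratio) &
                                         func$ac > 0], na.rm = TRUE)
  )
}

#' @export
autoplot.rv_burden <- function(object, population = attr(object, "primary"),
                               class = "functional", ...) {
  d <- object[object$population == population & object$class == class, ]
  d$log_or <- log2(pmax(pmin(d$odds_ratio, 1024), 1 / 1024))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_or,
                                  y = -log10(pmax(.data$q_fdr, 1e-20)),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "criteria")$fdr_max),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = log2(attr(object, "criteria")$or_min),
                        linetype = 2) +
    ggplot2::labs(x = "log2 odds ratio (capped)", y = "-log10 FDR q",
                  title = paste0("Gene burden, ", class, " class vs ",
                                 population)) +
    ggplot2::theme_minimal()
}

#' Write a burden report TSV
#'
#' One row per gene and class with per-population MAF/OR/CI/p/FDR columns
#' side by side, mirroring how such scans are reported in print.
#'
#' @param scan An `rv_burden` object.
#' @param path Output TSV.
#' @param hash Optional config hash; when given, written as a leading
#'   `# config_hash:` comment line.
#' @return `path`, invisibly.
#' @export
write_burden_report <- function(scan, path, hash = NULL) {
  wide <- tidy(scan) |>
    dplyr::select("gene", "class", "population", "n_variants", "ac",
                  "case_maf", "control_maf", "odds_ratio", "ci_lo", "ci_hi",
                  "p", "p_bonferroni", "q_fdr", "significant") |>
    tidyr::pivot_wider(names_from = "population",
                       values_from = c("control_maf", "odds_ratio", "ci_lo",
                                       "ci_hi", "p", "p_bonferroni", "q_fdr"),
                       names_sep = "_")
  if (!is.null(hash)) {
    readr::write_lines(paste0("# config_hash: ", hash), path)
    readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(wide, path)
  }
  invisible(path)
}
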