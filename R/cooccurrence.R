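# Per-individual co-occurrence of qualifying variants within a gene.
#
# "Haplotype" in the clinical-report sense here means unphased co-occurrence
# in one individual: the underlying calls are unphased short-read genotypes,
# so the report speaks of co-occurrence, not phase. A homozygous-alt call
# counts as one distinct variant carried.

#' Find individuals carrying multiple qualifying variants in one gene
#'
#' @param calls A QC'd `cohort_calls` object.
#' @param gene_list Optional gene restriction.
#' @param min_variants Minimum distinct variants carried (default 2).
#' @param classes Qualifying variant classes (default missense + lof).
#' @return Tibble `indiv, gene, n_variants, variant_ids (list), classes
#'   (list), genotypes (list), multi_carrier`, ordered by (gene, indiv).
#' @export
find_multicarriers <- function(calls, gene_list = NULL, min_variants = 2,
                               classes = c("missense", "lof")) {
  carried <- .carried_variants(calls, gene_list, classes)
  out <- carried |>
    dplyr::group_by(.data$indiv, .data$gene) |>
    dplyr::summarise(n_variants = dplyr::n_distinct(.data$variant_id),
                     variant_ids = list(sort(.data$variant_id)),
                     classes = list(.data$class),
                     genotypes = list(.data$gt), .groups = "drop") |>
    dplyr::filter(.data$n_variants >= min_variants) |>
    dplyr::mutate(multi_carrier = .data$n_variants >= 2) |>
    dplyr::arrange(.data$gene, .data$indiv)
  out
}

.carried_variants <- function(calls, gene_list, classes) {
  stopifnot(inherits(calls, "cohort_calls"))
  v <- calls$variants
  if (!is.null(gene_list)) v <- v[v$gene %in% gene_list, ]
  if (!is.null(classes)) v <- v[v$class %in% classes, ]
  calls$genotypes |>
    dplyr::filter(!is.na(.data$gt), .data$gt > 0) |>
    dplyr::inner_join(v[, c("variant_id", "gene", "class")], by = "variant_id")
}

#' Individuals sharing a synonymous and a missense variant in one gene
#'
#' All per-individual pairings of a carried synonymous variant with a
#' carried missense variant in the same gene. An empty result reproduces the
#' negative finding that synonymous burden does not travel with the missense
#' variants in the same carriers.
#'
#' @param calls A QC'd `cohort_calls` object.
#' @param gene_list Optional gene restriction.
#' @return Tibble `indiv, gene, syn_variant, mis_variant`.
#' @export
syn_mis_sharing <- function(calls, gene_list = NULL) {
  carried <- .carried_variants(calls, gene_list,
                               classes = c("synonymous", "missense"))
  syn <- carried[carried$class == "synonymous",
                 c("indiv", "gene", "variant_id")]
  mis <- carried[carried$class == "missense",
                 c("indiv", "gene", "variant_id")]
  dplyr::inner_join(syn, mis, by = c("indiv", "gene"),
                    suffix = c("_syn", "_mis"),
                    relationship = "many-to-many") |>
    dplyr::rename(syn_variant = "variant_id_syn",
                  mis_variant = "variant_id_mis") |>
    dplyr::arrange(.data$gene, .data$indiv)
}

#' Write a carrier report TSV
#'
#' @param carriers Output of [find_multicarriers()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_carrier_report <- function(carriers, path) {
  flat <- carriers |>
    tidyr::unnest(c("variant_ids", "classes", "genotypes")) |>
    dplyr::rename(variant = "variant_ids", class = "classes",
                  genotype = "genotypes")
  readr::write_tsv(flat, path)
  invisible(path)
}
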