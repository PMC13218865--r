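# Reference-panel allele frequencies used as pseudo-controls.
#
# A panel table has one row per variant per population. Absence of a row is
# informative: the variant was never observed in that population (novelty),
# which is distinct from an observed frequency of zero.

#' Population tags recognised in panel tables
#' @export
panel_populations <- function() {
  c("NFE", "Global", "CSVS", "EAS", "AMR", "FIN", "SAS", "ASH", "AFR")
}

#' Read or validate a reference-panel frequency table
#'
#' Accepts a TSV path or a data frame with columns
#' `CHROM, POS, REF, ALT, GENE, CONSEQUENCE, POP, AC, AN, AF`. `AC`/`AN` may
#' be `NA` for frequency-only dialects (CSVS publishes frequencies without
#' counts); when both counts are present `AF` is recomputed from them.
#'
#' @param x TSV path or data frame.
#' @return A `panel_table` tibble keyed by (variant, population).
#' @export
read_panel <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_tsv(x, show_col_types = FALSE, comment = "#",
                    col_types = readr::cols(CHROM = "c", POS = "i", REF = "c",
                                            ALT = "c", GENE = "c",
                                            CONSEQUENCE = "c", POP = "c",
                                            AC = "d", AN = "d", AF = "d"))
  } else tibble::as_tibble(x)
  need <- c("CHROM", "POS", "REF", "ALT", "POP", "AC", "AN", "AF")
  if (!all(need %in% names(tab)))
    stop("panel table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$variant_id <- .variant_id(tab$CHROM, tab$POS, tab$REF, tab$ALT)
  if (anyDuplicated(tab[c("variant_id", "POP")]))
    stop("duplicate (variant, population) rows in panel table")
  both <- !is.na(tab$AC) & !is.na(tab$AN)
  if (any(both & (tab$AC > tab$AN | tab$AC < 0)))
    stop("panel rows with AC > AN (or negative AC)")
  tab$AF[both] <- tab$AC[both] / tab$AN[both]
  if (any(is.na(tab$AF))) stop("panel rows with neither AF nor AC/AN")
  class(tab) <- c("panel_table", class(tab))
  tab
}

#' Look up case variants in the reference panels
#'
#' One row per requested variant per requested population; populations in
#' which the variant is absent appear with `absent = TRUE` and `NA`
#' frequency. The `novel` flag (on the per-variant summary attached as
#' attribute `"novelty"`) marks variants absent from every requested
#' population.
#'
#' @param panel A `panel_table`.
#' @param variant_id Character vector of `chrom:pos:ref:alt` keys.
#' @param populations Populations to query.
#' @return Tibble `variant_id, population, AC, AN, AF, absent`.
#' @export
panel_lookup <- function(panel, variant_id,
                         populations = c("NFE", "Global", "CSVS")) {
  stopifnot(inherits(panel, "panel_table"))
  if (length(populations) == 0) {
    return(tibble::tibble(variant_id = character(), population = character(),
                          AC = numeric(), AN = numeric(), AF = numeric(),
                          absent = logical()))
  }
  grid <- tidyr::expand_grid(variant_id = unique(variant_id),
                             population = populations)
  hit <- panel |>
    dplyr::select("variant_id", population = "POP", "AC", "AN", "AF") |>
    dplyr::filter(.data$population %in% populations)
  out <- grid |>
    dplyr::left_join(hit, by = c("variant_id", "population")) |>
    dplyr::mutate(absent = is.na(.data$AF))
  novelty <- out |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(novel = all(.data$absent), .groups = "drop")
  attr(out, "novelty") <- novelty
  out
}

#' Control allele counts from a panel frequency
#'
#' Converts a panel observation into the (alt, total) allele pair that enters
#' the control row of the 2x2 table. Known counts pass through; a bare
#' frequency is converted with round-half-to-even of `AF * AN` against the
#' supplied allele number; an absent variant contributes zero alt alleles out
#' of the configured default allele number.
#'
#' @param af Allele frequency (`NA` when absent).
#' @param ac,an Allele count/number when the panel publishes them.
#' @param default_an Allele number to assume for frequency-only or absent
#'   rows; required in those cases.
#' @return Tibble with columns `b` (alt alleles) and `B` (total alleles).
#' @examples
#' control_counts(af = 7.84e-5, default_an = 68058)   # b = 5
#' control_counts(af = NA, default_an = 68058)        # absent: b = 0
#' @export
control_counts <- function(af = NA_real_, ac = NA_real_, an = NA_real_,
                           default_an = NULL) {
  n <- max(length(af), length(ac), length(an))
  af <- rep_len(af, n); ac <- rep_len(ac, n); an <- rep_len(an, n)
  B <- ifelse(!is.na(an), an, NA_real_)
  if (any(is.na(B))) {
    if (is.null(default_an)) stop("panel AN unknown; supply default_an explicitly")
    B[is.na(B)] <- default_an
  }
  b <- dplyr::case_when(
    !is.na(ac) ~ ac,
    !is.na(af) ~ round(af * B),   # round() is round-half-to-even in R
    TRUE ~ 0                      # absent from the panel
  )
  tibble::tibble(b = b, B = B)
}
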