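# Missense-variant density along a gene's coding sequence and constrained
# (low-density) region calls. CDS coordinates are 0-based half-open
# internally; windows tile the CDS with a configurable step, the last window
# truncated at the CDS end and normalised by its actual length.

#' Sliding-window variant density along a CDS
#'
#' @param positions Distinct 0-based CDS coordinates of (typically panel
#'   missense) variants; must lie in `[0, cds_length)`.
#' @param cds_length CDS length in bp.
#' @param window_size Window width in bp (default 90, i.e. 30 codons).
#' @param step Step between window starts (default 30).
#' @return Tibble `window_start, window_end, width, n, density` with density
#'   in variants per bp. If `window_size > cds_length` a single whole-CDS
#'   window is returned with a warning.
#' @examples
#' variant_density(seq(0, 990, by = 10), 1000, 100, 100)  # constant 0.1
#' @export
variant_density <- function(positions, cds_length, window_size = 90,
                            step = 30) {
  stopifnot(cds_length >= 1, window_size >= 1, step >= 1)
  positions <- unique(as.numeric(positions))
  if (length(positions) > 0 &&
      (any(positions < 0) || any(positions >= cds_length)))
    stop("positions must lie in [0, cds_length)")
  if (window_size > cds_length) {
    warning("window_size exceeds cds_length; using a single whole-CDS window")
    window_size <- cds_length
    step <- cds_length
  }
  starts <- seq(0, cds_length - 1, by = step)
  starts <- starts[starts < cds_length]
  ends <- pmin(starts + window_size, cds_length)
  n <- vapply(seq_along(starts), function(i)
    sum(positions >= starts[i] & positions < ends[i]), numeric(1))
  width <- ends - starts
  tibble::tibble(window_start = starts, window_end = ends, width = width,
                 n = n, density = n / width)
}

#' Build a constraint profile for one gene and population
#'
#' @inheritParams variant_density
#' @param gene,population Labels carried through to outputs.
#' @return An `rv_constraint` object.
#' @export
constraint_profile <- function(positions, cds_length, gene = NA_character_,
                               population = NA_character_, window_size = 90,
                               step = 30) {
  dens <- variant_density(positions, cds_length, window_size, step)
  structure(list(gene = gene, population = population,
                 cds_length = cds_length, window_size = window_size,
                 step = step, density = dens),
            class = "rv_constraint")
}

#' @export
print.rv_constraint <- function(x, ...) {
  cat("<rv_constraint> ", x$gene, "/", x$population, ": ", nrow(x$density),
      " windows over ", x$cds_length, " bp CDS\n", sep = "")
  invisible(x)
}

#' Constrained (low-density) intervals of a profile
#'
#' Maximal unions of windows whose density does not exceed the given
#' quantile of the profile's density distribution. A constant (degenerate)
#' profile returns the whole CDS flagged as degenerate.
#'
#' @param profile An `rv_constraint` object.
#' @param quantile Density quantile defining "low" (default 0.25).
#' @return Tibble `start, end` of half-open CDS intervals; attribute
#'   `"degenerate"` is `TRUE` for flat profiles, and `"threshold"` records
#'   the density cutoff used.
#' @export
constrained_regions <- function(profile, quantile = 0.25) {
  stopifnot(inherits(profile, "rv_constraint"), quantile >= 0, quantile <= 1)
  d <- profile$density
  if (nrow(d) == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  if (diff(range(d$density)) == 0) {
    out <- tibble::tibble(start = 0, end = profile$cds_length)
    attr(out, "degenerate") <- TRUE
    attr(out, "threshold") <- d$density[1]
    return(out)
  }
  thr <- stats::quantile(d$density, quantile, names = FALSE)
  low <- d[d$density <= thr, c("window_start", "window_end")]
  out <- .merge_intervals(low$window_start, low$window_end)
  attr(out, "degenerate") <- FALSE
  attr(out, "threshold") <- thr
  out
}

.merge_intervals <- function(start, end) {
  if (length(start) == 0) return(tibble::tibble(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Classify a CDS site against a constraint profile
#'
#' @param position 0-based CDS coordinate(s).
#' @param profile An `rv_constraint` object.
#' @param quantile Passed to [constrained_regions()].
#' @return Tibble `position, classification, local_density` where
#'   classification is `low_density` (inside a constrained interval,
#'   half-open inclusion at the start) or `high_density`.
#' @export
classify_site <- function(position, profile, quantile = 0.25) {
  stopifnot(inherits(profile, "rv_constraint"))
  if (any(position < 0 | position >= profile$cds_length))
    stop("position outside the CDS")
  regions <- constrained_regions(profile, quantile)
  d <- profile$density
  purrr::map_dfr(position, function(p) {
    inside <- nrow(regions) > 0 && any(p >= regions$start & p < regions$end)
    covering <- d$density[p >= d$window_start & p < d$window_end]
    tibble::tibble(position = p,
                   classification = if (inside) "low_density" else "high_density",
                   local_density = mean(covering))
  })
}

#' Constraint profiles for genes in a reference panel
#'
#' Computes one missense-density profile per requested gene from a panel's
#' variants in one population, using the annotation table's CDS coordinates.
#'
#' @param panel A `panel_table`.
#' @param cds_map Tibble `variant_id, gene, cds_pos, cds_length` mapping
#'   genomic variants to CDS coordinates (the simulator's truth table
#'   provides one).
#' @param population Population whose variants form the background.
#' @param genes Genes to profile (default: all in `cds_map`).
#' @inheritParams variant_density
#' @return Named list of `rv_constraint` objects.
#' @export
panel_constraint_profiles <- function(panel, cds_map, population = "NFE",
                                      genes = NULL, window_size = 90,
                                      step = 30) {
  stopifnot(inherits(panel, "panel_table"))
  hits <- panel |>
    dplyr::filter(.data$POP == population,
                  classify_consequence(.data$CONSEQUENCE) == "missense") |>
    dplyr::inner_join(cds_map, by = "variant_id")
  genes <- genes %||% unique(cds_map$gene)
  out <- purrr::map(genes, function(g) {
    sub <- hits[hits$gene == g, ]
    len <- cds_map$cds_length[cds_map$gene == g][1]
    constraint_profile(sub$cds_pos, len, gene = g, population = population,
                       window_size = window_size, step = step)
  })
  setNames(out, genes)
}

#' @export
autoplot.rv_constraint <- function(object, quantile = 0.25, highlight = NULL,
                                   ...) {
  d <- object$density
  regions <- constrained_regions(object, quantile)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$window_start +
                                              .data$window_end) / 2,
                                       y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "CDS position (bp)", y = "variants / bp",
                  title = paste0(object$gene, " (", object$population, ")")) +
    ggplot2::theme_minimal()
  if (nrow(regions) > 0 && !isTRUE(attr(regions, "degenerate")))
    p <- p + ggplot2::geom_rect(data = regions,
                                ggplot2::aes(xmin = .data$start,
                                             xmax = .data$end),
                                ymin = -Inf, ymax = Inf, alpha = 0.15,
                                fill = "steelblue", inherit.aes = FALSE)
  if (!is.null(highlight))
    p <- p + ggplot2::geom_vline(xintercept = highlight, linetype = 2,
                                 colour = "firebrick")
  p
}
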