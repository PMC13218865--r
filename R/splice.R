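# Position-weight-matrix scoring of donor (9-mer) and acceptor (14-mer)
# splice signals, percent-variation calls on ref/alt pairs, and
# splicing-regulatory (ESE/ESS/ISE/ISS) motif deltas.
#
# Scores are consensus values on a 0-100 scale: 100 * (raw - min) / (max -
# min), where raw is the sum of per-position base weights and min/max are the
# least/most favourable attainable sums. The consensus k-mer therefore scores
# exactly 100 and the anti-consensus exactly 0. Absolute scores are
# matrix-relative: different weight tables place the same k-mer at different
# values, so only within-matrix comparisons (and the percent variation
# between ref and alt) are meaningful.

#' Construct a splice-site weight matrix
#'
#' @param weights Numeric matrix, rows `A,C,G,T`, one column per position
#'   (9 for donor sites spanning exon -3..-1 and intron +1..+6; 14 for
#'   acceptor sites spanning the pyrimidine tract, the AG dinucleotide and
#'   the first two exonic bases).
#' @param kind `"donor"` or `"acceptor"`.
#' @return A `splice_matrix` object with precomputed normalisation constants.
#' @export
splice_matrix <- function(weights, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == 4, all(rownames(weights) == c("A", "C", "G", "T")),
            all(is.finite(weights)))
  mins <- apply(weights, 2, min)
  maxs <- apply(weights, 2, max)
  if (sum(maxs) <= sum(mins)) stop("degenerate matrix: max score equals min score")
  structure(list(weights = weights, kind = kind, k = ncol(weights),
                 raw_min = sum(mins), raw_max = sum(maxs)),
            class = "splice_matrix")
}

#' @export
print.splice_matrix <- function(x, ...) {
  cat("<splice_matrix> ", x$kind, " site, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Read a splice matrix from TSV
#'
#' @param path TSV with columns `position, A, C, G, T`.
#' @param kind `"donor"` or `"acceptor"`; inferred from the column count
#'   (9 = donor, 14 = acceptor) when omitted.
#' @return A `splice_matrix`.
#' @export
read_splice_matrix <- function(path, kind = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("position", "A", "C", "G", "T") %in% names(tab)))
  w <- t(as.matrix(tab[order(tab$position), c("A", "C", "G", "T")]))
  rownames(w) <- c("A", "C", "G", "T")
  if (is.null(kind)) kind <- if (ncol(w) == 9) "donor" else "acceptor"
  splice_matrix(w, kind)
}

#' The packaged donor and acceptor matrices
#'
#' Shapiro-Senapathy-style per-position base frequency tables shipped with
#' the package as editable TSVs.
#'
#' @return Named list with elements `donor` and `acceptor`.
#' @export
default_splice_matrices <- function() {
  list(
    donor = read_splice_matrix(system.file("extdata", "donor_matrix.tsv",
                                           package = "rvburden", mustWork = TRUE),
                               "donor"),
    acceptor = read_splice_matrix(system.file("extdata", "acceptor_matrix.tsv",
                                              package = "rvburden",
                                              mustWork = TRUE), "acceptor")
  )
}

#' Score k-mers against a splice matrix
#'
#' @param kmer Character vector of k-mers (A/C/G/T only; ambiguous bases are
#'   an error, not imputed).
#' @param matrix A [splice_matrix()].
#' @return Numeric scores in \[0, 100\].
#' @examples
#' m <- default_splice_matrices()$donor
#' score_site(consensus_kmer(m), m)  # 100
#' @export
score_site <- function(kmer, matrix) {
  stopifnot(inherits(matrix, "splice_matrix"))
  vapply(kmer, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (length(ch) != matrix$k)
      stop("k-mer length ", length(ch), " does not match matrix k = ", matrix$k)
    idx <- match(ch, rownames(matrix$weights))
    if (anyNA(idx)) stop("k-mer contains non-ACGT base: ", s)
    raw <- sum(matrix$weights[cbind(idx, seq_along(idx))])
    100 * (raw - matrix$raw_min) / (matrix$raw_max - matrix$raw_min)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Consensus and anti-consensus k-mers of a matrix
#' @param matrix A [splice_matrix()].
#' @return The k-mer with maximal (resp. minimal) attainable score.
#' @export
consensus_kmer <- function(matrix) {
  paste(rownames(matrix$weights)[apply(matrix$weights, 2, which.max)],
        collapse = "")
}

#' @rdname consensus_kmer
#' @export
anticonsensus_kmer <- function(matrix) {
  paste(rownames(matrix$weights)[apply(matrix$weights, 2, which.min)],
        collapse = "")
}

#' Percent variation between wild-type and mutant site scores
#'
#' @param wt_score,mut_score Scores on the 0-100 scale; `wt_score` must be
#'   positive (a zero wild-type score leaves the relative change undefined).
#' @param digits Decimal places in the reported percentage (2, matching how
#'   such scores are conventionally printed); use `Inf` for no rounding.
#' @return `100 * (mut - wt) / wt`, rounded to `digits`.
#' @examples
#' variation_pct(46.68, 73.82)  # 58.14
#' @export
variation_pct <- function(wt_score, mut_score, digits = 2) {
  if (any(wt_score <= 0)) stop("variation undefined for wt_score <= 0")
  v <- 100 * (mut_score - wt_score) / wt_score
  if (is.finite(digits)) round(v, digits) else v
}

.revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan a ref/alt sequence pair for created or broken splice sites
#'
#' For each matrix, every k-mer frame overlapping the substituted base is
#' scored in both sequences. A frame where the mutant score reaches
#' `site_threshold` with a percent variation of at least `min_variation`
#' is called a new site; the reverse pattern (reference above threshold,
#' variation at or below `-min_variation`) is a broken site. Minus-strand
#' input is reverse-complemented before scoring; reported positions refer to
#' the scored (strand-oriented) sequence, 1-based at the site's first base.
#'
#' @param ref_seq,alt_seq Equal-length sequences differing at one base.
#' @param matrices List of [splice_matrix()] objects (default: packaged
#'   donor + acceptor).
#' @param strand `"+"` or `"-"`.
#' @param site_threshold Minimum score for a site to be considered present
#'   (default 60 on this package's matrix scale; see the methods vignette).
#' @param min_variation Minimum absolute percent variation.
#' @return Tibble of splice events: `matrix, kind, position, strand, ref_kmer,
#'   alt_kmer, ref_score, alt_score, variation_pct, signal, interpretation`.
#'   Zero rows when `ref_seq == alt_seq` or nothing is called.
#' @examples
#' scan_pair("GCAGGCAGG", "GCAGTCAGG")
#' @export
scan_pair <- function(ref_seq, alt_seq, matrices = default_splice_matrices(),
                      strand = "+", site_threshold = 60, min_variation = 10) {
  stopifnot(length(ref_seq) == 1, length(alt_seq) == 1,
            nchar(ref_seq) == nchar(alt_seq), strand %in% c("+", "-"))
  ref_seq <- toupper(ref_seq); alt_seq <- toupper(alt_seq)
  empty <- tibble::tibble(matrix = character(), kind = character(),
                          position = integer(), strand = character(),
                          ref_kmer = character(), alt_kmer = character(),
                          ref_score = numeric(), alt_score = numeric(),
                          variation_pct = numeric(), signal = character(),
                          interpretation = character())
  if (ref_seq == alt_seq) return(empty)
  if (strand == "-") {
    ref_seq <- .revcomp(ref_seq); alt_seq <- .revcomp(alt_seq)
  }
  rc <- strsplit(ref_seq, "")[[1]]; ac <- strsplit(alt_seq, "")[[1]]
  diffs <- which(rc != ac)
  if (length(diffs) != 1)
    stop("sequences must differ at exactly one base (", length(diffs), " found)")
  pos <- diffs
  L <- nchar(ref_seq)

  out <- purrr::imap(matrices, function(m, name) {
    k <- m$k
    lo <- max(1L, pos - k + 1L)
    hi <- min(pos, L - k + 1L)
    if (hi < lo) return(empty)   # sequence shorter than the motif window
    starts <- lo:hi
    ref_k <- substring(ref_seq, starts, starts + k - 1L)
    alt_k <- substring(alt_seq, starts, starts + k - 1L)
    rs <- score_site(ref_k, m)
    as_ <- score_site(alt_k, m)
    vp <- ifelse(rs > 0, round(100 * (as_ - rs) / rs, 2), NA_real_)
    new_site <- as_ >= site_threshold & !is.na(vp) & vp >= min_variation
    broken <- rs >= site_threshold & !is.na(vp) & vp <= -min_variation
    keep <- new_site | broken
    if (!any(keep)) return(empty)
    signal <- ifelse(new_site[keep], paste0("new_", m$kind), "broken_site")
    tibble::tibble(
      matrix = name, kind = m$kind, position = starts[keep], strand = strand,
      ref_kmer = ref_k[keep], alt_kmer = alt_k[keep],
      ref_score = round(rs[keep], 2), alt_score = round(as_[keep], 2),
      variation_pct = vp[keep], signal = signal,
      interpretation = ifelse(new_site[keep],
                              paste0("Activation of a cryptic ", m$kind, " site"),
                              paste0("Loss of a ", m$kind, " site")))
  })
  dplyr::bind_rows(out)
}

#' Read a splicing-regulatory motif set
#'
#' @param x TSV path or data frame with columns `motif` (ACGT k-mer) and
#'   `class` (one of ESE, ESS, ISE, ISS).
#' @return A validated tibble.
#' @export
read_motif_set <- function(x) {
  tab <- if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE,
                                              comment = "#")
         else tibble::as_tibble(x)
  stopifnot(all(c("motif", "class") %in% names(tab)))
  if (nrow(tab) == 0) stop("empty motif set")
  if (!all(tab$class %in% c("ESE", "ESS", "ISE", "ISS")))
    stop("motif class must be one of ESE, ESS, ISE, ISS")
  if (!all(grepl("^[ACGT]+$", tab$motif))) stop("motifs must be ACGT strings")
  tab
}

#' The packaged exemplar ESE/ESS motif sets
#' @return Motif tibble read from the package's editable TSV.
#' @export
default_motif_sets <- function() {
  read_motif_set(system.file("extdata", "ese_ess_motifs.tsv",
                             package = "rvburden", mustWork = TRUE))
}

# all (possibly overlapping) match start positions of a plain motif
.motif_hits <- function(seq, motif) {
  hits <- stringr::str_locate_all(seq, stringr::regex(paste0("(?=", motif, ")")))[[1]]
  if (nrow(hits) == 0) integer(0) else hits[, 1]
}

#' Splicing-regulatory motif delta between ref and alt sequences
#'
#' Exact overlapping-occurrence counts of each motif in both sequences.
#' The headline delta is the change in the enhancer-minus-silencer balance:
#' `(ESE - ESS)_alt - (ESE - ESS)_ref`. Created and broken motifs are the
#' per-instance (motif, position) set differences.
#'
#' @param ref_seq,alt_seq Sequences (equal length).
#' @param motif_sets Motif tibble as from [read_motif_set()].
#' @return List: `counts` (per class, ref and alt), `delta`, `created`,
#'   `broken` (tibbles of motif instances).
#' @export
motif_ratio_delta <- function(ref_seq, alt_seq,
                              motif_sets = default_motif_sets()) {
  motif_sets <- read_motif_set(motif_sets)
  ref_seq <- toupper(ref_seq); alt_seq <- toupper(alt_seq)
  inst <- function(seq) {
    purrr::pmap(motif_sets, function(motif, class) {
      p <- .motif_hits(seq, motif)
      tibble::tibble(motif = motif, class = class, position = p)
    }) |> dplyr::bind_rows()
  }
  ri <- inst(ref_seq); ai <- inst(alt_seq)
  created <- dplyr::anti_join(ai, ri, by = c("motif", "class", "position"))
  broken <- dplyr::anti_join(ri, ai, by = c("motif", "class", "position"))
  counts <- dplyr::bind_rows(
    dplyr::count(ri, .data$class, name = "ref"),
    dplyr::count(ai, .data$class, name = "alt")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(ref = sum(.data$ref, na.rm = TRUE),
                     alt = sum(.data$alt, na.rm = TRUE), .groups = "drop")
  n_of <- function(tab, cl) sum(tab$class == cl)
  delta <- (n_of(ai, "ESE") - n_of(ai, "ESS")) -
    (n_of(ri, "ESE") - n_of(ri, "ESS"))
  list(counts = counts, delta = delta, created = created, broken = broken)
}
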