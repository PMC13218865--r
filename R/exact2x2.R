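# Exact statistics on allelic 2x2 tables.
#
# Table layout throughout (alt = minor/qualifying allele):
#           alt   ref
#   cases     a     c     (a + c = case allele number, 2N after QC)
#   controls  b     d     (b + d = control allele number)
#
# Conditioning on both margins, the case alt count X follows a (noncentral)
# hypergeometric distribution; all p-values, CMLE odds ratios and exact
# confidence limits below are computed on that conditional distribution.

#' Build allelic 2x2 contingency tables
#'
#' @param a Case alt-allele counts.
#' @param c Case ref-allele counts.
#' @param b Control alt-allele counts.
#' @param d Control ref-allele counts.
#' @return A tibble with columns `a`, `c`, `b`, `d` (non-negative integers).
#' @examples
#' contingency(8, 734, 5, 68053)
#' @export
contingency <- function(a, c, b, d) {
  n <- max(length(a), length(c), length(b), length(d))
  out <- tibble::tibble(
    a = as.numeric(rep_len(a, n)), c = as.numeric(rep_len(c, n)),
    b = as.numeric(rep_len(b, n)), d = as.numeric(rep_len(d, n))
  )
  bad <- with(out, a < 0 | c < 0 | b < 0 | d < 0 |
                a != round(a) | c != round(c) | b != round(b) | d != round(d))
  if (any(bad)) stop("contingency entries must be non-negative integers")
  out
}

# support of the conditional distribution of the case alt count
.support <- function(a, c, b, d) {
  m <- a + b                       # alt-allele margin
  lo <- max(0, m - (b + d))
  hi <- min(m, a + c)
  seq.int(lo, hi)
}

#' Two-sided Fisher exact p-value
#'
#' Exact conditional p-value for association in an allelic 2x2 table. The
#' default `"point"` method sums, over the conditional support, all outcome
#' probabilities not exceeding the observed one (with a `1 + 1e-7` relative
#' slack for floating-point ties); `"doubling"` doubles the smaller one-sided
#' tail and caps at 1.
#'
#' @inheritParams contingency
#' @param method `"point"` (default) or `"doubling"`.
#' @return Numeric vector of p-values in (0, 1]. Tables with a zero margin
#'   return 1 with a warning.
#' @examples
#' fisher_exact_p(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_p <- function(a, c, b, d, method = c("point", "doubling")) {
  method <- match.arg(method)
  tab <- contingency(a, c, b, d)
  purrr::pmap_dbl(tab, function(a, c, b, d) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
      warning("degenerate 2x2 table (zero margin); p = 1 by convention")
      return(1)
    }
    xs <- .support(a, c, b, d)
    pr <- dhyper(xs, a + c, b + d, a + b)
    p_obs <- pr[xs == a]
    p <- if (method == "point") {
      sum(pr[pr <= p_obs * (1 + 1e-7)])
    } else {
      2 * min(sum(pr[xs <= a]), sum(pr[xs >= a]))
    }
    min(max(p, p_obs), 1)
  })
}

#' Odds ratio of an allelic 2x2 table
#'
#' @inheritParams contingency
#' @param method `"sample"` for the cross-product estimate `(a*d)/(c*b)`
#'   (the default), or `"cmle"` for the conditional maximum-likelihood
#'   estimate under the noncentral hypergeometric model (the estimator
#'   `stats::fisher.test()` reports).
#' @return Numeric vector. Conventions: `b = 0, a > 0` gives `Inf`;
#'   `a = 0, b > 0` gives 0; `a = 0, b = 0` gives `NaN` (undefined).
#' @examples
#' odds_ratio(8, 734, 5, 68053)
#' @export
odds_ratio <- function(a, c, b, d, method = c("sample", "cmle")) {
  method <- match.arg(method)
  tab <- contingency(a, c, b, d)
  if (method == "sample") {
    num <- tab$a * tab$d
    den <- tab$c * tab$b
    out <- ifelse(num == 0 & den == 0, NaN, num / den)
    # a = 0 with alt alleles present in controls is evidence of OR 0, not 0/0
    out[tab$a == 0 & tab$b > 0] <- 0
    out[tab$b == 0 & tab$a > 0] <- Inf
    return(out)
  }
  purrr::pmap_dbl(tab, function(a, c, b, d) .cmle_or(a, c, b, d))
}

# conditional expectation of X under odds psi, on log scale for stability
.nchg_weights <- function(xs, lw0, log_psi) {
  lw <- lw0 + xs * log_psi
  w <- exp(lw - max(lw))
  w / sum(w)
}

.cmle_or <- function(a, c, b, d) {
  xs <- .support(a, c, b, d)
  if (length(xs) == 1) return(NaN)
  if (a == min(xs)) return(0)
  if (a == max(xs)) return(Inf)
  lw0 <- lchoose(a + c, xs) + lchoose(b + d, (a + b) - xs)
  f <- function(lp) sum(xs * .nchg_weights(xs, lw0, lp)) - a
  exp(uniroot(f, c(-80, 80), tol = 1e-10)$root)
}

#' Exact conditional confidence interval for the odds ratio
#'
#' Inverts noncentral-hypergeometric tail probabilities: the lower limit
#' solves `P_psi(X >= a) = (1 - level)/2` and the upper limit solves
#' `P_psi(X <= a) = (1 - level)/2`, by root bisection on `log(psi)` to a
#' relative tolerance of 1e-8. When `a` sits at the bottom of the support the
#' lower limit is 0; at the top, the upper limit is `Inf` (so `b = 0` tables
#' always report an infinite upper bound but a finite, informative lower
#' bound).
#'
#' @inheritParams contingency
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `ci_lo` and `ci_hi`.
#' @examples
#' exact_ci(3, 17, 1, 19)
#' @export
exact_ci <- function(a, c, b, d, level = 0.95) {
  stopifnot(length(level) == 1, level > 0, level < 1)
  tab <- contingency(a, c, b, d)
  alpha <- (1 - level) / 2
  res <- purrr::pmap(tab, function(a, c, b, d) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
      warning("degenerate 2x2 table (zero margin); CI = (0, Inf)")
      return(c(0, Inf))
    }
    xs <- .support(a, c, b, d)
    if (length(xs) == 1) return(c(0, Inf))
    lw0 <- lchoose(a + c, xs) + lchoose(b + d, (a + b) - xs)
    tail_ge <- function(lp) sum(.nchg_weights(xs, lw0, lp)[xs >= a])
    tail_le <- function(lp) sum(.nchg_weights(xs, lw0, lp)[xs <= a])
    lo <- if (a == min(xs)) 0 else
      exp(.invert_tail(function(lp) tail_ge(lp) - alpha))
    hi <- if (a == max(xs)) Inf else
      exp(.invert_tail(function(lp) tail_le(lp) - alpha, decreasing = TRUE))
    c(lo, hi)
  })
  tibble::tibble(ci_lo = purrr::map_dbl(res, 1), ci_hi = purrr::map_dbl(res, 2))
}

# root of f on log(psi); tail_ge is increasing in psi, tail_le decreasing.
# brackets widened adaptively so extreme but finite limits are still found.
.invert_tail <- function(f, decreasing = FALSE) {
  lo <- -80; hi <- 80
  flo <- f(lo); fhi <- f(hi)
  tries <- 0
  while (sign(flo) == sign(fhi) && tries < 6) {
    lo <- lo * 2; hi <- hi * 2
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1
  }
  if (sign(flo) == sign(fhi)) stop("failed to bracket confidence limit")
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Bonferroni or Benjamini-Hochberg adjustment over a declared family
#'
#' Thin wrapper around [stats::p.adjust()] that makes the family size an
#' explicit argument: in a gene-burden scan the family is every gene tested
#' within one panel and variant class, whether or not it carried variants.
#'
#' @param p Raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param family_size Number of tests in the family; defaults to `length(p)`
#'   and must be at least that.
#' @return Adjusted p-values.
#' @examples
#' adjust_multiple(c(0.01, 0.02, 0.03), "bh")
#' adjust_multiple(0.01, "bonferroni", family_size = 63)
#' @export
adjust_multiple <- function(p, method = c("bonferroni", "bh"),
                            family_size = length(p)) {
  method <- match.arg(method)
  if (length(p) == 0) stop("empty p-value family")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (family_size < length(p)) stop("family_size smaller than the number of p-values")
  p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[[method]],
           n = family_size)
}
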