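# Shared fixtures: small simulation configs and an independent brute-force
# enumeration oracle for the Fisher exact test.

tiny_gene_spec <- function(n_genes = 3, n_variants = 3, cds_length = 900L) {
  tibble::tibble(gene = sprintf("G%02d", seq_len(n_genes)),
                 cds_length = cds_length,
                 n_variants = as.integer(n_variants))
}

tiny_config <- function(..., n_cases = 30, maf_range = c(1e-4, 5e-3),
                        seed = 1L) {
  sim_config(n_cases = n_cases, genes = tiny_gene_spec(),
             panel_an = c(NFE = 10000, CSVS = 4000),
             absent_prob = c(NFE = 0, CSVS = 0.2),
             maf_range = maf_range, seed = seed, ...)
}

# Brute-force two-sided Fisher p by direct enumeration of the conditional
# support, probabilities from log-factorials (independent of dhyper).
oracle_fisher_p <- function(a, c, b, d) {
  m <- a + b; k <- a + c; n2 <- b + d; N <- a + b + c + d
  if (m == 0 || k == 0 || n2 == 0 || (c + d) == 0) return(1)
  xs <- max(0, m - n2):min(m, k)
  # direct hypergeometric probability: choose(k,x) choose(n2, m-x) / choose(N, m)
  pr <- exp(lchoose(k, xs) + lchoose(n2, m - xs) - lchoose(N, m))
  p_obs <- pr[xs == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# psi-grid inversion oracle for the exact conditional CI (coarse but
# independent of the bisection code path)
oracle_exact_ci <- function(a, c, b, d, level = 0.95,
                            grid = 10^seq(-4, 4, length.out = 20001)) {
  xs <- max(0, (a + b) - (b + d)):min(a + b, a + c)
  lw0 <- lchoose(a + c, xs) + lchoose(b + d, (a + b) - xs)
  alpha <- (1 - level) / 2
  tail_ge <- vapply(grid, function(psi) {
    w <- exp(lw0 + xs * log(psi) - max(lw0 + xs * log(psi)))
    sum(w[xs >= a]) / sum(w)
  }, numeric(1))
  tail_le <- vapply(grid, function(psi) {
    w <- exp(lw0 + xs * log(psi) - max(lw0 + xs * log(psi)))
    sum(w[xs <= a]) / sum(w)
  }, numeric(1))
  lo <- if (a == min(xs)) 0 else grid[which(tail_ge >= alpha)[1]]
  hi <- if (a == max(xs)) Inf else grid[max(which(tail_le >= alpha))]
  c(lo, hi)
}

# write a small hand-rolled VCF for parser edge cases
write_mini_vcf <- function(body_lines, samples = c("S1", "S2"), path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}

mini_annotation <- function(chrom, pos, ref, alt, gene, consequence) {
  tibble::tibble(CHROM = chrom, POS = pos, REF = ref, ALT = alt,
                 GENE = gene, CONSEQUENCE = consequence)
}
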