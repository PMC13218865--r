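---
title: "Methods: rare-variant gene burden against reference-panel pseudo-controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant gene burden against reference-panel pseudo-controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The problem

Case cohorts for rare inner-ear and immune disorders are small — a few
hundred exomes — and matched genotyped controls are usually unavailable.
A practical alternative is to test gene-level aggregates of rare variant
alleles in cases against *public reference panels* (gnomAD-style AC/AN
tables, CSVS-style frequency tables) treated as pseudo-controls. rvburden
implements that design end to end: genotype-level QC, restriction to a
curated gene family (the packaged default is a 63-gene NF-κB pathway set),
a rarity filter on the Spanish reference panel, per-gene collapsing, exact
2×2 statistics, multiple-testing over the gene family, co-occurring-variant
reports, missense-density constraint profiles, and splice-signal scoring
for candidate variants.

## The statistical model

For gene $g$, qualifying variants (missense + loss-of-function by default;
synonymous as a control track) are collapsed by summing alt alleles across
variants and individuals:

$$a_g = \sum_{v \in g} \mathrm{AC}_v, \qquad A = 2N,$$

with $N$ the cohort size, fixed across genes (per-variant missingness after
QC reduces only that variant's contribution). The control side sums the
panel allele counts of the same variants, $b_g = \sum_v \mathrm{AC}^{panel}_v$,
against $B_g$, the median per-variant panel allele number (exactly constant
in simulated panels, and a robust choice when real panels report slightly
different AN per site). The allelic table $(a_g, A - a_g, b_g, B_g - b_g)$
is then tested with:

* **Fisher's exact test**, two-sided by the point-probability rule: the
  p-value sums all conditional hypergeometric outcomes whose probability
  does not exceed the observed one (with a $1 + 10^{-7}$ relative slack for
  floating-point ties). A tail-doubling variant is available by flag.
* **Odds ratio**: the sample cross-product $(ad)/(bc)$ by default, because
  it is what published burden tables print; the conditional
  maximum-likelihood estimate under the noncentral hypergeometric model is
  available as `method = "cmle"`. Conventions: $b = 0, a > 0 \Rightarrow
  +\infty$; $a = 0, b > 0 \Rightarrow 0$; both zero is undefined (`NaN`).
* **Exact conditional CI** by inverting noncentral-hypergeometric tail
  probabilities: the lower limit solves $P_\psi(X \ge a) = \alpha/2$, the
  upper solves $P_\psi(X \le a) = \alpha/2$, with bisection on $\log\psi$
  to a relative tolerance of $10^{-8}$ and weights computed in log space.
  Zero-cell tables keep the informative bound: $b = 0$ gives a finite lower
  limit and an infinite upper limit.
* **Multiple testing** over the declared family — every gene in the list,
  whether or not it carried variants ($m = 63$ for the packaged list) —
  with Bonferroni and Benjamini–Hochberg adjustment, applied separately per
  panel population and variant class. Ties in BH need no special handling;
  the step-up procedure resolves them naturally.

A gene is *prioritised* when FDR $< 0.05$ and OR $> 5$ in the primary panel
(NFE by default); both cutoffs are parameters of
`prioritisation_criteria()`. The direction is enrichment (OR above 1);
the synonymous track is reported alongside as a negative control.

### Why exact statistics behave conservatively here

At these allele counts the conditional distribution is strongly discrete.
Exact p-values are therefore *super-uniform* under the null —
$P(p \le t) \le t$ — not uniform; a plain goodness-of-fit test against the
uniform would reject any valid discrete exact test. The property suite
asserts super-uniformity on a grid, and the practical consequence
(the BH discovery fraction under a global null stays below the nominal
0.05) directly. For the same reason the exact CI *over-covers*: at the
study scale used in the acceptance checks (742 case alleles, 68,058
control alleles, control frequency $10^{-3}$, true conditional odds 5) the
measured coverage of the nominal 95% interval is about 97%, so individual
300-draw coverage estimates straddle 97% depending on the seed.

## Genotype and site QC

Defaults follow standard germline short-read practice, with all boundaries
inclusive:

| field | rule | applies to |
|---|---|---|
| allele balance (alt/total depth) | within [0.20, 0.80] | heterozygous calls |
| genotype quality | ≥ 20 | all calls |
| depth | ≥ 10 (≥ 5 haploid) | all calls |
| VQSR tranche | FILTER equals the pass label | sites |

A call with a missing required field fails as `MISSING_FIELD` — never a
silent pass. The tranche filter is a *site* property: non-pass sites are
excluded wholesale and their called genotypes logged with reason
`TRANCHE`. QC is idempotent, never increases an allele count, and writes a
per-genotype audit row for every call set to missing.

## Rarity, novelty, and panels

The rarity filter drops variants whose Spanish-panel (CSVS) frequency
strictly exceeds 0.05 — a variant at exactly 0.05 survives. Absence from a
panel is kept distinct from an observed frequency of zero with known AN:
absence is evidence of novelty and is carried as a flag; statistically both
contribute $b = 0$. Frequency-only panel dialects are supported through a
configured default allele number; converting a published frequency back to
a count uses round-half-to-even of $\mathrm{AF} \cdot \mathrm{AN}$, which
regenerates integer panel counts exactly for panels written by the
simulator.

## Co-occurrence

"Haplotype" reports from unphased short-read cohorts really mean *one
individual carrying two or more qualifying variants in the same gene*, and
that is what `find_multicarriers()` reports (a homozygous-alt call is one
distinct variant, not two). `syn_mis_sharing()` lists per-individual
pairings of a carried synonymous with a carried missense variant in the
same gene; an empty result is the interesting negative finding. Output is
identical under `/` and `|` genotype notation.

## Constraint density

`variant_density()` tiles a gene's CDS (0-based, half-open) with windows of
90 bp stepped by 30 bp by default — a codon-scale compromise: windows much
narrower than ~30 codons are dominated by Poisson noise at panel variant
densities, much wider ones blur real constraint boundaries. Both are
configurable and reported in every profile. The last window is truncated
and normalised by its actual width, so density × width sums exactly to the
variant count on non-overlapping tilings. Constrained regions are maximal
unions of windows at or below a density quantile (0.25 by default); a flat
profile returns the whole CDS flagged degenerate rather than an arbitrary
subset. Study variants are overlaid on profiles built from panel variants
only — they are never counted into their own background.

## Splice-signal scoring

Donor (9-mer: exon −3..−1, intron +1..+6) and acceptor (14-mer:
polypyrimidine tract, AG, first two exonic bases) sites are scored with
per-position frequency matrices shipped as editable TSVs, in the classic
consensus-value style:

$$\mathrm{CV} = 100 \cdot \frac{\mathrm{raw} - \min}{\max - \min},$$

so the consensus k-mer scores exactly 100 and the anti-consensus 0.
**Absolute scores are matrix-relative**: a different weight table places
the same k-mer elsewhere on the scale, so only within-matrix comparisons
and the percent variation between ref and alt,
$100 \cdot (s_{mut} - s_{wt})/s_{wt}$, are transferable between tools.
`scan_pair()` scores every k-mer frame overlapping the substituted base
(there are $k$ of them) in both sequences, on the supplied strand
(minus-strand input is reverse-complemented first), and calls a *new site*
when the mutant score reaches the site threshold with variation ≥ 10%, or
a *broken site* for the reverse pattern. The default site threshold is 60
on this package's scale: on the shipped matrices, annotated-consensus-like
sites score in the 60–100 range while random sequence averages ≈ 30, and
the widely used threshold of 65 from other tools belongs to *their* —
differently normalised, non-public — matrices, so it is not imported
blindly. Splicing-regulatory motif analysis (`motif_ratio_delta()`)
performs exact overlapping-occurrence counting over pluggable ESE/ESS/
ISE/ISS k-mer sets; the shipped sets are small published-style exemplars,
and the enhancer-minus-silencer delta depends entirely on the motif
database plugged in.

## The simulator

`sim_config()` + `simulate_cohort()` generate everything the pipeline
consumes — VCF, annotation table, panel TSV, gene list, truth JSON — with
the statistical structure the burden test assumes:

* per-variant base frequency $q$ log-uniform over $[10^{-6}, 5 \cdot
  10^{-2}]$ by default (rare to borderline-common);
* diploid genotypes as two Bernoulli($\min(\lambda q, 0.5)$) draws —
  per-gene enrichment $\lambda$ is the planted effect size, clamped with a
  warning if $\lambda q$ exceeds 0.5;
* panel counts $\mathrm{AC} = \mathrm{round}(q \cdot \mathrm{AN})$
  (round-half-even), per population, with NFE tracking the case base
  frequency, log-normal jitter for other populations, and per-population
  absence probabilities to exercise novelty handling; default allele
  numbers (NFE 68,058; Global 152,312; CSVS 4,074) are chosen so that
  published-scale frequencies round-trip to integer counts;
* a configurable fraction (2% by default) of genotype calls emitted with
  one QC field just outside its threshold, to exercise the filter — the
  truth object records each injected failure, and planted carriers are
  exempt so planting contracts survive QC;
* planted multi-variant carriers and synonymous+missense co-carriers per
  gene, recorded in the truth object.

Identical configurations (including the seed) produce byte-identical
files. The simulator deliberately does **not** model linkage
disequilibrium, read-level errors, population structure, relatedness, or
multi-allelic sites; passing tests therefore demonstrate the statistical
pipeline's correctness under its own assumptions, not robustness to
ancestry mismatch or technical confounding between a cohort and a panel —
the main real-world caveats of the pseudo-control design.

## Power of planted-enrichment recovery

The acceptance simulation plants $\lambda = 8$ in 3 of 60 genes (400
cases, 5 variants per gene, $q$ log-uniform over $[10^{-5}, 10^{-3}]$) and
asks how often all three planted genes rank top-3 by FDR. Expected planted
case allele count is $2N\lambda\sum_v q_v$; because $\sum_v q_v$ has
substantial mass below $3 \cdot 10^{-4}$, a planted gene's expected count
regularly falls under 2 alleles, where no test can rank it above 57 null
genes. The acceptance script measures the actual recovery rate (≈ 68% at
these settings); recovery approaches 1 only when per-gene $\sum q$ or
$\lambda N$ grows.

## Numerical and interface choices

* All hypergeometric weights are handled in log space with max-subtraction
  before exponentiation; confidence-limit brackets widen adaptively before
  bisection.
* Zero-margin tables return $p = 1$ and CI $(0, \infty)$ with a warning
  rather than an error, so genome-scale scans do not abort on empty genes.
* Gene symbols match exactly and case-sensitively; alias resolution belongs
  upstream in the annotation table.
* Multi-allelic VCF records are decomposed into biallelic rows, each ALT
  dosed independently from the genotype string.
* Coordinates are 1-based in VCF/genomic space and 0-based half-open in
  CDS space.
* Every pipeline output starts with a `# config_hash:` stamp (MD5 of the
  canonicalised configuration), and the run manifest records package
  version, seed, and input checksums, so any parameter change is visible in
  every artifact.

### Problem sizes used by the test suite

The suite exercises the exhaustive Fisher oracle on all $\binom{64}{4} =
635{,}376$ tables with grand total ≤ 60, 300 simulated tables for CI
coverage, 100 seeded cohorts (400 cases × 60 genes) for burden recovery, a
500-gene null scan for calibration, and 500 replicate small cohorts for
the binomial-expectation check — sizes picked to give stable Monte-Carlo
estimates while keeping a full run in the low minutes on one CPU.

## Known limitations

No covariate or ancestry adjustment (no regression/SKAT-style models);
no statistical phasing — co-occurrence is not proof of a cis haplotype;
constraint profiles are raw densities, not expectation-normalised
constraint metrics; splice calls are motif-based hypothesis generators,
not spliceosome models; and pseudo-control comparisons inherit any
technical or ancestry mismatch between cohort and panel.
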