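---
title: "Bayes-factor detection of ctDNA variants from deep amplicon sequencing"
author: "tamseqbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes-factor detection of ctDNA variants from deep amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamseqbf)
```

## The problem

Tumours shed DNA fragments into plasma. In localised disease the tumour
fraction of cell-free DNA is tiny, so a somatic variant may be supported by a
handful of reads among thousands at its locus — the same order as sequencing
error. Deep tagged-amplicon sequencing (TAm-Seq) buys depth (hundreds to tens
of thousands of filtered reads per locus), but calling sub-percent variants
still hinges on knowing, per locus, how the error process behaves: error
rates differ between positions and fluctuate between samples more than a
binomial allows (PCR and sequencing introduce correlated errors).

`tamseqbf` implements the full analysis: read filtering, a per-locus
Dirichlet-Multinomial error null fitted from control samples, Bayes-factor
scoring of case samples with MAP variant-allele-frequency estimates,
high-confidence filtering, per-sample ctDNA classification, and the survival
comparison between ctDNA-positive and ctDNA-negative patients.

## Read filtering

Aligned reads are assigned to the amplicon with the largest base-pair overlap
with their aligned span (ties: lower amplicon start, then lexicographic id).
A read is kept iff

* alignment length (reference-consuming CIGAR operations M/=/X/D/N) is at
  least 75 bp,
* it covers at least 75% of its amplicon's length, and
* its edit distance (`NM`) is at most 2.

All three boundaries are inclusive, reading "minimum", "at least" and "no
more than" literally. The overlap denominator is the amplicon length, not the
read length. Unmapped reads and reads with MAPQ 0 are dropped before
filtering, since their coordinates are meaningless. Each read of a pair is
counted independently at a locus; reconciling overlapping mates (counting
fragments once) would reduce effective depth roughly twofold inside the
overlap and is deliberately not the default, since the published filtering is
stated in terms of reads. Allele counts at a locus tally the base aligned
opposite the reference position; deletions, reference skips and N calls
contribute nothing, so depth at a locus can be below the number of
overlapping filtered reads.

## The sequencing-error null

At one locus, let $x_s = (x_{sA}, x_{sC}, x_{sG}, x_{sT})$ be the counts in
control sample $s$, $n_s = \sum_k x_{sk}$. The null is Dirichlet-Multinomial:

$$\log P(x \mid \alpha) = \log\binom{n}{x}
 + \log\Gamma(A) - \log\Gamma(n + A)
 + \sum_k \left[ \log\Gamma(x_k + \alpha_k) - \log\Gamma(\alpha_k) \right],
 \qquad A = \sum_k \alpha_k .$$

$\alpha / A$ is the expected base composition under error; $A$ controls
overdispersion — the variance of a count is the binomial variance inflated by
$(n + A)/(1 + A)$, so small $A$ means noisy error rates and $A \to \infty$
recovers the multinomial.

**Add-one smoothing.** Every allele count of every control sample is
incremented by 1 before fitting (`smoothing = 1`, exposed as an argument).
This guarantees each allele has been "observed" and keeps the MLE finite at
loci where an allele never occurs in controls. It is a deliberate
bias-variance trade: at depth $n$ the smoothed mean proportion of a
minor allele with true proportion $p$ is $(np + 1)/(n + 4)$, i.e. a relative
bias of $(1 - 4p) / ((n+4)p)$ — about +10% at $n = 1000$, $p = 1/103$, and
about +3% at the ~3200× depths typical of the data regime this package
targets. Tests of parameter *recovery* therefore evaluate the raw MLE
(`smoothing = 0`); the pipeline default remains 1.

**Optimization.** The likelihood is maximised in $\theta = \log\alpha$
(unconstrained). The initializer moment-matches: mean proportions scaled by a
concentration solved from the overdispersion of per-sample proportions,
floored at 1. Each iteration takes a Newton step $\theta - tH^{-1}g$ with
step-halving; if Newton yields no ascent (singular or indefinite Hessian —
this happens in flat concentration valleys), the fit takes the best of a
digamma fixed-point sweep and Levenberg-damped steps over a damping ladder
(which limit to gradient ascent). Convergence is declared when the gradient
max-norm in $\theta$ falls below `tol = 1e-8` (default; at most 200
iterations). Because the summed log-likelihood carries cancellation noise of
order $10^{-9}(1+|\ell|)$, only small full Newton steps may be accepted at
noise-equality; damped steps must gain more than that noise, so the
trajectory is non-decreasing up to that tolerance and cannot drift.

**The multinomial boundary.** The family contains the multinomial as its
$A \to \infty$ boundary, and with smoothed low-error counts the data can be
*under*-dispersed relative to any finite $A$ (the +1 shifts the mean without
adding variance), making the likelihood monotone in $A$. No gradient
tolerance is attainable there, so the fit detects $A > 10^8$, stops, and
reports `converged = TRUE, boundary = TRUE`: the fitted null is the
multinomial limit, which is perfectly usable for scoring (it is the tightest
null in the family, and the Bayes factor changes by $< 10^{-2}$ between
$A = 10^8$ and $A = 10^{10}$). Interior optima — including legitimately
large ones, which genuinely multinomial data produce — are found by the
Newton/damped machinery and cross-checked against a derivative-free optimizer
in the tests.

**Controls.** Which samples constitute "controls" is an explicit argument
(a sample-id manifest), not an assumption. A leave-one-out scheme over the
cohort itself is possible by running `fit_null_all()` per held-out sample,
but is not asserted to be the original design.

## Bayes-factor calling

The alternative model is the Dirichlet-Multinomial with the Jeffreys prior on
the base composition, all pseudocounts $\tfrac12$:

$$\log B = \log P(x \mid (\tfrac12,\tfrac12,\tfrac12,\tfrac12))
 - \log P(x \mid \hat\alpha_{\text{null}}) .$$

Natural logarithms throughout: the calling threshold $\log B \ge 6$ means
$B \ge e^6 \approx 403$. (A gloss of this threshold as "posterior odds of
50:1" implies prior odds of roughly 1:8 against a variant; under no common
logarithm base do equal prior odds give 50:1, so the package documents the
implication rather than silently reconciling it.) Case counts are *not*
add-one smoothed; smoothing is part of modelling the null from controls.

The candidate alternate allele is the non-reference base with the largest
count (ties broken in A<C<G<T order). Its VAF estimate is the mode of the
marginal posterior under the Jeffreys prior: the posterior over compositions
is Dirichlet$(x + \tfrac12)$, the alt marginal is
Beta$(x_{alt} + \tfrac12,\; n - x_{alt} + \tfrac32)$, and the MAP is
$(x_{alt} - \tfrac12)/n$, clamped into $[0, 1]$.

High-confidence filters, each a threshold argument with the defaults used
throughout:

| filter | default | meaning |
|---|---|---|
| `min_depth` | 500 reads | filtered depth at the locus |
| `min_log_bf` | 6 (natural log) | evidence against the error null |
| `max_pop_af` | 0.01 | population allele frequency; strictly greater is filtered, exactly 1% is retained |
| `max_cohort_count` | 3 samples | a variant called (depth+BF) in ≥ 4 case samples is flagged in all of them |

Scoring happens first and filtering second, so filtered calls remain visible
with their reason flags (`depth`, `bayes_factor`, `population_frequency`,
`cohort_frequency`); `pass` is true iff no flag is set, and a sample is
ctDNA-positive iff it has ≥ 1 passing call. The cohort filter counts samples
in which the variant is *called*, not samples with any non-zero alt count —
at error rates of $10^{-3}$ nearly every sample has a non-zero count at some
locus, which would make the filter vacuous. Whether the population-frequency
filter runs before or after scoring does not change the passing set; only
the bookkeeping of how many calls each filter removed.

## Survival comparison

Kaplan-Meier, the two-sided logrank test and the hazard ratio are implemented
directly (the `survival` package is the independent cross-check in the test
suite, never the implementation):

* $S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$, events before censorings at
  tied times (a subject censored at $t$ is still at risk at $t$);
* logrank: hypergeometric expectation and variance of group-1 events at each
  event time, $\chi^2 = (O_1 - E_1)^2 / V$ on 1 df;
* Mantel-Haenszel hazard ratio $\exp((O_1 - E_1)/V)$ with
  $\exp(\pm z_{0.975}/\sqrt V)$ confidence limits. This estimator is chosen
  over a Cox regression because it is self-contained and matches the logrank
  framing; the two differ in the second decimal at moderate effect sizes,
  and the known attenuation of the Mantel-Haenszel estimate at large hazard
  ratios is visible but within 15% at HR 2.4 in the recovery tests;
* "mean" survival is reported as the restricted mean (exact area under the
  KM step function) up to a horizon no later than the last observed time.

## The synthetic-data generators

No patient-level sequencing or outcome data ship with the package; generators
produce every input the pipeline consumes, as pure functions of a seeded
configuration.

* **Count tables** (`simulate_count_tables()`): per sample-locus depths are
  Poisson around `depth_mean` (default 3200, the order of mean filtered
  target-region coverage in deep TAm-Seq panels; the published mean depth at
  called variants is ~4× higher, so spike-in scenarios use 5000–10000).
  Control counts are Dirichlet-Multinomial draws from a reference-oriented
  `error_alpha` — default $4000 \times (0.997, 0.001, 0.001, 0.001)$, i.e.
  0.1% mean error per alternate base with concentration 4000. Real TAm-Seq
  error overdispersion is not published; the calibration study
  (`run_calibration()`) sweeps the concentration rather than trusting any
  single value. Spiked case counts draw the composition as
  $(1-v)\,p_{\text{err}} + v\,e_{alt}$ with $p_{\text{err}}$ a Dirichlet
  error draw, preserving the error model off the spiked allele; a truth
  table records realised alt counts and depths.
* **Read fixtures** (`simulate_read_set()`): each spec row (alignment
  length, overlap fraction, NM, optional base call at a locus) is realised
  exactly against a deterministic pseudo-reference (base = position mod 4),
  with a companion record of which reads must survive filtering — the oracle
  for filter tests. Emitted both as genuine SAM and as an equivalent TSV so
  the filter stage is testable through a real SAM parser and without one.
* **Survival cohorts** (`simulate_survival_cohort()`): exponential event
  times per group hazard with administrative censoring at a horizon.

What the generators do *not* emulate — and hence what green tests do not
certify about real data: PCR primer artefacts and polymerase context effects,
UMI family structure, base-quality information, strand bias,
trinucleotide-context error sharing, mate-pair overlap, contamination, and
clonal haematopoiesis (CHIP) variants that are real in the plasma but not
tumour-derived. The caller's operating characteristics on real plasma depend
on those; the synthetic results establish correctness of the machinery, not
clinical sensitivity or specificity.

## Numerical and design choices

* Newton tolerance `1e-8` (gradient max-norm in $\log\alpha$), 200 iteration
  cap — cheap in 4 dimensions; per-locus fits are independent (no information
  sharing across loci or trinucleotide contexts).
* Boundary cap $A = 10^8$; ray-jump acceleration (×10 concentration) only
  when it strictly beats the Newton candidate.
* Alt-allele and amplicon-assignment ties break deterministically
  (lexicographic / lower start), so reruns are byte-identical; the pipeline
  manifest records input digests, thresholds, package version, seed and
  output digests, and deliberately contains no timestamps.
* Degenerate inputs fail loudly: fewer than two controls, zero-depth VAF
  requests, missing NM annotations, loci outside every amplicon, spike-ins
  referencing unknown samples or loci, zero-event logrank.
* Test problem sizes: 500-control recovery at depth ~1000; 10,000 null
  scores and 1,000 spiked replicates for operating characteristics; a
  24-sample end-to-end rehearsal (6 controls, 18 cases, 3 spiked at VAF 2%,
  depth 5000); 200-seed logrank null calibration at 1000 subjects per group.
  These sizes give Monte-Carlo error comfortably below the margins being
  asserted while keeping the default suite fast.

## Known limitations

Substitutions only (no indels or multi-nucleotide variants — the allele space
is the four bases); no strand-specific error modelling; no CHIP deconvolution
against white-blood-cell sequencing; no pathogenicity annotation; no
multivariable or competing-risks survival analysis. The package consumes a
user-supplied population-frequency table (TSV or VCF with `AF`) rather than
retrieving one.
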