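# tamseqbf

Detection of circulating tumour DNA (ctDNA) variants in tagged-amplicon deep
sequencing (TAm-Seq) data, and survival comparison of ctDNA-positive versus
ctDNA-negative patients.

Somatic variants shed by a localised tumour appear in plasma cell-free DNA at
allele fractions of a fraction of a percent, far below the raw error rate of
amplicon sequencing. Calling them requires a locus-specific model of the
sequencing-error process, because error rates differ across positions and are
overdispersed relative to a binomial. `tamseqbf` is aimed at analysts of deep
amplicon panels (e.g. *TP53* tiling of plasma DNA) who need a reusable,
testable implementation of that analysis: read filtering, per-locus error
modelling from control samples, Bayes-factor variant calling, per-sample
ctDNA classification, and the downstream survival analysis.

## The model

At each targeted locus, the counts of the four bases across filtered reads of
a control sample, `x = (x_A, x_C, x_G, x_T)` with depth `n = Σ x_k`, are
modelled as Dirichlet-Multinomial:

    P(x | α) = C(n; x) · Γ(A)/Γ(n+A) · Π_k Γ(x_k + α_k)/Γ(α_k),   A = Σ_k α_k

The hyperparameter `α` (one positive 4-vector per locus) is fitted from
control samples by maximising the joint log-likelihood with Newton-Raphson in
`log α` coordinates, after add-one smoothing of the control counts. `α/A` is
the expected base composition under sequencing error; `A` measures how
overdispersed the errors are (multinomial as `A → ∞`).

A case sample's counts `x` at the locus are scored with a Bayes factor
against that null, using the Jeffreys prior (Dirichlet with all pseudocounts
1/2) as the variant-permitting alternative:

    log B = log P(x | α = (1/2, 1/2, 1/2, 1/2)) − log P(x | α̂_null)

The variant allele frequency is estimated as the maximum a posteriori value
of the marginal posterior for the non-reference allele, which is
Beta(x_alt + 1/2, n − x_alt + 3/2) with mode `(x_alt − 1/2)/n`.

High-confidence calls require filtered depth ≥ 500, natural-log Bayes factor
≥ 6, population allele frequency ≤ 1% (e.g. from gnomAD), and recurrence in
fewer than four case samples (recurrent "variants" in unrelated patients are
treated as artefacts). A sample is ctDNA-positive iff it carries at least one
passing call. Groups are compared with Kaplan-Meier curves, a two-sided
logrank test and a Mantel-Haenszel hazard ratio `exp((O₁−E₁)/V)`.

Reads enter the counts only if they align to their amplicon with ≥ 75 bp
alignment length, cover ≥ 75% of the amplicon, and have edit distance ≤ 2.

## Worked example

Fit an error null from 30 control samples at one locus (mean depth 3200,
reference A), score a case sample with 70 alternate reads out of 3200, and
compare survival in a cohort of 22 ctDNA-positive and 167 ctDNA-negative
patients:

```r
library(tamseqbf)
set.seed(1)
x <- rdirmult(30, rpois(30, 3200), c(3189, 4, 3, 4))   # control counts
fit <- fit_null(x)
fit
#> Dirichlet-Multinomial sequencing-error null
#>   controls: 30   mean depth: 3199
#>   alpha:
#>         A         C         G         T
#> 6082.9244   10.4237    6.6664   10.2565
#>   concentration: 6110.27   logLik: -208.891
#>   converged in 5 iterations (gradient max-norm 3.46e-10)

log_bayes_factor(c(3130, 70, 0, 0), fit)
#> [1] 44.2741
map_vaf(c(3130, 70, 0, 0), "C")
#> [1] 0.02171875
```

A log Bayes factor of 44 (threshold 6) flags the 2.2% VAF variant far above
the error process. Survival comparison:

```r
co <- simulate_survival_cohort(c(22, 167), c(0.24, 0.10), 10, seed = 5)
co$group <- factor(co$group, levels = c("ctDNA_positive", "ctDNA_negative"))
compare_survival(co)
#> ctDNA_positive: n = 22, events = 21, restricted mean = 3.61 y
#> ctDNA_negative: n = 167, events = 102, restricted mean = 6.60 y
#> Two-sided logrank test
#>           group observed expected
#>  ctDNA_positive       21     8.29
#>  ctDNA_negative      102   114.71
#> chi-square = 21.2080 (1 df), p = 4.12e-06
#> Mantel-Haenszel hazard ratio (ctDNA_positive vs ctDNA_negative): 5.305 (95% CI 2.608-10.793)
```

The whole pipeline (filter-count → fit-null → call → classify → survival)
runs from one configuration with `run_pipeline()`, writing TSV/VCF outputs
and a JSON manifest; `run_calibration()` sweeps depth × VAF × null
concentration and tabulates the caller's false-positive and detection rates.
A thin command-line wrapper is installed at `inst/scripts/tamseqbf.R`.

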