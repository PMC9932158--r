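# dnmrisk

Personalized recurrence-risk estimation for de novo mutations (DNMs)
from deep amplicon sequencing of parent–child trios.

## What it does, and for whom

A couple whose child carries a pathogenic DNM is conventionally quoted a
generic 1–2% recurrence risk for future pregnancies. For most couples
that number is wrong in one direction or the other: the actual risk
depends on when and in whom the mutation arose. `dnmrisk` is aimed at
statistical geneticists and clinical-genetics laboratories who have
locus-specific deep-sequencing and long-read phasing data for a trio and
want a defensible per-family risk instead of the population figure.

The workflow stratifies each family into one of seven mutational-origin
categories — paternal one-off (A), paternal confined gonadal mosaic
(B), paternal mixed mosaic (C), maternal one-off (D), maternal gonadal
mosaic (E), maternal mixed mosaic (F), post-zygotic in the proband
(G) — and reports a risk on the appropriate basis: measured sperm VAF
for paternal categories, a model-based estimate for maternal or
unresolved families, zero for post-zygotic probands.

## The statistical core

Deep sequencing reports a raw VAF contaminated by background errors.
With `k1/n1` alternate/total reads in unrelated controls and `k2/n2` in
the case sample, the package models

    L(p, q) = B(k1; n1, q) · B(k2; n2, p + (1 − p)·q)

where `p` is the fraction of cells carrying the variant, `q` the
per-site false-positive rate, and `B` the binomial pmf. The point
estimate maximizes the marginal likelihood of `p` (nuisance `q`
integrated out by adaptive quadrature, stabilized in log space); the 95%
interval inverts the profile likelihood ratio, `max_q log L(p, q)`, at
the `χ²₁(0.95)/2 = 1.9207` cutoff. Parent-of-origin comes from
phase-set logic on trio VCFs with a read-backed 2×2 Fisher-exact
fallback. Composite categories use
`risk = P(gonadal mosaic | composite) × E[gamete VAF]`, with prior
ratios 2/17 (proven maternal) and 2/88 (unresolved) under the default
category priors and a bootstrap over a germline VAF panel for the
interval.

## Worked example

Correct a pooled sperm measurement against pooled controls:

```r
library(dnmrisk)
control <- site_counts(3, 18000, "control")
sperm <- pool_replicates(list(site_counts(182, 6105),
                              site_counts(170, 5903),
                              site_counts(195, 6010)))
estimate_corrected_vaf(control, sperm)
#> <vaf_estimate> p_hat = 3.014% [2.775%, 3.278%] (95% profile CI), k/n = 547/18018, control 3/18000
```

The raw pooled VAF is 547/18018 = 3.04%; after correction for the
background rate implied by 3/18000 control reads, the best estimate of
the cell fraction is 3.01% with a profile-likelihood CI of 2.78–3.28%.
Read as a confined-gonadal sperm mosaic, that VAF *is* the estimated
per-conception recurrence risk.

Run the whole workflow on a synthetic paternal mixed-mosaic family
(soma ~2%, sperm ~8%, triplicates at ~6,000×):

```r
fam <- simulate_family("C", seed = 11)
res <- analyze_synthetic_family(fam)
res
#> <family_result> SIM1: category C
#> <risk_estimate> 8.56% [7.75%, 8.56%] (basis: sperm_vaf_upper_ci)

res$vaf_table[res$vaf_table$individual == "father",
              c("tissue_code", "p_hat", "ci_low", "ci_high", "k", "n")]
#>  tissue_code  p_hat ci_low ci_high    k     n
#>            1 0.0220 0.0199  0.0242  398 18040
#>            2 0.0206 0.0186  0.0228  378 18229
#>            3 0.0212 0.0192  0.0234  388 18179
#>            4 0.0181 0.0163  0.0202  328 17970
#>            5 0.0205 0.0185  0.0227  371 18005
#>            6 0.0815 0.0775  0.0856 1449 17767
```

The father is mosaic in every somatic tissue (~2%) with a higher sperm
fraction (~8%, tissue code 6), so the family is classified paternal
mixed mosaicism (C) and the reported risk is the conservative upper
95% bound of the corrected sperm VAF, 8.56%.

Model-based risks for families that cannot be measured directly:

```r
model_based_risk("D_or_E", seed = 1)       # proven maternal, no somatic signal
#> <risk_estimate> 0.49% [0.431%, 0.571%] (basis: model_maternal_DE)
model_based_risk("A_or_D_or_E", seed = 1)  # origin unresolved
#> <risk_estimate> 0.0946% [0.0832%, 0.11%] (basis: model_unresolved_ADE)
```

A command-line wrapper with `simulate`, `verify-trio`, `estimate-vaf`,
`phase-dnm`, `run` and `summarize` subcommands ships in
`inst/scripts/dnmrisk`.

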