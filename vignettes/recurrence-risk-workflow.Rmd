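---
title: "Stratifying de novo mutations and estimating recurrence risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying de novo mutations and estimating recurrence risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmrisk)
```

## The problem

When a child is diagnosed with a disorder caused by an apparently de novo
mutation (DNM), the couple is usually quoted a generic recurrence risk of
1–2% for future pregnancies, reflecting the possibility of occult
parental germline mosaicism. For any specific couple this figure is
almost always wrong: the true risk depends on *when* and *in whom* the
mutation arose. A mutation that occurred as a one-off copying error
during spermatogenesis carries a negligible recurrence risk; a mutation
that arose during the transmitting parent's own early embryogenesis may
populate a substantial fraction of their germline and carry a risk of
several percent; a mutation that arose post-zygotically in the child
carries essentially no recurrence risk at all.

`dnmrisk` implements a trio-based workflow that distinguishes these
situations from two kinds of laboratory evidence, both consumed as
processed tables rather than raw reads:

1. **Deep amplicon read counts** at the DNM site across many tissues of
   both parents and the child (plus unrelated controls), from which
   corrected variant allele fractions (VAFs) and mosaicism calls are
   derived.
2. **Phased variant calls and per-read allele observations** from
   long-read amplicon sequencing, from which the parental origin of the
   mutation is derived.

Families are stratified into seven mutational-origin categories:

| Category | Origin | Timing | Recurrence-risk profile |
|---|---|---|---|
| A | paternal | one-off, late gonadal / spermatogenesis | negligible; bounded by sperm assay |
| B | paternal | confined gonadal mosaic | measured directly in sperm |
| C | paternal | mixed (soma + germline) mosaic | measured directly in sperm, elevated |
| D | maternal | one-off | negligible, not directly measurable |
| E | maternal | confined gonadal mosaic | elevated, not directly measurable |
| F | maternal | mixed mosaic | elevated, unquantifiable (ovary inaccessible) |
| G | post-zygotic in proband | after fertilization | effectively zero for siblings |

Because ovarian tissue cannot be sampled, a maternal family without
somatic mosaicism cannot be split between D and E, and a family whose
origin cannot be phased cannot be split between A, D and E. These
composites (`D_or_E`, `A_or_D_or_E`) are first-class outputs with
model-based risks rather than forced single categories.

## The corrected-VAF model

Deep sequencing at 5,000–20,000x makes sub-percent mosaicism detectable,
but every site carries a background of false-positive alternate reads
(sequencing and PCR errors). Raw VAFs must therefore be corrected using
unrelated control DNA sequenced on the same amplicon.

Let $k_1, n_1$ be the alternate and total read counts in the pooled
controls and $k_2, n_2$ the same for the case sample. With $p$ the
unobserved fraction of cells carrying the variant and $q$ the per-site
false-positive rate, the joint likelihood is

$$
\mathcal{L}(p, q) = B(k_1;\, n_1,\, q) \cdot B(k_2;\, n_2,\, p + (1-p)\,q),
$$

where $B(k; n, \theta)$ is the binomial pmf: a case read showing the
alternate allele is either a true variant read (probability $p$) or a
background error on a non-variant read (probability $(1-p)q$).

The false-positive rate $q$ is a nuisance parameter and is handled two
ways, for two purposes:

* **Point estimate** — $q$ is integrated out over $[0, 1]$ by adaptive
  quadrature and $\hat p$ maximizes the resulting marginal likelihood.
  The integrand is evaluated in log space, stabilized by factoring out
  its maximum, and the integration interval is split at the peak of the
  joint likelihood in $q$ so the quadrature never steps over the sharp
  mode near $k_1/n_1$; this is numerically safe at depths of $10^5$
  reads and more.
* **Confidence interval** — the 95% interval is the set of $p$ whose
  *profile* log-likelihood, $\max_q \log \mathcal{L}(p, q)$, lies within
  $\chi^2_1(0.95)/2 = 1.9207$ log-units of the profile maximum, found by
  bracketed root search on each side and clipped to $[0, 1]$ at the
  boundaries.

The distinction matters. The chi-square calibration of the likelihood
ratio applies to the profiled curve; applying the same cutoff to the
integrated (marginal) curve shifts the effective background rate upward
(the flat prior over $q$ weights values above $k_1/n_1$) and biases the
interval low. In our own simulation at the conditions used throughout
this package ($p = 1\%$, $q = 2\times10^{-4}$, $n = 15{,}000$, 500
replicates) the marginal-curve interval covered the truth 89% of the
time while the profile interval covered 95.6% — which is why the
package computes the point estimate from the marginal likelihood but
the interval from the profile likelihood.

```{r estimate}
control <- site_counts(3, 18000, "control")
sperm <- pool_replicates(list(site_counts(182, 6105),
                              site_counts(170, 5903),
                              site_counts(195, 6010)))
estimate_corrected_vaf(control, sperm)
```

Technical replicates are pooled by summing counts (failed replicates,
$n = 0$, are dropped; a fully failed sample is reported as an explicit
`sample_failure`, never a silent zero). All case samples of a family are
corrected against the pooled counts of the unrelated controls run on the
same amplicon.

## Mosaicism calls

A **parent** is called mosaic when any tissue shows unambiguous signal:
the profile-CI lower bound excludes 0 *and* $\hat p$ reaches the
decision floor (default 0.3%). The floor separates genuine low-level
mosaics (the smallest published mosaic sperm VAF is about 0.2%) from
background-level fluctuation, and is configurable and recorded in every
report.

A **child** is expected to be a constitutional heterozygote ($p = 0.5$
in every tissue). Post-zygotic mosaicism is called when the variant is
present but at least one tissue's CI upper bound falls below the lower
edge of the constitutional band (default $[0.45, 0.55]$). The band
edge — not 50% itself — is the decision boundary on purpose: a 95% CI
excludes the true value on the low side in ~2.5% of constitutional
tissues by construction, so with three child tissues a naive
"CI excludes 0.5" rule would falsely reclassify roughly 7% of ordinary
constitutional probands. A genuine post-zygotic signature (e.g. blood
at ~42% with buccal samples at 8–10%) clears the band edge by a wide
margin.

## Parent-of-origin phasing

The primary route uses trio phased VCFs (`GT:PS:DP`): SNPs sharing the
DNM's phase set (depth strictly greater than 10) identify the haplotype
carrying the mutation, and the parental genotypes at those SNPs identify
which parent transmitted that haplotype. A SNP is informative in the
classic configuration — child heterozygous, one parent homozygous for
the complement of the in-phase allele, the other parent carrying it.
Strict unanimity is required: if two informative SNPs disagree the
family is returned `unresolved` with a conflict flag rather than
majority-voted, since a single switch error can otherwise silently flip
a call. A DNM called in a parent is rejected as "not de novo" — a
distinct condition from `unresolved`.

The fallback route works from per-read allele observations spanning the
DNM and the nearest child-heterozygous SNP with a known-variant
annotation: a 2x2 table (DNM REF/ALT x SNP REF/ALT) is tested with a
two-sided Fisher's exact test (implemented by direct hypergeometric
enumeration), and when $p < \alpha$ (default 0.01) the origin is the
parent whose transmissible SNP allele co-occurs in excess with the
DNM-ALT reads. Non-significant tables are returned unresolved with the
table attached for manual review. When the nearest SNP is itself
uninformative, a second SNP can be phased transitively (SNP1 to the DNM,
SNP2 to SNP1 within the same read set) with informativeness evaluated at
SNP2.

Two prior-knowledge shortcuts take precedence over sequencing: an
X-linked locus in a male proband is obligately maternal, and an
imprinted locus with a configured obligate origin is assigned directly.
Externally asserted results (e.g. allele-specific PCR for large indels)
enter through an explicit override in the family manifest, never by
inference.

## Category assignment and risk

The decision tree: post-zygotic proband → G; paternal somatic
mosaicism (with or without sperm) → C; sperm-only paternal
mosaicism → B; maternal somatic mosaicism → F; otherwise paternal
origin → A, maternal origin → `D_or_E`, unresolved → `A_or_D_or_E`.
Contradictory evidence (a mosaic parent opposite the phased origin, or
simultaneous proband and parental mosaicism) raises a conflict error for
manual resolution — never a silent pick.

Risks are reported on three bases:

* **Measured (A, B, C)** — the corrected sperm VAF is taken 1:1 as the
  per-conception transmission risk. The default is the conservative CI
  upper bound; `conservative = FALSE` reports the point estimate.
* **Model-based (`D_or_E`, `A_or_D_or_E`)** — only the confined-gonadal
  member of the composite carries risk, so
  $\text{risk} = P(\text{gonadal mosaic} \mid \text{composite}) \times
  E[\text{gamete VAF} \mid \text{gonadal mosaic}]$. With the default
  priors (A 71%, D 15%, E 2%) the conditional probabilities are
  $2/17$ for proven-maternal and $2/88$ for unresolved families. The
  expected gamete VAF comes from a panel of sperm VAFs of confined
  gonadal mosaics, used as the ovarian proxy (germline specification
  precedes sex determination, so the magnitudes are expected to match).
  Uncertainty is propagated by a percentile bootstrap over the panel.
* **Qualitative** — maternal mixed mosaicism (F) is flagged
  `unquantifiable_increased` (the maternal germline cannot be sampled);
  post-zygotic probands (G) are reported as risk 0.

```{r risks}
model_based_risk("D_or_E", seed = 1)
model_based_risk("A_or_D_or_E", seed = 1)
```

### The germline VAF panel is synthetic

The shipped panel (`germline_vaf_model()`: 16 values, 2.8–8.5%, mean
4.2%, right-skewed) is a **synthetic reference set**, not patient data.
It was constructed to be representative of deep sperm-WGS studies of
confined gonadal mosaics and calibrated so that the two cohort-level
combined risks above reproduce the published clinical estimates (0.49%,
95% CI 0.43–0.57%, for proven-maternal families; 0.09%, 95% CI
0.08–0.11%, for origin-unresolved families). Note that the implied mean
gamete VAF (~4.2%) is somewhat above the ~3% often quoted as the average
sperm-only mosaic VAF; the published combined risks are only consistent
with the higher value, and the panel follows the risks. Sites with an
empirical panel should replace `vafs` in the configuration; the
bootstrap machinery is unchanged.

The priors for the directly observable categories B, C, F, G are not
individually identified by the published headline figures; the default
allocation (3%, 4%, 3%, 2% of the remaining 12%) is an editable
configuration and does not enter either composite risk.

## The synthetic-family generator

Every downstream stage is testable without patient data via
`simulate_family()`, which emulates the study design:

* up to 14 samples per trio — father: buccal left/right, blood, saliva,
  urine, sperm (tissue codes 1–6); mother: codes 1–5; child: buccal
  left/right and diagnostic gDNA (codes 1, 2, 7);
* triplicate reactions per sample with per-replicate totals drawn
  Poisson around `depth_mean` (default 6,000, the lower end of the
  study's target depth, chosen to exercise the workflow under its least
  favourable sanctioned conditions; no overdispersion model is published
  for replicate depth, so Poisson is the simplest defensible choice);
* three unrelated controls, also in triplicate, at the same depth;
* a per-site background error rate (default $2\times10^{-4}$, the
  middle of the observed $10^{-4}$–$10^{-3}$ range);
* scenario-specific true fractions: confined gonadal ~3% (sperm only),
  mixed mosaics 2% soma / 8% sperm in the father and ~4% soma in the
  mother, post-zygotic probands with strong inter-tissue variation
  (8%/10%/42%), one-off events at 0 in every sampled parental tissue;
* a 154-SNP trio genotype panel at Hardy–Weinberg proportions with
  Mendelian (or deliberately non-Mendelian) children;
* phasing reads at 200x with a 1% per-read switch-error rate and either
  an informative or an uninformative parental SNP configuration.

One RNG stream is derived per family from `(master seed, family index)`,
so cohorts are reproducible family-by-family and bit-identical across
runs.

What the generator does **not** emulate: raw reads, alignment artifacts,
homopolymer-specific long-read error, PCR allele bias between
replicates, and overdispersion of the background error across amplicons.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated noise model, not robustness to every failure
mode of real assays; the workflow's manual-review hooks (attached
2x2 tables, conflict errors, explicit overrides) exist for exactly the
cases the model does not cover.

```{r endtoend}
fam <- simulate_family("C", seed = 11)
res <- analyze_synthetic_family(fam)
res
```

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate` at relative tolerance $10^{-9}$, split
  at the joint-likelihood peak in $q$; non-convergence raises an error
  carrying the $(p, k_1, n_1, k_2, n_2)$ context.
* Optimization: golden-section (`stats::optimize`) at tolerance
  $10^{-10}$ on $p$, with explicit boundary checks at $p = 0$ and
  (when $k_2 = n_2$) $p = 1$; the marginal and profile maximizers differ
  by $O(1/n_1)$ and the point estimate is clamped into the CI to keep
  the reporting invariant.
* Fisher's exact test sums hypergeometric probabilities not exceeding
  the observed table's probability, with the conventional $1+10^{-7}$
  relative tie tolerance. A table with a single populated margin
  returns $p = 1$ (no association is testable); an all-zero table is an
  error.
* A sample with all replicates failed propagates as `sample_failure`; a
  paternal-category family whose sperm sample failed falls back to the
  origin-unresolved model risk with a warning.
* The phase-set depth filter is strict: a SNP at depth exactly 10 is
  excluded.
* Coordinates are 1-based inclusive (VCF convention) throughout.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulation studies
as follows: estimator-versus-oracle agreement on 10 randomized count
configurations (depths to 50,000) against a 2001x2001 log-spaced grid
oracle; interval coverage at 500 replicates of the
$p=1\%,\ q=2\times10^{-4},\ n=15{,}000$ condition; category recovery on
50 families per scenario at depth 6,000; and the one-off-paternal sperm
bound (upper CI below 0.05%) on 30 families at the 19,000x replicate
depth at which that bound is a property of the assay — at depth 6,000
pooled case-side Poisson noise alone places roughly one clean sperm
sample in eight above 0.05%, so the bound is reported at depth 6,000
only by its median.

## Known limitations

* The D/E and A/D/E risks inherit the synthetic germline VAF panel's
  calibration; they are cohort-level figures, not per-family
  measurements.
* Maternal mixed mosaicism yields no quantitative risk at all — somatic
  VAFs are poor predictors of the germline, as families with low blood
  VAF but multiple recurrences demonstrate.
* The constitutional band $[0.45, 0.55]$ leaves a gray zone: a child
  tissue truly at, say, 46% is reported constitutional.
* Genotype calling, read alignment and variant calling are upstream of
  this package; their systematic errors (e.g. allele-biased capture)
  are invisible to the correction model, which sees only counts.
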