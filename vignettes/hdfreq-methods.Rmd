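---
title: "Modelling expanded HTT CAG repeat frequency and clinical ascertainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling expanded HTT CAG repeat frequency and clinical ascertainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdfreq)
```

## The estimation problem

Huntington's disease prevalence is a count of diagnosed patients, not of
disease-causing genotypes. Three processes separate the two: expanded-repeat
carriers may not yet have reached their onset age; carriers die (of the
disease and of other causes) and so deplete with age; and symptomatic
carriers may never be diagnosed. `hdfreq` models each process explicitly so
that, given a clinically ascertained cohort's allele spectrum and a
prevalence figure, the size of each gap can be estimated.

## The exponential decay law

The empirical CAG spectrum in European-ancestry populations peaks at 17
repeats and decreases log-linearly beyond the peak, a trend that continues
across the unexpanded/expanded boundary. The package models the expected
allele count at repeat length $c$ as

$$n(c) = 10^{\beta_0 + \beta_1 c},$$

estimating $(\beta_0, \beta_1)$ by unweighted least squares of
$\log_{10} n(c)$ on $c$ (`fit_decay()`). A weighted or Poisson-GLM variant
would change bin influence; the unweighted log-scale fit is the convention
this estimator follows, and over the default unexpanded range (CAG 18–35,
where counts are large) the difference is immaterial. Zero-count bins
inside a fit range abort the fit rather than being dropped: the default
ranges are chosen so this cannot happen on cohort-scale data, and silently
omitting a bin would bias the slope.

`decay_model()` extends the fitted law over CAG 17–55 and attaches the
allele-pool denominator. One subtlety deserves emphasis: with the reference
coefficients ($\beta_0 = 5.552482$, $\beta_1 = -0.13925$, fitted to a
7578-subject cohort contributing one unexpanded allele each), $n(c)$ is an
expected *count per 7578-allele pool*. The population allele fraction is
therefore $n(c)/7578$ — at CAG 42 this gives $6.67\times10^{-5}$, i.e.
0.00667% of chromosomes. Treating $n(c)$ directly as a percentage would be
off by orders of magnitude; the `allele_pool` field makes the conversion
explicit and mandatory.

Carrier frequencies double the allele fraction. At these magnitudes
homozygotes are vanishingly rare ($\sim f^2$), so the heterozygote
approximation is accurate to well below every tolerance used here; it also
reproduces the familiar band reciprocals (about one carrier in 17 for
intermediate alleles 27–35, one in 415 for reduced-penetrance alleles
36–39). Reciprocals are reported as `floor(1/f)`, the convention under
which a prevalence of $12.4\times10^{-5}$ reads "one in 8064".

Before committing to the decay law, `fit_reference_distributions()` fits
eight textbook families (normal, Poisson, negative binomial, Cauchy,
gamma, log-normal, logistic, Weibull) by maximum likelihood via
**fitdistrplus**; none captures the sharp peak plus log-linear tail, which
is the diagnostic motivation for the decay model.

`prevalence_anchored_distribution()` scales the unexpanded spectrum to the
population implied by a prevalence anchor (for the reference cohort:
$7578 \times 8064$ people, hence $2 \times 61\,108\,992 - 7578 =
122\,210\,406$ unexpanded chromosomes). The deterministic mode apportions
counts with largest-remainder rounding, chosen because it conserves the
target total exactly with at most one unit of per-bin distortion; the
sampled mode is a seeded multinomial bootstrap.

## Onset and death models

Ages at motor onset and ages at death are modelled per CAG as log-normal.
Because the input is fully observed event ages (no censoring), the MLE is
closed-form: `meanlog` is the mean log age and `sdlog` the n-denominator
log-scale standard deviation. `fit_event_model()` computes exactly that,
and the test suite cross-checks it against `survival::survreg`, which
solves the same likelihood iteratively. Censored input is rejected
outright rather than silently mishandled — censored survival analysis is
out of scope. Samples below `min_n = 30` ages fit but carry a `low_n`
flag, since per-CAG death data outside CAG 40–50 are typically too sparse
to trust.

Carrier survival combines two independent hazards: the disease-specific
survival $S_{HD}(c,a) = 1 - F_{death}(c,a)$ and general-population
survival $S_{pop}(a)$ from an actuarial life table, as a plain product.
$S_{pop}$ compounds one-year survival probabilities using the arithmetic
male/female mean of $q(a)$; averaging survivor curves instead would differ
only in the fourth decimal at these magnitudes.

## Age adjustment and cohort comparison

Inside the adjustment band (CAG 40–50, where death models are reliable)
the birth carrier frequency is multiplied by $S_{HD} \times S_{pop}$;
outside it (notably the reduced-penetrance 36–39 range) the birth value is
used unchanged — extrapolating a survival model fitted on 40–50 down to
alleles with much weaker mortality effects would overstate depletion. Two
conventions are deliberate:

* The product is **not** renormalised by the surviving general population.
  The quantity is "carriers per birth-cohort member", matching how
  prevalence denominators are constructed downstream. Frequency among
  *survivors* would divide by $S_{pop}$; that variant is documented but
  not the default.
* `cohort_expected_spectrum()` marginalises the surface over an age
  distribution by exact expectation. Sampling adds nothing but noise for
  model validation; a seeded Poisson-sampled mode exists for illustration.

`chi_squared_compare()` implements the Pearson test with the two
behaviours cohort comparisons need: expected counts are rescaled to the
observed total (shape comparison), and bins with expected count below 5
are pooled into their lower neighbour, since the asymptotic chi-squared
reference is unreliable on sparse bins. The exact CAG window and pooling
rule for any given biobank comparison are user choices; the defaults are
stated, not hidden.

## Population census and ascertainment

`realize_age_structure()` turns decade-band pyramid weights (the packaged
EU 2020 pyramid carries the eleven band totals from 0–9 up to 100+, the
open band realised as ages 100–104) into per-age person counts, uniform
within bands, scaled to the requested population. The census then sums
$w(a)\,f(c,a)$ for carriers and $w(a)\,f(c,a)\,F_{onset}(c,a)$ for
symptomatic carriers. Fractional expectations are kept exact internally —
so symptomatic + asymptomatic equals carriers to machine precision — and
only the print layer rounds to whole persons.

The ascertainment rate divides band-adjusted prevalence by the
symptomatic-carrier frequency. Two published figures coexist for the
CAG 40–50 band adjustment of 12.4 per 100 000: the share statement (90%,
giving 11.16) and the printed adjusted figure 11.6. Both are supported;
the printed 11.6 is the default because it is the figure the reference
ascertainment estimate is built on. A rate above 1 is physically
inconsistent (more diagnoses than symptomatic carriers) and is flagged
with a warning, never clamped.

## The packaged calibration

`hd_calibration()` constructs every model deterministically from published
anchors:

| Parameter | Value | Origin |
|---|---|---|
| decay $\beta_0, \beta_1$ | 5.552482, −0.13925 | reference cohort fit |
| allele pool | 7578 | one unexpanded allele per subject |
| onset medians, CAG 41–45 | 56.5, 52, 48, 43.5, 40.5 y | published 50%-onset ages |
| onset `sdlog` | 0.2 | chosen; see below |
| onset→death gap | 15 y | typical disease duration |
| death `sdlog` | solved ≈ 0.159 | anchor: $S_{HD}(42, 64) = 0.612$ |
| life table $A, G$ | $5\times10^{-4}$, 0.085 | realistic Makeham background and Gompertz doubling (~8 y) |
| life table $B$ | solved ≈ $5.26\times10^{-5}$ | anchor: $S_{pop}(64) = 0.845$ |

The onset-median curve is a log-linear least-squares fit through the five
anchors (they are almost exactly log-linear; residuals ≤ 0.4 y),
extrapolated over CAG 40–50 — onset genetics supports approximate
log-linearity of median onset in repeat length. The two `sdlog`-type
solves use `uniroot` to $10^{-12}$; construction fails loudly if an anchor
is infeasible (e.g. a death median pushed at or below 64 cannot reach
survival 0.612 there).

The onset `sdlog` of 0.2 deserves honesty: the source models' log-scale
spreads are not published. 0.2 gives onset-age coefficients of variation
of ~20%, consistent with reported onset-age spreads at these repeat
lengths. All downstream headline numbers that mix frequency, survival and
onset (the 63/22 census, the ~52% ascertainment rate, the one-in-321
expanded-carrier reciprocal) inherit this choice, which is why their
acceptance tolerances are 10–20% rather than printed-digit agreement.

## The synthetic-data generator

`simulate_hd_cohort()` draws cohorts with the structure the analysis
assumes: one unexpanded allele (decay law on 17–35 plus a steep geometric
sub-17 shoulder, ratio 0.3 per repeat, so the spectrum peaks at 17 — the
shoulder exists for spectral realism only and never enters a fitted
range), one expanded allele (same law on 36–55), log-normal onset ages on
the calibrated median curve, and death = onset + gamma(shape 4, mean 15 y)
duration. The gamma gap produces a right-skewed duration with ~7.5 y
spread; refitting the resulting death ages log-normally downstream mirrors
the estimator's own fitting choice. `simulate_population_cohort()` adds
volunteer-cohort features: a multiplicative carrier `depletion` factor
(healthy-volunteer bias) and Bernoulli diagnosis thinning among
symptomatic carriers.

What the generator does **not** emulate: repeat-length measurement error,
somatic or intergenerational instability, family structure, and real
cohorts' non-uniform within-decade age profiles. Passing recovery tests on
generated data therefore demonstrates estimator correctness under the
model's own assumptions, not robustness to those artefacts.

## Numerical and testing choices

Problem sizes were picked so the full suite runs in well under a minute:
slope-recovery uses $10^6$ simulated alleles (sampling error ~$10^{-3}$ on
the slope), onset refits use $10^4$ ages per CAG (median standard error
~0.13 y against ±1 y tolerances), and the census uses the exact
expectation, which is size-free. Stochastic assertions are seeded and
sized so their false-failure probability is small: the chi-squared null
battery uses 100 seeds for its ">90% of p-values above 0.05" check, and
diagnosis-thinning recovery is asserted on the 20-seed battery mean
(per-seed Monte-Carlo sd at 2000 carriers is ~0.03, so a per-seed ±0.05
bound would fail by chance in most runs).

## Known limitations

* Everything inherits the decay law's extrapolation: if the spectrum
  departs from log-linearity above CAG 50, carrier estimates there are
  unanchored.
* Uncensored event models presume recorded event ages represent the
  carrier population; ascertainment bias in who gets an onset age recorded
  is not modelled.
* The 36–39 band is never age-adjusted, so its carrier counts are
  birth-frequency upper bounds at older ages.
* The ascertainment rate is an expectation ratio; no sampling uncertainty
  interval is attached to it.
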