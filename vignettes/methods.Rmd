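---
title: "Methods: genotype-count meta-analysis and Wald-ratio Mendelian randomization"
author: "hcymr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-count meta-analysis and Wald-ratio Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcymr)
```

## The scientific problem

Elevated plasma total homocysteine (tHcy) is observationally associated
with gastric cancer (GC), but the association is entangled with
confounding (diet, folate status, *H. pylori* infection) and possible
reverse causation. The MTHFR C677T polymorphism lowers
methylenetetrahydrofolate-reductase activity and raises tHcy in a
per-allele fashion, and genotypes are assigned at meiosis independently
of lifestyle — the classic premise of Mendelian randomization (MR).
`hcymr` implements the two-stage design this enables:

1. estimate the gene–disease association by meta-analysis of
   case–control genotype counts, and
2. rescale it by the known gene–exposure effect to obtain the causal
   effect of tHcy on GC risk.

This vignette records the model, the estimators, the tunable
parameters, the synthetic-data generator that stands in for the
literature, and the design decisions taken where the methodology was
genuinely open.

## Stage 1: the meta-analytic model

### Per-study effects

Each study contributes genotype counts (CC, CT, TT) for cases and
controls. A genetic-model contrast collapses these into a 2×2 table
(`genetic_contrast()`): allele (T vs C, persons contributing two
alleles), homozygous (TT vs CC), heterozygous (CT vs CC), dominant
(TT+CT vs CC), recessive (TT vs CT+CC). The homozygous and heterozygous
contrasts are pure 2×2 comparisons of the two named genotypes — carriers
of the excluded genotype simply do not enter the table, the standard
reading of these contrasts.

The per-study effect is the log odds ratio
$\hat\theta_i = \ln(a_i d_i / b_i c_i)$ with the large-sample SE
$\sqrt{1/a_i + 1/b_i + 1/c_i + 1/d_i}$. **Zero cells** are handled by
the Haldane–Anscombe rule: if any cell is zero, 0.5 is added to all four
cells (the dominant convention in genetic meta-analysis; the `corrected`
flag records it). A table with an entire row or column of zeros carries
no information about the OR; such studies are flagged non-estimable and
excluded from pooling with a warning rather than silently dropped.

The allele model treats the two alleles of a person as independent
observations. This is the convention of the case–control SNP literature
this package addresses; it is exact under Hardy–Weinberg equilibrium and
slightly anti-conservative under inbreeding-type departures, which is
one reason the HWE screen and the HWE-exclusion sensitivity analysis
exist.

### Pooling

With inverse-variance weights $w_i = 1/SE_i^2$:

* fixed effect: $\hat\theta_F = \sum w_i \hat\theta_i / \sum w_i$,
  $SE_F = 1/\sqrt{\sum w_i}$;
* Cochran's $Q = \sum w_i (\hat\theta_i - \hat\theta_F)^2$, referred to
  $\chi^2_{k-1}$; $I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$;
* DerSimonian–Laird:
  $\hat\tau^2 = \max\!\big(0,\, (Q - (k-1)) \big/ (\sum w_i - \sum w_i^2/\sum w_i)\big)$,
  then random-effects weights $w_i^* = 1/(SE_i^2 + \hat\tau^2)$ and the
  same inverse-variance algebra.

DL was chosen for $\hat\tau^2$ (it is what the field's standard software
computes by default); REML and Paule–Mandel are out of scope. When
$Q \le k-1$ the estimate truncates to zero and the random-effects result
coincides exactly — bitwise — with the fixed-effect result, which the
tests assert. For a single study the conventions $Q = 0$, $p_Q = 1$,
$I^2 = 0$ apply.

**Model choice.** The reported model is random-effects when
$p_Q < 0.1$ *or* $I^2 > 50\%$, fixed-effect otherwise. The source
literature's description of this rule is self-contradictory as printed;
we resolved it to the standard practice its stated thresholds imply, and
side-step the ambiguity operationally by always computing and reporting
*both* pooled results (`meta_pool$fixed`, `meta_pool$random`), with
`selected` recording the rule's verdict. 95% intervals use 1.96 (the
normal quantile to the precision the conventions of this literature
use); all p-values are two-sided.

### Hardy–Weinberg screening

Control genotypes are tested against HWE proportions
$p^2 : 2p(1-p) : (1-p)^2$ by the asymptotic Pearson χ² with 1 df
(`hwe_test()`), matching the field's usual screen; no exact or mid-p
variant is provided. Monomorphic control arms return probability 1 by
convention (logged): a fixed sample offers no evidence against HWE.
Studies with $p_{HWE} < 0.05$ are flagged, and `hwe_exclusion()`
re-pools without them.

### Subgroup and sensitivity analyses

`subgroup_analysis()` re-runs the full pipeline within strata of
ethnicity (Asian / Caucasian / Mixed) or source of controls
(population / hospital). Unrecognized stratum labels map to
Mixed / hospital with a warning — the conservative "don't invent a
stratum" choice. `leave_one_out()` repeats the pooling k times omitting
each study, re-applying the model-selection rule each time, and flags
whether each reduced pool remains significant.

### Publication-bias diagnostics

**Egger's test** regresses the standardized effect
$\hat\theta_i/SE_i$ on precision $1/SE_i$ by OLS; the intercept is the
asymmetry parameter and $t = b_0/SE(b_0)$ is referred to $t_{k-2}$.
This standardized parameterization is algebraically identical to the
weighted regression of $\hat\theta$ on $SE$ with multiplicative
dispersion (the tests confirm exact agreement with `metafor`'s
implementation of the classical test). Two degenerate inputs are
reported rather than crashed on: all SEs equal (no precision spread —
slope and intercept inseparable) and an exact linear relation (zero
residual variance); both warn and return p = 1 when no asymmetry
evidence exists.

**Begg's test** forms variance-stabilized deviates
$u_i = (\hat\theta_i - \hat\theta_F)/\sqrt{SE_i^2 - 1/\sum w_j}$ and
rank-correlates them with the variances $SE_i^2$ (Kendall), using the
tie-corrected null variance of the S statistic and a continuity
correction for the two-sided normal p — the Begg–Mazumdar construction.

`funnel_data()` exports the per-study points and pseudo-95% boundary
columns for plotting; no trim-and-fill or selection models are offered.

## Stage 2: the Wald ratio

With the pooled per-T-allele log OR $\hat\theta$ and the gene–exposure
effect $\beta$ (SD of ln-tHcy per T allele),

$$\widehat{\log OR}_{GC/hcy} = \hat\theta / \beta.$$

Two delta-method SEs are available (`se_mode`):

* `simplified` (default): $SE(\hat\theta)/|\beta|$, treating $\beta$ as
  a known constant;
* `full-delta`:
  $\sqrt{SE^2/\beta^2 + \hat\theta^2 SE_\beta^2/\beta^4}$, first-order
  propagation of both uncertainties — recommended whenever a credible
  $SE_\beta$ is available.

The default is `simplified` because back-calculation shows the
literature's headline point estimate is the plain ratio, and because
$\beta$ here comes from a GWAS meta-analysis (44,147 individuals) an
order of magnitude larger than the case–control material; its default
value is 0.158 SD ln-tHcy per allele with $SE_\beta = 0$, both
overridable (`gene_exposure()`). A $|\beta|$ below 0.01 SD/allele flags
the result `weak_instrument`; $\beta = 0$ is a usage error.

**A documented discrepancy.** Feeding the published allele-model pooled
OR of 1.16 into the ratio gives $\exp(\ln 1.16 / 0.158) = 2.56$ per SD
ln-tHcy, reproducing the published point estimate exactly. The
published interval around it (2.41–2.72) is, however, far narrower than
*any* delta-method propagation of its own inputs: the simplified SE
$0.0461/0.158 \approx 0.292$ gives (1.44, 4.53). No combination of the
published inputs yields the published CI or its p-value, so this
package reproduces the point estimate, reports the delta-method
interval it can defend, and validates interval behaviour by coverage
simulation instead (see below). The contradiction is reported, not
resolved: with α = 0.05 labelling, an Egger p of 0.045 is "significant
asymmetry" even where the source narrative says otherwise; the package
prints the numbers and leaves the labelling to the reader.

## The synthetic-study generator

No per-study genotype counts are redistributable for the 27-study
literature, so `simulate_studies()` generates collections with known
truth; it is first-class, tested code, not a fixture.

Per study $i$: control T-allele frequency
$q_i \sim U(\text{maf\_range})$; study effect
$\delta_i = \text{true\_log\_or} + N(0, \tau)$; control genotype
probabilities HWE($q_i$), distorted for violating studies by an
inbreeding coefficient $F$
($f_{TT} = q^2 + Fq(1-q)$, $f_{CT} = 2q(1-q)(1-F)$ — allele frequency
preserved, heterozygotes deficient); case genotype probabilities
proportional to $\text{HWE}(q_i)\, e^{\delta_i g}$ with $g$ the
T-allele count — the multiplicative per-allele odds model, the simplest
generative model whose population allele-level OR is exactly
$e^{\delta_i}$; counts multinomial at arm sizes drawn uniformly from
the configured ranges.

Reproducibility choices worth recording:

* **Substreams.** Study $i$ seeds its own RNG substream derived from
  the root seed and $i$, so enlarging `k` appends studies without
  reshuffling earlier ones, and a collection is byte-identical across
  runs.
* **Prefix-stable violation assignment.** Study $i$ violates HWE iff
  $\lfloor i f \rfloor > \lfloor (i-1) f \rfloor$ — a Bresenham-style
  rule giving exactly $\lfloor k f \rfloor$ violators, stable under
  growth of $k$.
* **Small-study bias.** When enabled, studies with a case arm below the
  midpoint of the size range are redrawn until their observed allele
  log OR reaches the true value — one-sided censoring of small
  unfavourable studies, the textbook mechanism funnel asymmetry tests
  target.

`mthfr_gc_config()` encodes the emulated study conditions:
k = 27 studies; true per-allele OR 1.16; τ = 0.15 (moderate
heterogeneity, I² around 50%, consistent with a literature analyzed
under random effects); case arms 50–420 and control arms 60–550
(averaging ≈ 235 and ≈ 305, matching the literature's totals of 6,266
cases and 8,250 controls across 27 studies); control T-allele
frequencies 0.20–0.55 (spanning East-Asian and European MTHFR 677T
frequencies, majority-Asian ethnicity mix); 7 of 27 studies
HWE-violating with F = 0.2 (detectable but not overwhelming distortion
at these sample sizes). These values were fixed once, from the
literature's own description, and are the conditions under which the
calibration tests run.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: genotyping error other than the inbreeding
distortion, covariate-level confounding, overlapping or duplicated
study populations, ethnicity-linked allele-frequency/effect
correlation, pleiotropy of the instrument, and any non-multiplicative
penetrance. Calibration under the generator is a necessary, not a
sufficient, condition for trusting the pipeline on literature data.

## Numerical choices and degenerate inputs

* 1.96 is used literally for all 95% intervals; p-values are two-sided
  normal (pooling, MR) or $t_{k-2}$ (Egger).
* $I^2$ and $\hat\tau^2$ truncate at zero; both are reported for the
  fixed- and random-effects objects alike.
* Normalized pooling weights must sum to 1 within 1e−9 (asserted in
  tests).
* Bias tests require $k \ge 3$, leave-one-out $k \ge 2$; below that
  they are skipped with warnings in the pipeline and are usage errors
  when called directly.
* Begg's $u_i$ denominator $SE_i^2 - 1/\sum w_j$ is strictly positive
  for $k \ge 2$; it is floored at machine epsilon as belt-and-braces.
* Readers/writers use 10 significant digits in JSON so that a report
  round-trip is faithful to well beyond 6 significant figures.

## Problem sizes used by the validation suite

The test suite's simulation sizes are a deliberate compromise between
Monte-Carlo resolution and a suite a maintainer will actually run:
coverage claims use 2,000 replicates (MC SE ≈ 0.5 percentage points on
a 95% coverage probability, against acceptance bands of ±1.5 points);
τ² recovery and end-to-end causal-effect recovery use 500 replicates of
the full 27-study design; bias-test size uses 2,000 replicates with
power checked against 300 censored replicates; oracle-equivalence
checks (HWE vs brute-force Pearson over all control tables with
total ≤ 50, Begg vs all-pairs enumeration, Egger and the pooled
estimators vs explicit normal equations) are exhaustive or
tolerance-1e−10 and run in seconds.

## Known limitations

* Single-instrument MR only: no IVW across variants, MR-Egger or
  weighted-median estimators, and no way to detect pleiotropy
  internally.
* DL interval coverage is known to dip a few points below nominal at
  moderate k with substantial heterogeneity; the package inherits this
  property of the estimator it implements (the 27-study coverage
  acceptance band, ≥ 93%, reflects it).
* The asymptotic HWE χ² is anti-conservative for very small control
  arms; an exact test is deliberately out of scope.
* The allele model's independence assumption is exact only under HWE
  in both arms.
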