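# hcymr

Genotype-count meta-analysis and Wald-ratio Mendelian randomization for
the MTHFR C677T polymorphism, plasma homocysteine and gastric cancer.

## What it does and for whom

Observational studies associate elevated plasma total homocysteine (tHcy)
with gastric cancer (GC), but confounding and reverse causation make the
association hard to interpret. The MTHFR C677T variant raises tHcy in a
dose-per-allele fashion and is assigned at meiosis, so it can serve as an
instrumental variable. `hcymr` is for epidemiologists and biostatisticians
who want to run — or stress-test — the two-stage analysis this design
implies, starting from nothing more than a flat table of per-study
genotype counts:

**Stage 1 — genotype-count meta-analysis.** For each case–control study
with genotype counts (CC, CT, TT) in both arms, the package builds 2×2
tables under the five standard genetic contrasts (allele T vs C,
homozygous TT vs CC, heterozygous CT vs CC, dominant TT+CT vs CC,
recessive TT vs CT+CC), computes per-study log odds ratios
θ̂ᵢ = ln(aᵢdᵢ/bᵢcᵢ) with SE √(1/aᵢ+1/bᵢ+1/cᵢ+1/dᵢ), and pools them by
inverse variance. Both the fixed-effect pool (wᵢ = 1/SEᵢ²) and the
DerSimonian–Laird random-effects pool
(τ̂² = max(0, (Q−(k−1))/(Σw−Σw²/Σw)), wᵢ* = 1/(SEᵢ²+τ̂²)) are always
computed; the reported model follows the usual heterogeneity rule
(random when the Cochran Q p-value < 0.1 or I² > 50%). Around the pool:
a Hardy–Weinberg χ² screen of every control arm, subgroup analyses by
ethnicity and source of controls, leave-one-out and HWE-exclusion
sensitivity analyses, and Egger regression / Begg–Mazumdar
rank-correlation tests for small-study bias.

**Stage 2 — Wald-ratio MR.** The pooled per-T-allele log OR is divided
by the per-allele effect of C677T on tHcy (β = 0.158 SD of ln-tHcy per
allele, from a GWAS meta-analysis of 44,147 individuals; supplied as a
constant and overridable):

    log OR_GC/hcy = log OR_GC/per-T-allele / β_hcy/per-T-allele

with delta-method SE, either `simplified` (SE/|β|) or `full-delta`
(propagating an SE for β as well).

Because per-study genotype counts for the published 27-study literature
are not redistributable, the package ships a seeded synthetic-study
generator with known truth (`sim_config()`, `simulate_studies()`,
`mthfr_gc_config()`); every stage of the pipeline is validated against
it and against closed-form oracles.

## Worked example

```r
library(hcymr)

studies <- simulate_studies(mthfr_gc_config(seed = 42))  # 27 studies
fit <- run_pipeline(studies)
print(fit)
```

```
Two-stage genotype meta-analysis + MR (27 studies)
HWE screen: 6 studies deviating at alpha = 0.05

Pooled odds ratios:
        model  k    or ci_low ci_high   p_value     Q      q_p i_squared tau_squared effects_model
       allele 27 1.182 1.0953   1.276 1.759e-05 51.98 0.001810     49.98     0.01947        random
   homozygous 27 1.282 1.0978   1.498 1.712e-03 45.34 0.010803     42.65     0.06763        random
 heterozygous 27 1.291 1.1629   1.432 1.573e-06 42.41 0.022289     38.69     0.02783        random
     dominant 27 1.296 1.1687   1.436 8.530e-07 46.49 0.008041     44.07     0.03098        random
    recessive 27 1.137 0.9996   1.293 5.078e-02 39.79 0.040933     34.65     0.03766        random
allele model bias: Egger t = -0.07 (p = 0.947), Begg z = -0.29 (p = 0.77)
...

Wald-ratio Mendelian-randomization estimate
  OR per SD ln-tHcy: 2.8858  95% CI [1.7789, 4.6814]  p = 1.759e-05
  log OR 1.0598 (SE 0.2468, simplified delta method)
```

Reading the output: the generator's true per-allele OR is 1.16
(`mthfr_gc_config()` default) with between-study SD 0.15 on the log
scale, so the allele-model pool of 1.182 with a random-effects CI
[1.095, 1.276] covers the truth; I² ≈ 50% reflects the injected
heterogeneity; six control arms fail the HWE screen (seven are
generated with an inbreeding distortion — one escapes detection at this
seed); and the MR stage converts the pooled per-allele OR into an OR
per SD of ln-tHcy via the 0.158 constant.

Published summary statistics can be fed in directly. With the reported
allele-model pooled OR of 1.16 (95% CI 1.06–1.27):

```r
mr_from_published(1.16, 1.06, 1.27, beta = 0.158)
#> Wald-ratio Mendelian-randomization estimate
#>   OR per SD ln-tHcy: 2.5584  95% CI [1.4439, 4.5329]  p = 0.001287
#>   log OR 0.9394 (SE 0.2918, simplified delta method)
```

A thin command-line front end with `run`, `simulate` and `mr`
subcommands is installed at
`system.file("scripts", "hcymr", package = "hcymr")`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","hcymr",package="hcymr"))') \
    simulate --out studies.tsv --k 27 --seed 1
Rscript .../hcymr run --input studies.tsv --out report.json --tsv models.tsv
Rscript .../hcymr mr --or 1.16 --ci-low 1.06 --ci-high 1.27 --beta 0.158
```

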