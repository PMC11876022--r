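# mrmediate

Two-sample Mendelian randomization (MR) with multivariable MR and
product-of-coefficients mediation analysis, for epidemiologists asking not
just *whether* an exposure causes an outcome but *through what* — e.g.
whether obesity-related traits act on a disease outcome through circulating
proteins or metabolites. The package consumes per-SNP GWAS summary
statistics (TSV), so no individual-level data are needed, and ships a
seeded summary-statistics generator with a known
exposure → mediator → outcome causal structure so the whole pipeline is
testable offline.

## What it computes

Given exposure and outcome summary statistics aligned to a shared effect
allele (betas `β̂_Xi`, `β̂_Yi`, SEs `s_Xi`, `s_Yi`, weights `w_i = 1/s_Yi²`):

- **Instrument selection** — genome-wide significance (`p < 5e-8`), greedy
  LD clumping (`r² < 0.001` within 10,000 kb), and the strength filter
  `F = (N−k−1)/k · R²/(1−R²)` with `R² = 2β²·MAF(1−MAF)`, dropping `F < 10`.
- **Five estimators** — IVW (fixed / multiplicative random effects, the
  headline switching on Cochran Q p < 0.05), MR-Egger (free intercept =
  directional-pleiotropy test), weighted median, simple and weighted mode,
  plus single-SNP Wald ratios; odds ratios as `exp(β)` with
  `exp(β ± 1.96·SE)` CIs and two-sided normal p-values.
- **Sensitivity** — Cochran Q and `I² = max(0, (Q−df)/Q)`, MR-Egger
  intercept, leave-one-out, Steiger directionality
  (instrument-explained variance on each side), funnel-plot data.
- **Multivariable MR** — IVW-style weighted multiple regression of outcome
  betas on several exposures' betas, no intercept: per-exposure *direct*
  effects.
- **Mediation** — `β_M = β_A·β_B`,
  `SE_M = sqrt((β_A·SE_B)² + (β_B·SE_A)²)`, Sobel `z = β_M/SE_M`, and the
  stepwise classification into complete mediation, partial mediation
  (proportion `β_M/β_C`), covering effect (ratio `|β_M/β_C′|`), or no
  mediation.
- **Synthetic GWAS** — `sim_config()` / `simulate_triple()` generate the
  three trait tables, an LD matrix and the ground truth under configurable
  `a` (exposure→mediator), `b` (mediator→outcome), `c_direct`, pleiotropy,
  heterogeneity, palindromic/flipped alleles.

## Worked example

```r
library(mrmediate)

cfg <- sim_config(n_snps_instrument = 100, n_snps_instrument_med = 100,
                  n_snps_null = 20, a = 0.2, b = 0.2, c_direct = 0, seed = 1)
sim <- simulate_triple(cfg)
wf <- run_mediation_workflow(list(sim$exposure), list(sim$mediator),
                             sim$outcome, sim$ld,
                             mr_config(n_boot = 1000, seed = 1))
wf
#> Mediation workflow
#>             stage n
#>      exposures_in 1
#>  exposures_passed 1
#>      mediators_in 1
#>  mediators_passed 1
#>      pairs_tested 1
#>      pairs_passed 1
#>     models_fitted 1
#>
#> Models:
#>    model     exposure     mediator    beta_m    sobel_pval     classification
#>  model_1 sim-exposure sim-mediator 0.0388713 6.290832e-156 complete-mediation
#>  proportion
#>          NA
```

The simulated truth is `a·b = 0.2 × 0.2 = 0.04` with zero direct effect:
the exposure and the mediator both pass the univariate causal screen
against the outcome (IVW p < 0.05 and correct Steiger direction), the
exposure passes against the mediator, the two-exposure multivariable MR
finds a significant mediator→outcome direct effect (`β_B`) but no residual
exposure→outcome direct effect (`β_C′`), and the indirect effect is
estimated at 0.0389 — hence the complete-mediation call.

Lower-level entry points: `read_summary_stats()`, `harmonize()`,
`select_instruments()`, `mr_all()`, `sensitivity_report()`, `mvmr_ivw()`,
`estimate_mediation()`. A thin command-line wrapper lives at
`inst/cli/mr_pipeline.R` (`simulate`, `screen`, `mediate`, `run-all`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a seeded synthetic study, runs the full screening + mediation
workflow end to end, prints the stage counts and fitted models, and writes
the (empty) target report as JSON.

See `vignettes/mr-mediation-methods.Rmd` for the model, the assumptions,
every tunable default and why, what the generator does and does not
emulate, and known limitations.
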