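---
title: "Methods: two-sample MR with mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone, using genetic
variants as instrumental variables. `mrmediate` implements the full workflow
for studies that additionally ask *through what* an exposure acts: a
univariate causal screen of many candidate exposures against one outcome,
multivariable MR (MVMR) to separate direct from mediated effects, and a
product-of-coefficients mediation analysis with a Sobel test and a stepwise
significance classification. Because the motivating study design consumes
dozens of exposure GWAS and thousands of candidate mediators (plasma
proteins, blood metabolites) that cannot be redistributed, the package ships
a seeded generator of summary statistics with a known
exposure → mediator → outcome causal structure, so every stage is testable
offline.

# Model and assumptions

For SNP $i$, let $\hat\beta_{Xi}, \hat\beta_{Yi}$ be the per-allele effects
on exposure and outcome with standard errors $s_{Xi}, s_{Yi}$, aligned to a
common effect allele. A valid instrument satisfies relevance, independence
from confounders, and the exclusion restriction (it affects the outcome only
through the exposure).

**Instrument selection.** SNPs pass at $p < 5\times10^{-8}$, are greedily
LD-clumped (keep the smallest-$p$ SNP, discard SNPs with $r^2 \ge 0.001$
within 10,000 kb of an accepted SNP), and are strength-filtered with

$$F = \frac{N - k - 1}{k}\cdot\frac{R^2}{1 - R^2},\qquad
R^2 = 2\,\beta^2\,\mathrm{MAF}(1-\mathrm{MAF}),$$

dropping SNPs with $F < 10$. By default $k = 1$ per SNP (the usual
single-variant strength check, under which $F \approx z^2$); the set-size
reading ($k$ = number of clumped SNPs for every SNP) is available as
`f_k_mode = "set"` for auditing but is not the default because with
realistic genome-wide-significant instruments the per-SNP $R^2$ is of order
$30/N$, so $F \approx 30(N-k-1)/(kN)$ falls below 10 for any $k \gtrsim 3$
and the filter would empty essentially every realistic instrument set. A
set-level $F$ (sum of per-SNP $R^2$, $k$ = set size) is always reported. One
published rendering of the $R^2$ formula carries a linear $\beta$ term
("$2\beta$"); that is dimensionally inconsistent with a variance fraction
and is treated as a typo, though `r2_formula = "as-printed"` evaluates it
verbatim for comparison.

**Estimators.** With weights $w_i = 1/s_{Yi}^2$:

* *IVW*: weighted regression of $\hat\beta_{Y}$ on $\hat\beta_{X}$ through
  the origin. Fixed-effects SE fixes the residual variance at 1; the
  multiplicative random-effects SE inflates it by
  $\max(1, \sqrt{Q/(n-1)})$. The headline IVW uses fixed effects and
  switches to random effects when Cochran $Q$ has $p < 0.05$.
* *MR-Egger*: the same regression with a free intercept after orienting all
  rows to $\hat\beta_{X} \ge 0$; the intercept estimates directional
  pleiotropy, the slope the causal effect; both SEs carry the
  $\max(1, \sqrt{Q/(n-2)})$ inflation.
* *Weighted median*: the Wald ratios $\hat\beta_{Yi}/\hat\beta_{Xi}$
  ordered, weighted by the inverse variance of each ratio
  ($s_{Yi}^2/\hat\beta_{Xi}^2$); the estimate interpolates the cumulative
  normalized weight at 0.5.
* *Simple and weighted mode*: argmax of a normal-kernel density of the
  ratios (unweighted / inverse-variance weighted), bandwidth
  $0.9\min(\mathrm{sd},\mathrm{MAD})\,n^{-1/5}$ times a configurable factor
  (default 1); a zero MAD falls back to the SD so the bandwidth vanishes
  only for literally constant ratios.
* *Wald ratio* for single-SNP instruments, SE $s_{Y}/|\hat\beta_{X}|$.

Median and mode SEs come from a seeded parametric bootstrap (default 5000
replicates) that redraws both exposure and outcome betas from
$\mathcal N(\hat\beta, s)$. All p-values are two-sided normal and 95% CIs
use $\beta \pm 1.96\,s$ — the normal-z convention is what reproduces the
published odds-ratio tables the acceptance tests check to 6 decimal places.

**Sensitivity.** Cochran $Q = \sum_i w_i(\hat\beta_{Yi} -
\hat\beta\,\hat\beta_{Xi})^2$ on $n-1$ df;
$I^2 = \max(0, (Q - \mathrm{df})/Q)$, labelled none/mild/moderate/high at
0/25/50%. MR-Egger intercept test at $\alpha = 0.05$ (requires $\ge 3$
SNPs; smaller instruments skip pleiotropy and leave-one-out but stay in the
causal screen). Leave-one-out refits IVW without each SNP under the same
effects-model switch. The Steiger test compares instrument-explained
variance on the two sides ($R^2 = \sum_i 2\hat\beta_i^2
\mathrm{MAF}_i(1-\mathrm{MAF}_i)$, on the observed log-odds scale for
binary traits, no liability-scale correction); the p-value compares
$\mathrm{atanh}\sqrt{R^2}$ via Fisher's z with the two sample sizes — the
source workflow does not state its construction, so this is an
implementation choice, documented rather than asserted. Funnel data
(ratio vs. precision) are exported, not rendered or formally tested.

**Harmonization.** Outcome rows are aligned to the exposure's effect
allele: swapped codings negate the outcome beta and complement the
frequency; strand-complement codings (A/G vs T/C) are resolved before a row
is declared irreconcilable. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from alleles alone; the default policy drops them when the
exposure allele frequency is in [0.42, 0.58] and otherwise aligns by which
side of 0.5 the two frequencies fall on. `drop-all` and `keep` are
available because the source workflow never states its policy.

**MVMR.** Instruments are the union of each exposure's significant SNPs,
jointly re-clumped ranking by the minimum p across exposures. The estimator
is inverse-variance-weighted multiple regression of the outcome betas on
the exposure-beta matrix with no intercept; SEs carry
$\max(1, \sqrt{Q/(n-p)})$. Rank-deficient designs abort with the offending
exposures named. A heuristic conditional instrument-strength diagnostic is
reported per exposure but never used for filtering.

**Mediation.** With $\beta_A$ (exposure→mediator, univariate MR),
$\beta_B$ (mediator→outcome direct effect, from the two-exposure MVMR),
$\beta_C$ (univariate total effect) and $\beta_{C'}$ (MVMR direct effect):

$$\beta_M = \beta_A \beta_B,\qquad
SE_M = \sqrt{(\beta_A SE_B)^2 + (\beta_B SE_A)^2},\qquad
z_{Sobel} = \beta_M / SE_M.$$

The stepwise classification: the indirect effect is significant when both
$\beta_A$ and $\beta_B$ are, otherwise when the Sobel p is below $\alpha$;
given a significant indirect effect, a non-significant $\beta_{C'}$ means
complete mediation; a significant $\beta_{C'}$ of opposite sign to
$\beta_M$ is a covering (suppression) effect with ratio
$|\beta_M/\beta_{C'}|$; matching signs give partial mediation with
proportion $\beta_M/\beta_C$. The two denominators follow the literal
symbols of the source formulation and both are reported so either
convention can be audited. Mediation CIs are $\beta_M \pm 1.96\,SE_M$; the
published table this mirrors prints indirect-effect intervals roughly 50×
narrower than that formula yields from its own printed components — the
formula, not the printed intervals, is authoritative here.

# The synthetic generator

`sim_config()` / `simulate_triple()` state a world, not a dial to tune:

* Exposure instruments draw true effects from
  $\mathcal N(0, \texttt{beta\_gx\_scale})$ truncated to genome-wide
  significance at the exposure sample size (exact tail inverse-CDF;
  an unreachable truncation is a configuration error). The default scale
  0.05 puts observed effects in the $10^{-3}$–$10^{-1}$ range seen in
  large anthropometric and molecular GWAS, with instrument z-scores spread
  well above the threshold instead of piled against it (a pile-up both
  misrepresents real instrument panels and exaggerates winner's-curse
  attenuation).
* Mediator-specific instruments (`n_snps_instrument_med`, default equal)
  are this package's one structural addition: with only exposure
  instruments the true mediator column is exactly $a$ times the exposure
  column and the MVMR design is collinear, so the mediator's direct effect
  $b$ would be unidentifiable. They make the mediation chain estimable, as
  in any real study where the mediator has its own GWAS hits.
* True mediator/outcome effects follow the causal diagram
  ($\beta_M = a\beta_X$, $\beta_Y = (c' + ab)\beta_X$ at exposure
  instruments; $\beta_Y = b\beta_M$ at mediator instruments), plus optional
  balanced heterogeneity noise and a directional-pleiotropy intercept. The
  intercept is applied in the trait-raising-allele orientation
  ($\times\,\mathrm{sign}(\beta)$): a constant added in the arbitrary
  coded-allele orientation would cancel under MR-Egger's sign alignment and
  be undetectable by construction.
* Observed betas are true betas plus $\mathcal N(0, s_i)$ with the exact
  analytic $s_i = 1/\sqrt{2 n\,\mathrm{maf}_i(1-\mathrm{maf}_i)}$ (no
  hidden SE noise); sample-size defaults are 300,000, UK-Biobank scale, and
  case–control imbalance is emulated only through effective sample size.
* A configurable fraction of SNPs is palindromic and a fraction of
  mediator/outcome rows is allele-flipped, so harmonization is genuinely
  exercised rather than bypassed.
* LD is near-identity with optional constant-$r^2$ blocks; no attempt is
  made to mimic reference-panel LD structure.

What a green test on this generator does **not** establish: robustness to
realistic LD, to liability-scale effects in strongly imbalanced
case–control outcomes, to sample overlap between the two GWAS, or to
winner's curse from selecting instruments in the same GWAS that estimates
them (present here in mild form, since selection uses observed p-values).

# Numerical and design choices

* Clumping ties (equal p) break lexicographically by SNP id, making
  selection order-invariant.
* The F filter is single-pass: F is not recomputed after removals.
* Bootstrap estimators restore the caller's RNG state (`seed` argument);
  identical seed and configuration give byte-identical output files.
* Screening gates use raw $p < 0.05$ with no multiple-testing correction,
  mirroring the source workflow; `mr_config(p_adjust=)` exposes
  `stats::p.adjust` methods for stricter gating, off by default.
* Whether the source study required Steiger $p < 0.05$ in addition to the
  correct direction is not crisply stated; both are enforced and reported
  separately.
* The "no significant mediating effects in the remaining models (P < 0.05)"
  phrasing in the source is read logically as $P \ge 0.05$.
* The degenerate Sobel case ($SE_M = 0$, $\beta_M \ne 0$) is reported with
  $p = 0$ and flagged rather than erroring.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_snps_instrument = 100, n_snps_instrument_med = 100,
                  a = 0.2, b = 0.2, c_direct = 0, seed = 1)
sim <- simulate_triple(cfg)
wf <- run_mediation_workflow(list(sim$exposure), list(sim$mediator),
                             sim$outcome, sim$ld,
                             mr_config(n_boot = 1000, seed = 1))
wf$mediation[, c("beta_a", "beta_b", "beta_m", "sobel_pval",
                 "classification")]
```

The true indirect effect is $a\,b = 0.04$ with no direct effect, so the
expected classification is complete mediation; the estimate's accuracy and
the calibration of $SE_M$ are exercised quantitatively in the test suite
(coverage of the true indirect effect, null calibration of the Egger
intercept and Cochran Q, Steiger direction recovery).

# Known limitations

* No MR-PRESSO, contamination mixture, or robust adjusted profile score;
  no MVMR-Egger or MVMR-median; one mediator per model.
* No OpenGWAS client, VCF parsing, liftover, or proxy-SNP search; LD is
  consumed as a supplied matrix, never computed from genotypes.
* Steiger on binary outcomes uses the observed log-odds scale; liability-
  scale variance explained would differ.
* The conditional-F diagnostic in MVMR is a heuristic, not the
  Sanderson–Windmeijer statistic.
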