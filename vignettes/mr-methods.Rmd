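---
title: "Two-sample Mendelian randomization with mrpipe: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem and the model

Mendelian randomization (MR) estimates the causal effect of an exposure
(here, hormonal reproductive traits such as age at menarche, age at natural
menopause, or age at first birth) on a disease outcome (osteoarthritis) by
using genetic variants as instrumental variables. Because alleles are
assigned at conception, variant-outcome associations are protected from the
confounding and reverse causation that afflict observational estimates — to
the extent that each variant satisfies the three instrumental conditions:
it is robustly associated with the exposure (relevance), shares no
confounder with the outcome (independence), and affects the outcome only
through the exposure (exclusion restriction).

In the two-sample design, all the pipeline sees are per-variant GWAS summary
statistics from two non-overlapping samples: exposure-side estimates
$\hat\gamma_j$ with standard errors $\sigma_{Xj}$, and outcome-side
estimates $\hat\Gamma_j$ with $\sigma_{Yj}$, aligned to a common effect
allele. Under a linear structural model with causal effect $\beta$ and
per-variant direct (pleiotropic) effects $\alpha_j$,

$$\Gamma_j = \beta\,\gamma_j + \alpha_j ,$$

and every estimator in the package is a different rule for combining the
per-variant Wald ratios $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ under a
different assumption about the $\alpha_j$.

## Pipeline stages

**Instrument selection.** Variants pass a genome-wide significance screen
(strictly $p < 5\times10^{-8}$), then greedy LD clumping: the
smallest-$p$ variant is retained and every remaining candidate with
$r^2 > 0.01$ against it discarded, repeating until exhaustion. The clump
depends only on p-values and the LD table, not input order. An optional
physical window (`window_bp`, default off; 10 Mb is conventional when
positions are present) discards near neighbours on the same chromosome
regardless of tabulated LD, since pairwise LD tables are typically sparse.
LD itself is consumed as a precomputed pairwise-$r^2$ table; computing it
from a reference panel is out of scope.

**Instrument strength.** Per variant, the exposure variance explained is

$$R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,SE^2\,N\,f(1-f)},
\qquad F = \frac{R^2 (N-2)}{1-R^2},$$

with $f$ the effect-allele frequency and $N$ the sample size. The factor
$2f(1-f)$ cancels, so $R^2 = \beta^2/(\beta^2 + SE^2 N)$; the package
implements the full form and the test suite verifies the simplification to
$10^{-12}$. Variants with $F < 10$ are rejected per-SNP as weak
instruments; the set's mean F is reported over retained instruments.

**Harmonization.** The exposure table's allele convention is the reference.
Outcome records with swapped alleles have their effect negated and
frequency complemented; strand-complement records are relabelled;
palindromic variants (A/T, G/C) are oriented by frequency side-agreement
and dropped as ambiguous when either side's frequency lies inside
[0.42, 0.58]. The window makes an inherently fuzzy rule deterministic and
configurable; with no outcome frequency, palindromes are always dropped.
Instruments absent from the outcome GWAS are substituted by their
strongest-LD proxy at $r^2 > 0.8$ (ties broken by smaller outcome p, then
identifier), keeping the original exposure-side effect — standard proxy
practice. Every instrument lands exactly once in the harmonized records or
the dropped list, with a reason.

**Estimators.**

* *IVW*: precision-weighted mean of the ratios with weights
  $w_j = \gamma_j^2/\sigma_{Yj}^2$, identical to weighted regression of
  $\Gamma$ on $\gamma$ through the origin. The default is multiplicative
  random effects: the fixed-effect standard error is inflated by
  $\max\{1, \sqrt{Q/(n-1)}\}$, where $Q$ is Cochran's statistic. The floor
  means the model never claims more precision than the fixed-effect
  analysis; with no stated preference in the motivating analyses,
  random-effects is the defensible default and `model = "fixed"` is a flag.
* *MR-Egger*: weighted regression with a free intercept after orienting all
  $\gamma_j \ge 0$; the slope estimates $\beta$ under the InSIDE assumption
  and the intercept estimates average directional pleiotropy. The same
  multiplicative overdispersion floor applies. No SIMEX correction for
  exposure-side measurement error is attempted.
* *Weighted median*: ratios are ordered and the estimate interpolates
  linearly at 50% of cumulative weight using midpoint ranks
  $S_j = \sum_{k\le j} w'_k - w'_j/2$; consistent when at least half the
  weight is valid.
* *Weighted mode*: the argmax of a weighted normal-kernel density of the
  ratios with modified Silverman bandwidth
  $h = \phi\, 0.9 \min(sd, IQR/1.349)\, n^{-1/5}$, evaluated on a 512-point
  grid spanning the ratios $\pm 3h$; consistent when the largest
  effect-homogeneous cluster is valid. $\phi$ defaults to 1 and is exposed.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1000 replicates): effects are redrawn from
$N(\hat\gamma_j, \sigma_{Xj})$ and $N(\hat\Gamma_j, \sigma_{Yj})$ and the
statistic recomputed. All p-values are two-sided normal; at the instrument
counts involved (10-349) the difference from $t$ quantiles is negligible,
and the suite verifies the intercept test's size empirically.

**Diagnostics.** MR-PRESSO compares the observed weighted residual sum of
squares around leave-one-out IVW predictions with its parametric simulation
distribution (global test, p-value resolution $1/(n_{sim}+1)$); per-SNP
squared residuals against their simulated distributions flag outliers at a
Bonferroni-corrected level; the distortion test compares the estimate shift
after outlier removal with the shift under random removal of equally many
SNPs. Note that $n_{sim}$ must exceed $n/\alpha$ for the outlier threshold
to be reachable at all. Leave-one-out re-estimation and funnel data (ratio
vs precision, with a weighted sign-symmetry summary) complete the
sensitivity toolkit. The funnel symmetry number is a descriptive aid, not a
calibrated test.

**Reporting.** Outcome GWAS effects are log-odds, so estimates exponentiate
to odds ratios per exposure unit; no unit rescaling is performed. The
primary (IVW) family over the exposure-by-outcome grid is
Bonferroni-corrected — 3 exposures by 4 outcomes gives $0.05/12 \approx
0.004$ — and rows are flagged at both the nominal 0.05 and the corrected
threshold. Confounder-aware sensitivity rows re-run the grid after pruning
instruments that reach genome-wide significance in a confounder GWAS
(e.g. BMI), keyed on exact variant identifier.

## The synthetic generator

`simulate_two_sample()` draws, per variant: a frequency
$f \sim U(f_{min}, f_{max})$; a true exposure effect (zero for nulls,
$|N(\mu_\gamma, \sigma_\gamma)|$ for instruments, coded on the
exposure-increasing allele — the standard convention, and the one that
makes "directional" pleiotropy a consistent-sign shift of the ratio
estimates); a true outcome effect $\beta\gamma_j + \alpha_j$, optionally
with a shared-confounder path ($\gamma_j \mathrel{+}= c_x\lambda_j$,
$\Gamma_j \mathrel{+}= c_y\lambda_j$, with the confounded variants reaching
genome-wide significance in a generated confounder GWAS); and independent
sampling noise in each sample with variance $1/(2f(1-f)N)$ — traits are
variance-normalized, which makes the $R^2$/F formulas exact in expectation.
Palindromic alleles, outcome missingness with $r^2 = 0.9$ proxies
(attenuating the proxy's true effect by $\sqrt{0.9}$), random outcome-side
allele/strand relabelling, LD-correlated null blocks, and 10-$\sigma$
pleiotropic outliers are injected at configured fractions. Generation is
byte-identical under a seed.

What it does *not* emulate: LD between true instruments (a post-clumping
world is assumed; LD lives only in decoy null blocks), individual-level
binary-outcome sampling (the case-control GWAS is approximated by the same
Gaussian model on the log-odds scale), realistic allele-frequency spectra,
and sample overlap. Passing tests therefore demonstrate correctness of the
estimators and plumbing under the stated generative model, not robustness
to every pathology of real GWAS data.

### Preset calibration

Presets mirror the scale of the motivating analyses and were fixed once,
from the published scales, before any validation was run:

| preset | instruments | $N_{exp}$ | true effect | $|\gamma|$ mean (sd) | analytic mean F |
|---|---|---|---|---|---|
| `afb_like` | 10 | 251,151 | $\ln 0.80$ | 0.019 (0.003) | $\approx 37$ |
| `aam_like` | 349 | 329,345 | $\ln 0.91$ | 0.025 (0.005) | $\approx 64$ |
| `anm_like` | 54 | 69,360 | 0 | 0.049 (0.008) | $\approx 68$ |

using $E[F] \approx 1 + E[\gamma^2]\,E[2f(1-f)]\,N$ with
$E[2f(1-f)] \approx 0.393$ for $f \sim U(0.1, 0.9)$. The outcome GWAS size
is set to 450,000, a realistic UK Biobank-scale osteoarthritis GWAS; the
exposure sizes are the published ones. `confounded_bmi` makes 2 of 10
instruments act through a BMI-like confounder (GWAS size 806,834) strongly
enough that pruning them moves the IVW estimate materially;
`directional_pleiotropy` gives 30% of 20 instruments direct effects of mean
0.02 (about five times $|\beta\bar\gamma|$, a strong but realistic shared
pathway); `outlier_injection` shifts one instrument's outcome effect by
10 standard errors.

## Numerical and design choices

* Strict inequality at the significance threshold and retention at
  $F \ge 10$ exactly ("lower than 10" rejected).
* Confidence intervals use $z = 1.959964$ throughout; `ci_low < estimate <
  ci_high` is an invariant.
* The weighted-mode grid argmax is validated against a 10-times-finer scan;
  all-equal ratios short-circuit to that ratio (bandwidth would be zero).
* p-values are floored at the smallest positive double rather than
  underflowing to zero.
* Estimator-level validation harmonizes the generator's true instruments
  directly rather than re-running the significance screen first: parameter
  recovery is a property of the estimators, while re-selection at
  $5\times10^{-8}$ superimposes winner's-curse bias — a property of
  selection that is real, expected, and visible in the separate
  selection-recovery test (with true $z$ near 6, roughly a third of
  borderline instruments drop per replicate).
* Egger-intercept size is checked at 50 instruments (the
  age-at-natural-menopause scale); at much smaller counts the normal
  quantiles would be mildly anticonservative, which is a documented
  limitation rather than a bug.
* Validation problem sizes (500 recovery replicates, 1000 size replicates,
  200 robustness/PRESSO replicates at $n_{sim} = 1000$) balance
  Monte-Carlo error against a single-CPU run of the whole suite in well
  under a minute of estimator time.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_two_sample(scenario_preset("afb_like", seed = 7))
instruments <- select_instruments(sim$exposure, sim$ld)
data <- harmonize_set(instruments, sim$outcome, ld = sim$ld)
fit <- mr_all(data, seed = 7)
tidy(fit)
autoplot(fit)
mr_presso(data, seed = 7)
autoplot(funnel_data(data))
```

Or end-to-end, over a grid, from a configuration:

```{r pipeline, eval = FALSE}
cfg <- mr_config(
  exposures = list(AFB = sim$exposure),
  outcomes = list(hip_knee_oa = sim$outcome),
  ld = sim$ld, seed = 7
)
res <- run_mr_pipeline(cfg)
res$results
plot_forest(res$results, methods = "ivw_re")
```

## Known limitations

Steiger directionality filtering, multivariable MR, SIMEX-corrected Egger,
radial MR and $I^2$ heterogeneity summaries are deliberately out of scope.
Proxy lookup keys the confounder pruning on exact identifiers (no proxy
search in the confounder GWAS). Genome builds are metadata only; no
liftover is attempted. The distortion test reports `NA` when no outliers
are flagged.
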