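---
title: "Epigenetic aging models for equids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epigenetic aging models for equids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the models it implements, the
assumptions behind them, and the design choices made where the design was
genuinely open. The worked numbers in the README and the `analysis/`
scripts are produced by the code itself; nothing here states a result the
tests or the acceptance script do not compute.

## The scientific setting

Chronological age is hard to measure in wild animals, yet age structure
drives demographic inference and conservation planning. DNA methylation
offers a way out: the methylated fraction (beta value, in [0, 1]) of many
CpG sites changes predictably over the lifespan. The package implements
two complementary estimators of epigenetic age for equid cohorts, plus
the downstream analyses that connect epigenetic aging to inbreeding.

## The epigenetic clock (EC)

The clock is a penalized linear model predicting a transform of
chronological age from beta values:

$$\hat g(\text{age}) = w_0 + \sum_j w_j \beta_j, \qquad
  g(\text{age}) = \sqrt{\text{age} + \delta}.$$

The square-root transform (offset $\delta = 0$ by default) linearizes the
fast-early/slow-late dynamics of methylation in growing animals; it is
invertible, and negative transformed predictions — possible when a clock
extrapolates into another species — are clamped to 0 years and flagged
rather than treated as errors.

Weights come from the elastic net,

$$\min_{w_0, w} \frac{1}{2n}\sum_i (y_i - w_0 - x_i^\top w)^2
  + \lambda\Big(\alpha \lVert w\rVert_1
  + \tfrac{1-\alpha}{2}\lVert w\rVert_2^2\Big),$$

fit by cyclic coordinate descent with soft-thresholding in compiled code
(`src/enet.cpp`), with internal per-column standardization (mean 0, sd 1,
denominator $n$) and back-transformed weights. Numerical contract: a fit
returns only when the largest coefficient change in a sweep is below
`tol` ($10^{-7}$ by default) *and* every coordinate satisfies the KKT
stationarity condition to `kkt_tol` ($10^{-6}$). The path implementation
uses warm starts, sequential strong-rule screening and active-set
iteration; these affect speed only, and the unit tests pin the solutions
against closed-form oracles (ridge linear solve, univariate
soft-threshold) and against an independent solver.

Tunable parameters that matter:

* `alpha` (penalty mixing, default 0.5): the clock literature's
  convention; the mixing weight is rarely decisive and is exposed in the
  config.
* `lambda`: selected by cross-validation over a log-spaced path of 100
  values from $\lambda_{\max}$ (smallest value zeroing all weights) down
  to $10^{-3}\lambda_{\max}$. The default rule takes the CV-MSE minimum
  with ties broken toward the larger (sparser) lambda; a one-standard-error
  rule is available (`rule = "1se"`) and is the right choice when a
  reliably sparse model under a noisy CV curve matters more than raw CV
  error — on pure-noise responses the plain minimum chases CV noise and
  keeps spurious predictors roughly 30% of the time, while the 1-SE rule
  does not.
* Cross-validation folds: model evaluation is strict leave-one-sample-out
  (LOO) — for every held-out sample the whole pipeline, lambda selection
  included, is re-run without it. Inside that loop the lambda-selection CV
  defaults to 10-fold rather than LOO: the two select indistinguishable
  penalties here while keeping the nested loop linear rather than
  quadratic in cohort size. Full LOO-in-LOO is a config switch.
* CV fold fits run at a looser coordinate tolerance (`cv_tol = 1e-4`,
  with the KKT tolerance scaled accordingly): the CV error curve is
  insensitive to coefficient error orders of magnitude below the
  fold-to-fold prediction noise, and every model actually returned is
  refit at full tolerance.

Accuracy is summarized by Pearson's r and the **median** absolute error
(MAE, years), optionally stratified at a cut age — medians because
cross-species extrapolation produces a few large errors that would
dominate a mean.

## The epigenetic pacemaker (EPM)

The pacemaker drops the linearity-in-transformed-age assumption. Each
site has a rate $r_j$ and baseline $m_{0j}$, each sample a latent
epigenetic state $s_i$:

$$\beta_{ij} = m_{0j} + r_j s_i + \varepsilon_{ij},$$

fit by minimizing total squared error with alternating least squares:
(a) per-site simple regression of $\beta_j$ on the current states,
(b) per-sample state update
$s_i = \sum_j r_j(\beta_{ij} - m_{0j}) / \sum_j r_j^2$. States are
initialized at chronological ages; both half-steps are exact minimizers
given the other block, so the recorded error trace is non-increasing (a
tested invariant), and on data generated exactly from the model the fit
lands on the truth in a single sweep. Convergence: relative error
improvement below $10^{-6}$ or 100 iterations, both in the config. The
state scale is identified only up to an affine gauge anchored by the age
initialization; tests therefore score state recovery by correlation with
the generating truth, not by absolute value.

Sites enter the model by marginal screening: absolute Pearson correlation
with age of at least 0.75 within a tissue (0.6 for the combined-tissue
model, where tissue offsets depress marginal correlations). LOO states
re-fit the whole model per held-out sample and compute the held-out state
from the trained rates.

States are translated to years through a shifted-log trend curve
$s = a\ln(\text{age} + c) + d$ fit by bounded Levenberg–Marquardt with
five multi-starts over $c$ (the one genuinely nonlinear parameter);
translation inverts the curve and clamps at 0 years. The shifted-log
family is a documented modeling choice: it reproduces the fast-early /
slow-late shape the pacemaker literature reports, is invertible, and has
interpretable parameters. Constant states are a degeneracy error, not a
silent fit. Pacemaker age acceleration is reported in two forms: the
state residual from the trend curve at the sample's age (default for
association models) and the translated-age difference in years.

## Inbreeding from genotypes

Variant input is biallelic SNPs (VCF; multiallelic and indel records are
skipped with counts). Hard filters follow standard short-variant
practice: a site is removed iff it violates **any** of QD < 2, FS > 60,
SOR > 3, MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8, or minor
allele frequency < 0.01 (strict inequalities; a missing annotation
passes its criterion and is logged). Singletons and private doubletons
are removed as a minor-allele-count rule (count ≥ 3 retained).

Two inbreeding estimates:

* **Method-of-moments F**: excess homozygosity,
  $\hat F = (O_{hom} - E_{hom}) / (L - E_{hom})$ with
  $E_{hom} = \sum_l (1 - 2p_lq_l)$ over the individual's non-missing
  polymorphic loci. With frequencies estimated from a small panel the
  plain form carries a $\approx -1/(2n)$ bias; the unbiased-heterozygosity
  correction ($2p_lq_l \cdot n_{al}/(n_{al}-1)$) is available and is what
  the calibration tests use. The plain form is the default.
* **F_ROH**: total length of runs of homozygosity divided by the screened
  genome length (a required input — the screened length is a property of
  the study design, not of the segment list). ROH detection is a
  sliding-window scan: 150-SNP windows are called homozygous when they
  contain no heterozygote and at most two missing calls; a SNP qualifies
  when at least 5% of the windows covering it are homozygous; runs of
  consecutive qualifying SNPs become segments when they contain ≥ 150
  SNPs and span ≥ 1.5 Mb. The window unit is SNP count (the scanning
  tool's native unit), a documented interpretation. The implementation is
  pinned against an exhaustive window-enumeration oracle on fuzzed
  chromosomes.

## Age-acceleration association models

Age acceleration defaults to the residual of predicted age regressed on
chronological age (exactly age-uncorrelated by construction); the raw
difference and the literal reversed-direction residual variant are also
implemented, because the two common definitions disagree and the choice
should be visible, not silent. Clock acceleration uses LOO predictions —
in-sample predictions are shrunk toward the truth and would mask
acceleration signal.

The association grid is 2 × 2: (clock, pacemaker) acceleration against
(F, F_ROH), each model
`accel ~ sex + age + inbreeding + age:inbreeding` fit by QR least squares
with Huber–White robust covariance. HC3 is the default flavor (best
small-sample behavior at cohort sizes near 70); HC0/HC1 are available and
all three are pinned to the direct sandwich-formula evaluation and to an
independent implementation. Inference uses the Student-t reference with
$n - k$ degrees of freedom. A leverage-1 point makes HC3 undefined and is
an error. Known outliers are excluded by an explicit id list in the
config, never by an automatic rule.

## EWAS and meta-analysis

Per site and tissue: Pearson r against age,
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided p from the t distribution, and
the signed normal score $z = \mathrm{sign}(r)\,\Phi^{-1}(1 - p/2)$.
Perfect correlations underflow p; their z is capped at |z| = 40 and
flagged so extreme sites stay finite and ordered. Tissues are combined by
Stouffer's method with $\sqrt{n}$ weights (sample sizes of 76 vs 20 make
weighting material; unweighted mode exists). The meta value is computed
only for sites scored in every tissue. Significance is counted at
p < 10⁻⁴ by direction; overlap sectors classify sites as shared,
divergent, or tissue-specific (significant in one tissue, p > 0.05 in the
other). Top-k selection (500 per z direction, ties broken
lexicographically for determinism) feeds the annotation summaries: TSS
position class counts by z sign and an island vs non-island z comparison
by two-sided Wilcoxon rank-sum — the rank-sum is a documented choice
where the field's convention is unstated.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth
without any external download. It emulates:

* **Ages**: log-uniform on [0.15, 25] years — right-skewed like managed
  cohorts (means near 5 years), with min/mean/max exposed but no claim of
  matching any real cohort's shape.
* **Methylation**: three site roles — clock sites linear in √age (slope
  magnitude 0.02 per √year by default, random sign), pacemaker sites
  sharing one trajectory $s(\text{age}) = 5\ln(\text{age}+1)$, and null
  sites; Gaussian noise (sd 0.01–0.02), additive tissue/sex offsets,
  clipped to [0, 1]. The truth record carries every per-site parameter
  and per-sample state, so recovery is scoreable with no hidden
  randomness.
* **Related species**: a conserved fraction of sites keeps its
  parameters; the rest get Gaussian intercept shifts — divergence of
  baseline methylation with conserved age dynamics.
* **Genotypes**: Hardy–Weinberg draws at uniform allele frequencies with
  planted homozygous runs (lengths 1.5–60 Mb, summing exactly to the
  target F_ROH per individual over a 1 Gb ten-chromosome genome),
  optional per-SNP contamination and missingness.
* **Acceleration phenotypes**: a pure age-by-inbreeding interaction with
  configurable main effects and noise whose sd grows 10% per decade of
  age by default — the heteroskedasticity that motivates the robust
  covariance step.

What it does **not** emulate: linkage disequilibrium, pedigree structure,
probe-level measurement artifacts, normalization residue, or cell-type
composition. Passing tests therefore demonstrate correctness of the
estimators under the stated models, not robustness to everything real
arrays and sequencers produce.

## Numerical choices and degenerate inputs

* Elastic-net convergence: coefficient-change < 10⁻⁷ plus full KKT check
  ≤ 10⁻⁶; constant-variance predictors are excluded with a warning and
  weight 0; non-finite input is an error.
* Lambda-path depth: the default floor of $10^{-3}\lambda_{\max}$ leaves
  visible shrinkage bias on noiseless data; exact-recovery tests deepen
  the path via the exposed `lambda_min_ratio` rather than changing the
  default.
* Pacemaker: all-zero rates (flat sites) and zero-variance states are
  explicit degeneracy errors; n = 3 is the smallest supported cohort
  (LOO refits run on n − 1 = 2).
* Trend fit: five starts over c; failure of all starts is an error
  carrying the per-start messages.
* On strongly correlated site sets (many near-duplicate age-tracking
  CpGs) coordinate descent's convergence rate approaches 1 and
  full-tolerance fits dominate runtime; the looser tolerance of the CV
  fold fits is what keeps the nested LOO evaluation tractable, and the
  final model fit is always the slow, full-tolerance one.
* Problem sizes in the test-suite and acceptance script (2000 sites,
  cohorts of 70–120, 10⁵ null sites for calibration) were chosen as the
  smallest sizes at which the recovery targets are statistically
  meaningful.

## Known limitations

* The pacemaker's state scale is gauge-fixed only through the age
  initialization; downstream consumers should rely on correlations and
  residuals, not raw state values.
* The interaction-recovery check at n = 70 sits close to the estimator's
  true finite-sample coverage; its Monte-Carlo verdict is summarized
  through the replicate spread (with a separate calibration assertion on
  the reported robust SEs) to keep it stable.
* Cross-species application assumes shared site identity; probe
  remapping between genomes is out of scope, so site ids must already be
  comparable.
* The EWAS screen is marginal and unadjusted; it inherits the usual
  caveats of correlation screening (no cell-composition or batch
  adjustment).
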