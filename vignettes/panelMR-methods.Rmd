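---
title: "Methods and design of panelMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of panelMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelMR)
```

## The two-sample summary-data model

For SNP $j$, let $\gamma_j$ (SE $\sigma_{Xj}$) be its association with
the exposure and $\Gamma_j$ (SE $\sigma_{Yj}$) its association with the
outcome, estimated in two non-overlapping GWAS samples. If the SNP is a
valid instrument — associated with the exposure, independent of
confounders, and affecting the outcome only through the exposure — then
under a linear causal model $\Gamma_j = \beta\,\gamma_j$, and each
ratio $\Gamma_j/\gamma_j$ estimates the causal effect $\beta$. A
pleiotropic SNP instead follows $\Gamma_j = \beta\gamma_j + \alpha_j$
with a direct effect $\alpha_j$ on the outcome.

All estimators consume a `HarmonizedPanel`: aligned
$(\gamma_j, \sigma_{Xj}, \Gamma_j, \sigma_{Yj})$ pairs oriented so that
every effect allele increases the exposure ($\gamma_j > 0$). The
orientation is a pure sign convention — it changes no estimator — but
makes panels comparable and scatter plots interpretable.

### Harmonization rules

Records are joined on rsid (genomic positions are never used). Outcome
alleles are aligned to the exposure's by letter: identical pairs pass,
swapped pairs flip the sign of $\Gamma_j$ and complement the outcome
frequency, and strand-complement pairs (e.g. A/G reported as T/C) are
resolved the same way. Pairs that match under none of these are
irreconcilable and dropped with a log entry.

Palindromic SNPs (A/T, C/G) are letter-ambiguous: the complement of the
pair is the pair itself. We keep them only when both datasets report an
effect-allele frequency and both are outside $[0.42, 0.58]$; the minor
allele then identifies the orientation (discordant sides of 0.5 imply a
strand flip, so $\Gamma_j$ is negated). Within the band, or with a
missing frequency, the SNP is dropped with a warning. This
frequency-based rescue is the conservative community default; the band
is a tunable argument of `harmonizePanel()`. SNPs without frequencies
are otherwise kept but excluded from explained-variance computations,
which require a MAF.

## Estimators

**IVW.** The fixed-effect inverse-variance-weighted estimate
$\hat\beta = \sum_j w_j\gamma_j\Gamma_j / \sum_j w_j\gamma_j^2$,
$w_j = \sigma_{Yj}^{-2}$, equals a weighted regression of $\Gamma$ on
$\gamma$ through the origin, and reduces to the inverse-variance-
weighted average of the per-SNP ratios. The fixed-effect standard error
$(\sum_j w_j \gamma_j^2)^{-1/2}$ is the default because the original
formulation of the method is fixed-effect; a multiplicative
random-effects inflation $\max(1, \sqrt{Q/(k-1)})$ is available behind
the `randomEffects` flag. Inference is normal; the 95% interval uses
the multiplier 1.959964 rather than 2 so that interval widths match the
normal quantile exactly.

**MR-Egger.** Weighted least squares of $\Gamma_j$ on $\gamma_j$ *with*
an intercept. Under InSIDE (pleiotropic effects independent of
instrument strength) the slope remains a consistent estimate of $\beta$
even when every instrument is invalid, and the intercept estimates the
average directional pleiotropic effect. The SE convention is not
standardized in the literature; we scale the weighted-regression
covariance by $\max(1, Q/(k-2))$ — overdispersion inflates the SE,
underdispersion never deflates it — and use $t_{k-2}$ inference, which
is conservative at small $k$. This choice affects p-values only, never
point estimates.

**Weighted median.** Ratios are sorted; normalized inverse-variance
weights $w_j$ accumulate to midpoint positions $p_j = S_j - w_j/2$; the
estimate linearly interpolates the sorted ratios at $p = 1/2$. It is
consistent while valid instruments carry more than half the total
weight. The SE comes from a parametric bootstrap (redraw
$\gamma_j, \Gamma_j$ from their estimated sampling distributions;
default `nBoot = 10000`; the seed is a mandatory argument because no
default seed could be simultaneously reproducible and honest).

**Multivariable IVW.** For correlated exposures measured on the same
SNPs (the lipid-fraction situation), $\Gamma_j$ is regressed on all
exposure betas simultaneously without intercept, weights
$\sigma_{Yj}^{-2}$; the coefficient of the exposure of interest is its
direct effect holding the others fixed. Inference is $t_{k-m}$ with the
same dispersion convention as MR-Egger. Covariate tables are aligned to
the exposure-increasing allele by harmonizing each against the exposure
table before the betas enter the design matrix.

## Instrument diagnostics

**Explained variance.**
$R^2 = \sum_i \beta_i^2\, 2\,\mathrm{MAF}_i (1-\mathrm{MAF}_i)/\mathrm{var}(X)$,
the per-SNP coefficient of determination under Hardy–Weinberg genotype
variance, with $\mathrm{var}(X) = 1$ for traits analyzed in SD units.
The per-variant F statistic cannot be computed from summary data, but
genome-wide-significant, mutually independent instruments correspond to
F > 30 per variant, so weak-instrument bias is negligible for panels
selected that way.

**Cross-trait exclusion.** SNPs appearing in another trait's instrument
list, or in LD ($r^2 > 0.8$, strictly) with one, can be excluded as
potentially pleiotropic. LD is always supplied as a precomputed table —
the package never computes LD from genotypes. A `restrictTo` argument
supports consulting only non-overlapping trait families (e.g. excluding
only non-lipid overlaps when lipid instrument sets deliberately share
SNPs and are instead handled by multivariable adjustment).

**Stepwise Q filter.** Homogeneity of the per-SNP causal estimates is
tested with Cochran's $Q = \sum_j w_j(\Gamma_j - \hat\beta\gamma_j)^2$
against $\chi^2_{k-1}$. While significant (default threshold 0.05), the
SNP with the largest individual Q contribution is removed and the IVW
model refit. Removal by largest contribution rather than by best
post-removal fit was a genuinely open choice; on small panels the two
coincide (verified against an exhaustive leave-one-out oracle in the
tests), and contribution-based removal is cheaper and deterministic.
Ties break by lexicographically smaller rsid so runs are reproducible.
The filter stops at a floor of two SNPs — a Q test needs at least two —
returning a warning flag rather than an error if the floor is hit while
still significant.

## NOME and SIMEX

Measurement error in $\hat\gamma_j$ attenuates the MR-Egger slope
towards zero (the weighted median and IVW are far less sensitive). The
$I^2_{GX}$ statistic,
$\max(0, (Q_{GX} - (k-1))/Q_{GX})$ with
$Q_{GX} = \sum_j \sigma_{Xj}^{-2}(\gamma_j - \bar\gamma)^2$, estimates
the fraction of the spread of the $\hat\gamma_j$ that is real; the
expected attenuation factor of the Egger slope is approximately
$I^2_{GX}$, so $1 - I^2_{GX}$ is the expected relative shrinkage. This
first-order equivalence is accurate in the mild-error regime (checked
empirically at $I^2_{GX} \approx 0.85$ to within $\pm 0.05$); at severe
error ($I^2_{GX} \lesssim 0.6$) it understates the attenuation.

`mrEggerSimex()` corrects the slope by simulation extrapolation: extra
noise of variance $\lambda\sigma_{Xj}^2$ is added over a grid
$\lambda \in \{0.5, 1, 1.5, 2\}$ (`nSim = 1000` replicates per level),
the mean slope is fitted as a quadratic in $\lambda$ together with the
unperturbed point, and the fit is evaluated at $\lambda = -1$ — the
standard SIMEX configuration. Two caveats are intrinsic and documented
rather than hidden:

- The quadratic extrapolant recovers only part of the exact (rational)
  attenuation curve — about three quarters of the bias at
  $I^2_{GX} = 0.7$ — and inflates the sampling variance of the
  corrected slope (extrapolation leverage). At moderate attenuation the
  variance cost can offset much of the bias gain in mean-squared-error
  terms; at severe attenuation the correction wins decisively. This is
  a property of SIMEX itself, not of the implementation.
- The SE of the corrected estimate extrapolates the per-$\lambda$
  difference between the model-based variance and the between-replicate
  variance (a jackknife-style construction), anchored at the naive
  variance at $\lambda = 0$. It is approximate and flagged
  `approximate_se`; if the extrapolated variance is non-positive the
  naive SE is reported with a `naive_se_fallback` flag.

A multiplicative $1/I^2_{GX}$ correction would be an alternative for
the mild-error regime; SIMEX is the implemented default because it also
covers the severe regime and is the method named for this purpose in
the MR literature.

## Power analysis

On standardized scales the smallest detectable causal effect at
two-sided level $\alpha$ and power $1-\beta$ is
$\beta_{det} = (z_{1-\alpha/2} + z_{pow}) / \sqrt{n\,R^2_{GX}}$ with
$n$ the *outcome* GWAS size (the ratio estimator's variance involves
only the outcome dataset), and $\beta_{det}^2$ is the detectable causal
$R^2$. `powerAtEffect()` is the exact two-sided inverse including the
opposite-tail term $\Phi(-z_{1-\alpha/2} - |\beta|\sqrt{nR^2_{GX}})$;
the round trip therefore reproduces the target power up to that term,
which is below $10^{-9}$ at $\alpha = 0.00625$ and 80% power but
reaches $4\times10^{-5}$ at $\alpha = 0.05$ and 50% power. The default
threshold $0.05/8 = 0.00625$ corresponds to eight tests over four
correlated trait blocks and is a configurable plan parameter, not a
constant.

## The synthetic generator

`simulatePanel()` emulates the two-sample design: MAFs uniform on
(0.1, 0.5); true instrument effects
$\gamma_j \sim N(0.1, 0.1)$ truncated positive — a spread of weak to
strong instruments whose strongest members explain about 1% of the
exposure each, comparable to large lipid-GWAS panels — and standard
errors $\sigma = (2n\,\mathrm{maf}(1-\mathrm{maf}))^{-1/2}$, the
standardized-trait GWAS form. Observed estimates are drawn
independently around the truth in the two samples. Pleiotropy is
`none`, `balanced` ($\alpha_j$ centred at zero) or `directional`
($\alpha_j \sim N(0.02, 0.01)$ by default, a direct effect of about a
fifth of the mediated effect), always independent of $\gamma_j$, so
InSIDE holds by construction. Default sample sizes are 50,000 per GWAS.

The generator deliberately does **not** emulate: LD between instruments
(real panels are pruned to $r^2 < 0.1$), sample overlap between the two
GWAS (a known source of bias the methods here do not model), allele
miscoding or strand errors (exercised separately through
`harmonizePanel()` fixtures), or non-linear causal effects. Passing
tests on synthetic panels therefore validate the estimators under the
model's own assumptions, not robustness to these real-data features.

Truncating $\gamma_j$ positive makes generated panels satisfy the
orientation invariant by construction; observed $\hat\gamma_j \le 0$
(vanishingly rare at default sizes) are dropped with a provenance note,
mirroring the selection of exposure-increasing genome-wide-significant
instruments. `simulateMVPanel()` mixes independent latent effects
through a loadings matrix to create correlated exposures for the
multivariable estimator; note that with near-collinear exposures
(0.9 cross-loadings give a 0.99 exposure correlation) the conditional
signal is tiny and exposure measurement error produces a genuine
partial-regression attenuation in multivariable MR — isolating the
adjustment property in tests requires a very precise exposure GWAS.

### Known finite-sample behaviour worth knowing

- The weighted median carries a finite-sample bias under one-sided
  contamination: with fraction $f < 0.5$ of the weight shifted in one
  direction, the estimate sits at the $0.5/(1-f)$ weighted quantile of
  the valid ratios, a shift of order
  $z_{0.5/(1-f)} \cdot \sigma_{ratio}$ (about 0.016 at $f = 0.3$ under
  the default conditions, versus an IVW bias of about 0.11). The
  consistency guarantee is asymptotic in the instrument precision; the
  bias is real at any finite GWAS size and shows up in sufficiently
  large replicate studies.
- Simulation problem sizes used by the test suite and the acceptance
  script (e.g. 200–1000 replicates, $k = 50$, bootstrap 100–10,000)
  were chosen to make Monte-Carlo error small relative to the effects
  being demonstrated while keeping a full run in the minutes range.

## Pipeline conventions

`runBidirectionalAnalysis()` analyzes each pair in both causal
directions, skipping (with a logged reason) any method whose minimum
instrument count exceeds the harmonized panel — with two or three
instruments only IVW is meaningful, a situation that arises routinely
in the reverse direction of biomarker studies. Filters operate on
copies; no method sees another's modified panel. Manual, judgment-based
exclusions (e.g. a variant flagged from a funnel plot for low
precision) are supported as named exclusion lists but deliberately not
automated: a precision-based outlier rule would be a new method, not a
reproduction of practice. The exit status reflects operational success
only, never the scientific outcome. Reports are one TSV row per
(exposure, outcome, method) with a `significant = p < alpha` flag, and
runs are byte-reproducible for a fixed seed because every stochastic
stage derives its own stream from the plan seed via `deriveSeed()`.
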