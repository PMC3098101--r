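---
title: "Shrinkage estimation of fold change from two count samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage estimation of fold change from two count samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascount)
```

## The problem

Sequencing-based expression assays (DGE tag profiling, RNA-seq) report, for
every gene, a count out of a library of $N \sim 10^7$ reads. When each
condition is measured by a single library, the obvious analysis — testing
equality of the two proportions gene by gene — answers the wrong question:
it detects any difference between the two *samples*, however small, and its
power grows with expression level, so the top of the list fills with highly
expressed genes showing trivial fold changes. Meanwhile the biological
variation that would be visible between replicates is not accounted for at
all.

`ascount` treats the gene-wise log fold change as a random effect whose
spread across genes *is* the biological variation, estimated by pooling
information across the whole transcriptome. Every gene then gets an
empirical-Bayes shrinkage estimate of its log fold change and a posterior
probability that the change exceeds a user-chosen effect size. Genes with
sparse counts — where large apparent ratios arise easily by chance — are
shrunk aggressively; deeply covered genes keep essentially their observed
ratio.

## The model

For counts $x_1, x_2$ with library sizes $N_1, N_2$:

$$x_i \mid \pi_i \sim \mathrm{Binomial}(N_i, \pi_i), \qquad
\log_{10} \pi_1 = \lambda + \delta/2, \quad
\log_{10} \pi_2 = \lambda - \delta/2,$$

with priors

$$\delta \mid \lambda \sim N(0, \tau^2), \qquad
\lambda \sim \mathrm{Exp}(\alpha, \lambda_0)\ \text{(shifted exponential)}.$$

$\delta$ is the log10 fold change (the inferential target), $\lambda$ the
log10 average proportion (a nuisance). The posterior

$$p(\delta \mid x) \propto \int p(x \mid \lambda, \delta)\,
p(\delta \mid \lambda)\, p(\lambda)\, d\lambda$$

has no closed form; the package integrates it numerically per gene and
reports the posterior mean $\tilde\delta = E[\delta \mid x]$ (the shrinkage
estimate) and $P(|\delta| > \Delta_0 \mid x)$ for a threshold $\Delta_0$
(default $\log_{10} 2$). Selection at a posterior-probability cutoff (default
0.9) comes with a direct-posterior FDR: the mean of $1 - P$ over the selected
genes.

All logs are base 10. That choice makes the two empirical anchors of the
model consistent: a biological SD of $\tau = 0.122$ in log10 units equals
$0.122 \ln 10 = 0.28$ on the natural-log scale, and `convert_log_base()`
moves between the two exactly.

Two deliberate simplifications, both load-bearing:

* **The exponential shift $\lambda_0$ is never estimated.** By
  memorylessness, shifted exponentials with the same rate have proportional
  densities, so only the decay $e^{-\alpha\lambda}$ enters the posterior.
* **$\tau$ is one global constant.** The spread of observed log-ratio
  differences among high-count genes is flat across expression levels, so
  no $\tau(\lambda)$ model is fitted.

## Hyperparameter estimation

`estimate_hyperparams()` runs both estimators on the count table:

* **$\alpha$** by quantile matching on the per-gene average log10 rpm: with
  empirical quantiles $\ell_i = \hat F^{-1}(q_i)$,
  $\hat\alpha = -[\log(1-q_1) - \log(1-q_2)]/(\ell_1 - \ell_2)$, defaults
  $q_1 = 0.8$, $q_2 = 0.9$. A method-of-moments alternative
  (`estimate_alpha_moment()`) uses the mean exceedance above a quantile.
  The posterior is insensitive to this choice; the package's acceptance
  suite measures the maximum effect of switching to $(0.9, 0.95)$ on
  $\tilde\delta$ and finds it orders of magnitude below the 0.04 bound.
* **$\tau$** from genes with total counts above 1000 (`min_total`), where
  binomial noise in $\log_{10} p_1 - \log_{10} p_2$ is negligible:
  $\hat\tau = \mathrm{IQR}[\log_{10} p_1 - \log_{10} p_2] / 1.34898$. The
  IQR (not the SD) keeps genuinely differentially expressed outliers from
  inflating the estimate; replacing 1% of qualifying genes by extreme
  ratios moves $\hat\tau$ by under 5%. At least 20 qualifying genes are
  required (a guardrail; thousands are typical at real depths).

Quantiles are always the continuous type-7 sample quantile (linear
interpolation between order statistics); with thousands of genes any
continuous definition differs negligibly.

## Numerical integration

The joint density over $(\lambda, \delta)$ is evaluated on a per-gene
rectangular grid in log space with exact binomial log-pmfs (via log-gamma;
no Gaussian approximation, no special treatment of zero counts) and
normalized by log-sum-exp. Design choices that matter:

* **Per-gene adaptive geometry.** The posterior width in $\lambda$ scales
  as $1/(\ln 10 \sqrt{x_1 + x_2})$ — three orders of magnitude across a
  real table. Fixed spacing either aliases the narrow high-count posteriors
  (a step larger than the posterior SD samples the integrand incoherently)
  or wastes huge grids on low-count genes. Spacings are therefore set in
  *points per posterior SD* (defaults: 10 for $\delta$, 4 for $\lambda$;
  midpoint-rule aliasing error decays like $e^{-2\pi^2(\sigma/h)^2}$, so
  four points per SD already gives ~1e-15 relative accuracy).
* **Centering.** The $\delta$ grid is centered on the Gaussian-approximation
  posterior mode $c = \mathrm{alr}\cdot\tau^2/(\tau^2 + \mathrm{se}^2)$ with
  halfwidth $\max(12\,\mathrm{sd}, |\mathrm{alr}| + 6\,\mathrm{se} - |c|)$,
  so the grid always also covers the unshrunk ratio. The $\lambda$ grid is
  anchored at the per-gene ML value (mean of the floored per-sample log
  proportions), halfwidth capped at 3 log10 units.
* **Safety nets.** If more than $10^{-4}$ of posterior mass lands in the
  outermost two cells of either marginal, the affected halfwidth doubles
  once; a second hit is an error, never a silent truncation. A hard floor
  $\lambda \ge \log_{10}(0.25/(N_1+N_2))$ (a quarter-read proportion) keeps
  the integral proper for tiny totals, where the exponential prior can
  otherwise grow faster than the likelihood decays.
* **Tail probabilities.** $P(|\delta| > \Delta_0)$ treats the straddling
  grid cell as a linear density (slope from neighbouring cells) and applies
  the midpoint-rule boundary correction $-(h^2/24) f'$; both matter for the
  $10^{-4}$ agreement with a brute-force fine-grid oracle that the test
  suite demands across counts from 0 to $10^5$. $\Delta_0 = 0$ returns 1
  exactly (continuous density).
* **Degenerate genes.** $x_1 = x_2 = 0$ carries no fold-change information;
  such genes are flagged `"no-signal"` with $\tilde\delta = 0$, $P = 0$
  rather than integrated (the posterior would just reproduce the prior up
  to the floor artifact).

The run is deterministic: no randomness anywhere in estimation or
integration.

## Synthetic data

Two generators support method evaluation, both seeded and byte-reproducible:

* `simulate_fig1b()` — the constant-variation design: given base log10
  proportions, draw $\delta \sim N(0, \sigma^2)$, split it
  symmetrically, and add Poisson (default) or binomial counting noise.
  Its purpose is the classic demonstration that the inflated spread of
  log-rpm differences at low counts is counting noise, not extra biological
  variation (`binned_sd_log_rpm()` makes the figure-ready table), and
  parameter recovery: the IQR estimator returns $\sigma$ to within a few
  percent from high-count genes.
* `simulate_generative()` — the full hierarchical model used generatively:
  $\lambda \sim \lambda_{\min} + \mathrm{Exp}(\alpha)$, Gaussian $\delta$
  with SD $\sigma$, an optional differentially expressed subset with an
  extra fixed effect of random sign, and binomial (default) or Poisson
  counts.

Defaults describe a deep DGE-style experiment: libraries of 12,525,833 and
13,431,745 tags, 20,000 genes, $\sigma = 0.122$, 5% of genes carrying an
extra two-fold effect. Where the underlying expression profile is not
dictated by those anchors, the package fixes it once at
$\alpha = 2.8$ per log10 unit with $\lambda_{\min} = -6.5$: that yields a
median of roughly 5–10 counts per gene, a long right tail reaching tens of
thousands of counts, and around 60 genes above 1000 total counts — the
shape of a deep tag-profiling experiment. Counts are drawn independently
per gene (no multinomial coupling; proportions are far below 1, so the
dependence is negligible and matches the per-gene binomial model).

What the generators do *not* emulate: tag-mapping ambiguity, sequencing
error, transcript-length or GC bias, and library-preparation effects.
Passing recovery tests on these simulations therefore validates the
statistical machinery under the model's own assumptions, not robustness to
those artifacts.

## Problem sizes and test design

The test suite checks the integrator against an independent brute-force
oracle (a naive fine-grid rectangle rule written before the integrator, step
$10^{-3}$) on a 50-case panel spanning counts 0 to $10^5$, demanding
agreement to $10^{-4}$ on both $\tilde\delta$ and the exceedance
probability. Study-scale checks run on 20,000-gene tables at the real
library depths: recovery of $\sigma = 0.122$ to $\pm 0.01$, the
quantile-choice sensitivity bound, an exhaustive shrinkage sweep over all
count pairs $1 \le x_2 < x_1 \le 200$, and a full analysis timed end to
end. These sizes keep the default suite comfortably within a desktop run
while exercising every code path at realistic depth.

## Known limitations

* Two samples only; no replicate-aware dispersion estimation and no
  multi-condition designs.
* The model produces $\tilde\delta$ and posterior probabilities, not
  p-values; the Z-test and Fisher machinery exist for comparison, not as
  the method's inference.
* $\tau$ is global; expression-dependent biological variation would be
  absorbed into, not resolved by, the estimate.
* The selection FDR is the direct-posterior estimate (mean posterior
  probability of non-exceedance among selected genes); it is exact only as
  far as the hierarchical model itself holds.
* Comparisons with software that parameterizes the same model on the
  natural-log scale differ by the exact factor $\ln 10$ in $\alpha$ and
  $\tau$; `convert_log_base()` performs the conversion.
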