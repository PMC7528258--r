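---
title: "Compatibility and surprisal: the model behind the package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compatibility and surprisal: the model behind the package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisal)
```

## The model

Everything in this package rests on one approximation: the reported
estimator, on a suitable *analysis scale*, is normally distributed around
the true parameter with a known standard error (the Wald model). For
ratio measures — hazard, odds, rate, and risk ratios — the analysis scale
is the natural log; for differences it is the identity. Given a reported
point estimate $\hat\theta$ and level-$L$ limits $(\ell, u)$, the standard
error is recovered by inverting the Wald interval,

$$\widehat{SE} = \frac{T(u) - T(\ell)}{2\,\Phi^{-1}\!\big(\tfrac{1+L}{2}\big)},$$

with $T$ the scale transform. For any hypothesized value $\theta_0$ the
Wald statistic is $z = (T(\theta_0) - T(\hat\theta))/\widehat{SE}$ and the
two-sided P-value is $p = 2(1 - \Phi(|z|))$.

The P-value is read *descriptively*, as the compatibility between the
test hypothesis and the data given every background assumption of the
model — not as an error rate attached to a decision, and not as the
probability of the hypothesis. Three further translations make its
information content legible:

* the **S-value** $s = -\log_2 p$, in bits: the number of consecutive
  heads in fair coin tosses carrying the same information against the
  hypothesis. The scale repairs a known cognitive distortion of the
  P-value scale: $p = 0.9999$ vs $0.90$ differ by a trivial fraction of a
  bit, while $p = 0.10$ vs $0.0001$ differ by ten full bits;
* the **maximum-likelihood ratio** $\exp(z^2/2)$, the factor by which the
  best-supported parameter value beats the hypothesis in likelihood;
* the **deviance statistic** $2\ln(\mathrm{MLR}) = z^2$.

A happy numerical accident worth knowing: rounded to the nearest integer,
$s$ in bits and $z^2$ coincide for $p$ between 0.005 and 0.10, exactly the
contested region of most applied work.

## Interval estimates as level sets

The level-$L$ *compatibility interval* is the set of hypothesis values
with $p > 1 - L$ — the conventional confidence interval, renamed for what
it actually displays about one dataset. The package's defaults show the
proportionally spaced trio 75/95/99% ($p > 0.25, 0.05, 0.01$), which
discourages treating any single interval as a verdict. *Likelihood
intervals* are level sets of the relative likelihood $\exp(-z^2/2)$;
under the Wald model the cutoff $1/\mathrm{MLR}(1-L)$ reproduces the
level-$L$ compatibility interval exactly, e.g. $1/6.83$ for 95%.

Interval endpoints are always computed from the closed forms
$T^{-1}(T(\hat\theta) \pm q\,\widehat{SE})$, never read off the plotted
grid: the curve is for the eye, the formula for the numbers, so grid
resolution can never leak into a reported endpoint. The hypothesis grid
itself (default: 400 points spanning the 99.9% interval, uniform on the
analysis scale) is built symmetrically around the point estimate, which
is always itself a grid point, so the displayed peak is exactly $p = 1$.

## Numerical choices

* Normal quantiles are exact (`qnorm`), never the rounded 1.96.
* Tail probabilities are computed in log space
  (`pnorm(..., log.p = TRUE)`), so the S-value of an extreme hypothesis
  is exact even where the linear-scale P-value would underflow; the
  linear P-value is clamped to the smallest positive double rather than
  ever reported as 0.
* S-values above 10 bits are *displayed* rounded to the nearest integer
  (two decimals below that); stored values keep full precision. Exported
  CSVs carry 17 significant digits, which round-trips a double exactly.
* If a user supplies both interval limits and a standard error and the
  two disagree by more than 1% relative, construction fails loudly;
  silently preferring one source would hide exactly the kind of
  inconsistency the toolkit exists to surface.
* The scale of analysis is a mandatory argument. Automatic detection
  ("looks like a ratio") was considered and rejected: a silent wrong
  guess inverts the meaning of every downstream number.

## The worked example and printed precision

The package's canonical fixture is a reported hazard ratio of 1.61 with
95% limits (0.997, 2.59). Those three printed numbers are themselves
rounded, and they are not perfectly Wald-consistent: 1.61 is not quite
the geometric mean of the limits, so reconstructing the limits from the
back-calculated standard error gives (0.9989, 2.595) — agreement to about
0.2%, which is precisely the slack the inputs' own three-significant-
figure rounding propagates. The test suite therefore compares
reconstructed limits at that tolerance, while quantities the fixture
defines exactly (endpoint P-values, the likelihood/compatibility duality)
are checked at machine or three-significant-figure precision. One row of
the reanalysis panel illustrates the same point from the other side: the
derived P-value at a tripled hazard is 0.0106, printed upstream as 0.01.

## Combining evidence and validity checking

Natural-log surprisals $-\ln p_k$ of $K$ independent, same-convention
P-values for a shared hypothesis are summed and doubled, and
$2\sum_k(-\ln p_k)$ is referred to $\chi^2_{2K}$ (Fisher's method). Under
the shared hypothesis each $-\ln p_k$ has expectation 1 (1/ln 2 ≈ 1.44
bits), so the undoubled sum has expectation $K$ — the reason combination
is forced to nats; bit-valued inputs are converted, never mixed. With
$K = 1$ the referral returns the input P-value identically. The
combination is one-directional in evidence and has no two-sided variant.
Callers must declare whether their inputs are one- or two-sided
(`sided=`); the declaration is carried into reports because the two
conventions cannot be distinguished from the numbers. Quantities that are
not valid P-values in the uniformity sense (e.g. posterior predictive
P-values) are excluded by documentation, not detection — no test on the
values themselves can identify them.

A P-value is *valid* when it is uniform on (0,1) under the test
hypothesis and all background assumptions. `check_uniformity()` makes
that operational with a Kolmogorov–Smirnov comparison of an empirical
P-value sample against uniform(0,1).

## What the simulator emulates — and what it does not

`simulate_studies()` draws analysis-scale estimates from
$N(\theta_{\mathrm{true}}, SE^2)$ and wraps them as effect estimates:
the regime in which *every* background assumption of the Wald machinery
holds exactly. Its defaults in the tests mirror the worked example
(true log hazard ratio $\ln 1.61$, per-study SE 0.2435, the value the
fixture's limits imply). Under this generator, P-values tested at the
true effect are uniform, level-$L$ intervals cover at rate $L$, and the
combined test holds its type-I error — and the test suite verifies all
three. What passing those tests does *not* show is robustness to
anything real data add: bias and confounding, heterogeneity across
studies, non-normal sampling distributions, selection effects, or
rounding of inputs. The simulator validates the arithmetic of the
toolkit, not the background assumptions of any application.

Simulation sizes were chosen to pin each Monte-Carlo standard error well
below the quantity being checked: $10^5$ study sets for the combined
test's type-I error (MC SE ≈ 0.0007 at $\alpha = 0.05$), $10^4$ estimates
for interval coverage (MC SE ≈ 0.002), with agreement asserted within
three Monte-Carlo standard errors throughout. Each simulated set carries
one explicit integer seed and restores the global RNG state, so results
are bit-for-bit reproducible and order-independent.

## Known limitations

* Everything is a normal approximation on one scale; small samples,
  boundary parameters, and exact methods are out of scope, as is fitting
  models to raw data.
* MLR and deviance are defined only for simple one-parameter hypotheses
  via the two-sided inversion; panels built from one-sided P-values
  refuse to emit them rather than emit a wrong convention.
* Multi-degree-of-freedom fit statistics, meta-analytic pooling of
  effect sizes, multiplicity adjustment, and Bayesian translations are
  deliberately absent.
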