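---
title: "Interval estimation for the common percentile of delta-lognormal populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation for the common percentile of delta-lognormal populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlnpctile)
```

## The model

Environmental series such as daily rainfall mix exact zeros (dry stations)
with strictly positive, strongly right-skewed amounts. The delta-lognormal
model treats an observation as zero with probability $\delta'$ and as
lognormal otherwise: for $X \sim \mathrm{DLN}(\mu, \sigma^2, \delta')$,
$\Pr(X = 0) = \delta'$ and $\log X \mid X > 0 \sim N(\mu, \sigma^2)$.

For a level $p > \delta'$ the $p$-th quantile of this mixture is the
$\eta$-th quantile of the positive part, with
$\eta = (p - \delta')/(1 - \delta')$, so on the log scale

$$\lambda_p = \mu + \Phi^{-1}(\eta)\,\sigma, \qquad q_p = e^{\lambda_p}.$$

For $p \le \delta'$ the quantile is exactly zero and no log-scale
percentile exists; every function in this package refuses that case
explicitly rather than returning a degenerate answer.

With $k$ independent groups sharing a percentile of interest, the *common
percentile* is defined through a precision-weighted average of the
per-group log-scale percentile estimates,
$\hat\lambda_p = \sum_i \hat\lambda_{p_i}/v_i \big/ \sum_i 1/v_i$, with
$v_i = \widehat{\mathrm{Var}}(\hat\lambda_{p_i})$, and
$\hat\theta = e^{\hat\lambda_p}$. The variance $v_i$ combines two
components evaluated on the back-transformed scale (`var_ybar1()`,
`var_s2_1()`); see below for the one structural ambiguity in how they are
combined.

Per group, the plug-in pieces are the log-scale mean `ybar1` and unbiased
variance `s2_1` of the positive observations ($n_1 - 1$ divisor) and the
zero-probability estimate $\hat\delta' = n_0/n$, the MLE under the
binomial component. Zeros are exact zeros; small positive values are never
thresholded, because the model's mass at zero is a point mass.

## The four interval constructions

All four methods consume the same group summaries (`summarize_groups()`)
and return a `dln_ci` with limits on both the log and the original scale.

**FGCI** (`ci_fgci()`). A fiducial generalized pivotal quantity is built
per group and per Monte Carlo iteration: a chi-square pivot for
$\sigma^2$, the classical generalized pivot for $\mu$, and a
truncated-Beta$(n_0 + \tfrac12,\, n_1 + \tfrac12)$ fiducial draw for
$\delta'$, bounded above by $p$ so the induced $\eta$ stays in $(0,1)$.
These combine into a percentile pivot per group; the per-iteration draws
are precision-weighted across groups and the interval is the pair of
equal-tailed empirical quantiles (type 7) of the $m$ combined draws,
exponentiated at the end.

**Adjusted MOVER** (`ci_mover()`). The only closed-form method. Each
group gets symmetric limits about `ybar1` from a noncentral-$t$ quantile
with noncentrality $\Phi^{-1}(\hat\eta)\sqrt{n_1}$; from each half-width a
variance is "recovered" by dividing by $z_{\alpha/2}^2$. The common
estimate uses the average recovered variance per group, and the margins
recombine the per-group half-widths with weights built from powers of the
one-sided recovered variances.

**Bayesian, fiducial quantity (BS1)** (`ci_bayes(variant = "bs1")`).
Conjugate posteriors $\sigma^2 \mid y \sim
\mathrm{InvGamma}\!\big(\tfrac{n_1-1}{2}, \tfrac{(n_1-1)s^2_1}{2}\big)$ and
$\mu \mid \sigma^2, y \sim N(\bar y_1, \sigma^2/n_1)$ feed the same
percentile-pivot form as the FGCI (truncated-beta zero probability,
normal/chi-square perturbation). The interval is the exponential of the
shortest highest-posterior-density window of the combined draws.

**Bayesian, approximate fiducial distribution (BS2)**
(`ci_bayes(variant = "bs2")`). The same posterior draws are shifted by a
fixed noncentral-$t$ quantile at level $1-\alpha$ (the plug-in
$\hat\eta$ sets the noncentrality; the quantile is a data constant, so
randomness enters only through $(\mu, \sigma^2)$). This construction is
deliberately conservative in location, and in the coverage study its
coverage collapses as $n$ grows — the draw centre is biased upward by the
$t$ quantile while the spread shrinks — which is the qualitative behaviour
reported for it in the literature this package follows.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `p` | percentile level | 0.95 | the conventional upper-tail level for heavy-rainfall summaries |
| `alpha` | 1 − confidence | 0.05 | 95% intervals throughout |
| `m` | inner Monte Carlo draws | 1000 | the draw count used in the analysis this package reproduces; the empirical-quantile error is $O(1/\sqrt m)$ |
| `variance_form` | combination of the two variance components | `"additive"` | see below |
| `alpha_mode` (MOVER) | level of the noncentral-$t$ quantile | `"one-sided"` ($1-\alpha$) | verbatim source form; `"two-sided"` ($1-\alpha/2$) is the conventional two-sided reading |
| `margin_power` (MOVER) | power of the recovered variances in the margins | 2 | verbatim source form; 1 is the Zou-style reading |

## Structural ambiguities and how they were resolved

The source material for these methods prints a few formulas in more than
one form; the package exposes each as a documented switch, with the
default chosen by consistency arguments and by checking which reading
reproduces the large-sample behaviour of the accompanying simulation
study.

**Variance combination.** One printed form multiplies the whole variance
by $\hat\lambda^2$ (`"factored"`); the other multiplies only the
$\mathrm{Var}(\bar Y)$ term (`"additive"`). The additive form is the
default because the fiducial and both Bayesian constructions print it
consistently, making the factored parenthesisation the likely typo.

**Chi-square normalisation in the percentile pivot.** The one-sample
pivot defines its denominator as $\sqrt{\chi^2_{n_1-1}/(n_1-1)}$, while
the multi-group equations write $\sqrt{U}$ with $U$ a chi-square. Taken
literally, the raw $\sqrt U$ shrinks the $\Phi^{-1}(\eta)$ term by a
factor of about $\sqrt{n_1 - 1}$ and destroys the pivot's centering (its
observed value would no longer be the parameter, violating the defining
property of a fiducial pivot). The package therefore normalises the
trailing chi-square by its degrees of freedom in the percentile pivot,
while the mean pivot keeps the raw chi-square (which is exactly the
classical generalized pivot for a normal mean). This reading reproduces
the reference simulation's average lengths closely (e.g. 6.71 vs 6.55 for
the FGCI and 6.26 vs 6.22 for BS1 at $k = 3$, $n = 30$, homogeneous
groups).

**Draw independence.** The same $Z$ and chi-square symbols appear in the
mean pivot and the percentile pivot. Sharing them partially cancels the
mean-pivot noise and demonstrably under-disperses the draws relative to
the reference simulation; the package draws each role independently.

**MOVER margins.** The printed margins weight the squared half-widths by
*squared* recovered variances; the MOVER literature otherwise uses first
powers. Both are implemented (`margin_power`); neither — under either
`alpha_mode`, from the raw data or from the published summary statistics —
reproduces the reference empirical interval for the rainfall data exactly,
so the verbatim printed form remains the default and the acceptance test
documents every setting's result. The reference analysis also reports the
MOVER's average simulated length *growing* with $n$, which cannot occur
for any margin built from the recovered half-widths (the upper half-width
tends to zero); this corner of the reference results is treated as not
reproducible.

## The data and two documented inconsistencies

`rainfall_fixture()` ships the five-region Thai daily rainfall series
(1 September 2021, Thai Meteorological Department) exactly as tabulated:
29, 28, 22, 15 and 29 observations. For the Southern region the tabulated
series (6 zeros, 23 positives) is inconsistent with the summary
statistics published alongside the original analysis of these data
(13 zeros, 16 positives, log-mean 2.07, log-variance 3.66); the other
four regions agree to every printed digit. No subset of the tabulated
Southern positives reproduces the published moments, so the conflict is
not recoverable. `rainfall_statistics()` exposes the published statistics
so the interval methods can be driven from either source.

Separately, the published AIC table for the candidate fits matches this
package's normal, lognormal and gamma fits to four decimals (for the four
consistent regions) but sits exactly 1.0 below the standard
$2k - 2\ell$ value for the exponential fit in every region — a
one-parameter penalty slip in the source. The package uses the standard
definition.

## The simulation harness

`run_coverage_study()` implements the evaluation loop: generate $k$
delta-lognormal samples, summarize, construct each selected interval,
record containment of the true common percentile and the interval length.
The true value is `true_common_percentile()`: the per-group
$\lambda_{p_i}$ at the true parameters, combined with the same precision
weights the estimators use (with $n_1$ replaced by its expectation
$n(1-\delta')$, since the positive count is random). For homogeneous
configurations the weights are immaterial.

Replications in which any group draws fewer than two positives, or an
estimated zero probability at or above $p$, are regenerated with a retry
bound; the number of regenerations is reported. Each replication runs on
its own seed derived from the master seed, so per-method results are
comparable across method subsets.

The reference study uses $M = 5000$ outer replications with $m = 1000$
inner draws. The package's tests and the acceptance script run a
desk-scale version, $M = 1000$ and $m = 500$, for which the binomial
Monte Carlo error on a coverage probability near 0.95 is about
$\pm 0.007$ (one SE); comparisons are made at $\pm 0.02 \approx 3$ SE.
The acceptance band for nominal coverage is `nominal_band()`:
$c \pm z_{\alpha/2}\sqrt{c(1-c)/M}$.

### What the generator does and does not emulate

`rdln()` draws i.i.d. delta-lognormal observations — a point mass at zero
plus a lognormal. Real rainfall data exhibit spatial and temporal
correlation between stations, detection limits (traces recorded as zero),
and seasonal nonstationarity, none of which the generator models. Passing
the coverage study therefore validates the interval constructions under
the model's own assumptions, not their robustness to violations of
independence or to censored zeros.

## Numerical choices

* The truncated-beta inverse-CDF draw is computed in log space:
  `pbeta(p, n0 + 0.5, n1 + 0.5)` underflows to 1 when $p$ is deep in the
  beta's upper tail, which would break the $v = 1 \mapsto p$ endpoint.
* All interval arithmetic happens on the log scale; exponentiation is the
  final step, avoiding overflow for large $\sigma^2$.
* Empirical quantiles use the type-7 (linear interpolation) convention,
  the default of mainstream numerical environments; differences between
  conventions are $O(1/m)$.
* The empirical HPD estimator slides a window of
  $\lceil (1-\alpha) m\rceil$ consecutive order statistics and takes the
  first narrowest window (deterministic tie-break).
* The gamma MLE is delegated to `fitdistrplus::fitdist()`
  (moment-started numeric maximisation); all other fits are closed form.

## Known limitations

* Only the model's printed variance expressions are offered; no bootstrap
  or delta-method alternatives.
* No censoring/detection-limit handling, and no station metadata.
* Single common-percentile intervals only — no simultaneous or
  multiple-comparison adjustment across several levels $p$.
* The reference empirical intervals for the MOVER and BS2 methods on the
  rainfall data could not be reproduced under any documented reading (see
  the acceptance tests for the per-setting record). The BS1 interval
  length reproduces the reference value within Monte Carlo variation, and
  the FGCI comes within a few percent of it; both reproduce the reference
  simulation's coverage and average lengths closely.

## A worked example

```{r example}
s <- summarize_groups(rainfall_fixture())
s

ci_mover(s)

set.seed(1)
ci_fgci(s, m = 1000)

set.seed(1)
ci_bayes(s, "bs1", m = 1000)
```

```{r sim, eval = FALSE}
# Desk-scale coverage study (about a minute)
cfg <- dln_sim_config(n = c(10, 10, 10), mu = 1, sigma2 = 0.5,
                      delta_prime = 0.1, M = 1000, m = 500, seed = 1)
run_coverage_study(cfg)
```
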